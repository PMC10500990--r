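test_that("diabatic potential reproduces its defining terms", {
  # Franck-Condon point: constants only
  H <- random_lvc(3, 4, seed = 2)
  expect_equal(diabatic_potential(H, rep(0, 4)), electronic_matrix(H))

  # one state, one mode: V = E + w q^2 / 2 + lambda q
  H1 <- lvc_hamiltonian(mode_basis(1), list(diabatic_state("s", "LE", 2, 1)))
  expect_equal(drop(diabatic_potential(H1, 1)), 3.5)

  # term-by-term brute-force oracle on a random instance
  set.seed(7)
  for (rep in 1:5) {
    q <- rnorm(4)
    V <- diabatic_potential(H, q)
    w <- H$modes$frequencies
    harm <- sum(0.5 * w * q^2)
    ns <- 3
    Vref <- matrix(0, ns, ns)
    for (i in seq_len(ns))
      Vref[i, i] <- H$states[[i]]$energy0 + harm + sum(H$states[[i]]$gradient * q)
    for (cp in H$couplings) {
      Vref[cp$i, cp$j] <- Vref[cp$j, cp$i] <-
        cp$constant + sum(if (is.null(cp$linear)) 0 else cp$linear * q)
    }
    expect_equal(unname(V), Vref, tolerance = 1e-12)
  }
  expect_error(diabatic_potential(H, rep(0, 3)), "modes")
})

test_that("V(q) is exactly symmetric for random draws", {
  worst <- 0
  for (s in 1:40) {
    H <- random_lvc(sample(2:5, 1), sample(1:6, 1), seed = s)
    for (r in 1:25) {
      q <- rnorm(H$modes$n)
      V <- diabatic_potential(H, q)
      worst <- max(worst, max(abs(V - t(V))))
    }
  }
  expect_identical(worst, 0)
})

test_that("adiabatic analysis matches closed-form exciton splitting", {
  # degenerate pair, J = 0.05, parallel dipoles: dark lower / bright upper
  H <- two_level(2, 2, 0.05, mu1 = c(1, 0, 0), mu2 = c(1, 0, 0))
  ad <- adiabatic_states(H)
  expect_equal(ad$energies, c(1.95, 2.05))
  expect_equal(sum(ad$dipoles[, 1]^2), 0, tolerance = 1e-24)
  expect_equal(sum(ad$dipoles[, 2]^2), 2, tolerance = 1e-12)
  expect_equal(ad$f[1], 0)
  expect_equal(ad$f[2], (2 / 3) * (2.05 / hartree_ev) * 2, tolerance = 1e-12)

  # uncoupled pure CT state is dark
  Hct <- lvc_hamiltonian(mode_basis(),
                         list(diabatic_state("le", "LE", 2, dipole = c(1, 0, 0)),
                              diabatic_state("ct", "CT", 2.3)))
  adct <- adiabatic_states(Hct)
  expect_equal(adct$f[adct$composition[, "CT"] > 99], 0)
  expect_equal(unname(adct$composition[2, "CT"]), 100)
})

test_that("eigen-decomposition satisfies defining identities on a random 8-state model", {
  H <- random_lvc(8, 3, seed = 11)
  q <- rnorm(3)
  V <- diabatic_potential(H, q)
  ad <- adiabatic_states(H, q)
  # residuals, orthonormality, trace and Frobenius identities: an
  # oracle independent of any particular diagonalization routine
  for (k in 1:8) {
    expect_lt(max(abs(V %*% ad$vectors[, k] - ad$energies[k] * ad$vectors[, k])),
              1e-10)
  }
  expect_lt(max(abs(crossprod(ad$vectors) - diag(8))), 1e-12)
  expect_equal(sum(ad$energies), sum(diag(V)), tolerance = 1e-12)
  expect_equal(sum(ad$energies^2), sum(V^2), tolerance = 1e-12)
  expect_false(is.unsorted(ad$energies))
})

test_that("eigenvalues and oscillator-strength sum are invariant under diabatic rotations", {
  H <- random_lvc(4, 3, seed = 5)
  q <- c(0.3, -0.2, 0.5)
  ad <- adiabatic_states(H, q)
  for (s in 1:5) {
    R <- random_orthogonal(4, seed = s)
    adr <- adiabatic_states(rotate_diabatic_basis(H, R), q)
    expect_lt(max(abs(ad$energies - adr$energies)), 1e-10)
    expect_lt(abs(sum(ad$f) - sum(adr$f)), 1e-10)
  }
})

test_that("diabatic minima follow the closed form and a numerical optimizer", {
  H <- make_displaced_monomer(2, omega = 0.1, S = 0.5)  # lambda = 0.1
  dm <- diabatic_minimum(H, 1)
  expect_equal(dm$q_min, -1)
  expect_equal(dm$e_reorg, 0.05)
  expect_equal(dm$e_min, 1.95)

  H0 <- make_displaced_monomer(2, omega = 0.1, S = 0)
  expect_equal(diabatic_minimum(H0, 1)$q_min, 0)
  expect_equal(diabatic_minimum(H0, 1)$e_min, 2)

  # multi-mode random case vs numerical minimization of V_ii(q)
  Hr <- random_lvc(2, 5, seed = 3)
  dm2 <- diabatic_minimum(Hr, 2)
  opt <- optim(rep(0, 5), function(q) diabatic_potential(Hr, q)[2, 2],
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(dm2$e_min, opt$value, tolerance = 1e-9)
  expect_lt(max(abs(dm2$q_min - opt$par)), 1e-5)
  expect_error(diabatic_minimum(Hr, 7), "state")
})

test_that("coupling classes toggle independently", {
  H <- make_kasha_ct_dimer(2, 0.05, 0.3, 0.04, t_ctct = 0.02, S = 0.2,
                           omega = 0.15, jt = 0.03)
  chars <- vapply(H$states, `[[`, character(1), "character")
  cls <- vapply(H$couplings, vibronic:::coupling_class, character(1), chars)
  expect_setequal(unique(cls), c("JT", "LE-LE", "LE-CT", "CT-CT"))

  none <- toggle_couplings(H, character(0))
  expect_length(none$couplings, 0)

  all_ <- toggle_couplings(H, c("LE-LE", "LE-CT", "CT-CT", "JT"))
  expect_length(all_$couplings, length(H$couplings))

  lele <- toggle_couplings(H, "LE-LE")
  kept <- vapply(lele$couplings, vibronic:::coupling_class, character(1), chars)
  expect_true(all(kept == "LE-LE"))
  # intra-state terms untouched
  expect_equal(lele$states, H$states)
  expect_error(toggle_couplings(H, "LE-XX"), "unknown coupling class")
})

test_that("dimer assembly pads gradients block-wise and wires CT/JT terms", {
  modes <- mode_basis(c(0.1, 0.15, 0.2))
  g <- c(0.02, 0.03, 0.04); gp <- c(0.01, 0.02, 0.03)
  jt <- c(0, 0.05, 0)
  gc <- c(0.01, 0.01, 0.01); ga <- c(0.02, 0.02, 0.02); gap <- c(0.03, 0.03, 0.03)
  fr <- fragment_data(modes, 2.0, 2.05, g, gp, jt, gc, ga, gap,
                      c(1, 0, 0), c(0, 1, 0), 2.4, 2.45)
  J <- matrix(0, 8, 8); J[1, 3] <- J[3, 1] <- 0.05
  H <- assemble_dimer_hamiltonian(fr, fr, J)
  expect_equal(H$modes$n, 6)
  expect_length(H$states, 8)
  expect_equal(vapply(H$states, `[[`, character(1), "character"),
               c(rep("LE", 4), rep("CT", 4)))
  z <- rep(0, 3)
  expect_equal(H$states[[1]]$gradient, c(g, z))    # g1 = {g, 0}
  expect_equal(H$states[[3]]$gradient, c(z, g))    # g2 = {0, g}
  expect_equal(H$states[[5]]$gradient, c(gc, ga))  # CT(1->2) = {g+, g-}
  expect_equal(H$states[[6]]$gradient, c(gc, gap)) # CT'(1->2) = {g+, g-'}
  expect_equal(H$states[[7]]$gradient, c(ga, gc))  # CT(2->1) = {g-, g+}
  # CT states dark
  for (s in 5:8) expect_equal(H$states[[s]]$dipole, c(0, 0, 0))
  # JT pairs: zero constant, block-padded linear vector
  jt1 <- Filter(function(cp) cp$i == 1 && cp$j == 2, H$couplings)[[1]]
  expect_equal(jt1$constant, 0)
  expect_equal(jt1$linear, c(jt, z))
  jt2 <- Filter(function(cp) cp$i == 3 && cp$j == 4, H$couplings)[[1]]
  expect_equal(jt2$linear, c(z, jt))

  # all ionic gradients zero -> every CT state has zero reorganization
  fr0 <- fragment_data(modes, 2.0, 2.05, g, gp, jt, z, z, z,
                       c(1, 0, 0), c(0, 1, 0), 2.4, 2.45)
  H0 <- assemble_dimer_hamiltonian(fr0, fr0, J)
  for (s in 5:8) expect_equal(diabatic_minimum(H0, s)$e_reorg, 0)

  # error paths
  fr2 <- fragment_data(mode_basis(c(0.1, 0.2)), 2, 2, c(0, 0), c(0, 0),
                       c(0, 0), c(0, 0), c(0, 0), c(0, 0),
                       c(1, 0, 0), c(0, 1, 0), 2.4, 2.4)
  expect_error(assemble_dimer_hamiltonian(fr, fr2, J), "same number of modes")
  Jbad <- J; Jbad[1, 3] <- 0.1
  expect_error(assemble_dimer_hamiltonian(fr, fr, Jbad), "symmetric")
})

test_that("parameter files round-trip losslessly and reject unknown keys", {
  H <- random_lvc(3, 4, seed = 9)
  H$metadata <- list(note = "fixture", delta_numdiff = 0.01)
  p <- withr::local_tempfile(fileext = ".json")
  write_lvc(H, p)
  H2 <- read_lvc(p)
  expect_identical(H2$modes$frequencies, H$modes$frequencies)
  for (i in seq_along(H$states)) {
    expect_identical(H2$states[[i]]$gradient, H$states[[i]]$gradient)
    expect_identical(H2$states[[i]]$energy0, H$states[[i]]$energy0)
    expect_identical(H2$states[[i]]$dipole, H$states[[i]]$dipole)
  }
  for (k in seq_along(H$couplings)) {
    expect_identical(H2$couplings[[k]]$constant, H$couplings[[k]]$constant)
    expect_identical(H2$couplings[[k]]$linear, H$couplings[[k]]$linear)
  }

  txt <- readLines(p)
  bad <- sub("\"format\":", "\"formattt\":", txt)
  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines(bad, p2)
  expect_error(read_lvc(p2), "unknown key")

  # dense mode-coupling matrices survive the round trip too
  hier <- build_hierarchy(H, 1)
  Ht <- hems_transform(hier, H)
  p3 <- withr::local_tempfile(fileext = ".json")
  write_lvc(Ht, p3)
  expect_equal(read_lvc(p3)$mode_coupling, Ht$mode_coupling, tolerance = 1e-15)
})

test_that("gradient CSV import reads per-mode vectors", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frequency = c(0.1, 0.2), g = c(0.01, 0.02),
                   g_plus = c(0.03, 0.04))
  write.csv(df, p, row.names = FALSE)
  got <- read_gradients_csv(p)
  expect_equal(got$modes$frequencies, c(0.1, 0.2))
  expect_equal(got$gradients$g, c(0.01, 0.02))
  expect_equal(got$gradients$g_plus, c(0.03, 0.04))
})
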