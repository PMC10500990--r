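# Fixture builders shared across the test files. Everything is generated
# in code with explicit seeds; no data files are read.

# random LVC Hamiltonian with dense couplings (all states bright so that
# rotation-invariance checks are meaningful)
random_lvc <- function(n_states = 3, n_modes = 4, seed = 1) {
  set.seed(seed)
  modes <- mode_basis(runif(n_modes, 0.05, 0.25))
  states <- lapply(seq_len(n_states), function(i)
    diabatic_state(paste0("s", i), "LE", runif(1, 1.5, 2.5),
                   rnorm(n_modes, sd = 0.05), rnorm(3, sd = 0.5)))
  couplings <- list()
  for (i in seq_len(n_states - 1)) for (j in (i + 1):n_states) {
    couplings <- c(couplings,
                   list(interstate_coupling(i, j, rnorm(1, sd = 0.03),
                                            rnorm(n_modes, sd = 0.01))))
  }
  lvc_hamiltonian(modes, states, couplings)
}

random_orthogonal <- function(n, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n)))
}

# apply a global orthogonal rotation R to the diabatic basis: constant
# matrix, linear-coupling tensor and dipoles rotate together
rotate_diabatic_basis <- function(H, R) {
  ns <- length(H$states)
  nm <- H$modes$n
  E <- electronic_matrix(H)
  lam <- array(0, c(nm, ns, ns))
  for (i in seq_len(ns)) lam[, i, i] <- H$states[[i]]$gradient
  for (cp in H$couplings) {
    if (!is.null(cp$linear)) {
      lam[, cp$i, cp$j] <- cp$linear
      lam[, cp$j, cp$i] <- cp$linear
    }
  }
  Er <- t(R) %*% E %*% R
  lamr <- array(0, c(nm, ns, ns))
  for (a in seq_len(nm)) lamr[a, , ] <- t(R) %*% lam[a, , ] %*% R
  mur <- matrix(unlist(lapply(H$states, `[[`, "dipole")), nrow = 3) %*% R
  states <- lapply(seq_len(ns), function(i)
    diabatic_state(paste0("r", i), "LE", Er[i, i], lamr[, i, i], mur[, i]))
  couplings <- list()
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    couplings <- c(couplings,
                   list(interstate_coupling(i, j, Er[i, j], lamr[, i, j])))
  }
  lvc_hamiltonian(H$modes, states, couplings)
}

# two-level electronic Hamiltonian (no modes): Rabi / exciton fixtures
two_level <- function(e1 = 2, e2 = 2, v = 0.1,
                      mu1 = c(1, 0, 0), mu2 = c(0, 0, 0),
                      char2 = "LE") {
  lvc_hamiltonian(mode_basis(),
                  list(diabatic_state("a", "LE", e1, dipole = mu1),
                       diabatic_state("b", char2, e2, dipole = mu2)),
                  list(interstate_coupling(1, 2, v)))
}

# coupled two-state model over shared modes (HEMS fixtures)
two_state_coupled <- function(w, l1, l2, e = c(2.0, 2.1), j = 0.05,
                              mu2 = c(0.5, 0, 0)) {
  lvc_hamiltonian(mode_basis(w),
                  list(diabatic_state("A", "LE", e[1], l1, c(1, 0, 0)),
                       diabatic_state("B", "LE", e[2], l2, mu2)),
                  list(interstate_coupling(1, 2, j)))
}

# brute-force superposed RMSD: coarse Euler-angle grid search followed
# by Nelder-Mead refinement (independent of the Kabsch SVD route)
grid_rmsd <- function(pa, pb, step = 0.25) {
  pa <- sweep(pa, 2, colMeans(pa))
  pb <- sweep(pb, 2, colMeans(pb))
  euler_rot <- function(ang) {
    a <- ang[1]; b <- ang[2]; c_ <- ang[3]
    rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    rz2 <- matrix(c(cos(c_), sin(c_), 0, -sin(c_), cos(c_), 0, 0, 0, 1), 3, 3)
    rz1 %*% ry %*% rz2
  }
  obj <- function(ang) sqrt(sum((pa - pb %*% euler_rot(ang))^2) / nrow(pa))
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (c_ in seq(0, 2 * pi - step, by = step)) {
        v <- obj(c(a, b, c_))
        if (v < bestv) { bestv <- v; best <- c(a, b, c_) }
      }
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))$value
}
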