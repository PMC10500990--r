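test_that("FC|VG correlation has the right limits and magnitude", {
  modes <- mode_basis(0.15)
  times <- seq(0, 50, by = 0.1)
  # no displacement: pure phase evolution
  s0 <- diabatic_state("s", "LE", 2, 0, c(1, 0, 0))
  phi0 <- fcvg_correlation(s0, modes, times)
  expect_lt(max(abs(Mod(phi0) - 1)), 1e-12)
  expect_equal(phi0[1], 1 + 0i)
  expect_equal(Arg(phi0[11]), Arg(exp(-1i * 2 * 1 / hbar_ev_fs)),
               tolerance = 1e-10)
  # S = 0.5 magnitude against the closed form
  s5 <- make_displaced_monomer(2, 0.15, 0.5)$states[[1]]
  phi5 <- fcvg_correlation(s5, modes, times)
  expect_equal(Mod(phi5), exp(0.5 * (cos(0.15 * times / hbar_ev_fs) - 1)),
               tolerance = 1e-12)
  expect_equal(phi5[1], 1 + 0i)
})

test_that("requested Gaussian broadening is what the spectrum measures", {
  grid <- seq(1.0, 3.0, by = 0.0005)
  times <- seq(0, 400, by = 0.25)
  modes <- mode_basis(0.15)
  s0 <- diabatic_state("s", "LE", 2, 0, c(1, 0, 0))
  phi <- fcvg_correlation(s0, modes, times)
  for (hw in c(0.02, 0.04, 0.08)) {
    sp <- spectrum_from_correlations(matrix(phi), times, 1, hwhm_to_gamma(hw),
                                     grid)
    expect_equal(peak_position(sp), 2, tolerance = 1e-3)
    expect_equal(measure_hwhm(sp), hw, tolerance = 5e-4)
  }
  # doubling hwhm doubles the measured width (round trip within 1%)
  sp1 <- spectrum_from_correlations(matrix(phi), times, 1, hwhm_to_gamma(0.03), grid)
  sp2 <- spectrum_from_correlations(matrix(phi), times, 1, hwhm_to_gamma(0.06), grid)
  expect_equal(measure_hwhm(sp2) / measure_hwhm(sp1), 2, tolerance = 0.01)
  expect_error(hwhm_to_gamma(-1), "positive")
})

test_that("band areas follow the dipole sum rule and broadening conserves area", {
  modes <- mode_basis(c(0.15, 0.1))
  times <- seq(0, 300, by = 0.25)
  grid <- seq(1.0, 3.6, by = 0.001)
  sa <- diabatic_state("a", "LE", 1.8, c(0.05, 0.02), c(1, 0, 0))
  sb <- diabatic_state("b", "LE", 2.6, c(0.03, 0.04), c(2, 0, 0))  # |mu|^2 4x
  phi <- cbind(fcvg_correlation(sa, modes, times),
               fcvg_correlation(sb, modes, times))
  sp <- spectrum_from_correlations(phi, times, c(1, 4), hwhm_to_gamma(0.03),
                                   grid, component_names = c("a:a", "b:b"))
  aa <- spectrum_area(sp, range = c(1.0, 2.2), component = "a:a")
  ab <- spectrum_area(sp, range = c(2.2, 3.6), component = "b:b")
  expect_equal(ab / aa, 4, tolerance = 1e-3)

  # increasing Gamma lowers the peak but conserves the integral
  areas <- heights <- numeric(0)
  for (hw in c(0.02, 0.04, 0.08)) {
    s <- spectrum_from_correlations(matrix(phi[, 1]), times, 1,
                                    hwhm_to_gamma(hw), grid)
    areas <- c(areas, spectrum_area(s))
    heights <- c(heights, max(s$total))
  }
  expect_true(all(diff(heights) < 0))
  expect_lt(max(abs(areas / areas[1] - 1)), 1e-6)
})

test_that("cross-correlation components integrate to zero", {
  H <- make_kasha_ct_dimer(2, 0.1, 0.4, 0.05, S = 0.2, omega = 0.15)
  grid <- seq(1.0, 3.4, by = 0.002)
  sp <- lvc_spectrum(H, n_max = 7, t_max = 100, dt = 0.2, hwhm = 0.04,
                     grid = grid)
  cn <- colnames(sp$components)
  auto <- vapply(strsplit(cn, ":"), function(p) p[1] == p[2], logical(1))
  auto_area <- max(vapply(cn[auto], function(k)
    spectrum_area(sp, component = k), numeric(1)))
  for (k in cn[!auto])
    expect_lt(abs(spectrum_area(sp, component = k)) / auto_area, 1e-6)
  # total equals the sum of the components everywhere
  expect_lt(max(abs(sp$total - rowSums(sp$components))), 1e-12)
})

test_that("stick progressions are product Poisson distributions", {
  modes <- mode_basis(0.15)
  st <- make_displaced_monomer(2, 0.15, 0.5)$states[[1]]
  pr <- stick_spectrum_fcvg(st, modes, max_quanta = 25)
  # I(0-0) = e^{-S}; I(0-1)/I(0-0) = S
  expect_equal(pr$sticks$intensity[1], exp(-0.5), tolerance = 1e-12)
  expect_equal(pr$sticks$intensity[2] / pr$sticks$intensity[1], 0.5,
               tolerance = 1e-12)
  expect_equal(pr$e00, 2 - 0.5 * 0.15)
  expect_equal(sum(pr$sticks$intensity), 1, tolerance = 1e-10)

  # S = 0: a single unit stick at the vertical energy
  st0 <- diabatic_state("s", "LE", 2, 0, c(1, 0, 0))
  pr0 <- stick_spectrum_fcvg(st0, modes, 10)
  expect_equal(pr0$sticks$intensity[1], 1)
  expect_equal(pr0$sticks$position[1], 2)

  # two incommensurate modes: product of per-mode Poisson terms,
  # complete as max -> inf
  m2 <- mode_basis(c(0.15, 0.095))
  st2 <- make_displaced_monomer(2, c(0.15, 0.095), c(0.4, 0.3))$states[[1]]
  pr2 <- stick_spectrum_fcvg(st2, m2, 20)
  expect_equal(sum(pr2$sticks$intensity), 1, tolerance = 1e-9)
  target <- pr2$e00 + 2 * 0.15 + 1 * 0.095
  idx <- which(abs(pr2$sticks$position - target) < 1e-9)
  expect_equal(sum(pr2$sticks$intensity[idx]),
               dpois(2, 0.4) * dpois(1, 0.3), tolerance = 1e-12)
})

test_that("uncoupled multi-state spectra agree between propagation and the analytic route", {
  H <- lvc_hamiltonian(mode_basis(c(0.15, 0.08)),
                       list(diabatic_state("a", "LE", 1.9, c(0.08, 0.03), c(1, 0, 0)),
                            diabatic_state("b", "LE", 2.3, c(0.05, 0.04), c(0, 0.7, 0))))
  grid <- seq(1.2, 3.2, by = 0.002)
  sq <- lvc_spectrum(H, n_max = c(12, 10), t_max = 100, dt = 0.1, hwhm = 0.04,
                     grid = grid)
  sa <- fcvg_spectrum(H, t_max = 100, dt = 0.1, hwhm = 0.04, grid = grid)
  expect_lt(max(abs(sq$total - sa$total)) / max(sa$total), 1e-5)
})

test_that("H-dimer exciton coupling blue-shifts the maximum by J with a dark lower state", {
  J <- 0.3
  grid <- seq(1.2, 3.0, by = 0.002)
  H0 <- two_level(2, 2, 0, mu1 = c(1, 0, 0), mu2 = c(1, 0, 0))
  HJ <- two_level(2, 2, J, mu1 = c(1, 0, 0), mu2 = c(1, 0, 0))
  s0 <- lvc_spectrum(H0, n_max = integer(0), t_max = 150, dt = 0.2,
                     hwhm = 0.04, grid = grid)
  sJ <- lvc_spectrum(HJ, n_max = integer(0), t_max = 150, dt = 0.2,
                     hwhm = 0.04, grid = grid)
  expect_equal(peak_position(sJ) - peak_position(s0), J, tolerance = 0.002)
  # lower exciton (at E - J) carries essentially no band area
  dark <- spectrum_area(sJ, range = c(2 - J - 0.06, 2 - J + 0.06))
  expect_lt(abs(dark) / spectrum_area(sJ), 1e-8)
})

test_that("cluster-weighted averaging is an exact convex combination", {
  grid <- seq(1.0, 3.0, by = 0.002)
  times <- seq(0, 200, by = 0.25)
  mk <- function(e) {
    st <- diabatic_state("s", "LE", e, numeric(1) * 0, c(1, 0, 0))
    phi <- fcvg_correlation(st, mode_basis(0.15), times)
    spectrum_from_correlations(matrix(phi), times, 1, hwhm_to_gamma(0.03), grid)
  }
  s1 <- mk(1.7); s2 <- mk(2.4); s3 <- mk(2.0)
  # degenerate weights return the first spectrum exactly
  w1 <- weighted_average_spectrum(list(s1, s2, s3), c(1, 0, 0))
  expect_identical(w1$total, s1$total)
  # equal weights give the arithmetic mean
  weq <- weighted_average_spectrum(list(s1, s2), c(0.5, 0.5))
  expect_equal(weq$total, (s1$total + s2$total) / 2, tolerance = 1e-15)
  # 0.6 / 0.4 on two separated bands: band areas in that ratio
  wv <- weighted_average_spectrum(list(s1, s2), c(0.6, 0.4))
  a1 <- spectrum_area(wv, range = c(1.0, 2.05))
  a2 <- spectrum_area(wv, range = c(2.05, 3.0))
  expect_equal(a1 / a2, 0.6 / 0.4, tolerance = 1e-4)
  expect_error(weighted_average_spectrum(list(s1, s2), c(0.7, 0.4)), "sum to 1")
  sbad <- mk(2.0); sbad$grid <- sbad$grid + 0.001
  expect_error(weighted_average_spectrum(list(s1, sbad), c(0.5, 0.5)), "grid")
})

test_that("progression parameters are recovered from a broadened spectrum", {
  w <- 0.15; S <- 0.5
  H <- make_displaced_monomer(2, w, S)
  grid <- seq(1.4, 3.2, by = 0.002)
  sp <- fcvg_spectrum(H, t_max = 300, dt = 0.2, hwhm = w / 4, grid = grid)
  est <- estimate_progression(sp)
  expect_lte(abs(est$omega - w), 0.002 + 1e-12)   # within one grid step
  expect_lt(abs(est$S - S) / S, 0.05)
})

test_that("coarse time grids are rejected by the Nyquist guard", {
  times <- seq(0, 100, by = 2)
  phi <- exp(-1i * 2 * times / hbar_ev_fs)
  expect_error(spectrum_from_correlations(matrix(phi), times, 1, 0.1,
                                          seq(0, 3, 0.01)), "too coarse")
})

test_that("spectra round-trip through the CSV export", {
  H <- make_displaced_monomer(2, 0.15, 0.3)
  sp <- fcvg_spectrum(H, t_max = 100, dt = 0.2, hwhm = 0.04)
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, p, normalize = TRUE)
  df <- read.csv(p)
  expect_equal(max(df$total), 1, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$hwhm_ev, 0.04, tolerance = 1e-12)
  expect_true(meta$normalized)
})
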