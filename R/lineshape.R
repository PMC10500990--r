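#' Analytic vertical-gradient (FC|VG) correlation function
#'
#' Zero-temperature autocorrelation of a single displaced-oscillator
#' (adiabatic, uncoupled) excited state with ground-state frequencies:
#' phi(t) = exp(-i E_v t / hbar) *
#'          exp(sum_a S_a (e^{-i w_a t / hbar} - 1 + i w_a t / hbar)),
#' with Huang-Rhys factors S_a = lambda_a^2 / (2 w_a^2). Its Fourier
#' transform is the Poisson Franck-Condon progression with the 0-0 line
#' at E_v - sum_a S_a w_a. This is the uncoupled limit of the wavepacket
#' propagator and serves as its analytic cross-check.
#'
#' @param state a [diabatic_state].
#' @param modes the [mode_basis] the state lives on.
#' @param times numeric time grid in fs.
#' @return complex vector phi(t).
#' @export
fcvg_correlation <- function(state, modes, times) {
  stopifnot(inherits(state, "diabatic_state"), inherits(modes, "mode_basis"))
  if (length(state$gradient) != modes$n)
    stop("state gradient does not match the mode basis", call. = FALSE)
  w <- modes$frequencies
  s <- huang_rhys(state$gradient, w)
  phase <- -1i * state$energy0 * times / hbar_ev_fs
  for (a in seq_along(w)) {
    wt <- w[a] * times / hbar_ev_fs
    phase <- phase + s[a] * (exp(-1i * wt) - 1 + 1i * wt)
  }
  exp(phase)
}

#' Huang-Rhys factors of a gradient vector
#'
#' @param gradient lambda vector (eV).
#' @param frequencies mode frequencies (eV).
#' @return S_a = lambda_a^2 / (2 w_a^2), dimensionless.
#' @export
huang_rhys <- function(gradient, frequencies) {
  gradient^2 / (2 * frequencies^2)
}

#' Gaussian damping parameter from a target spectral width
#'
#' The time-domain damping exp(-Gamma^2 t^2 / 2) broadens every line
#' into a frequency-domain Gaussian; requesting a half-width at half
#' maximum `hwhm` (eV) gives Gamma = hwhm / (hbar sqrt(2 ln 2)) in
#' fs^-1.
#'
#' @param hwhm Gaussian half width at half maximum, eV.
#' @return Gamma in fs^-1.
#' @export
hwhm_to_gamma <- function(hwhm) {
  if (!is.numeric(hwhm) || hwhm <= 0) stop("hwhm must be positive", call. = FALSE)
  hwhm / (hbar_ev_fs * sqrt(2 * log(2)))
}

#' Absorption spectrum from correlation functions
#'
#' Computes per-pair spectral components
#' eps_ij(w) = c(w) (mu_i . mu_j) 2 Re int_0^T dt e^{i w t / hbar}
#'             phi_ji(t) e^{-Gamma^2 t^2 / 2}
#' by trapezoid quadrature on a uniform time grid, using the Hermitian
#' extension phi(-t) = phi(t)* implicitly through the one-sided
#' transform. The auto components carry the total intensity (their
#' integral is proportional to |mu_i|^2); cross components integrate to
#' zero and only redistribute the shape. `c(w) = w` when
#' `prefactor = TRUE`, 1 otherwise (shape-only default; an overall
#' molar-absorptivity constant can be applied by the caller).
#'
#' @param phi complex matrix, one column per (i, j) component,
#'   phi_ji(t) on `times`.
#' @param times uniform time grid (fs) starting at 0.
#' @param dipole_products numeric vector mu_i . mu_j per column.
#' @param gamma Gaussian damping parameter (fs^-1); see
#'   [hwhm_to_gamma()].
#' @param grid frequency grid in eV.
#' @param prefactor logical, include the c(w) = w factor.
#' @param component_names optional column labels ("i:j").
#' @return An object of class `vibronic_spectrum` with fields `grid`,
#'   `components` (matrix), `total`, `gamma`, `hwhm`, `prefactor`.
#' @export
spectrum_from_correlations <- function(phi, times, dipole_products, gamma,
                                       grid, prefactor = FALSE,
                                       component_names = NULL) {
  phi <- as.matrix(phi)
  nt <- length(times)
  if (nrow(phi) != nt) stop("phi and times disagree", call. = FALSE)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 || times[1] != 0)
    stop("times must be a uniform grid starting at 0", call. = FALSE)
  dt <- dt[1]
  if (length(dipole_products) != ncol(phi))
    stop("one dipole product per correlation column is required", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  # Nyquist guard: the time step must resolve the largest grid energy
  if (max(abs(grid)) * dt / hbar_ev_fs > pi)
    stop(sprintf(paste("time step %.3g fs is too coarse for the requested",
                       "frequency grid (max %.3g eV); need dt < %.3g fs"),
                 dt, max(abs(grid)), pi * hbar_ev_fs / max(abs(grid))),
         call. = FALSE)
  damp <- exp(-0.5 * gamma^2 * times^2)
  wts <- rep(dt, nt); wts[c(1, nt)] <- dt / 2
  kern <- exp(1i * outer(grid, times) / hbar_ev_fs)
  comp <- matrix(0, length(grid), ncol(phi))
  cw <- if (prefactor) grid else rep(1, length(grid))
  for (k in seq_len(ncol(phi))) {
    comp[, k] <- dipole_products[k] * cw *
      2 * Re(kern %*% (phi[, k] * damp * wts))
  }
  if (!is.null(component_names)) colnames(comp) <- component_names
  structure(list(grid = grid, components = comp, total = rowSums(comp),
                 gamma = gamma, hwhm = gamma * hbar_ev_fs * sqrt(2 * log(2)),
                 prefactor = prefactor),
            class = "vibronic_spectrum")
}

#' @exportS3Method base::print
print.vibronic_spectrum <- function(x, ...) {
  cat(sprintf("vibronic spectrum: %d grid points in [%.3f, %.3f] eV, HWHM %.3g eV\n",
              length(x$grid), min(x$grid), max(x$grid), x$hwhm))
  cat(sprintf("  maximum at %.4f eV; %d component(s)\n",
              peak_position(x), ncol(x$components)))
  invisible(x)
}

#' Nonadiabatic spectrum from wavepacket propagations
#'
#' Assembles the vibronic absorption spectrum of an LVC model from
#' propagation results, one per bright initial diabatic state i,
#' pairing each recorded correlation phi_ji(t) with the dipole product
#' mu_i . mu_j.
#'
#' @param H the [lvc_hamiltonian] that was propagated.
#' @param results list of [propagate()] results whose initial states are
#'   pure diabatic states (as produced when `initial` is an index).
#' @param hwhm Gaussian broadening HWHM in eV (default 0.04).
#' @param grid frequency grid in eV; `NULL` builds one spanning the
#'   diabatic energies plus a margin.
#' @param prefactor include the c(w) = w factor.
#' @return A `vibronic_spectrum`.
#' @export
spectrum_from_propagation <- function(H, results, hwhm = 0.04, grid = NULL,
                                      prefactor = FALSE) {
  if (inherits(results, "propagation_result")) results <- list(results)
  mu <- state_dipoles(H)
  if (is.null(grid)) grid <- default_grid(H, hwhm)
  phis <- list(); dps <- numeric(0); nms <- character(0)
  for (res in results) {
    i <- which(Mod(res$initial - 1) < 1e-12)
    if (length(i) != 1L || sum(Mod(res$initial)^2 > 1e-24) != 1L)
      stop("each result must start from a single pure diabatic state",
           call. = FALSE)
    for (j in seq_len(n_states(H))) {
      dp <- sum(mu[, i] * mu[, j])
      if (dp == 0) next
      phis <- c(phis, list(res$correlations[, j]))
      dps <- c(dps, dp)
      nms <- c(nms, paste0(state_labels(H)[j], ":", state_labels(H)[i]))
    }
  }
  if (!length(phis))
    stop("no bright components: every involved dipole product is zero",
         call. = FALSE)
  spectrum_from_correlations(do.call(cbind, phis), results[[1]]$times,
                             dps, hwhm_to_gamma(hwhm), grid,
                             prefactor = prefactor, component_names = nms)
}

default_grid <- function(H, hwhm, step = 0.002) {
  e <- state_energies(H)
  reorg <- vapply(seq_len(n_states(H)),
                  function(i) diabatic_minimum(H, i)$e_reorg, numeric(1))
  cpl <- if (length(H$couplings))
    max(abs(vapply(H$couplings, `[[`, numeric(1), "constant"))) else 0
  lo <- min(e) - max(reorg) - 3 * cpl - 10 * hwhm
  hi <- max(e) + 2 * max(reorg) + 3 * cpl + 10 * hwhm + 0.5
  seq(lo, hi, by = step)
}

#' Full LVC spectrum driver
#'
#' Propagates the wavepacket from every bright diabatic state of `H` and
#' assembles the nonadiabatic vibronic spectrum.
#'
#' @param H an [lvc_hamiltonian].
#' @param n_max quanta per mode for [build_basis()].
#' @param t_max,dt propagation settings (fs); the defaults (100 fs,
#'   HWHM 0.04 eV) are the package's standard spectroscopy settings.
#' @param hwhm Gaussian broadening HWHM (eV).
#' @param grid frequency grid (eV) or `NULL`.
#' @param prefactor include the c(w) = w factor.
#' @param ... passed to [propagate()].
#' @return A `vibronic_spectrum`.
#' @export
lvc_spectrum <- function(H, n_max = 10, t_max = 100, dt = 0.1, hwhm = 0.04,
                         grid = NULL, prefactor = FALSE, ...) {
  bright <- which(colSums(state_dipoles(H)^2) > 0)
  if (!length(bright)) stop("the model has no bright states", call. = FALSE)
  basis <- build_basis(H, n_max)
  dots <- list(...)
  prep <- do.call(prepare_propagator,
                  c(list(H = H, basis = basis),
                    dots[intersect(names(dots), c("method", "exact_limit"))]))
  results <- lapply(bright, function(i)
    do.call(propagate,
            c(list(H = H, basis = basis, initial = i, t_max = t_max, dt = dt,
                   prepared = prep),
              dots[setdiff(names(dots), c("method", "exact_limit"))])))
  spectrum_from_propagation(H, results, hwhm = hwhm, grid = grid,
                            prefactor = prefactor)
}

#' Adiabatic FC|VG spectrum of uncoupled states
#'
#' Spectrum from the analytic displaced-oscillator correlation functions
#' of one or more uncoupled diabatic states (auto terms only).
#'
#' @param H an [lvc_hamiltonian]; inter-state couplings are ignored (the
#'   model is assumed uncoupled).
#' @param t_max,dt time grid (fs).
#' @param hwhm Gaussian broadening HWHM (eV).
#' @param grid frequency grid or `NULL`.
#' @param prefactor include the c(w) = w factor.
#' @return A `vibronic_spectrum`.
#' @export
fcvg_spectrum <- function(H, t_max = 100, dt = 0.1, hwhm = 0.04, grid = NULL,
                          prefactor = FALSE) {
  times <- seq(0, t_max, by = dt)
  if (is.null(grid)) grid <- default_grid(H, hwhm)
  mu2 <- colSums(state_dipoles(H)^2)
  bright <- which(mu2 > 0)
  if (!length(bright)) stop("the model has no bright states", call. = FALSE)
  phi <- vapply(bright, function(i)
    fcvg_correlation(H$states[[i]], H$modes, times), complex(length(times)))
  spectrum_from_correlations(phi, times, mu2[bright], hwhm_to_gamma(hwhm),
                             grid, prefactor = prefactor,
                             component_names = paste0(state_labels(H)[bright],
                                                      ":", state_labels(H)[bright]))
}

#' Franck-Condon stick spectrum in the FC|VG limit
#'
#' Multi-mode product Poisson progression: sticks at
#' E_00 + sum_a n_a w_a with E_00 = E_v - sum_a S_a w_a and intensities
#' prod_a e^{-S_a} S_a^{n_a} / n_a!. Intensities sum to 1 as the
#' maximum quanta go to infinity.
#'
#' @param state a [diabatic_state].
#' @param modes the [mode_basis].
#' @param max_quanta maximum quanta per mode in the enumeration.
#' @return An object of class `fc_progression` with `sticks` (data frame
#'   of position/intensity), `S`, `e00`.
#' @export
stick_spectrum_fcvg <- function(state, modes, max_quanta = 10) {
  w <- modes$frequencies
  s <- huang_rhys(state$gradient, w)
  e00 <- state$energy0 - sum(s * w)
  if (!length(w)) {
    sticks <- data.frame(position = state$energy0, intensity = 1)
  } else {
    qs <- do.call(expand.grid, lapply(w, function(...) 0:max_quanta))
    if (nrow(qs) > 2e6) stop("progression enumeration too large", call. = FALSE)
    inten <- rep(1, nrow(qs))
    pos <- rep(e00, nrow(qs))
    for (a in seq_along(w)) {
      inten <- inten * stats::dpois(qs[[a]], s[a])
      pos <- pos + qs[[a]] * w[a]
    }
    ord <- order(pos)
    sticks <- data.frame(position = pos[ord], intensity = inten[ord])
  }
  structure(list(sticks = sticks, S = s, e00 = e00, e_vertical = state$energy0),
            class = "fc_progression")
}

#' @exportS3Method base::print
print.fc_progression <- function(x, ...) {
  cat(sprintf("FC progression: %d sticks, 0-0 at %.4f eV, sum of intensities %.6f\n",
              nrow(x$sticks), x$e00, sum(x$sticks$intensity)))
  invisible(x)
}

#' Cluster-weighted average spectrum
#'
#' Pointwise convex combination sum_k C^k eps^k(w) of per-conformer
#' spectra on a common grid, with C^k the cluster population weights.
#'
#' @param spectra list of `vibronic_spectrum` objects on identical
#'   grids.
#' @param weights numeric weights summing to 1 (within 1e-9).
#' @param cluster_ids optional identifiers recorded in the result.
#' @return A `vibronic_spectrum` (components are combined when all
#'   inputs share the same component set, otherwise dropped).
#' @export
weighted_average_spectrum <- function(spectra, weights, cluster_ids = NULL) {
  if (length(spectra) != length(weights))
    stop("one weight per spectrum is required", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  g <- spectra[[1]]$grid
  for (sp in spectra) {
    if (length(sp$grid) != length(g) || max(abs(sp$grid - g)) > 1e-12)
      stop("spectra must share a common frequency grid", call. = FALSE)
  }
  total <- Reduce(`+`, Map(function(sp, w) w * sp$total, spectra, weights))
  same_comp <- length(unique(lapply(spectra, function(sp) colnames(sp$components)))) == 1 &&
    length(unique(vapply(spectra, function(sp) ncol(sp$components), integer(1)))) == 1
  comps <- if (same_comp) {
    Reduce(`+`, Map(function(sp, w) w * sp$components, spectra, weights))
  } else matrix(total, dimnames = list(NULL, "total"))
  structure(list(grid = g, components = comps, total = total,
                 gamma = spectra[[1]]$gamma, hwhm = spectra[[1]]$hwhm,
                 prefactor = spectra[[1]]$prefactor,
                 cluster_ids = if (is.null(cluster_ids)) seq_along(spectra) else cluster_ids,
                 weights = weights),
            class = "vibronic_spectrum")
}

#' Normalize a spectrum to unit maximum height
#'
#' @param spec a `vibronic_spectrum`.
#' @return The spectrum scaled so max(total) = 1.
#' @export
normalize_spectrum <- function(spec) {
  m <- max(spec$total)
  if (m <= 0) stop("cannot normalize a non-positive spectrum", call. = FALSE)
  spec$total <- spec$total / m
  spec$components <- spec$components / m
  spec
}

#' Position of the absorption maximum
#'
#' @param spec a `vibronic_spectrum`.
#' @return grid energy (eV) of the maximum of the total spectrum.
#' @export
peak_position <- function(spec) spec$grid[which.max(spec$total)]

#' Integrated spectral area by trapezoid quadrature
#'
#' @param spec a `vibronic_spectrum`.
#' @param range optional c(lo, hi) energy window in eV.
#' @param component column name of `spec$components`, or `"total"`.
#' @return numeric area.
#' @export
spectrum_area <- function(spec, range = NULL, component = "total") {
  y <- if (identical(component, "total")) spec$total else spec$components[, component]
  x <- spec$grid
  if (!is.null(range)) {
    sel <- x >= range[1] & x <= range[2]
    x <- x[sel]; y <- y[sel]
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Measured half width at half maximum of a band
#'
#' Locates the highest peak and the half-maximum crossings on both
#' sides by linear interpolation.
#'
#' @param spec a `vibronic_spectrum`.
#' @return HWHM in eV.
#' @export
measure_hwhm <- function(spec) {
  y <- spec$total; x <- spec$grid
  ip <- which.max(y)
  half <- y[ip] / 2
  left <- NA_real_; right <- NA_real_
  for (k in ip:2) if (y[k - 1] <= half) {
    left <- x[k - 1] + (half - y[k - 1]) / (y[k] - y[k - 1]) * (x[k] - x[k - 1])
    break
  }
  for (k in ip:(length(y) - 1)) if (y[k + 1] <= half) {
    right <- x[k] + (half - y[k]) / (y[k + 1] - y[k]) * (x[k + 1] - x[k])
    break
  }
  if (is.na(left) || is.na(right))
    stop("band extends beyond the frequency grid", call. = FALSE)
  (right - left) / 2
}

#' Recover vibronic-progression parameters from a spectrum
#'
#' Detects the local maxima of a broadened Franck-Condon progression and
#' estimates the vibrational frequency (spacing of the two lowest peaks)
#' and the Huang-Rhys factor (height ratio of the first to the zeroth
#' peak), valid for a single-mode progression at broadening HWHM <= w/4.
#'
#' @param spec a `vibronic_spectrum`.
#' @param min_height peaks lower than `min_height * max` are ignored.
#' @return list with `omega` (eV), `S`, `peaks` (data frame).
#' @export
estimate_progression <- function(spec, min_height = 0.01) {
  y <- spec$total; x <- spec$grid
  n <- length(y)
  ip <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  ip <- ip[y[ip] >= min_height * max(y)]
  if (length(ip) < 2) stop("fewer than two peaks detected", call. = FALSE)
  ip <- ip[order(x[ip])]
  peaks <- data.frame(position = x[ip], height = y[ip])
  list(omega = peaks$position[2] - peaks$position[1],
       S = peaks$height[2] / peaks$height[1],
       peaks = peaks)
}

#' Write a spectrum as CSV plus JSON metadata
#'
#' @param spec a `vibronic_spectrum`.
#' @param path CSV output path; metadata goes to `paste0(path, ".json")`.
#' @param normalize write the unit-maximum normalized spectrum.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path, normalize = FALSE) {
  if (normalize) spec <- normalize_spectrum(spec)
  df <- data.frame(energy_ev = spec$grid, total = spec$total)
  if (!is.null(colnames(spec$components)))
    for (nm in colnames(spec$components)) df[[nm]] <- spec$components[, nm]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(hwhm_ev = spec$hwhm, gamma_fs = spec$gamma,
               prefactor = spec$prefactor, normalized = normalize)
  if (!is.null(spec$weights)) {
    meta$weights <- spec$weights
    meta$cluster_ids <- spec$cluster_ids
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}
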