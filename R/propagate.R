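#' Exact wavepacket propagation on coupled LVC surfaces
#'
#' Propagates |psi(0)> = sum_s c_s |d_s; 0> (the ground vibrational
#' wavepacket placed on one diabatic state, or on a fixed combination of
#' them) under the full vibronic Hamiltonian in a truncated
#' harmonic-oscillator product basis, and records the correlation
#' functions phi_js(t) = <d_j; 0| psi(t)>, the diabatic populations
#' P_s(t), the wavepacket norm and the basis-occupancy diagnostic.
#' Energies are measured from the ground-vibrational reference (the
#' zero-point energy of the shared modes is subtracted), so the
#' correlation phases feed directly into the absorption lineshape.
#'
#' Small problems (dimension <= `exact_limit`, default 4000) are solved
#' by dense diagonalization, which is unitary and exact in the basis;
#' larger ones use a short-iterative Lanczos (Krylov) propagator with a
#' per-step error estimate.
#'
#' @param H an [lvc_hamiltonian].
#' @param basis a [build_basis()] result (built with defaults when
#'   `NULL`).
#' @param initial integer diabatic-state index, or a numeric/complex
#'   coefficient vector over the diabatic states (normalized
#'   internally).
#' @param t_max propagation length in fs.
#' @param dt recording/propagation time step in fs.
#' @param method `"auto"`, `"exact"` or `"krylov"`.
#' @param krylov_order Lanczos subspace size per step.
#' @param krylov_tol per-step error tolerance.
#' @param exact_limit largest dimension admitted to the dense
#'   diagonalization path.
#' @param snapshot_every spacing (fs) of stored wavepacket snapshots and
#'   of the energy/occupancy diagnostics.
#' @param store_snapshots keep full wavepacket snapshots (needed by
#'   [populations_in_combination_basis()]).
#' @param prepared optional [prepare_propagator()] result, reused across
#'   several runs on the same Hamiltonian/basis (e.g. one per bright
#'   initial state when assembling a spectrum).
#' @return An object of class `propagation_result` with fields `times`,
#'   `correlations` (complex, one column per diabatic state),
#'   `populations`, `norm`, `energy` (eV, at snapshot times),
#'   `top_occupancy` (largest population found in any mode's highest
#'   oscillator level), `snapshot_times`, `snapshots` (optional),
#'   `state_labels`, `state_characters`, `initial`.
#' @export
propagate <- function(H, basis = NULL, initial = 1L, t_max = 100, dt = 0.1,
                      method = c("auto", "exact", "krylov"),
                      krylov_order = 15L, krylov_tol = 1e-9,
                      exact_limit = 4000L, snapshot_every = 0.5,
                      store_snapshots = FALSE, prepared = NULL) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(basis)) basis <- build_basis(H)
  ns <- n_states(H)
  m <- basis$m
  d <- basis$dim
  gidx <- (seq_len(ns) - 1L) * m + 1L          # |d_s; 0> basis positions
  # initial vector
  if (length(initial) == 1L && is.numeric(initial) &&
      initial == as.integer(initial) && ns > 1L || (length(initial) == 1L && ns == 1L)) {
    coef <- rep(0 + 0i, ns); coef[as.integer(initial)] <- 1
  } else {
    if (length(initial) != ns)
      stop("initial must be a state index or a length-n_states coefficient vector",
           call. = FALSE)
    coef <- as.complex(initial)
    nrm <- sqrt(sum(Mod(coef)^2))
    if (nrm == 0) stop("initial vector must be nonzero", call. = FALSE)
    coef <- coef / nrm
  }
  psi0 <- rep(0 + 0i, d)
  psi0[gidx] <- coef
  times <- seq(0, t_max, by = dt)
  nt <- length(times)
  snap_stride <- max(1L, round(snapshot_every / dt))
  snap_sel <- seq(1L, nt, by = snap_stride)
  if (snap_sel[length(snap_sel)] != nt) snap_sel <- c(snap_sel, nt)
  if (is.null(prepared)) {
    prepared <- prepare_propagator(H, basis, method = method,
                                   exact_limit = exact_limit)
  }
  Hs <- prepared$Hs
  method <- prepared$method

  top_masks <- lapply(seq_len(H$modes$n), function(alpha)
    rep(mode_quanta(basis, alpha) == basis$n_max[alpha], times = ns))

  corr <- matrix(0 + 0i, nt, ns)
  pops <- matrix(0, nt, ns)
  nrm_t <- numeric(nt)
  energy <- numeric(length(snap_sel))
  top_occ <- 0
  snaps <- if (store_snapshots) matrix(0 + 0i, d, length(snap_sel)) else NULL

  record <- function(psi, it, isnap) {
    corr[it, ] <<- psi[gidx]
    pm <- matrix(Mod(psi)^2, m, ns)
    pops[it, ] <<- colSums(pm)
    nrm_t[it] <<- sum(pm)
    if (!is.na(isnap)) {
      hp <- cmatvec(Hs, psi)
      energy[isnap] <<- Re(sum(Conj(psi) * hp))
      for (mask in top_masks)
        top_occ <<- max(top_occ, sum(Mod(psi[mask])^2))
      if (store_snapshots) snaps[, isnap] <<- psi
    }
  }

  if (method == "exact") {
    eig <- prepared$eig
    c0 <- drop(crossprod(eig$vectors, Re(psi0))) +
      1i * drop(crossprod(eig$vectors, Im(psi0)))
    psi_t <- eig$vectors %*%
      (c0 * exp(-1i * outer(eig$values, times) / hbar_ev_fs))
    corr <- t(psi_t[gidx, , drop = FALSE])
    pm <- Mod(psi_t)^2
    nrm_t <- colSums(pm)
    dim(pm) <- c(m, ns, nt)
    pops <- t(matrix(colSums(pm), ns, nt))
    snap_psi <- psi_t[, snap_sel, drop = FALSE]
    hr <- as.matrix(Hs %*% Re(snap_psi)); hi <- as.matrix(Hs %*% Im(snap_psi))
    energy <- colSums(Re(snap_psi) * hr + Im(snap_psi) * hi)
    snap_pm <- Mod(snap_psi)^2
    for (mask in top_masks)
      top_occ <- max(top_occ, max(colSums(snap_pm[mask, , drop = FALSE])))
    if (store_snapshots) snaps <- snap_psi
  } else {
    psi <- psi0
    record(psi, 1L, match(1L, snap_sel))
    for (it in 2L:nt) {
      psi <- krylov_step(Hs, psi, dt, krylov_order, krylov_tol)
      record(psi, it, match(it, snap_sel))
    }
  }
  colnames(corr) <- colnames(pops) <- state_labels(H)
  structure(list(times = times, correlations = corr, populations = pops,
                 norm = sqrt(nrm_t), energy = energy,
                 top_occupancy = top_occ,
                 snapshot_times = times[snap_sel], snapshots = snaps,
                 basis = basis, state_labels = state_labels(H),
                 state_characters = state_characters(H),
                 initial = coef, method = method, dt = dt),
            class = "propagation_result")
}

#' Prepare a propagation operator for reuse
#'
#' Assembles the sparse Hamiltonian matrix and, for the dense
#' (`"exact"`) path, its eigendecomposition, so that several
#' propagations on the same model (e.g. one per bright initial state)
#' share the expensive setup.
#'
#' @inheritParams propagate
#' @return list with `Hs` (sparse matrix), `method` (resolved), `eig`
#'   (eigendecomposition or `NULL`).
#' @export
prepare_propagator <- function(H, basis, method = c("auto", "exact", "krylov"),
                               exact_limit = 4000L) {
  method <- match.arg(method)
  d <- basis$dim
  Hs <- hamiltonian_matrix(H, basis)
  if (method == "auto") method <- if (d <= min(1500L, exact_limit)) "exact" else "krylov"
  if (method == "exact" && d > exact_limit)
    stop(sprintf("dimension %d exceeds exact_limit %d; use method = 'krylov'",
                 d, exact_limit), call. = FALSE)
  eig <- if (method == "exact") eigen(as.matrix(Hs), symmetric = TRUE) else NULL
  list(Hs = Hs, method = method, eig = eig)
}

# real sparse matrix times complex vector
cmatvec <- function(Hs, psi) {
  drop(as.vector(Hs %*% Re(psi))) + 1i * drop(as.vector(Hs %*% Im(psi)))
}

# one short-iterative Lanczos step exp(-i Hs dt / hbar) psi
krylov_step <- function(Hs, psi, dt, order, tol) {
  tau <- dt / hbar_ev_fs
  nrm0 <- sqrt(sum(Mod(psi)^2))
  v <- psi / nrm0
  d <- length(psi)
  V <- matrix(0 + 0i, d, order)
  alpha <- numeric(order)
  beta <- numeric(order)          # beta[k] couples k and k+1
  V[, 1] <- v
  w <- cmatvec(Hs, v)
  alpha[1] <- Re(sum(Conj(v) * w))
  w <- w - alpha[1] * v
  k <- 1L
  while (k < order) {
    beta[k] <- sqrt(sum(Mod(w)^2))
    if (beta[k] < 1e-14) break    # happy breakdown: subspace is invariant
    vnew <- w / beta[k]
    V[, k + 1L] <- vnew
    w <- cmatvec(Hs, vnew)
    alpha[k + 1L] <- Re(sum(Conj(vnew) * w))
    w <- w - alpha[k + 1L] * vnew - beta[k] * V[, k]
    k <- k + 1L
  }
  Tm <- diag(alpha[seq_len(k)], nrow = k)
  if (k > 1L) {
    idx <- seq_len(k - 1L)
    Tm[cbind(idx, idx + 1L)] <- beta[idx]
    Tm[cbind(idx + 1L, idx)] <- beta[idx]
  }
  te <- eigen(Tm, symmetric = TRUE)
  small <- drop(te$vectors %*% (exp(-1i * te$values * tau) * te$vectors[1, ]))
  err <- if (k < order) 0 else sqrt(sum(Mod(w)^2)) * abs(tau) * Mod(small[k])
  if (err > tol)
    stop(sprintf(paste("Krylov step error estimate %.2e exceeds tolerance %.2e;",
                       "reduce dt or increase krylov_order"), err, tol),
         call. = FALSE)
  drop(V[, seq_len(k), drop = FALSE] %*% small) * nrm0
}

#' @exportS3Method base::print
print.propagation_result <- function(x, ...) {
  cat(sprintf("propagation: %d states, %.1f fs in steps of %g fs (%s)\n",
              ncol(x$populations), max(x$times), x$dt, x$method))
  cat(sprintf("  final populations: %s\n",
              paste(sprintf("%s=%.3f", x$state_labels,
                            x$populations[nrow(x$populations), ]),
                    collapse = " ")))
  cat(sprintf("  max |norm-1| = %.2e, top-level occupancy = %.2e\n",
              max(abs(x$norm - 1)), x$top_occupancy))
  invisible(x)
}

#' Propagate with automatic basis-size convergence
#'
#' Re-runs [propagate()] with every `n_max` raised by 2 until the
#' top-level occupancy diagnostic falls below `occ_tol`.
#'
#' @inheritParams propagate
#' @param n_max starting quanta per mode.
#' @param occ_tol occupancy threshold.
#' @param max_rounds maximum number of enlargement rounds.
#' @param ... passed to [propagate()].
#' @return A `propagation_result`.
#' @export
propagate_converged <- function(H, n_max = 10, occ_tol = 1e-6,
                                max_rounds = 4L, ...) {
  for (round in seq_len(max_rounds)) {
    basis <- build_basis(H, n_max)
    res <- propagate(H, basis, ...)
    if (res$top_occupancy < occ_tol) return(res)
    n_max <- n_max + 2L
  }
  warning("top-level occupancy still above tolerance after enlargement rounds")
  res
}

#' Populations of fixed combinations of diabatic states
#'
#' Projects stored wavepacket snapshots on an orthonormal set of fixed
#' coefficient vectors over the diabatic basis (for example the
#' Franck-Condon-point adiabatic eigenvectors, i.e. "delocalized
#' states"). The vectors do not depend on the nuclear coordinates, so a
#' complete orthonormal set always sums to the total population.
#'
#' @param result a [propagate()] result obtained with
#'   `store_snapshots = TRUE`.
#' @param vectors n_states x k matrix with orthonormal columns.
#' @return list with `times` and `populations` (length(times) x k).
#' @export
populations_in_combination_basis <- function(result, vectors) {
  if (is.null(result$snapshots))
    stop("propagate() must be run with store_snapshots = TRUE", call. = FALSE)
  vectors <- as.matrix(vectors)
  ns <- length(result$state_labels)
  if (nrow(vectors) != ns)
    stop("vectors must have one row per diabatic state", call. = FALSE)
  gram <- Conj(t(vectors)) %*% vectors
  if (max(Mod(gram - diag(ncol(vectors)))) > 1e-8)
    stop("combination vectors must be orthonormal", call. = FALSE)
  m <- result$basis$m
  nsnap <- ncol(result$snapshots)
  pops <- matrix(0, nsnap, ncol(vectors))
  for (k in seq_len(nsnap)) {
    psim <- matrix(result$snapshots[, k], m, ns)
    amp <- psim %*% Conj(vectors)
    pops[k, ] <- colSums(Mod(amp)^2)
  }
  colnames(pops) <- colnames(vectors)
  list(times = result$snapshot_times, populations = pops)
}

#' Total charge-transfer population at a query time
#'
#' Sums the populations of all CT-labelled diabatic states at `t_query`
#' (linear interpolation between recorded times). Given a list of
#' propagation results (e.g. runs started from |L1> and |L1'>), returns
#' the average over runs, which is the quantity correlated with the
#' inter-monomer stacking distances.
#'
#' @param result a `propagation_result` or a list of them.
#' @param t_query time in fs.
#' @return scalar CT population fraction.
#' @export
ct_population_summary <- function(result, t_query = 100) {
  if (inherits(result, "propagation_result")) result <- list(result)
  vals <- vapply(result, function(r) {
    ct <- which(r$state_characters == "CT")
    if (!length(ct)) stop("no CT-labelled states in this model", call. = FALSE)
    if (t_query < min(r$times) || t_query > max(r$times))
      stop("t_query outside the propagation time grid", call. = FALSE)
    tot <- rowSums(r$populations[, ct, drop = FALSE])
    stats::approx(r$times, tot, xout = t_query)$y
  }, numeric(1))
  mean(vals)
}

#' Export diabatic populations as CSV
#'
#' @param result a `propagation_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_populations_csv <- function(result, path) {
  df <- data.frame(time_fs = result$times, result$populations,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export correlation functions as CSV
#'
#' Writes the time grid plus real and imaginary parts of every recorded
#' correlation function phi_js(t).
#'
#' @param result a `propagation_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlations_csv <- function(result, path) {
  df <- data.frame(time_fs = result$times)
  for (j in seq_along(result$state_labels)) {
    df[[paste0("re_", result$state_labels[j])]] <- Re(result$correlations[, j])
    df[[paste0("im_", result$state_labels[j])]] <- Im(result$correlations[, j])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
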