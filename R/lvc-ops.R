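#' Diabatic potential matrix at a nuclear configuration
#'
#' Evaluates V(q) with V_ii = E_ii(0) + q' W q / 2 + lambda_ii . q and
#' V_ij = E_ij(0) + lambda_ij . q (lambda_ij defaults to zero). The
#' result is exactly symmetric for every q.
#'
#' @param H an [lvc_hamiltonian].
#' @param q numeric vector of dimensionless coordinates (length = number
#'   of modes).
#' @return Symmetric n_states x n_states matrix in eV.
#' @export
diabatic_potential <- function(H, q) {
  q <- as.numeric(q)
  if (length(q) != H$modes$n)
    stop(sprintf("q has length %d but the Hamiltonian has %d modes",
                 length(q), H$modes$n), call. = FALSE)
  V <- electronic_matrix(H)
  harm <- if (H$modes$n) 0.5 * drop(crossprod(q, H$mode_coupling %*% q)) else 0
  if (H$modes$n) {
    lam <- state_gradients(H)
    diag(V) <- diag(V) + harm + drop(crossprod(lam, q))
    for (cp in H$couplings) {
      if (!is.null(cp$linear)) {
        add <- sum(cp$linear * q)
        V[cp$i, cp$j] <- V[cp$i, cp$j] + add
        V[cp$j, cp$i] <- V[cp$i, cp$j]
      }
    }
  } else {
    diag(V) <- diag(V) + harm
  }
  V
}

#' Adiabatic states at a nuclear configuration
#'
#' Diagonalizes V(q) and reports adiabatic energies (ascending),
#' eigenvectors over the diabatic basis, rotated transition dipoles,
#' oscillator strengths and the LE/CT percentage composition of each
#' state. Eigenvector signs are fixed deterministically (largest
#' magnitude component positive) so composition reports are
#' reproducible, including for (near-)degenerate states.
#'
#' @param H an [lvc_hamiltonian].
#' @param q evaluation point (defaults to the Franck-Condon point q = 0).
#' @param oscillator_strength if `TRUE` (default), compute
#'   f_i = (2/3) dE\[hartree\] |mu\[a.u.\]|^2.
#' @return An object of class `adiabatic_states` with fields `energies`,
#'   `vectors`, `dipoles` (3 x n), `f`, `composition` (percent LE / CT
#'   per state) and `q`.
#' @export
adiabatic_states <- function(H, q = rep(0, H$modes$n),
                             oscillator_strength = TRUE) {
  V <- diabatic_potential(H, q)
  eig <- eigen(V, symmetric = TRUE)
  ord <- order(eig$values)                       # ascending in energy
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {               # deterministic sign fix
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  mu_d <- state_dipoles(H)
  mu_a <- mu_d %*% vecs
  f <- if (oscillator_strength) {
    (2 / 3) * (vals / hartree_ev) * colSums(mu_a^2)
  } else rep(NA_real_, length(vals))
  chars <- state_characters(H)
  w2 <- vecs^2
  comp <- cbind(LE = 100 * colSums(w2[chars == "LE", , drop = FALSE]),
                CT = 100 * colSums(w2[chars == "CT", , drop = FALSE]))
  structure(list(energies = vals, vectors = vecs, dipoles = mu_a, f = f,
                 composition = comp, q = q),
            class = "adiabatic_states")
}

#' @exportS3Method base::print
print.adiabatic_states <- function(x, ...) {
  cat("adiabatic states (diagonalized LVC potential)\n")
  df <- data.frame(energy_eV = round(x$energies, 4), f = round(x$f, 4),
                   LE_pct = round(x$composition[, "LE"], 1),
                   CT_pct = round(x$composition[, "CT"], 1))
  print(df)
  invisible(x)
}

#' Minimum of a diabatic surface
#'
#' For the harmonic diagonal LVC surface the minimum is available in
#' closed form: q_min,a = -lambda_a / w_a, reorganization energy
#' E_reorg = sum_a lambda_a^2 / (2 w_a) and E_min = E_ii(0) - E_reorg.
#' With a dense mode-coupling matrix W the quadratic form is inverted
#' instead (q_min = -W^{-1} lambda).
#'
#' @param H an [lvc_hamiltonian].
#' @param i state index.
#' @return list with `q_min`, `e_min` (eV) and `e_reorg` (eV).
#' @export
diabatic_minimum <- function(H, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_states(H)) stop("no such state", call. = FALSE)
  if (!H$modes$n)
    return(list(q_min = numeric(0), e_min = H$states[[i]]$energy0, e_reorg = 0))
  lam <- H$states[[i]]$gradient
  q_min <- -solve(H$mode_coupling, lam)
  e_reorg <- -0.5 * sum(lam * q_min)
  list(q_min = drop(q_min), e_min = H$states[[i]]$energy0 - e_reorg,
       e_reorg = e_reorg)
}

coupling_class <- function(cp, chars) {
  if (!is.null(cp$linear) && any(cp$linear != 0)) return("JT")
  a <- chars[cp$i]; b <- chars[cp$j]
  if (a == "LE" && b == "LE") "LE-LE"
  else if (a == "CT" && b == "CT") "CT-CT"
  else "LE-CT"
}

#' Switch coupling classes on or off
#'
#' Returns a copy of the Hamiltonian in which all inter-state couplings
#' outside the selected classes are removed; intra-state terms (energies
#' and gradients) are untouched. Classes are `"LE-LE"`, `"LE-CT"`,
#' `"CT-CT"` and `"JT"` (intra-monomer linear couplings between
#' quasi-degenerate LE states). This reproduces the
#' progressive-switching numerical experiments used to attribute the
#' aggregation blue shift to exciton (LE-LE) couplings.
#'
#' @param H an [lvc_hamiltonian].
#' @param classes character vector, subset of
#'   `c("LE-LE", "LE-CT", "CT-CT", "JT")`; `character(0)` removes every
#'   inter-state coupling.
#' @return An [lvc_hamiltonian].
#' @export
toggle_couplings <- function(H, classes = character(0)) {
  known <- c("LE-LE", "LE-CT", "CT-CT", "JT")
  bad <- setdiff(classes, known)
  if (length(bad))
    stop("unknown coupling class: ", paste(bad, collapse = ", "), call. = FALSE)
  chars <- state_characters(H)
  H$couplings <- Filter(function(cp) coupling_class(cp, chars) %in% classes,
                        H$couplings)
  H
}
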