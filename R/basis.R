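#' Harmonic-oscillator product basis for wavepacket propagation
#'
#' Builds the direct-product number-state basis |s> x |n_1 ... n_N>
#' used by the exact propagator: each mode is truncated at `n_max`
#' quanta, and the full dimension is n_states * prod(n_max + 1).
#' Basis-set occupancy of the top oscillator level is reported by
#' [propagate()] so convergence with respect to `n_max` can be
#' monitored.
#'
#' @param H an [lvc_hamiltonian].
#' @param n_max maximum quanta per mode; scalar (recycled) or one value
#'   per mode.
#' @param cap maximum allowed total dimension (number of complex
#'   amplitudes); exceeding it raises an error suggesting an
#'   effective-mode reduction ([build_hierarchy()]).
#' @return An object of class `product_basis`.
#' @export
build_basis <- function(H, n_max = 10, cap = 5e6) {
  stopifnot(inherits(H, "lvc_hamiltonian"))
  nmode <- H$modes$n
  n_max <- as.integer(n_max)
  if (length(n_max) == 1L) n_max <- rep(n_max, nmode)
  if (length(n_max) != nmode)
    stop("n_max must be scalar or one value per mode", call. = FALSE)
  if (nmode && any(n_max < 1L))
    stop("n_max must be >= 1 for every mode", call. = FALSE)
  levels <- n_max + 1L
  m <- prod(as.numeric(levels))
  d <- m * n_states(H)
  if (d > cap)
    stop(sprintf(paste("basis dimension %.3g exceeds the cap %.3g;",
                       "reduce n_max or apply a hierarchical effective-mode",
                       "truncation (build_hierarchy / hems_truncate)"),
                 d, cap), call. = FALSE)
  structure(list(n_max = n_max, levels = levels, m = as.integer(m),
                 dim = as.integer(d), n_states = n_states(H)),
            class = "product_basis")
}

#' @exportS3Method base::print
print.product_basis <- function(x, ...) {
  cat(sprintf("product basis: %d states x %d vibrational configurations = %d\n",
              x$n_states, x$m, x$dim))
  if (length(x$n_max))
    cat("  quanta per mode:", paste(x$n_max, collapse = " "), "\n")
  invisible(x)
}

# quantum numbers of mode `alpha` for every vibrational basis index
# (mode 1 varies fastest)
mode_quanta <- function(basis, alpha) {
  lv <- basis$levels
  before <- if (alpha > 1) prod(as.numeric(lv[seq_len(alpha - 1)])) else 1
  after <- basis$m / (before * lv[alpha])
  rep(rep(0:(lv[alpha] - 1L), each = before), times = after)
}

# lift a single-mode operator to the full vibrational space
lift_mode_op <- function(op, alpha, basis) {
  lv <- basis$levels
  before <- if (alpha > 1) prod(as.numeric(lv[seq_len(alpha - 1)])) else 1
  after <- basis$m / (before * lv[alpha])
  out <- op
  if (before > 1) out <- kronecker(out, Matrix::Diagonal(before))
  if (after > 1) out <- kronecker(Matrix::Diagonal(after), out)
  out
}

# single-mode ladder operators in the truncated number basis
ladder_ops <- function(l) {
  n <- seq_len(l - 1L)
  lower <- Matrix::sparseMatrix(i = n, j = n + 1L, x = sqrt(n), dims = c(l, l))
  list(a = lower, adag = Matrix::t(lower))
}

#' Sparse Hamiltonian matrix in the product basis
#'
#' Assembles H as a real symmetric sparse matrix. The vibrational part
#' is sum_a W_aa n_a (energies measured from the ground-vibrational
#' reference, i.e. the zero-point energy of the shared ground-state
#' modes is subtracted) plus, for a dense mode-coupling matrix W, the
#' number-conserving bilinear terms
#' W_ab (q_a q_b + p_a p_b)/... = W_ab (a_a adag_b + adag_a a_b) for
#' a < b. Position operators q_a (tridiagonal,
#' <n+1|q|n> = sqrt((n+1)/2)) carry the intra- and inter-state linear
#' couplings.
#'
#' @param H an [lvc_hamiltonian].
#' @param basis a [build_basis()] result for `H`.
#' @return A `dgCMatrix` of dimension `basis$dim`.
#' @export
hamiltonian_matrix <- function(H, basis) {
  ns <- n_states(H)
  m <- basis$m
  nmode <- H$modes$n
  W <- H$mode_coupling
  # vibrational block shared by all states
  evib <- numeric(m)
  for (alpha in seq_len(nmode))
    evib <- evib + W[alpha, alpha] * mode_quanta(basis, alpha)
  hvib <- Matrix::Diagonal(m, x = evib)
  qops <- vector("list", nmode)
  if (nmode) {
    lifted <- lapply(seq_len(nmode), function(alpha) {
      lad <- ladder_ops(basis$levels[alpha])
      list(a = lift_mode_op(lad$a, alpha, basis),
           adag = lift_mode_op(lad$adag, alpha, basis))
    })
    for (alpha in seq_len(nmode))
      qops[[alpha]] <- (lifted[[alpha]]$a + lifted[[alpha]]$adag) / sqrt(2)
    if (nmode > 1) {
      for (alpha in seq_len(nmode - 1)) for (beta in (alpha + 1):nmode) {
        if (W[alpha, beta] != 0)
          hvib <- hvib + W[alpha, beta] *
            (lifted[[alpha]]$a %*% lifted[[beta]]$adag +
             lifted[[alpha]]$adag %*% lifted[[beta]]$a)
      }
    }
  }
  unit <- function(i, j) Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(ns, ns))
  Hfull <- kronecker(Matrix::Diagonal(ns), hvib)
  for (s in seq_len(ns)) {
    blk <- Matrix::Diagonal(m, x = rep(H$states[[s]]$energy0, m))
    for (alpha in seq_len(nmode)) {
      lam <- H$states[[s]]$gradient[alpha]
      if (lam != 0) blk <- blk + lam * qops[[alpha]]
    }
    Hfull <- Hfull + kronecker(unit(s, s), blk)
  }
  for (cp in H$couplings) {
    blk <- Matrix::Diagonal(m, x = rep(cp$constant, m))
    if (!is.null(cp$linear)) {
      for (alpha in seq_len(nmode)) {
        if (cp$linear[alpha] != 0) blk <- blk + cp$linear[alpha] * qops[[alpha]]
      }
    }
    Hfull <- Hfull + kronecker(unit(cp$i, cp$j) + unit(cp$j, cp$i), blk)
  }
  methods::as(Matrix::drop0(Hfull), "CsparseMatrix")
}
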