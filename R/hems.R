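#' Hierarchical effective-mode transformation (HEMS)
#'
#' Builds an orthogonal coordinate transformation that concentrates all
#' vibronic coupling of an LVC Hamiltonian into a leading block of
#' effective modes: block 1 is an orthonormal basis of the span of all
#' nonzero intra-state gradients and linear inter-state couplings
#' (obtained by SVD with a relative singular-value threshold); blocks
#' 2..m follow by a block-Lanczos recursion that applies the frequency
#' matrix to the previous block and orthogonalizes against everything
#' built so far. Modes beyond the last block carry no coupling (within
#' threshold) and only bilinear frequency terms, so truncating after a
#' few blocks preserves the short-time dynamics, hence the spectral
#' shape.
#'
#' @param H an [lvc_hamiltonian].
#' @param n_blocks requested hierarchy depth m (>= 1). If the chain
#'   terminates earlier, the achieved depth is returned with
#'   `truncated_chain = TRUE` and a warning.
#' @param svd_tol relative singular-value threshold for rank decisions.
#' @return An object of class `effective_mode_hierarchy` with fields
#'   `transform` (orthogonal N x N matrix T, effective modes first),
#'   `block_index` (per transformed mode: block number, 0 for residual
#'   modes), `frequency_matrix` (T' Omega T, dense, carrying the
#'   bilinear inter-mode couplings), `n_blocks`, `truncated_chain`.
#' @export
build_hierarchy <- function(H, n_blocks = 1L, svd_tol = 1e-8) {
  stopifnot(inherits(H, "lvc_hamiltonian"))
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  n <- H$modes$n
  if (!n) stop("the Hamiltonian has no modes", call. = FALSE)
  omega <- H$mode_coupling
  lc <- linear_couplings(H)
  lam <- cbind(state_gradients(H),
               if (length(lc$vectors)) matrix(unlist(lc$vectors), nrow = n))
  lam <- lam[, colSums(lam^2) > 0, drop = FALSE]

  orth_cols <- function(mat, against = NULL) {
    if (!ncol(mat)) return(matrix(0, n, 0))
    if (!is.null(against) && ncol(against)) {
      mat <- mat - against %*% crossprod(against, mat)
      mat <- mat - against %*% crossprod(against, mat)   # re-orthogonalize
    }
    sv <- svd(mat)
    keep <- sv$d > svd_tol * max(sv$d, 0) & sv$d > 1e-12 * max(abs(omega))
    sv$u[, keep, drop = FALSE]
  }

  blocks <- list()
  built <- matrix(0, n, 0)
  truncated <- FALSE
  if (ncol(lam)) {
    b1 <- orth_cols(lam)
    blocks[[1]] <- b1
    built <- b1
    k <- 1L
    while (k < n_blocks && ncol(built) < n) {
      cand <- orth_cols(omega %*% blocks[[k]], against = built)
      if (!ncol(cand)) { truncated <- TRUE; break }
      k <- k + 1L
      blocks[[k]] <- cand
      built <- cbind(built, cand)
    }
    if (k < n_blocks && !truncated && ncol(built) >= n) truncated <- TRUE
  } else {
    truncated <- n_blocks > 0L   # no coupling at all: block 1 is empty
  }
  if (truncated)
    warning(sprintf("hierarchy chain ended at depth %d (requested %d)",
                    length(blocks), n_blocks))
  # complete T with an orthonormal residual basis
  resid <- if (ncol(built) < n) {
    q <- qr.Q(qr(cbind(built, diag(n))))[, seq_len(n), drop = FALSE]
    q[, seq(ncol(built) + 1L, n), drop = FALSE]
  } else matrix(0, n, 0)
  transform <- cbind(built, resid)
  block_index <- c(rep(seq_along(blocks), vapply(blocks, ncol, integer(1))),
                   rep(0L, ncol(resid)))
  structure(list(transform = transform, block_index = block_index,
                 frequency_matrix = crossprod(transform, omega %*% transform),
                 n_blocks = length(blocks), truncated_chain = truncated,
                 svd_tol = svd_tol),
            class = "effective_mode_hierarchy")
}

#' @exportS3Method base::print
print.effective_mode_hierarchy <- function(x, ...) {
  sizes <- tabulate(x$block_index[x$block_index > 0], nbins = x$n_blocks)
  cat(sprintf("effective-mode hierarchy: %d block(s) of sizes [%s], %d residual mode(s)\n",
              x$n_blocks, paste(sizes, collapse = ", "),
              sum(x$block_index == 0)))
  invisible(x)
}

# rotate a Hamiltonian onto a subset of transformed modes
hems_project <- function(hier, H, keep) {
  tk <- hier$transform[, keep, drop = FALSE]
  wk <- hier$frequency_matrix[keep, keep, drop = FALSE]
  # make numerically-exact symmetry
  wk <- (wk + t(wk)) / 2
  modes <- mode_basis(diag(wk),
                      paste0("eff", seq_along(keep)))
  states <- lapply(H$states, function(s) {
    diabatic_state(s$label, s$character, s$energy0,
                   drop(crossprod(tk, s$gradient)), s$dipole)
  })
  couplings <- lapply(H$couplings, function(cp) {
    lin <- if (is.null(cp$linear)) NULL else drop(crossprod(tk, cp$linear))
    interstate_coupling(cp$i, cp$j, cp$constant, lin)
  })
  lvc_hamiltonian(modes, states, couplings, mode_coupling = wk,
                  metadata = H$metadata)
}

#' Truncate an LVC Hamiltonian to the leading hierarchy blocks
#'
#' Returns the reduced Hamiltonian over blocks 1..`m_keep`: bilinear
#' frequency couplings among kept modes are retained exactly, couplings
#' from kept to discarded modes are dropped, and the Frobenius norm of
#' the dropped frequency block is reported as
#' `metadata$hems$dropped_coupling_norm`.
#'
#' @param hier a [build_hierarchy()] result.
#' @param H the [lvc_hamiltonian] the hierarchy was built from.
#' @param m_keep number of blocks to keep (<= built depth).
#' @return A reduced [lvc_hamiltonian].
#' @export
hems_truncate <- function(hier, H, m_keep) {
  if (hier$n_blocks > 0L && m_keep > hier$n_blocks)
    stop("m_keep exceeds the built hierarchy depth", call. = FALSE)
  keep <- which(hier$block_index >= 1L & hier$block_index <= m_keep)
  if (!length(keep)) {        # no coupled modes at all: bare electronic H
    Hred <- lvc_hamiltonian(mode_basis(numeric(0)),
                            lapply(H$states, function(s)
                              diabatic_state(s$label, s$character, s$energy0,
                                             numeric(0), s$dipole)),
                            lapply(H$couplings, function(cp)
                              interstate_coupling(cp$i, cp$j, cp$constant)),
                            metadata = H$metadata)
    Hred$metadata$hems <- list(m_keep = m_keep, dropped_coupling_norm = 0)
    return(Hred)
  }
  drop_ <- setdiff(seq_len(H$modes$n), keep)
  Hred <- hems_project(hier, H, keep)
  Hred$metadata$hems <- list(
    m_keep = m_keep,
    dropped_coupling_norm =
      sqrt(sum(hier$frequency_matrix[keep, drop_, drop = FALSE]^2)))
  Hred
}

#' Rotate an LVC Hamiltonian to the full effective-mode frame
#'
#' Applies the complete orthogonal transformation (all blocks plus
#' residual modes), yielding a Hamiltonian unitarily equivalent to the
#' input: identical adiabatic energies, correlation functions and
#' spectra.
#'
#' @inheritParams hems_truncate
#' @return An [lvc_hamiltonian] over the transformed coordinates.
#' @export
hems_transform <- function(hier, H) {
  hems_project(hier, H, seq_len(H$modes$n))
}

#' Serialize a hierarchy transformation
#'
#' Writes the orthogonal matrix, block index and frequency matrix as a
#' JSON sidecar next to the LVC parameter file.
#'
#' @param hier a [build_hierarchy()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hier, path) {
  jsonlite::write_json(list(format = "hems-hierarchy", version = 1L,
                            transform = hier$transform,
                            block_index = hier$block_index,
                            frequency_matrix = hier$frequency_matrix,
                            n_blocks = hier$n_blocks,
                            truncated_chain = hier$truncated_chain),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
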