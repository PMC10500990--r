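#' Pairwise RMSD matrix after least-squares superposition
#'
#' Computes the symmetric matrix of root-mean-square deviations between
#' all frame pairs, in nm, after optimal (unweighted Kabsch)
#' rotation/translation superposition on the fit set. By default the fit
#' and measurement set is the union of both rings' selected atoms - the
#' relative orientation and distance of the macrocycle rings is what
#' matters for dimer photophysics, while flexible side chains would
#' blur the clustering.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param fit_atoms atom indices to superpose and measure on; defaults
#'   to `c(ring1, ring2)`.
#' @return n_frames x n_frames symmetric matrix in nm with zero
#'   diagonal.
#' @export
pairwise_rmsd <- function(ensemble, fit_atoms = NULL) {
  nf <- dim(ensemble$coords)[1]
  if (nf < 2L) stop("at least two frames are required", call. = FALSE)
  if (is.null(fit_atoms))
    fit_atoms <- c(ensemble$selections$ring1, ensemble$selections$ring2)
  xyz <- matrix(0, nf, 3L * length(fit_atoms))
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(ensemble$coords[f, fit_atoms, ]))
  out <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      r <- bio3d::rmsd(xyz[i, ], xyz[j, ], fit = TRUE)
      out[i, j] <- out[j, i] <- r / 10       # Angstrom -> nm
    }
  }
  out
}
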