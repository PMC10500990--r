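#' Inter-monomer geometry descriptors of a stacked dimer frame
#'
#' For one frame, computes the descriptors that rationalize the optical
#' response of pi-stacked chromophore dimers:
#' \describe{
#'   \item{d_zn_zn}{metal-metal distance (Angstrom), the global
#'     inter-monomer distance.}
#'   \item{d_p_p}{inter-ring distance (Angstrom): the mean absolute
#'     projection of the paired ring-atom displacements onto the ring
#'     normal (SVD plane fit). Rings need not be planar, so this is an
#'     averaged interatomic distance along the stacking axis; because of
#'     tilting it can be smaller than d_zn_zn even for well-separated
#'     metals.}
#'   \item{alpha}{eight angles (degrees, folded to \[0, 90\]) between
#'     the inter-metal vector and the four in-plane reference axes of
#'     each ring; a perfectly cofacial stack has all alpha_i = 90.}
#'   \item{beta}{signed twist (degrees) between the rings' primary
#'     in-plane axes about the mean ring normal.}
#' }
#'
#' @param frame n_atoms x 3 coordinate matrix (Angstrom), or a
#'   [conformer_ensemble()] together with `frame_index`.
#' @param selections selection map (taken from the ensemble when
#'   omitted).
#' @param frame_index frame number when `frame` is an ensemble.
#' @param normal `"ring1"` (default) projects onto the ring-1 plane
#'   normal; `"average"` uses the mean of both ring normals.
#' @return list with `d_zn_zn`, `d_p_p`, `alpha` (length 8), `beta`.
#' @export
geometry_descriptors <- function(frame, selections = NULL, frame_index = 1L,
                                 normal = c("ring1", "average")) {
  normal <- match.arg(normal)
  if (inherits(frame, "conformer_ensemble")) {
    if (is.null(selections)) selections <- frame$selections
    frame <- frame$coords[frame_index, , ]
  }
  if (is.null(selections)) stop("a selection map is required", call. = FALSE)
  frame <- as.matrix(frame)
  sel <- validate_selections(selections, nrow(frame))
  r1 <- frame[sel$ring1, , drop = FALSE]
  r2 <- frame[sel$ring2, , drop = FALSE]
  zn1 <- frame[sel$metal1, ]
  zn2 <- frame[sel$metal2, ]
  n1 <- ring_normal(r1)
  n2 <- ring_normal(r2)
  sep <- colMeans(r2) - colMeans(r1)
  if (sum(n1 * sep) < 0) n1 <- -n1          # orient ring1 normal toward ring2
  if (sum(n2 * n1) < 0) n2 <- -n2
  nref <- if (normal == "ring1") n1 else normalize3(n1 + n2)
  d_p_p <- mean(abs((r2 - r1) %*% nref))
  v <- zn2 - zn1
  d_zn_zn <- sqrt(sum(v^2))
  axis_vec <- function(pair) normalize3(frame[pair[2], ] - frame[pair[1], ])
  axes <- rbind(t(apply(sel$axes1, 1L, axis_vec)),
                t(apply(sel$axes2, 1L, axis_vec)))
  vhat <- normalize3(v)
  cosang <- pmin(1, abs(drop(axes %*% vhat)))
  alpha <- acos(cosang) * 180 / pi          # folded to [0, 90]; 90 = cofacial
  # twist: signed angle between the primary in-plane axes about nref
  a1 <- axis_vec(sel$axes1[1L, ])
  a2 <- axis_vec(sel$axes2[1L, ])
  p1 <- normalize3(a1 - sum(a1 * nref) * nref)
  p2 <- normalize3(a2 - sum(a2 * nref) * nref)
  beta <- atan2(sum(nref * cross3(p1, p2)), sum(p1 * p2)) * 180 / pi
  list(d_zn_zn = d_zn_zn, d_p_p = d_p_p, alpha = alpha, beta = beta)
}

ring_normal <- function(ring) {
  centered <- sweep(ring, 2L, colMeans(ring))
  sv <- svd(centered)
  normalize3(sv$v[, 3L])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate axis (zero length)", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Geometry descriptors for every frame of an ensemble
#'
#' @param ensemble a [conformer_ensemble()].
#' @param ... passed to [geometry_descriptors()].
#' @return data frame with one row per frame: `d_zn_zn`, `d_p_p`,
#'   `alpha1`..`alpha8`, `beta`.
#' @export
descriptor_table <- function(ensemble, ...) {
  nf <- dim(ensemble$coords)[1]
  rows <- lapply(seq_len(nf), function(f) {
    g <- geometry_descriptors(ensemble, frame_index = f, ...)
    as.data.frame(c(list(frame = f, d_zn_zn = g$d_zn_zn, d_p_p = g$d_p_p),
                    stats::setNames(as.list(g$alpha), paste0("alpha", 1:8)),
                    list(beta = g$beta)))
  })
  do.call(rbind, rows)
}
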