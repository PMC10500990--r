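#' Daura (GROMOS) RMSD clustering
#'
#' Greedy neighbor-count clustering: the frame with the most neighbors
#' within the RMSD cutoff founds a cluster together with its neighbors;
#' the cluster is removed and the procedure repeats until every frame is
#' assigned. Cluster weights C^k are the population fractions entering
#' the weighted spectral average, and each cluster's central structure
#' is the member with the smallest average RMSD to all other members
#' (the representative conformation whose spectrum stands in for the
#' whole cluster). Ties in neighbor count and centrality are broken by
#' the lowest original frame index, so the result is deterministic and
#' invariant under frame permutation up to relabeling.
#'
#' @param rmsd symmetric RMSD matrix in nm ([pairwise_rmsd()]).
#' @param cutoff neighbor cutoff in nm (default 0.10 nm).
#' @return An object of class `cluster_result` with fields `assignment`
#'   (cluster id per frame, in discovery order), `sizes`, `weights`,
#'   `central` (central-structure frame index per cluster), `cutoff`.
#' @export
daura_cluster <- function(rmsd, cutoff = 0.10) {
  rmsd <- as.matrix(rmsd)
  n <- nrow(rmsd)
  if (n != ncol(rmsd) || max(abs(rmsd - t(rmsd))) > 1e-12)
    stop("rmsd must be a symmetric matrix", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  assignment <- integer(n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining)) {
    sub <- rmsd[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)       # includes self; ties -> lowest index
    founder <- which.max(counts)
    members <- remaining[sub[founder, ] <= cutoff]
    k <- k + 1L
    assignment[members] <- k
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(assignment, nbins = k)
  central <- integer(k)
  for (c_ in seq_len(k)) {
    members <- which(assignment == c_)
    if (length(members) == 1L) {
      central[c_] <- members
    } else {
      avg <- rowMeans(rmsd[members, members, drop = FALSE]) *
        length(members) / (length(members) - 1)   # exclude self-distance 0
      central[c_] <- members[which.min(avg)]
    }
  }
  structure(list(assignment = assignment, sizes = sizes,
                 weights = sizes / sum(sizes), central = central,
                 cutoff = cutoff),
            class = "cluster_result")
}

#' @exportS3Method base::print
print.cluster_result <- function(x, ...) {
  cat(sprintf("Daura clustering at cutoff %.3g nm: %d cluster(s)\n",
              x$cutoff, length(x$sizes)))
  for (k in seq_along(x$sizes))
    cat(sprintf("  cluster %d: %d frames (weight %.3f), central frame %d\n",
                k, x$sizes[k], x$weights[k], x$central[k]))
  invisible(x)
}

#' Export cluster assignments as CSV and the summary as JSON
#'
#' @param clusters a [daura_cluster()] result.
#' @param csv_path per-frame assignment CSV path.
#' @param json_path cluster summary JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_clusters <- function(clusters, csv_path, json_path = paste0(csv_path, ".json")) {
  utils::write.csv(data.frame(frame = seq_along(clusters$assignment),
                              cluster = clusters$assignment),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(sizes = clusters$sizes, weights = clusters$weights,
                            central = clusters$central, cutoff_nm = clusters$cutoff),
                       json_path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(csv_path)
}
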