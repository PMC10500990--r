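test_that("XYZ trajectories round-trip and validate selections", {
  ens <- make_stacked_trajectory(frames_per_cluster = c(2, 1, 1), noise = 0.03,
                                 seed = 4)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(ens, p)
  ens2 <- read_trajectory(p, stacked_dimer_selections())
  expect_equal(dim(ens2$coords), dim(ens$coords))
  expect_lt(max(abs(ens2$coords - ens$coords)), 1e-3)   # format precision

  sel <- stacked_dimer_selections()
  sel$metal2 <- 999L
  expect_error(conformer_ensemble(ens$coords, sel), "out of range")
  sel2 <- stacked_dimer_selections(); sel2$metal1 <- NULL
  expect_error(conformer_ensemble(ens$coords, sel2), "missing")
  expect_error(read_trajectory("no-such-file.xyz", stacked_dimer_selections()),
               "no such file")
  p3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("not-a-count", "x"), p3)
  expect_error(read_trajectory(p3, stacked_dimer_selections()), "malformed")
})

test_that("superposed RMSD removes rigid-body motion and matches a brute-force oracle", {
  ens <- make_stacked_trajectory(frames_per_cluster = c(2, 1, 1), noise = 0.05,
                                 seed = 8)
  rmat <- pairwise_rmsd(ens)
  expect_equal(diag(rmat), rep(0, 4))
  expect_lt(max(abs(rmat - t(rmat))), 1e-12)

  # frame vs rigidly rotated + translated copy of itself
  th <- 0.8
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens$coords[1, , ] %*% rot + matrix(c(3, -2, 5), dim(ens$coords)[2],
                                              3, byrow = TRUE)
  co <- array(0, c(2, dim(ens$coords)[2], 3))
  co[1, , ] <- ens$coords[1, , ]; co[2, , ] <- moved
  e2 <- conformer_ensemble(co, ens$selections)
  expect_lt(pairwise_rmsd(e2)[1, 2], 1e-10)

  # 4-atom toy frames against the rotation-grid brute-force oracle
  set.seed(3)
  pa <- matrix(rnorm(12, sd = 2), 4, 3)
  pb <- pa + matrix(rnorm(12, sd = 0.4), 4, 3)
  sel4 <- list(ring1 = 1:4, ring2 = 1:4, metal1 = 1L, metal2 = 1L,
               axes1 = cbind(rep(1, 4), c(2, 3, 4, 2)),
               axes2 = cbind(rep(1, 4), c(2, 3, 4, 2)))
  co4 <- array(0, c(2, 4, 3)); co4[1, , ] <- pa; co4[2, , ] <- pb
  e4 <- conformer_ensemble(co4, sel4)
  got <- pairwise_rmsd(e4, fit_atoms = 1:4)[1, 2]
  expect_lt(abs(got - grid_rmsd(pa, pb) / 10), 1e-4)
})

test_that("Daura clustering handles the degenerate cutoffs", {
  ens <- make_stacked_trajectory(seed = 2)
  rmat <- pairwise_rmsd(ens)
  # cutoff above the largest RMSD: one cluster with weight 1
  all_in <- daura_cluster(rmat, max(rmat) + 0.01)
  expect_equal(all_in$sizes, nrow(rmat))
  expect_equal(all_in$weights, 1)
  # cutoff below the smallest off-diagonal RMSD: all singletons
  singles <- daura_cluster(rmat, min(rmat[rmat > 0]) * 0.9)
  expect_equal(singles$sizes, rep(1L, nrow(rmat)))
  expect_equal(sum(singles$weights), 1)
})

test_that("planted 12/5/3 structure is recovered with correct weights and centers", {
  ens <- make_stacked_trajectory(seed = 42)
  rmat <- pairwise_rmsd(ens)
  cl <- daura_cluster(rmat, 0.10)
  expect_equal(cl$sizes, c(12L, 5L, 3L))
  expect_equal(cl$weights, c(0.60, 0.25, 0.15))
  expect_equal(cl$assignment, attr(ens, "labels"))
  expect_equal(sum(cl$weights), 1)
  # central structures minimize the mean RMSD to their cluster members
  # (brute-force check over all members)
  for (k in seq_along(cl$sizes)) {
    members <- which(cl$assignment == k)
    means <- vapply(members, function(f) mean(rmat[f, setdiff(members, f)]),
                    numeric(1))
    expect_equal(cl$central[k], members[which.min(means)])
  }
})

test_that("clustering is invariant under frame permutation up to relabeling", {
  ens <- make_stacked_trajectory(seed = 19)
  rmat <- pairwise_rmsd(ens)
  cl <- daura_cluster(rmat, 0.10)
  set.seed(5)
  perm <- sample(nrow(rmat))
  clp <- daura_cluster(rmat[perm, perm], 0.10)
  expect_equal(sort(clp$sizes), sort(cl$sizes))
  # membership sets agree after mapping back through the permutation
  orig_sets <- lapply(seq_along(cl$sizes),
                      function(k) sort(which(cl$assignment == k)))
  perm_sets <- lapply(seq_along(clp$sizes),
                      function(k) sort(perm[which(clp$assignment == k)]))
  expect_setequal(vapply(perm_sets, paste, character(1), collapse = ","),
                  vapply(orig_sets, paste, character(1), collapse = ","))
})

test_that("geometry descriptors reproduce the ideal stacking limits", {
  sel <- stacked_dimer_selections()
  cof <- vibronic:::stacked_frame(4.0, 0, 0)
  g <- geometry_descriptors(cof, sel)
  expect_equal(g$d_zn_zn, 4.0, tolerance = 1e-10)
  expect_equal(g$d_p_p, 4.0, tolerance = 1e-10)
  expect_equal(g$alpha, rep(90, 8), tolerance = 1e-8)
  expect_equal(g$beta, 0, tolerance = 1e-8)

  # rigid +1.55 A translation along the ring normal shifts d_P-P exactly
  shifted <- cof
  ring2 <- sel$ring2
  shifted[ring2, 3] <- shifted[ring2, 3] + 1.55
  g2 <- geometry_descriptors(shifted, sel)
  expect_equal(g2$d_p_p - g$d_p_p, 1.55, tolerance = 1e-10)
  expect_equal(g2$d_zn_zn - g$d_zn_zn, 1.55, tolerance = 1e-10)

  # twisting one ring about the shared normal changes beta only
  tw <- vibronic:::stacked_frame(4.0, -20, 0)
  g3 <- geometry_descriptors(tw, sel)
  expect_equal(g3$beta, -20, tolerance = 1e-8)
  expect_equal(g3$d_p_p, 4.0, tolerance = 1e-10)

  # tilting can make d_P-P and d_Zn-Zn differ
  ti <- vibronic:::stacked_frame(4.0, 0, 30)
  g4 <- geometry_descriptors(ti, sel)
  expect_equal(g4$d_zn_zn, 4.0, tolerance = 1e-10)
  expect_true(all(g4$alpha >= 0 & g4$alpha <= 90))
})

test_that("descriptors are invariant under global rigid motion", {
  sel <- stacked_dimer_selections()
  f <- vibronic:::stacked_frame(4.2, 25, 15)
  g <- geometry_descriptors(f, sel)
  th <- c(0.4, -1.1, 2.2)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3, 3)
  ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3, 3)
  rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  f2 <- f %*% t(rx %*% ry %*% rz) + matrix(c(10, -4, 7), nrow(f), 3, byrow = TRUE)
  g2 <- geometry_descriptors(f2, sel)
  expect_equal(g2$d_zn_zn, g$d_zn_zn, tolerance = 1e-9)
  expect_equal(g2$d_p_p, g$d_p_p, tolerance = 1e-9)
  expect_equal(g2$alpha, g$alpha, tolerance = 1e-9)
  expect_equal(g2$beta, g$beta, tolerance = 1e-9)
})

test_that("ordinary least squares matches closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- linear_correlation(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # constant y: R^2 = 0 by convention
  fit0 <- linear_correlation(x, rep(3, 5))
  expect_equal(fit0$r_squared, 0)

  # random six-point set vs the normal equations
  set.seed(10)
  x6 <- rnorm(6); y6 <- rnorm(6)
  fit6 <- linear_correlation(x6, y6)
  slope <- (sum(x6 * y6) - 6 * mean(x6) * mean(y6)) /
    (sum(x6^2) - 6 * mean(x6)^2)
  icept <- mean(y6) - slope * mean(x6)
  expect_equal(fit6$slope, slope, tolerance = 1e-12)
  expect_equal(fit6$intercept, icept, tolerance = 1e-12)
  expect_error(linear_correlation(rep(1, 5), x), "constant")
  expect_error(linear_correlation(1:2, 1:2), "3 points")
})

test_that("descriptor tables correlate distance with planted geometry", {
  e0 <- make_stacked_trajectory(frames_per_cluster = c(2, 2, 2), noise = 0.02,
                                seed = 3)
  df <- descriptor_table(e0)
  planted <- rep(c(3.4, 4.6, 5.8), each = 2)
  expect_lt(max(abs(df$d_zn_zn - planted)), 0.1)
  fit <- linear_correlation(planted, df$d_zn_zn)
  expect_gt(fit$r_squared, 0.99)
})
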