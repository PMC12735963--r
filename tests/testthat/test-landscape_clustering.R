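test_that("PCA recovers planted directions and satisfies model invariants", {
  set.seed(2)
  n <- 12
  base <- matrix(rnorm(n * 3, sd = 5), n, 3)
  dir1 <- matrix(rnorm(n * 3), n, 3); dir1 <- dir1 / sqrt(sum(dir1^2))
  frames <- lapply(1:60, function(k) base + rnorm(1, sd = 3) * dir1)
  pm <- pca_project(frames_to_ensemble(frames), align = FALSE)
  expect_gte(pm$explained[1], 0.99)

  expect_true(all(diff(pm$eigenvalues) <= 1e-9))
  expect_true(all(pm$eigenvalues >= -1e-12))
  gram <- crossprod(pm$loadings)
  expect_lt(max(abs(gram - diag(ncol(pm$loadings)))), 1e-8)
  expect_equal(nrow(pm$scores), 60)

  # isotropic noise: no dominant component
  iso <- lapply(1:300, function(k) base + matrix(rnorm(n * 3, sd = 1), n, 3))
  pm_iso <- pca_project(frames_to_ensemble(iso), align = FALSE)
  expect_lt(pm_iso$explained[1], 3 / (3 * n))

  # duplicating every frame leaves the eigenvectors unchanged
  pm_dup <- pca_project(frames_to_ensemble(c(frames, frames)), align = FALSE)
  expect_equal(abs(cor(pm_dup$loadings[, 1], pm$loadings[, 1])), 1,
               tolerance = 1e-9)
  expect_error(pca_project(frames_to_ensemble(frames[1:2])), "insufficient")
})

test_that("k-distance elbow separates cluster from outlier scales and scales homogeneously", {
  set.seed(5)
  blob1 <- cbind(rnorm(100, 0, 0.2), rnorm(100, 0, 0.2))
  blob2 <- cbind(rnorm(100, 6, 0.2), rnorm(100, 6, 0.2))
  outliers <- cbind(runif(20, -15, 20), runif(20, -15, 20))
  pts <- rbind(blob1, blob2, outliers)
  eps <- suppressWarnings(kdistance_eps(pts, k = 4))
  kd_out <- conflock:::.knn_distance(outliers, 1)
  # below the 5th percentile of outlier k-distances (outliers are mutually far)
  expect_lt(as.numeric(eps), quantile(conflock:::.knn_distance(pts, 4)[201:220], 0.05))
  expect_gt(as.numeric(eps), 0.1)

  eps_scaled <- suppressWarnings(kdistance_eps(pts * 3.7, k = 4))
  expect_equal(as.numeric(eps_scaled), 3.7 * as.numeric(eps), tolerance = 1e-9)

  grid <- as.matrix(expand.grid(seq(0, 1, length.out = 15),
                                seq(0, 1, length.out = 15)))
  expect_warning(e_grid <- kdistance_eps(grid, k = 4), "no")
  expect_true(is.finite(as.numeric(e_grid)) && as.numeric(e_grid) > 0)

  expect_error(kdistance_eps(pts[1:4, ], k = 4), "insufficient")
})

test_that("DBSCAN separates blobs, flags outliers, and honors degenerate settings", {
  set.seed(6)
  blob <- function(cx, n = 50) cbind(rnorm(n, cx, 0.3), rnorm(n, 0, 0.3))
  pts <- rbind(blob(0), blob(10), c(5, 0), c(5, 5), c(-5, 3))
  labels <- dbscan_cluster(pts, eps = 1.2, min_samples = 4)
  expect_equal(length(unique(labels[labels >= 0])), 2)
  expect_true(all(labels[101:103] == -1))
  expect_true(all(labels[1:50] == labels[1]))
  expect_true(all(labels[51:100] == labels[51]))

  same <- matrix(1, 7, 2)
  expect_equal(census(dbscan_cluster(same, eps = 0.5, min_samples = 7))$n_states, 1)

  set.seed(7)
  any_pts <- matrix(rnorm(40), 20, 2)
  l1 <- dbscan_cluster(any_pts, eps = 0.3, min_samples = 1)
  expect_true(all(l1 >= 0))  # every point core: noise impossible

  expect_error(dbscan_cluster(pts, eps = 0), "parameter error")
  expect_error(dbscan_cluster(pts, eps = 1, min_samples = 0), "parameter error")
})

test_that("DBSCAN matches the brute-force density-reachability oracle on random instances", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(30:200, 1)
    k_blobs <- sample(1:4, 1)
    centers <- matrix(runif(k_blobs * 2, -8, 8), k_blobs, 2)
    pts <- do.call(rbind, lapply(seq_len(k_blobs), function(b)
      matrix(rnorm(2 * ceiling(n / k_blobs), sd = runif(1, 0.2, 1.2)),
             ncol = 2) + matrix(centers[b, ], ceiling(n / k_blobs), 2,
                                byrow = TRUE)))
    pts <- rbind(pts, matrix(runif(2 * sample(0:15, 1), -12, 12), ncol = 2))
    eps <- runif(1, 0.3, 1.5)
    ms <- sample(2:6, 1)
    labels <- dbscan_cluster(pts, eps, ms)
    oracle <- oracle_dbscan(pts, eps, ms)
    # noise sets identical; cluster partition of core points identical
    expect_identical(which(labels == -1L), oracle$noise)
    mine_parts <- lapply(split(seq_len(nrow(pts)), labels)[
      as.character(sort(unique(labels[labels >= 0])))],
      function(ix) intersect(ix, oracle$core))
    expect_identical(canonical_partition(mine_parts),
                     canonical_partition(oracle$components))
  }
})

test_that("DBSCAN core partition and noise set are point-order invariant", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(100, sd = 0.4), ncol = 2),
               matrix(rnorm(100, sd = 0.4) + 6, ncol = 2),
               matrix(runif(30, -10, 16), ncol = 2))
  eps <- 0.8; ms <- 4
  l0 <- dbscan_cluster(pts, eps, ms)
  core0 <- oracle_dbscan(pts, eps, ms)$core
  for (t in 1:3) {
    perm <- sample(nrow(pts))
    lp <- dbscan_cluster(pts[perm, ], eps, ms)
    inv <- integer(nrow(pts)); inv[perm] <- seq_len(nrow(pts))
    lback <- lp[inv]
    expect_identical(which(lback == -1L), which(l0 == -1L))
    p1 <- lapply(split(core0, l0[core0]), sort)
    p2 <- lapply(split(core0, lback[core0]), sort)
    expect_identical(canonical_partition(p1), canonical_partition(p2))
  }
})

test_that("census arithmetic and population tables follow their definitions", {
  cen <- census(c(0L, 0L, 1L, -1L))
  expect_equal(cen$n_states, 2)
  expect_equal(cen$noise_fraction, 0.25)
  expect_equal(cen$largest_state_fraction, 0.5)
  expect_equal(sum(cen$populations) + cen$noise_fraction, 1, tolerance = 1e-9)

  all_noise <- census(rep(-1L, 10))
  expect_equal(all_noise$n_states, 0)
  expect_equal(all_noise$noise_fraction, 1)

  set.seed(10)
  labs <- sample(c(-1L, 0L, 1L, 2L), 200, replace = TRUE)
  shuf <- census(sample(labs))
  orig <- census(labs)
  expect_equal(shuf$populations, orig$populations)
  expect_equal(shuf$noise_fraction, orig$noise_fraction)

  pt <- population_table(census(c(rep(0L, 6), rep(1L, 4))))
  expect_equal(pt$fraction, c(0.6, 0.4, 0))
  pt10 <- population_table(census(rep(0:9, each = 10)))
  expect_equal(pt10$fraction, c(rep(0.1, 6), 0.4))

  # long-tail (Zipf-like) populations: Other outweighs each of S4-S6
  sizes <- round(200 / seq_len(12)^1.2)
  labs_z <- rep.int(seq_along(sizes) - 1L, sizes)
  ptz <- population_table(census(labs_z))
  other <- ptz$fraction[ptz$state == "Other"]
  expect_true(all(other > ptz$fraction[ptz$state %in% c("S4", "S5", "S6")]))
})

test_that("free-energy landscapes follow the Boltzmann inversion closed forms", {
  # all frames in one bin
  one <- matrix(0, 20, 2)  # degenerate range: every frame in the same bin
  f1 <- fel(one, n_bins = 4)
  expect_equal(min(f1$dG), 0)
  expect_equal(sum(f1$P), 1, tolerance = 1e-12)
  expect_true(all(f1$dG[f1$P == 0] > 0))
  expect_equal(max(f1$dG[f1$P > 0]), 0)  # single occupied bin is the mode

  # two occupied bins with 2:1 occupancy at 310 K
  pts <- rbind(matrix(rep(c(0, 0), 40), ncol = 2, byrow = TRUE),
               matrix(rep(c(10, 10), 20), ncol = 2, byrow = TRUE))
  f2 <- fel(pts, temperature = 310, n_bins = 2)
  occupied <- sort(f2$dG[f2$P > 0])
  expect_equal(occupied[2] - occupied[1], 0.0019872 * 310 * log(2),
               tolerance = 1e-9)
  expect_equal(occupied[2] - occupied[1], 0.427, tolerance = 5e-4)

  # uniform occupancy: flat landscape at zero
  grid_pts <- as.matrix(expand.grid(1:6, 1:6)) - 0.5
  f3 <- fel(grid_pts, n_bins = 6)
  expect_true(all(abs(f3$dG) < 1e-12))
  expect_error(fel(pts, n_bins = 1), "n_bins")
})

test_that("the fitted landscape ties census, FEL mode, and projection together", {
  spec <- synthetic_spec(n_residues = 30, n_basins = 3, basin_separation = 4,
                         intra_basin_sigma = 0.5, mean_dwell = 18,
                         target_noise_fraction = 0.10, n_replicates = 3,
                         n_frames = 300, seed = 44)
  sim <- simulate_ensemble(spec)
  cl <- suppressWarnings(
    conformational_landscape(sim$ensemble, which(sim$topology$calpha)))
  expect_s3_class(cl, "conf_landscape")
  expect_equal(cl$census$n_states, 3)
  expect_equal(cl$census$noise_fraction, sim$ground_truth$noise_fraction,
               tolerance = 0.02)

  # FEL modal bin coincides with the largest state's centroid bin
  mode_idx <- which(cl$fel$dG == 0, arr.ind = TRUE)[1, ]
  states <- cl$labels[cl$labels >= 0]
  biggest <- as.integer(names(which.max(table(states))))
  centroid <- colMeans(cl$pca$scores[cl$labels == biggest, 1:2, drop = FALSE])
  cbin <- c(findInterval(centroid[1], cl$fel$edges$pc1, rightmost.closed = TRUE),
            findInterval(centroid[2], cl$fel$edges$pc2, rightmost.closed = TRUE))
  expect_true(all(abs(unname(mode_idx) - cbin) <= 1))

  # frozen eps reuse gives the identical census
  cl2 <- conformational_landscape(sim$ensemble, which(sim$topology$calpha),
                                  eps = cl$eps)
  expect_identical(cl2$labels, cl$labels)
})
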