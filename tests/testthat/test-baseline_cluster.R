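test_that("the ANOVA prefilter removes unchanging signals", {
  flat <- signal("flat", 0:3, matrix(2, 4, 3))
  set.seed(3)
  strong <- signal("strong", 0:3,
                   matrix(c(0, 0, 0, 10), 4, 3) +
                     matrix(rnorm(12, 0, 0.01), 4, 3))
  res <- suppressWarnings(anova_filter(list(flat, strong), alpha = 0.05))
  expect_named(res$signals, "strong")

  res_all <- suppressWarnings(anova_filter(list(strong), alpha = 1.0))
  expect_length(res_all$signals, 1L)

  single <- signal("single", 0:3, matrix(1:4, 4, 1))
  expect_warning(res2 <- anova_filter(list(single)), "single-replicate")
  expect_identical(res2$skipped, "single")
})

test_that("z-scores center, scale and ignore affine shifts", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(20)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(3 * x + 7), z)
  expect_error(zscore(rep(2, 5)), "sd = 0")
})

test_that("k-means separates well-separated clouds deterministically", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 10, 4),
             matrix(rnorm(40, 5, 0.2), 10, 4))
  rownames(X) <- paste0("s", 1:20)
  r1 <- kmeans_signals(X, 2, seed = 7)
  expect_equal(length(unique(r1$assignments[1:10])), 1L)
  expect_equal(length(unique(r1$assignments[11:20])), 1L)
  expect_false(r1$assignments[1] == r1$assignments[20])

  r2 <- kmeans_signals(X, 2, seed = 7)
  expect_identical(r1$assignments, r2$assignments)

  r_all <- kmeans_signals(X, 20, seed = 1, restarts = 5)
  expect_equal(r_all$inertia, 0, tolerance = 1e-10)
})

test_that("the gap statistic recovers the number of blobs", {
  set.seed(15)
  centers <- diag(3)[rep(1:3, each = 12), ] * 4
  agree3 <- 0L
  agree1 <- 0L
  for (sd_ in 1:10) {
    X <- centers + matrix(rnorm(length(centers), 0, 0.05), nrow(centers))
    g <- gap_statistic(X, 1:6, n_refs = 25, seed = sd_)
    if (g$optimal_k == 3L) agree3 <- agree3 + 1L
    X1 <- matrix(rnorm(90, 0, 1), 30, 3)
    g1 <- gap_statistic(X1, 1:4, n_refs = 25, seed = sd_)
    if (g1$optimal_k == 1L) agree1 <- agree1 + 1L
  }
  expect_gte(agree3, 8L)
  expect_gte(agree1, 8L)
  expect_error(gap_statistic(centers, 1:3, n_refs = 0), "positive")
})

test_that("the gap table is consistent with cluster::clusGap", {
  set.seed(44)
  X <- rbind(matrix(rnorm(60, 0, 0.3), 15, 4),
             matrix(rnorm(60, 6, 0.3), 15, 4))
  g <- gap_statistic(X, 1:4, n_refs = 40, seed = 2)
  ref <- cluster::clusGap(X, function(x, k) {
    set.seed(99)
    list(cluster = stats::kmeans(x, k, nstart = 10)$cluster)
  }, K.max = 4, B = 40, spaceH0 = "original", verbose = FALSE)
  # same qualitative structure: large jump in gap from k=1 to k=2 and
  # the same chosen k under the Tibshirani rule
  kref <- cluster::maxSE(ref$Tab[, "gap"], ref$Tab[, "SE.sim"],
                         method = "firstSEmax")
  expect_equal(g$optimal_k, kref)
  expect_equal(which.max(diff(g$table$gap)) + 1L,
               which.max(diff(ref$Tab[, "gap"])) + 1L)
})

test_that("fidelity diagnostics flag signals far from their centroid", {
  set.seed(19)
  base <- sin(seq(0, pi, length.out = 8))
  X <- rbind(t(replicate(15, base + rnorm(8, 0, 0.05))),
             t(replicate(15, -base + rnorm(8, 0, 0.05))))
  rownames(X) <- paste0("s", 1:30)
  res <- kmeans_signals(X, 2, seed = 3)
  fid <- cluster_fidelity(res, X)
  expect_equal(nrow(fid$per_signal), 30L)
  expect_true(all(fid$per_signal$r2 > 0.9, na.rm = TRUE))

  # an anti-correlated member forced into the cluster has low R^2
  mixed <- rbind(X[1:15, ], matrix(-base, 1,
                                   dimnames = list("anti", NULL)))
  res_m <- list(assignments = stats::setNames(rep(1L, 16), rownames(mixed)),
                centroids = matrix(colMeans(mixed[1:15, ]), 1), k = 1L,
                inertia = 0)
  class(res_m) <- "tc_cluster"
  # squared Pearson is sign-blind; the regression-mode R^2 exposes the
  # anti-correlated member
  fid_m <- cluster_fidelity(res_m, mixed, r2_mode = "regression")
  expect_lt(fid_m$per_signal$r2[16], 0)
  expect_gt(fid_m$per_signal$n_outside_pi[16], 0L)
})

test_that("members equal to the centroid sit inside the interval", {
  set.seed(25)
  cen <- c(0, 1, 2, 1, 0)
  X <- t(replicate(30, cen + rnorm(5, 0, 0.1)))
  X[1, ] <- cen
  rownames(X) <- paste0("s", 1:30)
  res <- kmeans_signals(X, 1, seed = 1)
  fid <- cluster_fidelity(res, X)
  expect_equal(fid$per_signal$n_outside_pi[1], 0L)
  # the centroid is the mean of noisy members, so the planted member
  # correlates with it only up to the residual noise
  expect_equal(fid$per_signal$r2[1], 1, tolerance = 1e-2)
  # ~5% of points outside the 95% interval in expectation
  share <- mean(fid$per_signal$n_outside_pi) / 5
  expect_lt(share, 0.15)
})
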