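test_that("weights are inverse-SD, mean-normalized, scale-invariant", {
  expect_equal(compute_weights(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(compute_weights(c(1, 2, 4)), c(12 / 7, 6 / 7, 3 / 7))
  s <- c(0.3, 1.2, 0.8, 2)
  expect_equal(compute_weights(s), compute_weights(2 * s))
  expect_warning(w0 <- compute_weights(c(0, 0, 0)), "uniform")
  expect_equal(w0, c(1, 1, 1))
  expect_equal(mean(compute_weights(runif(8, 0.1, 3))), 1)
  # literal and uniform modes
  expect_equal(compute_weights(c(1, 2, 4), mode = "sd"),
               c(1, 2, 4) / mean(c(1, 2, 4)))
  expect_equal(compute_weights(c(1, 2, 4), mode = "uniform"), rep(1, 3))
})

test_that("the active-set QP matches quadprog on random instances", {
  set.seed(31)
  ctx <- shared_ctx()
  specs <- list(
    shape_spec(parent_shape("increasing"), integer(), 8),
    shape_spec(parent_shape("extrema", 1, "max"), 4L, 8),
    shape_spec(parent_shape("extrema", 2, "min"), c(2L, 5L), 8))
  for (r in 1:12) {
    sp <- specs[[(r %% 3) + 1L]]
    Cm <- build_constraints(sp, ctx$h, ctx$B)$C
    y <- rnorm(8)
    w <- compute_weights(runif(8, 0.3, 2))
    qt <- qp_terms(ctx$bm, w, y, 10^runif(1, -1, 3))
    res <- solve_constrained_qp(qt$G, qt$cvec, Cm)
    ref <- quadprog::solve.QP(qt$G, -qt$cvec, t(Cm), rep(0, nrow(Cm)))
    expect_equal(res$a, ref$solution, tolerance = 1e-6)
    # feasibility and KKT stationarity on the null space of active rows
    expect_gt(min(Cm %*% res$a), -1e-8 * (1 + max(abs(res$a))))
  }
})

test_that("empty constraint sets give the closed-form minimum", {
  set.seed(5)
  ctx <- shared_ctx()
  y <- rnorm(8)
  qt <- qp_terms(ctx$bm, rep(1, 8), y, 10)
  res <- solve_constrained_qp(qt$G, qt$cvec, NULL)
  expect_equal(res$a, drop(solve(qt$G, -qt$cvec)), tolerance = 1e-9)
  expect_length(res$active_rows, 0L)
})

test_that("a decreasing step forced increasing is flattened with active rows", {
  ctx4 <- fit_context(0:3, 1)
  sp <- shape_spec(parent_shape("increasing"), integer(), 4)
  Cm <- build_constraints(sp, ctx4$h, ctx4$B)$C
  y <- c(1, 0, 0.6, 0.2)
  qt <- qp_terms(ctx4$bm, rep(1, 4), y, 50)
  res <- solve_constrained_qp(qt$G, qt$cvec, Cm)
  expect_true(all(diff(res$a) >= -1e-9))
  expect_gt(length(res$active_rows), 0L)
})

test_that("null-space bases are orthonormal and annihilate active rows", {
  expect_equal(null_space_basis(NULL, 5), diag(5))
  CA <- matrix(c(1, -1, 0, 0), 1)
  Z <- null_space_basis(CA, 4)
  expect_equal(ncol(Z), 3L)
  expect_equal(max(abs(CA %*% Z)), 0, tolerance = 1e-12)
  expect_equal(crossprod(Z), diag(3), tolerance = 1e-12)
  Zf <- null_space_basis(diag(4), 4)
  expect_equal(ncol(Zf), 0L)
})

test_that("mGCV reduces to RSS/n at rho = 0 and is 0 for a perfect fit", {
  set.seed(6)
  ctx <- shared_ctx()
  y <- rnorm(8)
  w <- rep(1, 8)
  qt <- qp_terms(ctx$bm, w, y, 10)
  expect_equal(mgcv_score(y, y, w, 10, diag(8), qt$G), 0)
  a <- solve_constrained_qp(qt$G, qt$cvec, NULL)$a
  sc0 <- mgcv_score(a, y, w, 10, diag(8), qt$G, rho = 0)
  expect_equal(sc0, sum((a - y)^2) / 8)
  # fully determined fit is excluded
  expect_identical(mgcv_score(a, y, w, 10, matrix(0, 8, 0), qt$G), Inf)
})

test_that("AICc follows the printed formula and penalizes extrema", {
  expect_equal(aicc(8, 8, 0), 0)
  expect_equal(aicc(8, 8, 2), 6.4)
  expect_equal(aicc(8 * exp(1), 8, 0), 8)
  expect_identical(aicc(0, 8, 1), -Inf)
  expect_identical(aicc(1, 8, 8), Inf)
  vals <- vapply(0:4, function(k) aicc(3.7, 8, k), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("noise-free monotone data is fitted essentially exactly", {
  ctx <- shared_ctx()
  y <- 0.1 * ctx$times
  sp <- shape_spec(parent_shape("increasing"), integer(), 8)
  cand <- fit_shape(y, rep(1, 8), sp, ctx)
  expect_lt(cand$weighted_rss, 1e-6 * var(y))
  expect_lt(roughness(cand$model), 1e-8)
})

test_that("a degenerate grid of one lambda returns that lambda", {
  ctx <- shared_ctx()
  set.seed(3)
  y <- 0.1 * ctx$times + rnorm(8, 0, 0.01)
  sp <- shape_spec(parent_shape("increasing"), integer(), 8)
  cand <- fit_shape(y, rep(1, 8), sp, ctx, grid = 3.7)
  expect_equal(cand$lambda, 3.7)
})

test_that("model selection evaluates all 11 parent candidates", {
  s <- make_signal("Max4", noise_sd = 0.05, seed = 42)
  fit <- select_model(s, ctx = shared_ctx())
  expect_s3_class(fit, "tc_fit")
  expect_equal(fit$n_candidates, 11L)
  expect_setequal(names(fit$candidates),
                  c("I", "D", "max1", "min1", "max2", "min2", "max3",
                    "min3", "max4", "min4", "U"))
  aiccs <- vapply(fit$candidates, `[[`, 0, "aicc")
  expect_equal(fit$selected$aicc, min(aiccs))
})

test_that("a flat noise-free signal is labelled constant", {
  s <- suppressWarnings(signal("flat", doubling_times(), matrix(5, 8, 3)))
  fit <- suppressWarnings(
    select_model(s, ctx = shared_ctx(), grid = lambda_grid(count = 15L)))
  expect_identical(fit$label, "C")
})

test_that("single-peak signals recover their class and peak interval", {
  ctx <- shared_ctx()
  hits <- 0L
  for (i in 1:10) {
    s <- make_signal("Max4", noise_sd = 0.05, seed = 500 + i)
    fit <- suppressWarnings(select_model(s, ctx = ctx))
    if (fit$label == "Max4") hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("outliers at noisy time points shift the fit less than the mean", {
  # weighting robustness, directional: perturbing the highest-variance
  # point moves the weighted spline fit less than the replicate mean
  ctx <- shared_ctx()
  ok <- 0L
  for (i in 1:20) {
    cfg <- generator_config(class_label = "D", noise_sd = seq(0.02, 0.12,
                                                              length.out = 8),
                            seed = 900 + i)
    s <- generate_signal(cfg, "x")
    j <- which.max(s$sds)
    reps2 <- s$replicates
    reps2[j, 1] <- reps2[j, 1] + 3 * s$sds[j]
    s2 <- signal("x2", s$times, reps2)
    f1 <- suppressWarnings(select_model(s, ctx = ctx,
                                        grid = lambda_grid(count = 15L)))
    f2 <- suppressWarnings(select_model(s2, ctx = ctx,
                                        grid = lambda_grid(count = 15L)))
    d_spline <- abs(f2$selected$model$a[j] - f1$selected$model$a[j])
    d_mean <- abs(s2$means[j] - s$means[j])
    if (d_spline < d_mean) ok <- ok + 1L
  }
  expect_gte(ok, 12L)
})
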