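test_that("interval coefficients reproduce the local cubic conditions", {
  expect_equal(interval_coefficients(0, 1, 0, 0, 1), c(0, 0, 1, 0))
  expect_equal(interval_coefficients(0, 0, 0, 6, 1), c(1, 0, -1, 0))
  # s(0)=a_i, s(1)=a_{i+1}, s''(0)=c_i h^2, s''(1)=c_{i+1} h^2 in general
  set.seed(13)
  for (r in 1:20) {
    ai <- rnorm(1); an <- rnorm(1); ci <- rnorm(1); cn <- rnorm(1)
    h <- runif(1, 0.2, 5)
    k <- interval_coefficients(ai, an, ci, cn, h)
    expect_equal(k[4], ai)
    expect_equal(sum(k), an)
    expect_equal(2 * k[2], ci * h^2)
    expect_equal(6 * k[1] + 2 * k[2], cn * h^2)
  }
})

test_that("extrema are the stationary points of each interval cubic", {
  # u^3 - u on one interval: minimum at 1/sqrt(3)
  m <- structure(list(times = c(0, 1), a = c(0, 0), c = c(0, 6)),
                 class = "tc_spline")
  ex <- find_extrema(m)
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$type, "min")
  expect_equal(ex$time, 1 / sqrt(3), tolerance = 1e-9)

  line <- spline_model(0:4, 1:5)
  expect_equal(nrow(find_extrema(line)), 0L)

  peak <- spline_model(0:2, c(0, 1, 0))
  exp_ <- find_extrema(peak)
  expect_equal(nrow(exp_), 1L)
  expect_equal(exp_$time, 1)
  expect_equal(exp_$type, "max")
})

test_that("extrema agree with a dense-grid oracle on random fitted splines", {
  set.seed(17)
  ctx <- shared_ctx()
  parents <- enumerate_parent_shapes(4)
  for (r in 1:50) {
    s <- make_signal(sample(c("I", "D", "Max3", "Min3", "Max4",
                              "Min3,Max4"), 1),
                     noise_sd = 0.08, seed = 4000 + r)
    p <- parents[[sample(11, 1)]]
    cand <- tryCatch(
      fit_parent(s$means, compute_weights(s$sds), p, ctx,
                 grid = 10^runif(1, 0, 3)),
      error = function(e) NULL)
    if (is.null(cand)) next
    ex <- find_extrema(cand$model)
    orc <- grid_extrema_oracle(cand$model, pts = 1e4)
    expect_equal(nrow(ex), nrow(orc))
    if (nrow(ex) && nrow(ex) == nrow(orc)) {
      h_at <- diff(ctx$times)[ex$interval]
      expect_true(all(abs(ex$time - orc$time) <=
                        pmax(1e-3 * h_at, orc$resolution)))
    }
  }
})

test_that("extrema count never exceeds the enforced parent k", {
  set.seed(23)
  ctx <- shared_ctx()
  for (r in 1:10) {
    s <- make_signal(sample(c("Max3", "Min3,Max4", "I"), 1),
                     noise_sd = 0.1, seed = 6000 + r)
    for (k in 1:3) {
      p <- parent_shape("extrema", k, sample(c("max", "min"), 1))
      cand <- tryCatch(
        fit_parent(s$means, compute_weights(s$sds), p, ctx,
                   grid = lambda_grid(count = 11L)),
        error = function(e) NULL)
      if (is.null(cand)) next
      expect_lte(nrow(find_extrema(cand$model)), k)
    }
  }
})

test_that("extrema map to nearest knots with earlier-knot ties", {
  ex <- data.frame(time = c(1.0, 1.4, 0.5), value = 1, type = "max",
                   interval = 1L)
  out <- assign_to_knots(ex, c(0, 1, 2))
  expect_equal(out$nearest_knot, c(2L, 2L, 1L))
})

test_that("quasi-constant detection compares range to pooled noise", {
  s_flat <- signal("f", 0:3, matrix(5, 4, 3))
  expect_true(is_quasi_constant(s_flat))

  reps <- matrix(rep(c(0, 10, 0, 10), 3), 4, 3) +
    matrix(rnorm(12, 0, 0.1), 4, 3)
  expect_false(is_quasi_constant(signal("s", 0:3, reps)))

  reps2 <- rbind(c(1.0, 1.1, 0.9), c(1.05, 0.95, 1.1),
                 c(1.02, 0.9, 1.05), c(1.0, 1.08, 0.94))
  expect_true(is_quasi_constant(signal("q", 0:3, reps2)))
})

test_that("labels join extrema tokens in time order", {
  s <- make_signal("Min3,Max4", noise_sd = 0.03, seed = 77)
  fit <- select_model(s, ctx = shared_ctx())
  expect_identical(fit$label, "Min3,Max4")
  expect_equal(fit$extrema$type, c("min", "max"))

  s_i <- make_signal("I", noise_sd = 0.02, seed = 78)
  expect_identical(select_model(s_i, ctx = shared_ctx())$label, "I")
})

test_that("labels are invariant under positive affine transforms", {
  ctx <- shared_ctx()
  for (seed in c(101, 202)) {
    s <- make_signal("Max3", noise_sd = 0.05, seed = seed)
    s2 <- signal(s$id, s$times, 7.5 * s$replicates + 3)
    f1 <- suppressWarnings(select_model(s, ctx = ctx,
                                        grid = lambda_grid(count = 21L)))
    f2 <- suppressWarnings(select_model(s2, ctx = ctx,
                                        grid = lambda_grid(count = 21L)))
    expect_identical(f1$label, f2$label)
  }
})

test_that("alternation of Max/Min tokens holds for fitted labels", {
  set.seed(41)
  ctx <- shared_ctx()
  for (r in 1:10) {
    s <- make_signal(sample(c("Max3", "Min2,Max5", "Min3,Max4"), 1),
                     noise_sd = 0.08, seed = 8000 + r)
    fit <- suppressWarnings(select_model(s, ctx = ctx,
                                         grid = lambda_grid(count = 21L)))
    if (fit$label %in% c("I", "D", "C")) next
    types <- fit$extrema$type
    if (length(types) > 1L)
      expect_true(all(types[-1] != types[-length(types)]))
  }
})
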