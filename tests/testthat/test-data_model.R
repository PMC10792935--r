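test_that("signal construction derives means and SDs from replicates", {
  reps <- matrix(c(1, 2, 3, 4,
                   1, 2, 3, 4,
                   1, 2, 3, 4), 4, 3)
  s <- signal("P1", 0:3, reps)
  expect_equal(s$means, c(1, 2, 3, 4))
  expect_equal(s$sds, rep(0, 4))
  expect_equal(s$n_obs, rep(3L, 4))

  set.seed(1)
  reps2 <- matrix(rnorm(24), 8, 3)
  s2 <- signal("P2", doubling_times(), reps2)
  expect_equal(s2$means, rowMeans(reps2))
  expect_equal(s2$sds, apply(reps2, 1, sd))
})

test_that("signal flags single-replicate time points instead of sd = 0", {
  reps <- matrix(c(1, NA, NA,
                   2, 2.5, NA,
                   3, 3.1, 3.2,
                   4, 4.4, NA), 4, 3, byrow = TRUE)
  s <- signal("P1", 0:3, reps)
  expect_equal(s$n_obs, c(1L, 2L, 3L, 2L))
  expect_true(is.na(s$sds[1]))
  expect_false(any(is.na(s$sds[-1])))
})

test_that("signal rejects invalid inputs", {
  m <- matrix(1, 4, 2)
  expect_error(signal("x", c(0, 0, 1, 2), m), "strictly increasing")
  expect_error(signal("x", 0:2, matrix(1, 3, 2)), "at least 4")
  expect_error(signal("x", 0:3, matrix(NA_real_, 4, 2)), "non-missing")
})

test_that("interval widths follow the time grid", {
  expect_equal(interval_widths(0:3), c(1, 1, 1))
  expect_equal(interval_widths(doubling_times()),
               c(0.5, 0.5, 1, 2, 4, 8, 8))
  expect_error(interval_widths(c(0, 0)), "strictly increasing")
})

test_that("long-format reader builds one signal per id", {
  df <- expand.grid(time = c(0, 1, 2, 3), replicate = 1:3)
  df$id <- "P1"
  df$value <- df$time + 0.1 * df$replicate
  path <- tempfile(fileext = ".tsv")
  write.table(df[, c("id", "time", "replicate", "value")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  sigs <- read_signals(path)
  expect_length(sigs, 1L)
  expect_equal(length(sigs$P1$times), 4L)
  expect_equal(ncol(sigs$P1$replicates), 3L)
  expect_equal(sigs$P1$means, c(0, 1, 2, 3) + 0.2)
})

test_that("reader errors name bad rows and rejects duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("id\ttime\treplicate\tvalue",
               "P1\t0\t1\t1.0", "P1\t1\t1\toops",
               "P1\t2\t1\t3.0", "P1\t3\t1\t4.0"), path)
  expect_error(read_signals(path), "non-numeric")

  writeLines(c("id\ttime\treplicate\tvalue",
               "P1\t0\t1\t1.0", "P1\t0\t1\t1.5",
               "P1\t1\t1\t2.0", "P1\t2\t1\t3.0", "P1\t3\t1\t4.0"), path)
  expect_error(read_signals(path), "duplicate")
})

test_that("signals with fewer than 4 time points are skipped with warning", {
  df <- rbind(
    data.frame(id = "short", time = c(0, 1, 2), replicate = 1, value = 1:3),
    data.frame(id = "ok", time = 0:3, replicate = 1,
               value = c(1, 2, 3, 4)))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(sigs <- read_signals(path), "skipped")
  expect_named(sigs, "ok")
})

test_that("wide format and csv dialect are understood", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,0_1,0_2,1_1,1_2,2_1,2_2,3_1,3_2",
               "P1,1,1.2,2,2.2,3,3.2,4,4.2"), path)
  sigs <- read_signals(path, format = "wide")
  expect_equal(sigs$P1$means, c(1.1, 2.1, 3.1, 4.1))
})

test_that("result tables round-trip labels and numeric fields", {
  ds <- generate_dataset(list(I = 2, Max4 = 2),
                         generator_config(noise_sd = 0.03), seed = 11)
  ctx <- shared_ctx()
  fits <- lapply(ds$signals, select_model, ctx = ctx,
                 grid = lambda_grid(count = 15L))
  path <- tempfile(fileext = ".tsv")
  write_results(fits, path)
  back <- read_results(path)
  expect_equal(back$class_label, vapply(fits, `[[`, "", "label"))
  for (i in seq_along(fits)) {
    expect_equal(back$knot_values[[i]], fits[[i]]$selected$model$a,
                 tolerance = 1e-9)
    expect_equal(back$knot_curvatures[[i]], fits[[i]]$selected$model$c,
                 tolerance = 1e-9)
  }
  lab <- back$extrema[[which(back$n_extrema > 0)[1]]]
  expect_true(all(c("time", "value", "type", "nearest_knot") %in%
                    names(lab)))
})

test_that("writing an empty fit collection yields a header-only table", {
  path <- tempfile(fileext = ".tsv")
  write_results(list(), path)
  back <- read_results(path)
  expect_equal(nrow(back), 0L)
  expect_true(all(c("id", "class_label", "lambda") %in% names(back)))
})
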