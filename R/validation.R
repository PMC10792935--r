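#' The four reference curve fitters
#'
#' A common interface over (i) the constrained smoothing spline of this
#' package (full model selection on the reduced data, weights recomputed
#' from the remaining SDs), (ii) polynomial interpolation of the sample
#' means (unique degree n-1 interpolant, via an orthogonal-polynomial
#' regression that reproduces the means exactly), (iii) linear spline
#' interpolation, and (iv) natural cubic spline interpolation.  Each
#' fitter is called as `fitter(times, means, sds)` and returns a
#' prediction function of time.
#'
#' @param grid,rho,max_extrema passed to the constrained-spline fitter
#'   (see [select_model()]); the default grid is coarser than the main
#'   pipeline's because the fitter is refit many times during
#'   cross-validation.
#' @return named list of fitter functions (`smoothing`, `polynomial`,
#'   `linear`, `cubic`).
#' @export
reference_fitters <- function(grid = lambda_grid(count = 21L), rho = 1.3,
                              max_extrema = 4L) {
  list(
    smoothing = function(times, means, sds) {
      core <- fit_signal_core(times, means, sds, max_extrema = max_extrema,
                              grid = grid, rho = rho)
      model <- core$selected$model
      function(t) evaluate(model, t)
    },
    polynomial = function(times, means, sds) {
      df <- data.frame(t = times, y = means)
      fit <- stats::lm(y ~ poly(t, degree = length(times) - 1L), data = df)
      exact_at_knots(function(t)
        unname(stats::predict(fit, newdata = data.frame(t = t))),
        times, means)
    },
    linear = function(times, means, sds) {
      exact_at_knots(stats::approxfun(times, means), times, means)
    },
    cubic = function(times, means, sds) {
      exact_at_knots(stats::splinefun(times, means, method = "natural"),
                     times, means)
    })
}

# interpolants pass through the means by definition; guarantee that
# bitwise at the knots
exact_at_knots <- function(fun, times, means) {
  function(t) {
    out <- fun(t)
    hit <- match(t, times)
    out[!is.na(hit)] <- means[hit[!is.na(hit)]]
    out
  }
}

#' Leave-one-time-point-out robustness analysis
#'
#' For every inner time point of every signal, all its replicates are
#' deleted, each fitter is refit on the reduced series, and two distances
#' are recorded at the deleted time: to the fitter's original (full-data)
#' prediction, and to the original sample mean.  For interpolating
#' fitters the two are identical because the full-data prediction passes
#' through the mean.  An 8-point series yields 6 records per signal and
#' fitter.
#'
#' @param signals list of [signal()] objects (`n >= 5` so the reduced
#'   series keeps at least 4 points; smaller signals are skipped with a
#'   warning).
#' @param fitters named list from [reference_fitters()] (or any subset).
#' @param squared use squared instead of absolute distances.
#' @return data frame with columns `id`, `deleted_index`, `deleted_time`,
#'   `fitter`, `distance_to_original_prediction`,
#'   `distance_to_sample_mean`, `deleted_point_variance`.
#' @export
loo_time_point <- function(signals, fitters = reference_fitters(),
                           squared = FALSE) {
  recs <- list()
  dist_fun <- if (squared) function(x) x^2 else abs
  for (s in signals) {
    n <- length(s$times)
    if (n < 5L) {
      warning("signal '", s$id,
              "' skipped in LOO: deleting a point leaves fewer than 4")
      next
    }
    full_pred <- lapply(fitters, function(ft) ft(s$times, s$means, s$sds))
    for (j in 2:(n - 1L)) {
      tj <- s$times[j]
      for (fname in names(fitters)) {
        red <- fitters[[fname]](s$times[-j], s$means[-j], s$sds[-j])
        pj <- red(tj)
        recs[[length(recs) + 1L]] <- data.frame(
          id = s$id, deleted_index = j, deleted_time = tj, fitter = fname,
          distance_to_original_prediction = dist_fun(pj - full_pred[[fname]](tj)),
          distance_to_sample_mean = dist_fun(pj - s$means[j]),
          deleted_point_variance = s$sds[j]^2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) stop("no LOO records produced")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Variance-binned summary of LOO distances
#'
#' Splits the records into equal-count bins by the variance of the
#' deleted time point's replicates (bins shared across fitters) and
#' reports, per bin and fitter, the SD of the distances — the
#' high-variance bins expose how strongly each fitter chases noisy
#' points.
#'
#' @param records data frame from [loo_time_point()].
#' @param n_bins number of equal-count bins (reduced, with a message,
#'   when there are fewer deletion events than bins).
#' @param which distance column to summarize.
#' @return data frame `bin`, `mean_variance`, `fitter`, `sd_distance`,
#'   `n`.
#' @export
variance_binned_summary <- function(records, n_bins = 20L,
                                    which = "distance_to_original_prediction") {
  key <- paste(records$id, records$deleted_index, sep = "\r")
  uk <- !duplicated(key)
  events <- data.frame(key = key[uk],
                       variance = records$deleted_point_variance[uk],
                       stringsAsFactors = FALSE)
  if (nrow(events) < n_bins) {
    message("fewer deletion events (", nrow(events), ") than bins; using ",
            nrow(events), " bins")
    n_bins <- nrow(events)
  }
  rk <- rank(events$variance, ties.method = "first")
  events$bin <- ceiling(rk * n_bins / nrow(events))
  records$bin <- events$bin[match(key, events$key)]
  parts <- split(records, list(records$bin, records$fitter), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) data.frame(
    bin = d$bin[1L], mean_variance = mean(d$deleted_point_variance),
    fitter = d$fitter[1L], sd_distance = stats::sd(d[[which]]),
    n = nrow(d), stringsAsFactors = FALSE)))
  out <- out[order(out$fitter, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-subsampling smoothness analysis
#'
#' Do signals look smoother when the abundance estimate improves?  For
#' each requested replicate count, replicates are subsampled without
#' replacement at every time point, the per-time means recomputed, and
#' two smoothness measures extracted: the second derivative of the
#' natural cubic interpolant at the inner knots (curvature) and the
#' per-interval slope of the linear interpolant.  The variances of both
#' measures across signals and draws are reported per replicate count;
#' with i.i.d. replicate noise they decrease as replicates are added.
#'
#' @param signals list of [signal()] objects with at least
#'   `max(replicate_counts)` replicates each.
#' @param replicate_counts integer vector of replicate numbers to use.
#' @param n_draws random subsample draws per count.
#' @param seed integer seed.
#' @return data frame `replicates`, `curvature_variance`,
#'   `slope_variance`.
#' @export
replicate_subsample_smoothness <- function(signals, replicate_counts,
                                           n_draws = 10L, seed = 1L) {
  rmax <- min(vapply(signals, function(s) ncol(s$replicates), 0L))
  if (any(replicate_counts > rmax))
    stop("replicate count exceeds available replicates (", rmax, ")")
  set.seed(as.integer(seed))
  out <- lapply(sort(unique(as.integer(replicate_counts))), function(r) {
    curv <- numeric(0)
    slope <- numeric(0)
    for (d in seq_len(n_draws)) {
      for (s in signals) {
        cols <- sample.int(ncol(s$replicates), r)
        m <- rowMeans(s$replicates[, cols, drop = FALSE], na.rm = TRUE)
        sf <- stats::splinefun(s$times, m, method = "natural")
        inner <- s$times[-c(1L, length(s$times))]
        curv <- c(curv, sf(inner, deriv = 2L))
        slope <- c(slope, diff(m) / diff(s$times))
      }
    }
    data.frame(replicates = r, curvature_variance = stats::var(curv),
               slope_variance = stats::var(slope))
  })
  do.call(rbind, out)
}
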