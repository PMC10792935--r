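#' Configuration for the synthetic replicate time-series generator
#'
#' The defaults emulate a perturbation-response proteomics design:
#' 8 time points on a doubling schedule (0, 0.5, 1, 2, 4, 8, 16, 24 h,
#' sampling density matched to the expected rate of system response),
#' 3 replicates, and heteroscedasticity-capable Gaussian replicate noise.
#'
#' @param n_timepoints number of time points (used when `times` is
#'   `"doubling"`).
#' @param times numeric vector of time points, or `"doubling"` for
#'   `0, 0.5, 1, 2, 4, ...` (interval doubling at each step).
#' @param n_replicates replicates per time point.
#' @param class_label target temporal class (e.g. `"I"`, `"D"`, `"C"`,
#'   `"Max4"`, `"Min3,Max4"`).
#' @param amplitude dynamic range (max - min) of the latent curve, in
#'   signal units.
#' @param noise_sd replicate noise SD: scalar or per-time-point vector,
#'   in signal units.
#' @param outlier_rate per-cell probability of replacing a replicate by
#'   an outlier.
#' @param outlier_scale outlier offset in units of the local noise SD.
#' @param noise_dist `"gaussian"` or `"t3"` (heavy-tailed, 3 df).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `tc_genconfig`.
#' @export
generator_config <- function(n_timepoints = 8L, times = "doubling",
                             n_replicates = 3L, class_label = "I",
                             amplitude = 1, noise_sd = 0.05,
                             outlier_rate = 0, outlier_scale = 3,
                             noise_dist = c("gaussian", "t3"),
                             seed = NULL) {
  noise_dist <- match.arg(noise_dist)
  if (identical(times, "doubling")) {
    if (n_timepoints < 2L) stop("need at least 2 time points")
    # 0, 0.5, 1, 2, 4, ... with the final interval repeating the previous
    # one (0, 0.5, 1, 2, 4, 8, 16, 24 for n = 8)
    times <- c(0, 0.5 * 2^(0:(n_timepoints - 2L)))
    if (n_timepoints >= 3L) {
      nt <- length(times)
      times[nt] <- times[nt - 1L] + (times[nt - 1L] - times[nt - 2L])
    }
  }
  times <- as.numeric(times)
  n <- length(times)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must be in [0, 1]")
  noise_sd <- rep_len(noise_sd, n)
  structure(list(times = times, n_timepoints = n,
                 n_replicates = as.integer(n_replicates),
                 class_label = class_label, amplitude = amplitude,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 outlier_scale = outlier_scale, noise_dist = noise_dist,
                 seed = seed),
            class = "tc_genconfig")
}

# Parse "Max3,Min5"-style labels into (knot index, type) or one of the
# extremum-free classes.
parse_class_label <- function(label, n) {
  if (label %in% c("I", "D", "C"))
    return(list(kind = label, knots = integer(), types = character()))
  tokens <- strsplit(label, ",", fixed = TRUE)[[1L]]
  m <- regexec("^(Max|Min)([0-9]+)$", tokens)
  parts <- regmatches(tokens, m)
  if (any(vapply(parts, length, 1L) != 3L))
    stop("unparseable class label: ", label)
  types <- tolower(vapply(parts, `[`, "", 2L))
  knots <- as.integer(vapply(parts, `[`, "", 3L))
  if (any(knots <= 1L) || any(knots >= n))
    stop("label '", label, "' places an extremum at a boundary time point; ",
         "not realizable as a smooth latent curve")
  if (is.unsorted(knots, strictly = TRUE))
    stop("label '", label, "' must list extrema in strictly increasing ",
         "time order")
  if (length(types) > 1L && any(types[-1] == types[-length(types)]))
    stop("label '", label, "' has non-alternating extrema; not realizable")
  list(kind = "extrema", knots = knots, types = types)
}

# Temporal class realized by the natural-spline interpolant of knot
# values v.
.class_of_values <- function(times, v) {
  model <- spline_model(times, v)
  ex <- assign_to_knots(find_extrema(model), times)
  if (nrow(ex) == 0L) {
    if (v[length(v)] >= v[1L]) "I" else "D"
  } else {
    paste0(ifelse(ex$type == "max", "Max", "Min"), ex$nearest_knot,
           collapse = ",")
  }
}

#' Smooth latent curve realizing a temporal class
#'
#' Ground truth for recovery studies, built in three steps.  (1) Raw
#' target values at the measured time points are laid out with the
#' monotone cubic step `3u^2 - 2u^3` between anchors (curve ends and
#' extrema; maxima at `amplitude`, minima at 0), running in the
#' log-warped coordinate `tau = log(t - t_1 + h_1)`: response-rate
#' sampling designs such as the interval-doubling schedule place time
#' points where comparable change is expected per sample, so a realistic
#' kinetic changes by comparable amounts between consecutive samples.
#' (2) The raw values are presmoothed by the shape-constrained smoothing
#' spline itself (uniform weights, the label's own monotonicity pattern,
#' a fixed smoothing ladder, smoothest class-preserving member kept):
#' the generator's premise — shared with the classifier — is that real
#' molecular kinetics are smooth, so the ground truth is drawn from the
#' smooth shape family rather than from an arbitrarily rough curve.
#' (3) The latent curve is the natural cubic spline interpolant through
#' the presmoothed values, rescaled to dynamic range `amplitude`.
#' Construction fails if no ladder member realizes the requested label
#' exactly.
#'
#' @param class_label target label (extrema must be at interior time
#'   points; `"Max1,Max2"`-style non-alternating labels are rejected).
#' @param times time points.
#' @param amplitude dynamic range of the knot values.
#' @return vectorized function `f(t)` with attribute `"knot_values"`.
#' @export
latent_curve <- function(class_label, times, amplitude = 1) {
  n <- length(times)
  p <- parse_class_label(class_label, n)
  if (p$kind == "C") {
    f <- function(t) rep(amplitude, length(t))
    attr(f, "knot_values") <- rep(amplitude, n)
    return(f)
  }
  t1 <- times[1L]
  tau <- log(times - t1 + times[2L] - t1)
  if (p$kind %in% c("I", "D")) {
    u <- (tau - tau[1L]) / (tau[n] - tau[1L])
    v0 <- if (p$kind == "I") u else 1 - u
    spec <- shape_spec(parent_shape(
      if (p$kind == "I") "increasing" else "decreasing"), integer(), n)
  } else {
    ev <- ifelse(p$types == "max", 1, 0)
    ktau <- tau[p$knots]
    klast <- ktau[length(ktau)]
    v_start <- if (p$types[1L] == "max") 0 else 1
    v_end <- if (p$types[length(p$types)] == "max") 0 else 1
    # transient-response kinetics: smooth monotone runs into and between
    # the extrema; after the last extremum a first-order exponential
    # relaxation toward the opposite level (reaching it exactly at the
    # last time point)
    anchors_tau <- c(tau[1L], ktau)
    anchors_v <- c(v_start, ev)
    before <- tau <= klast
    v0 <- numeric(n)
    j <- findInterval(tau[before], anchors_tau, rightmost.closed = TRUE)
    j[j >= length(anchors_tau)] <- length(anchors_tau) - 1L
    j[j < 1L] <- 1L
    u <- (tau[before] - anchors_tau[j]) /
      (anchors_tau[j + 1L] - anchors_tau[j])
    u <- pmin(pmax(u, 0), 1)
    v0[before] <- anchors_v[j] + (anchors_v[j + 1L] - anchors_v[j]) *
      (3 * u^2 - 2 * u^3)
    if (any(!before)) {
      s <- (tau[!before] - klast) / (tau[n] - klast)
      relax <- exp(-3 * s) - s * exp(-3)  # 1 at s = 0, 0 at s = 1
      vlast <- ev[length(ev)]
      v0[!before] <- v_end + (vlast - v_end) * relax
    }
    # one free interval per extremum, alternating between the interval
    # left and right of its knot so that a monotone run separates (and
    # pins) consecutive extrema
    free_ints <- p$knots - rep_len(c(1L, 0L), length(p$knots))
    spec <- shape_spec(parent_shape("extrema", k = length(p$knots),
                                    start = p$types[1L]),
                       free_ints, n)
  }
  h <- interval_widths(times)
  bm <- build_band_matrices(h)
  Cm <- build_constraints(spec, h, derivative_matrix(h, bm))$C
  v <- NULL
  for (lam in c(300, 1000, 3000, 10000, 100)) {
    qt <- qp_terms(bm, rep(1, n), v0, lam)
    cand <- tryCatch(solve_constrained_qp(qt$G, qt$cvec, Cm)$a,
                     error = function(e) NULL)
    if (is.null(cand) || .class_of_values(times, cand) != class_label)
      next
    # extrema must stay well separated from the neighbouring levels,
    # otherwise try a less aggressive presmoothing
    levels <- cand[unique(c(1L, p$knots, n))]
    if (p$kind %in% c("I", "D") ||
        min(abs(diff(levels))) >= 0.25 * (max(cand) - min(cand))) {
      v <- cand
      break
    }
  }
  if (is.null(v))
    stop("no smooth latent curve realizes label '", class_label,
         "' on this time grid")
  v <- (v - min(v)) / (max(v) - min(v)) * amplitude
  f <- stats::splinefun(times, v, method = "natural")
  attr(f, "knot_values") <- v
  f
}

#' Generate one synthetic replicate signal
#'
#' Replicates are the latent curve plus i.i.d. noise per cell; with
#' probability `outlier_rate` a cell is instead displaced by
#' `+/- outlier_scale` noise SDs.  Reproducible for a fixed seed.
#'
#' @param config a [generator_config()].
#' @param id signal identifier.
#' @return a [signal()].
#' @export
generate_signal <- function(config, id = "S1") {
  stopifnot(inherits(config, "tc_genconfig"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  f <- latent_curve(config$class_label, config$times, config$amplitude)
  n <- config$n_timepoints
  r <- config$n_replicates
  mu <- f(config$times)
  noise <- if (config$noise_dist == "gaussian")
    stats::rnorm(n * r) else stats::rt(n * r, df = 3)
  reps <- matrix(mu + config$noise_sd * noise, n, r)
  if (config$outlier_rate > 0) {
    hit <- matrix(stats::runif(n * r) < config$outlier_rate, n, r)
    if (any(hit)) {
      sgn <- matrix(sample(c(-1, 1), n * r, replace = TRUE), n, r)
      disp <- mu + sgn * config$outlier_scale * config$noise_sd
      reps[hit] <- disp[hit]
    }
  }
  signal(id, config$times, reps)
}

#' Generate a labelled synthetic dataset
#'
#' @param class_mix named integer vector or list: class label ->
#'   number of signals.
#' @param config shared [generator_config()] (its `class_label` is
#'   overridden per signal).
#' @param seed integer seed controlling both the per-signal noise and the
#'   final deterministic shuffle.
#' @return list with `signals` (list of [signal()]) and `truth` (data
#'   frame `id`, `label`).
#' @export
generate_dataset <- function(class_mix, config = generator_config(),
                             seed = 1L) {
  labels <- rep(names(class_mix), times = unlist(class_mix))
  if (!length(labels))
    return(list(signals = list(), truth = data.frame(
      id = character(), label = character(), stringsAsFactors = FALSE)))
  set.seed(as.integer(seed))
  signals <- vector("list", length(labels))
  ids <- character(length(labels))
  counter <- integer(0)
  for (i in seq_along(labels)) {
    lb <- labels[i]
    counter[lb] <- if (is.na(counter[lb])) 1L else counter[lb] + 1L
    ids[i] <- paste0(gsub("[^A-Za-z0-9]", "", lb), "_", counter[lb])
    cfg <- config
    cfg$class_label <- lb
    cfg$seed <- NULL  # draw from the seeded stream
    signals[[i]] <- generate_signal(cfg, id = ids[i])
  }
  ord <- sample.int(length(labels))
  list(signals = signals[ord],
       truth = data.frame(id = ids[ord], label = labels[ord],
                          stringsAsFactors = FALSE))
}
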