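# Shared fixtures: everything is generated in code at test time.

doubling_times <- function() c(0, 0.5, 1, 2, 4, 8, 16, 24)

# one shared fitting context for the standard 8-point design
shared_ctx <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) ctx <<- fit_context(doubling_times(), 4L)
    ctx
  }
})

# a quick replicate signal of a given class
make_signal <- function(class_label = "Max4", noise_sd = 0.05, seed = 1,
                        id = "S1", ...) {
  cfg <- generator_config(class_label = class_label, noise_sd = noise_sd,
                          seed = seed, ...)
  generate_signal(cfg, id = id)
}

# dense-grid local-extremum oracle: scans `pts` points per interval on
# one global grid and reports slope sign changes.  Short zero-slope
# runs (constraint-pinned or tangency-degenerate extrema) are located
# at their midpoint with the run half-width reported as the oracle's
# localization resolution; zero-runs spanning a sizeable fraction of an
# interval are constant plateaus, which carry no point extremum under
# the per-interval root convention and are skipped.
grid_extrema_oracle <- function(model, pts = 1e4) {
  tt <- model$times
  n <- length(tt)
  g <- unlist(lapply(seq_len(n - 1L), function(i)
    seq(tt[i], tt[i + 1L], length.out = pts)[-pts]))
  g <- c(g, tt[n])
  v <- evaluate(model, g)
  dv <- diff(v)
  thr <- 1e-12 * max(abs(v), 1e-12)
  sgn <- sign(dv)
  sgn[abs(dv) < thr] <- 0
  nz <- which(sgn != 0L)
  plateau <- 0.45 * min(diff(tt))
  out <- list()
  if (length(nz) > 1L) {
    for (k in seq_len(length(nz) - 1L)) {
      i1 <- nz[k]
      i2 <- nz[k + 1L]
      if (sgn[i1] * sgn[i2] < 0) {
        gap <- g[i2] - g[i1 + 1L]
        if (gap >= plateau) next
        out[[length(out) + 1L]] <- data.frame(
          time = (g[i1 + 1L] + g[i2]) / 2,
          type = if (sgn[i1] > 0) "max" else "min",
          value = v[i1 + 1L],
          resolution = max(gap / 2, g[i1 + 1L] - g[i1]))
      }
    }
  }
  if (!length(out))
    return(data.frame(time = numeric(), type = character(),
                      value = numeric(), resolution = numeric()))
  ex <- do.call(rbind, out)
  ex <- ex[order(ex$time), , drop = FALSE]
  # same prominence convention as find_extrema: alternating wiggles
  # below the solver's value resolution are noise
  tol_prom <- 1e-6 * (1 + max(abs(v)))
  repeat {
    m <- nrow(ex)
    if (m == 0L) break
    vals <- c(v[1L], ex$value, v[length(v)])
    gaps <- abs(diff(vals))
    if (m >= 2L) {
      pair <- which(gaps[2:m] < tol_prom)
      if (length(pair)) {
        ex <- ex[-c(pair[1L], pair[1L] + 1L), , drop = FALSE]
        next
      }
    }
    single <- which(pmax(gaps[-(m + 1L)], gaps[-1L]) < tol_prom)
    if (length(single)) {
      ex <- ex[-single[1L], , drop = FALSE]
      next
    }
    break
  }
  ex
}

# textbook penalized-spline oracle: exact quadratic assembled from
# stats::splinefun second derivatives and Simpson integration (the
# squared second derivative of a natural cubic spline is piecewise
# quadratic, so Simpson per interval is exact)
oracle_roughness_matrix <- function(times) {
  n <- length(times)
  rough <- function(f) {
    sf <- stats::splinefun(times, f, method = "natural")
    r <- 0
    for (i in seq_len(n - 1L)) {
      g <- c(times[i], (times[i] + times[i + 1L]) / 2, times[i + 1L])
      s2 <- sf(g, deriv = 2L)^2
      r <- r + (times[i + 1L] - times[i]) / 6 * (s2[1] + 4 * s2[2] + s2[3])
    }
    r
  }
  M <- matrix(0, n, n)
  basis <- diag(n)
  qf <- vapply(seq_len(n), function(i) rough(basis[i, ]), 0)
  for (i in seq_len(n))
    for (j in seq_len(n))
      M[i, j] <- if (i == j) qf[i] else
        (rough(basis[i, ] + basis[j, ]) - qf[i] - qf[j]) / 2
  M
}

oracle_smoothing_fit <- function(times, y, w, lambda,
                                 M = oracle_roughness_matrix(times)) {
  n <- length(y)
  solve(M + (lambda / n) * diag(w^2), (lambda / n) * (w^2 * y))
}
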