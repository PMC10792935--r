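#' Local cubic coefficients of one spline interval
#'
#' On interval `i` the spline in the local coordinate `u = (t - t_i)/h_i`
#' (so `u` runs over `[0, 1]`) is `s(u) = k1 u^3 + k2 u^2 + k3 u + k4`
#' with curvatures rescaled by the chain rule (`chat = c * h^2`):
#' `k1 = (chat_{i+1} - chat_i)/6`, `k2 = chat_i/2`,
#' `k3 = a_{i+1} - a_i - chat_i/3 - chat_{i+1}/6`, `k4 = a_i`.  These are
#' the unique coefficients with `s(0) = a_i`, `s(1) = a_{i+1}`,
#' `s''(0) = chat_i`, `s''(1) = chat_{i+1}`.
#'
#' @param a_i,a_next knot values at the interval ends.
#' @param c_i,c_next knot second derivatives (in original `t` units).
#' @param h interval width.
#' @return numeric vector `c(k1, k2, k3, k4)`.
#' @export
interval_coefficients <- function(a_i, a_next, c_i, c_next, h) {
  ci <- c_i * h^2
  cn <- c_next * h^2
  c((cn - ci) / 6, ci / 2, a_next - a_i - ci / 3 - cn / 6, a_i)
}

#' Extract the extrema of a fitted spline
#'
#' Per interval, the stationary points are the real roots of the
#' quadratic `s'(u) = 3 k1 u^2 + 2 k2 u + k3` inside `[0, 1)` (the final
#' interval uses `[0, 1]`); the type follows the sign of `s''` at the
#' root, and roots where `s''` vanishes (inflections/saddles) are
#' discarded.  The half-open convention avoids double-counting roots that
#' coincide with shared knots.
#'
#' @param model a `tc_spline`.
#' @return data frame with columns `time`, `value`, `type` (`"max"` /
#'   `"min"`), `interval`, sorted by `time` (zero rows when the spline is
#'   monotone).
#' @export
find_extrema <- function(model) {
  tt <- model$times
  n <- length(tt)
  scale_a <- max(abs(model$a), 1e-12)
  # curvature magnitude of the whole model in local (unit-interval)
  # coordinates; tangency artefacts of constrained fits sit many orders
  # of magnitude below it
  # the 1e-3 * scale floor keeps the typing threshold above the float
  # noise that exactly-constant fits carry in their curvatures
  h_all <- diff(tt)
  s2_scale <- max(abs(model$c[-n] * h_all^2), abs(model$c[-1] * h_all^2),
                  scale_a * 1e-3)
  out <- list()
  for (i in seq_len(n - 1L)) {
    h <- tt[i + 1L] - tt[i]
    k <- interval_coefficients(model$a[i], model$a[i + 1L],
                               model$c[i], model$c[i + 1L], h)
    ks <- max(abs(k), scale_a * .Machine$double.eps)
    A <- 3 * k[1]; Bq <- 2 * k[2]; Cq <- k[3]
    roots <- numeric(0)
    if (abs(A) <= 1e-12 * ks) {
      if (abs(Bq) > 1e-12 * ks) roots <- -Cq / Bq
    } else {
      disc <- Bq^2 - 4 * A * Cq
      if (disc >= 0) {
        sq <- sqrt(disc)
        # numerically stable quadratic roots
        q <- -(Bq + sign(Bq + (Bq == 0)) * sq) / 2
        roots <- unique(c(q / A, if (q != 0) Cq / q else -Bq / A - q / A))
      }
    }
    hi <- if (i == n - 1L) 1 + 1e-12 else 1
    roots <- roots[roots >= -1e-12 & roots < hi]
    for (u in roots) {
      s2 <- 6 * k[1] * u + 2 * k[2]
      type <- if (abs(s2) > 1e-6 * s2_scale) {
        if (s2 < 0) "max" else "min"
      } else {
        # degenerate stationary point (s'' ~ 0, typical when an active
        # monotonicity constraint pins the extremum to a knot): decide by
        # the slope sign change across the point, probing into the
        # neighbouring intervals; no sign change means an inflection or
        # a tangency artefact
        tr <- tt[i] + u * h
        delta <- 0.05 * h
        pl <- evaluate(model, max(tr - delta, tt[1]), deriv = 1L)
        pr <- evaluate(model, min(tr + delta, tt[n]), deriv = 1L)
        stol <- 1e-6 * (max(model$a) - min(model$a) +
                          scale_a * 1e-3) / h
        if (pl > stol && pr < -stol) "max"
        else if (pl < -stol && pr > stol) "min"
        else NA_character_
      }
      if (is.na(type)) next
      out[[length(out) + 1L]] <- data.frame(
        time = tt[i] + u * h,
        value = k[1] * u^3 + k[2] * u^2 + k[3] * u + k[4],
        type = type,
        interval = i, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(time = numeric(), value = numeric(),
                      type = character(), interval = integer(),
                      stringsAsFactors = FALSE))
  ex <- do.call(rbind, out)
  ex <- ex[order(ex$time), , drop = FALSE]
  # drop duplicate positions (roots landing on shared knots)
  keep <- c(TRUE, diff(ex$time) > 1e-10 * (tt[n] - tt[1]))
  ex <- ex[keep, , drop = FALSE]
  # prominence pruning: the QP solves knot values to a tolerance
  # relative to their magnitude, so alternating wiggles separated by
  # less than that resolution are solver noise, not structure
  tol_prom <- 1e-6 * (1 + scale_a)
  repeat {
    m <- nrow(ex)
    if (m == 0L) break
    vals <- c(model$a[1L], ex$value, model$a[n])
    gaps <- abs(diff(vals))   # length m + 1
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
  rownames(ex) <- NULL
  ex
}

#' Assign extrema to their nearest knots
#'
#' @param extrema data frame from [find_extrema()].
#' @param times knot positions.
#' @return the data frame with an added 1-based `nearest_knot` column
#'   (ties go to the earlier knot).
#' @export
assign_to_knots <- function(extrema, times) {
  extrema$nearest_knot <- vapply(extrema$time, function(p)
    which.min(abs(times - p)), 0L)
  extrema
}

#' Is a signal quasi-constant?
#'
#' A signal whose dynamic range does not exceed `threshold` times its
#' pooled replicate standard deviation carries no evidence of real
#' temporal change and is labelled constant rather than classified by
#' extrema.  The pooled SD combines per-time-point variances with their
#' degrees of freedom.
#'
#' @param sig a [signal()].
#' @param threshold range-to-noise multiplier (default 1).
#' @return logical.
#' @export
is_quasi_constant <- function(sig, threshold = 1) {
  rng <- max(sig$means) - min(sig$means)
  if (rng == 0) return(TRUE)
  df <- pmax(sig$n_obs - 1L, 0L)
  ok <- df > 0L & !is.na(sig$sds)
  if (!any(ok)) return(FALSE)
  pooled <- sqrt(sum(df[ok] * sig$sds[ok]^2) / sum(df[ok]))
  rng <= threshold * pooled
}

#' Temporal class label of a fitted signal
#'
#' Quasi-constant signals are labelled `"C"`.  Otherwise the selected
#' model's extrema are assigned to their nearest time points and joined
#' into tokens like `"Min3,Max4"`; a spline without extrema is labelled
#' `"I"` or `"D"` by its end-to-end trend.  Two extrema sharing a nearest
#' knot are merged to the dominant one (largest deviation from the mean
#' level), with a warning, and alternation of Max/Min tokens is restored
#' by dropping the less prominent of any same-type neighbours.
#'
#' @param fit a `tc_fit` from [select_model()] (or any list with a
#'   `selected$model` spline).
#' @param sig the corresponding [signal()].
#' @param threshold quasi-constant threshold, see [is_quasi_constant()].
#' @return list with `label` (string) and `extrema` (data frame with
#'   `nearest_knot`).
#' @export
temporal_label <- function(fit, sig, threshold = 1) {
  model <- fit$selected$model
  empty <- data.frame(time = numeric(), value = numeric(),
                      type = character(), interval = integer(),
                      nearest_knot = integer(), stringsAsFactors = FALSE)
  if (is_quasi_constant(sig, threshold))
    return(list(label = "C", extrema = empty))
  ex <- find_extrema(model)
  if (nrow(ex) == 0L) {
    a <- model$a
    lab <- if (a[length(a)] >= a[1]) "I" else "D"
    return(list(label = lab, extrema = empty))
  }
  ex <- assign_to_knots(ex, model$times)
  level <- mean(model$a)
  ex$prominence <- abs(ex$value - level)
  # merge extrema sharing a nearest knot, keeping the dominant one
  if (anyDuplicated(ex$nearest_knot)) {
    warning("signal '", fit$id,
            "': multiple extrema mapped to one knot; keeping the dominant")
    keep <- unlist(lapply(split(seq_len(nrow(ex)), ex$nearest_knot),
                          function(ii) ii[which.max(ex$prominence[ii])]))
    ex <- ex[sort(keep), , drop = FALSE]
  }
  # restore Max/Min alternation if merging broke it
  repeat {
    same <- which(ex$type[-1] == ex$type[-nrow(ex)])
    if (!length(same) || nrow(ex) < 2L) break
    j <- same[1L]
    drop_j <- if (ex$prominence[j] < ex$prominence[j + 1L]) j else j + 1L
    ex <- ex[-drop_j, , drop = FALSE]
  }
  ex$prominence <- NULL
  rownames(ex) <- NULL
  tokens <- paste0(ifelse(ex$type == "max", "Max", "Min"), ex$nearest_knot)
  list(label = paste(tokens, collapse = ","), extrema = ex)
}
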