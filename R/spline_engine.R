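#' Band matrices of the natural cubic spline roughness penalty
#'
#' For knots at the measured time points with interval widths `h`, the
#' natural cubic spline in the value/second-derivative representation is
#' governed by the symmetric tridiagonal matrix `D` ((n-2) x (n-2), with
#' diagonal `(h_i + h_{i+1})/3` and off-diagonal `h_i/6`) and the banded
#' matrix `H` ((n-2) x n, rows `1/h_i, -(h_i + h_{i+1})/(h_i h_{i+1}),
#' 1/h_{i+1}`).  Interior knot curvatures satisfy `D c = H a` and the
#' roughness integral of the spline equals `a' H' D^-1 H a`.
#'
#' @param h positive interval widths (length `n - 1`, `n >= 3`).
#' @return list with elements `D`, `H` and `n`.
#' @examples
#' build_band_matrices(c(1, 1))  # D = 2/3, H = (1, -2, 1)
#' @export
build_band_matrices <- function(h) {
  h <- as.numeric(h)
  if (any(h <= 0)) stop("interval widths must be positive")
  n <- length(h) + 1L
  if (n < 3L) stop("need at least 3 knots (one interior knot)")
  m <- n - 2L
  D <- matrix(0, m, m)
  H <- matrix(0, m, n)
  for (i in seq_len(m)) {
    D[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i < m) {
      D[i, i + 1L] <- h[i + 1L] / 6
      D[i + 1L, i] <- h[i + 1L] / 6
    }
    H[i, i] <- 1 / h[i]
    H[i, i + 1L] <- -(h[i] + h[i + 1L]) / (h[i] * h[i + 1L])
    H[i, i + 2L] <- 1 / h[i + 1L]
  }
  list(D = D, H = H, n = n)
}

#' Knot curvatures of the natural spline through given knot values
#'
#' Solves the tridiagonal system `D c = H a` for the interior second
#' derivatives and pads the natural boundary conditions `c_1 = c_n = 0`.
#' `D` is factorized, never inverted.
#'
#' @param bm band matrices from [build_band_matrices()].
#' @param a knot values (length `n`).
#' @return numeric vector `c` of length `n`.
#' @export
curvatures_from_values <- function(bm, a) {
  if (length(a) != bm$n) stop("length(a) must equal the number of knots")
  c(0, solve(bm$D, bm$H %*% as.numeric(a)), 0)
}

#' Assemble a fitted spline model
#'
#' Bundles knot values with the derived curvatures into an evaluable
#' natural cubic spline.
#'
#' @param times knot positions (the measured time points).
#' @param a knot values.
#' @param lambda smoothing factor used for the fit (`NA` for interpolants).
#' @param weights observation weights used for the fit.
#' @param shape the shape spec the fit was constrained to, or
#'   `"unconstrained"`.
#' @param active_rows indices of constraint rows active at the solution.
#' @return object of class `tc_spline`.
#' @export
spline_model <- function(times, a, lambda = NA_real_, weights = NULL,
                         shape = "unconstrained", active_rows = integer()) {
  times <- as.numeric(times)
  a <- as.numeric(a)
  stopifnot(length(times) == length(a))
  bm <- build_band_matrices(interval_widths(times))
  structure(
    list(times = times, a = a, c = curvatures_from_values(bm, a),
         lambda = lambda, weights = weights, shape = shape,
         active_rows = active_rows),
    class = "tc_spline")
}

#' @export
print.tc_spline <- function(x, ...) {
  cat("<tc_spline> ", length(x$times), " knots on [", x$times[1], ", ",
      x$times[length(x$times)], "], lambda = ", format(x$lambda), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a fitted spline
#'
#' Piecewise cubic evaluation in the value/curvature representation: on
#' `[t_i, t_{i+1}]` the spline is
#' `a_i (t_{i+1}-t)/h + a_{i+1} (t-t_i)/h + (c_i/6)((t_{i+1}-t)^3/h -
#' h (t_{i+1}-t)) + (c_{i+1}/6)((t-t_i)^3/h - h (t-t_i))`.
#' No extrapolation: `t` outside the knot range is an error.
#'
#' @param model a `tc_spline`.
#' @param t scalar or vector of evaluation points within the knot range.
#' @param deriv derivative order 0, 1 or 2.
#' @return numeric vector of values.
#' @export
evaluate <- function(model, t, deriv = 0L) {
  tt <- model$times
  n <- length(tt)
  t <- as.numeric(t)
  eps <- 1e-9 * (tt[n] - tt[1])
  if (any(t < tt[1] - eps | t > tt[n] + eps))
    stop("evaluation point outside the knot range [", tt[1], ", ", tt[n],
         "]; no extrapolation")
  t <- pmin(pmax(t, tt[1]), tt[n])
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  i[i >= n] <- n - 1L
  h <- tt[i + 1L] - tt[i]
  dl <- tt[i + 1L] - t   # distance to left.. (t_{i+1} - t)
  dr <- t - tt[i]
  a <- model$a; cc <- model$c
  if (deriv == 0L) {
    a[i] * dl / h + a[i + 1L] * dr / h +
      (cc[i] / 6) * (dl^3 / h - h * dl) +
      (cc[i + 1L] / 6) * (dr^3 / h - h * dr)
  } else if (deriv == 1L) {
    (a[i + 1L] - a[i]) / h +
      (cc[i] / 6) * (-3 * dl^2 / h + h) +
      (cc[i + 1L] / 6) * (3 * dr^2 / h - h)
  } else if (deriv == 2L) {
    cc[i] * dl / h + cc[i + 1L] * dr / h
  } else stop("deriv must be 0, 1 or 2")
}

#' @export
predict.tc_spline <- function(object, newdata, deriv = 0L, ...) {
  evaluate(object, newdata, deriv = deriv)
}

#' Integrated squared curvature of a fitted spline
#'
#' Returns the roughness integral of the squared second derivative over
#' the knot range, computed exactly as the quadratic form
#' `a' H' D^-1 H a` of the natural spline representation.
#'
#' @param model a `tc_spline`.
#' @return non-negative scalar.
#' @export
roughness <- function(model) {
  bm <- build_band_matrices(interval_widths(model$times))
  v <- bm$H %*% model$a
  drop(crossprod(v, solve(bm$D, v)))
}

#' Quadratic-program form of the penalized spline criterion
#'
#' The minimization of `roughness + (lambda/n) ||W(a - y)||^2` over knot
#' values `a` is the quadratic program `min (1/2) a' G a + c' a` with
#' `G = 2 (H' D^-1 H + (lambda/n) W'W)` and `c = -2 (lambda/n) W'W y`.
#'
#' @param bm band matrices from [build_band_matrices()].
#' @param w diagonal of the observation weight matrix `W` (length `n`).
#' @param y observed per-time-point means (length `n`).
#' @param lambda smoothing factor, `>= 0` (larger = closer to the data;
#'   `lambda -> Inf` interpolates, `lambda -> 0` approaches the weighted
#'   least-squares line).
#' @return list with matrix `G` and vector `cvec`.
#' @export
qp_terms <- function(bm, w, y, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  n <- bm$n
  stopifnot(length(w) == n, length(y) == n)
  K <- crossprod(bm$H, solve(bm$D, bm$H))
  w2 <- as.numeric(w)^2
  G <- 2 * (K + (lambda / n) * diag(w2, n))
  cvec <- -2 * (lambda / n) * (w2 * as.numeric(y))
  list(G = G, cvec = cvec)
}

# Penalty kernel H' D^-1 H (shared by qp_terms and the fit sweep).
penalty_kernel <- function(bm) {
  crossprod(bm$H, solve(bm$D, bm$H))
}
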