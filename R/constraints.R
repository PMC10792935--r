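#' Parent shapes of a constrained temporal profile
#'
#' A parent shape fixes the number of extrema (0-4) and the type of the
#' first one (maximum or minimum), or leaves the curve unconstrained.
#' With up to 4 extrema this gives 10 constrained parent shapes plus the
#' unconstrained case, i.e. 11 candidate fits per signal.
#'
#' @param kind one of `"increasing"`, `"decreasing"`, `"extrema"`,
#'   `"unconstrained"`.
#' @param k number of extrema (only for `kind = "extrema"`).
#' @param start `"max"` or `"min"`: type of the first extremum.
#' @return object of class `tc_parent`.
#' @export
parent_shape <- function(kind = c("increasing", "decreasing", "extrema",
                                  "unconstrained"),
                         k = 0L, start = NULL) {
  kind <- match.arg(kind)
  if (kind == "extrema") {
    if (k < 1L || k > 4L) stop("extrema parent needs k in 1..4")
    start <- match.arg(start, c("max", "min"))
  } else {
    k <- 0L
    start <- NULL
  }
  structure(list(kind = kind, k = as.integer(k), start = start),
            class = "tc_parent")
}

parent_shape_id <- function(p) {
  switch(p$kind,
         increasing = "I", decreasing = "D", unconstrained = "U",
         extrema = paste0(p$start, p$k))
}

#' Enumerate all parent shapes
#'
#' @param max_extrema maximum number of extrema allowed (0-4; the method
#'   caps this at 4 to keep the shape space manageable).
#' @return list of [parent_shape()] objects in deterministic order:
#'   increasing, decreasing, extrema shapes by `k` then start type
#'   (max before min), unconstrained last.
#' @examples
#' length(enumerate_parent_shapes(4))  # 11
#' @export
enumerate_parent_shapes <- function(max_extrema = 4L) {
  if (max_extrema < 0L || max_extrema > 4L)
    stop("max_extrema must be between 0 and 4")
  out <- list(parent_shape("increasing"), parent_shape("decreasing"))
  for (k in seq_len(max_extrema))
    for (st in c("max", "min"))
      out <- c(out, list(parent_shape("extrema", k, st)))
  c(out, list(parent_shape("unconstrained")))
}

#' Shape specification: a parent shape with a concrete extrema placement
#'
#' Each of the `n - 1` inter-timepoint intervals is labelled increasing
#' (+1), decreasing (-1) or free (0).  The free intervals are exactly the
#' intervals hosting the extrema; intervals before/between/after them get
#' alternating monotone senses consistent with the extremum types
#' (increasing before a maximum, decreasing after it, mirrored for
#' minima).
#'
#' @param parent a [parent_shape()].
#' @param extremum_intervals strictly increasing interval indices
#'   (1-based, in `1..n-1`) hosting the extrema; empty for monotone or
#'   unconstrained parents.
#' @param n number of time points.
#' @return object of class `tc_shape` with fields `parent`,
#'   `extremum_intervals` and `senses` (length `n - 1`).
#' @export
shape_spec <- function(parent, extremum_intervals = integer(), n) {
  ni <- n - 1L
  ei <- as.integer(extremum_intervals)
  if (length(ei) && (any(ei < 1L) || any(ei > ni)))
    stop("extremum interval index out of range 1..", ni)
  if (is.unsorted(ei, strictly = TRUE) && length(ei) > 1L)
    stop("extremum intervals must be strictly increasing")
  senses <- switch(parent$kind,
    unconstrained = rep(0L, ni),
    increasing = rep(1L, ni),
    decreasing = rep(-1L, ni),
    extrema = {
      if (length(ei) != parent$k)
        stop("need exactly ", parent$k, " extremum intervals")
      s <- integer(ni)
      # sense of the run before extremum j: +1 if extremum j is a max
      types <- rep_len(if (parent$start == "max") c(1L, -1L) else c(-1L, 1L),
                       parent$k)
      bounds <- c(0L, ei, ni + 1L)
      for (j in seq_len(parent$k + 1L)) {
        run <- seq.int(bounds[j] + 1L, bounds[j + 1L] - 1L)
        run <- run[run >= 1L & run <= ni]
        # before extremum j the curve heads toward it; after the last it
        # continues away from it
        s[run] <- if (j <= parent$k) types[j] else -types[parent$k]
      }
      s[ei] <- 0L
      s
    })
  structure(list(parent = parent, extremum_intervals = ei, senses = senses),
            class = "tc_shape")
}

#' Enumerate all extrema placements of a parent shape
#'
#' Monotone and unconstrained parents admit a single placement; a parent
#' with `k` extrema admits every strictly increasing `k`-subset of the
#' `n - 1` intervals.
#'
#' @param parent a [parent_shape()].
#' @param n number of time points (`>= 4`).
#' @return list of [shape_spec()] objects (empty if `k > n - 1`).
#' @export
enumerate_placements <- function(parent, n) {
  if (parent$kind != "extrema")
    return(list(shape_spec(parent, integer(), n)))
  ni <- n - 1L
  if (parent$k > ni) return(list())
  combs <- utils::combn(ni, parent$k, simplify = FALSE)
  lapply(combs, function(ei) shape_spec(parent, ei, n))
}

#' Knot-derivative matrix of the natural cubic spline
#'
#' Returns the `n x n` matrix `B` such that `B %*% a` is the spline first
#' derivative at every knot, for the natural spline with knot values `a`.
#' Built by composing the curvature solve `c = D^-1 H a` with the knot
#' derivative identities
#' `f'(t_i) = (a_{i+1} - a_i)/h_i - h_i (2 c_i + c_{i+1})/6` and
#' `f'(t_n) = (a_n - a_{n-1})/h_{n-1} + h_{n-1} (c_{n-1} + 2 c_n)/6`.
#'
#' @param h interval widths.
#' @param bm band matrices (recomputed from `h` when omitted).
#' @return `n x n` numeric matrix.
#' @export
derivative_matrix <- function(h, bm = build_band_matrices(h)) {
  n <- bm$n
  # a -> c (all n curvatures, natural boundary rows are zero)
  Cfull <- rbind(0, solve(bm$D, bm$H), 0)
  Sa <- matrix(0, n, n)
  Sc <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    Sa[i, i] <- -1 / h[i]
    Sa[i, i + 1L] <- 1 / h[i]
    Sc[i, i] <- -h[i] / 3
    Sc[i, i + 1L] <- -h[i] / 6
  }
  hn <- h[n - 1L]
  Sa[n, n - 1L] <- -1 / hn
  Sa[n, n] <- 1 / hn
  Sc[n, n - 1L] <- hn / 6
  Sc[n, n] <- hn / 3
  Sa + Sc %*% Cfull
}

#' Build the monotonicity constraint matrix for a shape spec
#'
#' Every interval labelled increasing contributes five rows of
#' `C a >= 0`: the secant condition `a_{i+1} - a_i >= 0`, non-negative
#' endpoint slopes `f'_i >= 0` and `f'_{i+1} >= 0`, and the
#' Fritsch-Carlson-type pair `3 (a_{i+1} - a_i)/h_i - f'_i >= 0` and
#' `3 (a_{i+1} - a_i)/h_i - f'_{i+1} >= 0`.  Decreasing intervals get the
#' same rows negated; free intervals contribute none.
#'
#' @param shape a [shape_spec()].
#' @param h interval widths.
#' @param B knot-derivative matrix from [derivative_matrix()].
#' @return list with matrix `C` (`m x n`, possibly zero rows) and a data
#'   frame `rows` recording each row's interval and condition.
#' @export
build_constraints <- function(shape, h, B = derivative_matrix(h)) {
  n <- length(h) + 1L
  rows <- list()
  meta <- list()
  for (i in seq_len(n - 1L)) {
    s <- shape$senses[i]
    if (s == 0L) next
    secant <- numeric(n)
    secant[i] <- -1
    secant[i + 1L] <- 1
    block <- rbind(secant,
                   B[i, ],
                   B[i + 1L, ],
                   (3 / h[i]) * secant - B[i, ],
                   (3 / h[i]) * secant - B[i + 1L, ])
    rows[[length(rows) + 1L]] <- s * block
    meta[[length(meta) + 1L]] <- data.frame(
      interval = i, sense = s,
      condition = c("secant", "slope_left", "slope_right",
                    "fc_left", "fc_right"))
  }
  C <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0L, n)
  rownames(C) <- NULL
  list(C = C,
       rows = if (length(meta)) do.call(rbind, meta) else
         data.frame(interval = integer(), sense = integer(),
                    condition = character()))
}

#' Enumerate all temporal class labels
#'
#' Generates every label string with `k = 1..max_extrema` alternating
#' extrema assigned to distinct time points (both starting types), plus
#' the three extremum-free classes `"C"`, `"I"`, `"D"`.
#'
#' @param n number of time points.
#' @param max_extrema maximum number of extrema.
#' @return character vector of distinct labels.
#' @export
enumerate_class_labels <- function(n, max_extrema = 4L) {
  labels <- c("C", "I", "D")
  for (k in seq_len(max_extrema)) {
    if (k > n) next
    combs <- utils::combn(n, k, simplify = FALSE)
    for (start in c("Max", "Min")) {
      types <- rep_len(if (start == "Max") c("Max", "Min") else
                         c("Min", "Max"), k)
      for (pos in combs)
        labels <- c(labels, paste0(types, pos, collapse = ","))
    }
  }
  unique(labels)
}

#' Count the distinct temporal shape classes
#'
#' Closed form `2 * sum_{k=1..max_extrema} choose(n, k) + 3`: alternating
#' Max/Min sequences of length `k` placed at `k` distinct time points with
#' either starting type, plus constant, increasing and decreasing.  For 8
#' time points and up to 4 extrema this is 327.
#'
#' @param n number of time points (`>= 2`).
#' @param max_extrema maximum number of extrema (1-4).
#' @return integer count.
#' @examples
#' count_classes(8, 4)  # 327
#' @export
count_classes <- function(n, max_extrema = 4L) {
  if (n < 2L) stop("n must be >= 2")
  if (max_extrema < 1L || max_extrema > 4L)
    stop("max_extrema must be in 1..4")
  as.integer(2 * sum(choose(n, seq_len(max_extrema))) + 3)
}
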