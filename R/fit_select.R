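#' Observation weights from replicate standard deviations
#'
#' Time points measured with high replicate variance should influence the
#' fit less, so the default initial weight is the reciprocal standard
#' deviation, floored at `floor_factor` times the median positive SD to
#' avoid infinite weights.  Initial weights are normalized by their mean,
#' making the weights invariant to a common rescaling of the SDs.
#'
#' @param sds per-time-point replicate standard deviations (`NA` entries,
#'   e.g. single-replicate time points, receive the mean initial weight).
#' @param mode `"inverse-sd"` (default), `"sd"` (weights proportional to
#'   the SD itself) or `"uniform"`.
#' @param floor_factor floor for the SD entering the reciprocal, as a
#'   fraction of the median positive SD.
#' @return positive weight vector with mean 1.
#' @examples
#' compute_weights(c(1, 2, 4))  # 12/7, 6/7, 3/7
#' @export
compute_weights <- function(sds, mode = c("inverse-sd", "sd", "uniform"),
                            floor_factor = 1e-3) {
  mode <- match.arg(mode)
  n <- length(sds)
  if (mode == "uniform") return(rep(1, n))
  pos <- sds[!is.na(sds) & sds > 0]
  if (length(pos) == 0L) {
    warning("all SDs are zero or missing; using uniform weights")
    return(rep(1, n))
  }
  floor_sd <- floor_factor * stats::median(pos)
  s <- pmax(sds, floor_sd)
  w_init <- if (mode == "inverse-sd") 1 / s else s
  w_init[is.na(w_init)] <- mean(w_init, na.rm = TRUE)
  w_init / mean(w_init)
}

#' Logarithmic smoothing-factor grid
#'
#' @param min,max grid end points (both `> 0`; the lower end is small
#'   enough that the fit is effectively the weighted least-squares line,
#'   the upper end effectively interpolates).
#' @param count number of log-spaced values.
#' @return numeric vector of length `count`.
#' @export
lambda_grid <- function(min = 1e-4, max = 1e7, count = 61L) {
  if (min <= 0 || max <= min || count < 1L)
    stop("need 0 < min < max and count >= 1")
  if (count == 1L) return(min)
  exp(seq(log(min), log(max), length.out = count))
}

#' Solve the shape-constrained spline quadratic program
#'
#' Minimizes `(1/2) a' G a + c' a` subject to `C a >= 0` by a primal
#' active-set method (compiled).  The constant vector is feasible for
#' every monotonicity constraint set built by [build_constraints()], so
#' a solution always exists for positive-definite `G`.
#'
#' @param G positive definite matrix (from [qp_terms()]).
#' @param cvec linear term.
#' @param C constraint matrix (`m x n`, may have zero rows).
#' @param tol active-set tolerance: row `j` is reported active when
#'   `|C_j a| <= tol * (1 + max|a|)`.
#' @param maxit iteration cap for the active-set loop.
#' @return list with `a` (solution), `active_rows` (1-based indices) and
#'   `iterations`.
#' @export
solve_constrained_qp <- function(G, cvec, C, tol = 1e-7, maxit = 200L) {
  n <- length(cvec)
  if (is.null(C) || nrow(C) == 0L) C <- matrix(0, 0L, n)
  x0 <- rep(mean(-cvec) / mean(diag(G)), n)  # scale-reasonable constant
  res <- .qp_active_set_cpp(G, cvec, C, x0, tol, as.integer(maxit))
  if (!res$converged)
    stop("active-set QP did not converge within ", maxit, " iterations")
  list(a = as.numeric(res$a), active_rows = as.integer(res$active_rows),
       iterations = res$iterations)
}

#' Orthonormal null-space basis of the active constraint rows
#'
#' @param C_A matrix of active constraint rows (`m x n`; zero rows give
#'   the identity).
#' @param n number of columns.
#' @return matrix `Z` with orthonormal columns spanning `null(C_A)`
#'   (possibly zero columns when `C_A` has full column rank).
#' @export
null_space_basis <- function(C_A, n) {
  if (is.null(C_A) || nrow(C_A) == 0L) return(diag(n))
  sv <- svd(C_A, nu = 0, nv = n)
  d <- sv$d
  tol <- max(dim(C_A)) * max(d, 0) * .Machine$double.eps
  rank <- sum(d > tol)
  if (rank >= n) return(matrix(0, n, 0L))
  sv$v[, (rank + 1L):n, drop = FALSE]
}

#' Modified generalized cross-validation score
#'
#' `n ||W(a - y)||^2 / (Tr(I - rho * A_lambda))^2` with influence matrix
#' `A_lambda = 2 (lambda/n) Z (Z' G Z)^-1 Z' W'W`, where `Z` spans the
#' null space of the active constraint rows.  The inflation factor
#' `rho = 1.3` compensates for the small sample sizes typical of short
#' time series.  Returns `Inf` when the denominator trace is not
#' positive or `Z` has no columns (fully determined fit).
#'
#' @param a fitted knot values.
#' @param y observed means.
#' @param w weight vector (diagonal of `W`).
#' @param lambda smoothing factor.
#' @param Z null-space basis from [null_space_basis()].
#' @param G quadratic term of the fit's QP.
#' @param rho compensatory inflation factor.
#' @return scalar score (>= 0, possibly `Inf`).
#' @export
mgcv_score <- function(a, y, w, lambda, Z, G, rho = 1.3) {
  n <- length(y)
  if (ncol(Z) == 0L) return(Inf)
  wrss <- sum((w * (a - y))^2)
  ZGZ <- crossprod(Z, G %*% Z)
  ZW2Z <- crossprod(Z * w^2, Z)
  tr <- tryCatch(sum(diag(solve(ZGZ, ZW2Z))), error = function(e) NA_real_)
  if (is.na(tr)) {
    warning("singular Z'GZ in mGCV; score set to Inf")
    return(Inf)
  }
  denom <- n - rho * 2 * (lambda / n) * tr
  if (denom <= 0) return(Inf)
  n * wrss / denom^2
}

#' Precompute the fitting context for a time grid
#'
#' All signals sharing a time grid share the band matrices, the penalty
#' kernel, the knot-derivative matrix and the constraint matrices of
#' every shape placement, so these are built once.
#'
#' @param times measured time points.
#' @param max_extrema maximum number of extrema (0-4).
#' @return object of class `tc_context`.
#' @export
fit_context <- function(times, max_extrema = 4L) {
  times <- as.numeric(times)
  h <- interval_widths(times)
  bm <- build_band_matrices(h)
  K <- penalty_kernel(bm)
  B <- derivative_matrix(h, bm)
  n <- bm$n
  parents <- lapply(enumerate_parent_shapes(max_extrema), function(p) {
    specs <- lapply(enumerate_placements(p, n), function(sp)
      list(shape = sp, C = build_constraints(sp, h, B)$C))
    list(parent = p, specs = specs)
  })
  structure(list(times = times, h = h, bm = bm, K = K, B = B, n = n,
                 max_extrema = as.integer(max_extrema), parents = parents),
            class = "tc_context")
}

# Build a FitCandidate from a compiled sweep result.
.candidate_from_sweep <- function(sw, spec, Cmat, ctx, y, w, grid) {
  if (sw$best_index < 1L) return(NULL)
  act <- as.integer(sw$active_rows)
  model <- spline_model(ctx$times, sw$a, lambda = grid[sw$best_index],
                        weights = w, shape = spec,
                        active_rows = act)
  list(model = model, shape = spec, lambda = grid[sw$best_index],
       mgcv = sw$mgcv[sw$best_index], weighted_rss = sw$wrss[sw$best_index],
       active_rows = act,
       Z = null_space_basis(Cmat[act, , drop = FALSE], ctx$n))
}

#' Fit one shape placement across the smoothing-factor grid
#'
#' For each grid value the constrained QP is solved, the active set and
#' its null-space basis determined, and the mGCV score computed; the
#' minimal-mGCV fit is returned (ties keep the smaller, smoother,
#' lambda).
#'
#' @param y per-time-point means.
#' @param w observation weights.
#' @param shape a [shape_spec()].
#' @param ctx fitting context from [fit_context()] for the signal's time
#'   grid.
#' @param grid smoothing-factor grid (all `> 0`).
#' @param rho mGCV inflation factor.
#' @param tol active-set tolerance.
#' @return a fit candidate (list with `model`, `shape`, `lambda`, `mgcv`,
#'   `weighted_rss`, `active_rows`, `Z`) or error if no grid value
#'   yields a finite score.
#' @export
fit_shape <- function(y, w, shape, ctx, grid = lambda_grid(), rho = 1.3,
                      tol = 1e-7) {
  if (!length(grid) || any(grid <= 0))
    stop("lambda grid must be non-empty and positive")
  Cmat <- build_constraints(shape, ctx$h, ctx$B)$C
  sw <- .fit_sweep_cpp(ctx$K, w, y, Cmat, grid, rho, tol, 200L)
  cand <- .candidate_from_sweep(sw, shape, Cmat, ctx, y, w, grid)
  if (is.null(cand) || !is.finite(cand$mgcv))
    stop("no feasible fit for shape '",
         parent_shape_id(shape$parent), "' on the lambda grid")
  cand
}

#' Best fit of a parent shape over all its extrema placements
#'
#' @param y,w,ctx,grid,rho,tol as in [fit_shape()].
#' @param parent a [parent_shape()].
#' @return the minimal-mGCV candidate across placements.
#' @export
fit_parent <- function(y, w, parent, ctx, grid = lambda_grid(), rho = 1.3,
                       tol = 1e-7) {
  entry <- NULL
  for (p in ctx$parents)
    if (identical(p$parent, parent)) { entry <- p; break }
  specs <- if (!is.null(entry)) entry$specs else
    lapply(enumerate_placements(parent, ctx$n), function(sp)
      list(shape = sp, C = build_constraints(sp, ctx$h, ctx$B)$C))
  if (!length(specs)) stop("parent shape has no feasible placement")
  best_sw <- NULL
  best_spec <- NULL
  best_score <- Inf
  for (sp in specs) {
    sw <- .fit_sweep_cpp(ctx$K, w, y, sp$C, grid, rho, tol, 200L)
    if (sw$best_index < 1L) next
    score <- sw$mgcv[sw$best_index]
    if (is.finite(score) && score < best_score) {
      best_score <- score
      best_sw <- sw
      best_spec <- sp
    }
  }
  if (is.null(best_sw))
    stop("no placement of parent '", parent_shape_id(parent),
         "' produced a finite mGCV")
  .candidate_from_sweep(best_sw, best_spec$shape, best_spec$C, ctx, y, w,
                        grid)
}

#' Extrema-penalized small-sample AIC
#'
#' `AICc = n ln(||W(a - y)||^2 / n) + 2k + (2k^2 + 2k)/(n - k - 1)` with
#' `k` the enforced number of extrema.  A zero residual (interpolating
#' fit) returns `-Inf` as a sentinel; `n - k - 1 <= 0` returns `Inf`
#' (candidate excluded).
#'
#' @param weighted_rss weighted residual sum of squares.
#' @param n number of time points.
#' @param k enforced number of extrema.
#' @return scalar.
#' @examples
#' aicc(8, 8, 2)  # 2*2 + 12/5 = 6.4
#' @export
aicc <- function(weighted_rss, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  if (weighted_rss <= 0) return(-Inf)
  n * log(weighted_rss / n) + 2 * k + (2 * k^2 + 2 * k) / (n - k - 1)
}

# Core selection on moments (times, means, sds); shared by select_model
# and the constrained-spline reference fitter.
fit_signal_core <- function(times, means, sds, max_extrema = 4L,
                            grid = lambda_grid(), rho = 1.3, tol = 1e-7,
                            weight_mode = "inverse-sd", ctx = NULL,
                            unconstrained_k = c("post-hoc", "zero")) {
  unconstrained_k <- match.arg(unconstrained_k)
  if (is.null(ctx) || !identical(ctx$times, as.numeric(times)) ||
      ctx$max_extrema < max_extrema)
    ctx <- fit_context(times, max_extrema)
  n <- ctx$n
  w <- compute_weights(sds, mode = weight_mode)
  y <- as.numeric(means)

  candidates <- list()
  for (entry in ctx$parents) {
    p <- entry$parent
    if (p$kind == "extrema" && p$k > max_extrema) next
    cand <- tryCatch(
      fit_parent(y, w, p, ctx, grid = grid, rho = rho, tol = tol),
      error = function(e) NULL)
    if (is.null(cand)) next
    k <- if (p$kind == "extrema") p$k
         else if (p$kind == "unconstrained" && unconstrained_k == "post-hoc")
           nrow(find_extrema(cand$model))
         else 0L
    cand$k <- k
    cand$aicc <- aicc(cand$weighted_rss, n, k)
    candidates[[parent_shape_id(p)]] <- cand
  }
  if (!length(candidates)) stop("all parent shapes failed to fit")

  # minimal AICc; ties prefer fewer extrema, then the parent order
  # (increasing before decreasing before the rest)
  aiccs <- vapply(candidates, `[[`, 0, "aicc")
  ks <- vapply(candidates, `[[`, 0L, "k")
  ord <- order(aiccs, ks, seq_along(candidates))
  selected <- candidates[[ord[1L]]]
  list(candidates = candidates, selected = selected, ctx = ctx,
       weights = w, n_candidates = length(candidates))
}

#' Fit all parent shapes to a signal and select the final model
#'
#' Runs the full per-signal procedure: for each parent shape (monotone,
#' 1-4 extrema starting with a maximum or minimum, unconstrained) the
#' best placement/smoothing combination is found by mGCV; the final model
#' is the one minimizing the extrema-penalized AICc, with ties broken
#' toward fewer extrema.  For the unconstrained candidate the AICc
#' extrema count is by default the number of extrema actually present in
#' its fit, so flexibility is still penalized.
#'
#' @param sig a [signal()].
#' @param max_extrema maximum number of extrema (0-4).
#' @param grid smoothing-factor grid.
#' @param rho mGCV inflation factor.
#' @param tol active-set tolerance.
#' @param weight_mode see [compute_weights()].
#' @param ctx optional precomputed [fit_context()] (shared across signals
#'   on the same time grid).
#' @param quasi_constant_threshold see [is_quasi_constant()].
#' @param unconstrained_k `"post-hoc"` (default) or `"zero"`: how many
#'   extrema the unconstrained candidate is charged for in AICc.
#' @return object of class `tc_fit`: list with `id`, `candidates` (one
#'   per parent shape, each with its AICc), `selected`, `label`,
#'   `extrema` (data frame), `n_candidates`.
#' @export
select_model <- function(sig, max_extrema = 4L, grid = lambda_grid(),
                         rho = 1.3, tol = 1e-7,
                         weight_mode = "inverse-sd", ctx = NULL,
                         quasi_constant_threshold = 1,
                         unconstrained_k = "post-hoc") {
  stopifnot(inherits(sig, "tc_signal"))
  core <- fit_signal_core(sig$times, sig$means, sig$sds,
                          max_extrema = max_extrema, grid = grid, rho = rho,
                          tol = tol, weight_mode = weight_mode, ctx = ctx,
                          unconstrained_k = unconstrained_k)
  fit <- structure(
    list(id = sig$id, candidates = core$candidates,
         selected = core$selected, n_candidates = core$n_candidates,
         weights = core$weights),
    class = "tc_fit")
  lab <- temporal_label(fit, sig, threshold = quasi_constant_threshold)
  fit$label <- lab$label
  fit$extrema <- lab$extrema
  fit
}

#' @export
print.tc_fit <- function(x, ...) {
  cat("<tc_fit> ", x$id, ": class ", x$label, ", parent ",
      parent_shape_id(x$selected$shape$parent), ", lambda = ",
      format(x$selected$lambda), ", AICc = ",
      format(x$selected$aicc), "\n", sep = "")
  invisible(x)
}
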