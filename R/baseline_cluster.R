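#' One-way ANOVA prefilter for clustering
#'
#' Clustering pipelines z-score each signal, which grossly distorts flat
#' signals; the customary guard is a one-way ANOVA across time points
#' (replicates as within-group observations), keeping signals whose mean
#' changes somewhere along the time course.
#'
#' @param signals list of [signal()] objects (each needs at least 2
#'   replicates per time point; others are skipped with a warning).
#' @param alpha p-value threshold (default 0.05; `alpha = 1` retains all
#'   testable signals).
#' @return list with `signals` (retained subset), `pvalues` (named, for
#'   all tested signals) and `skipped` (ids).
#' @export
anova_filter <- function(signals, alpha = 0.05) {
  pvals <- numeric(0)
  keep <- list()
  skipped <- character(0)
  for (s in signals) {
    if (any(s$n_obs < 2L)) {
      warning("signal '", s$id,
              "' skipped in ANOVA filter: single-replicate time point")
      skipped <- c(skipped, s$id)
      next
    }
    vals <- as.vector(s$replicates)
    grp <- factor(rep(seq_along(s$times), times = ncol(s$replicates)))
    ok <- !is.na(vals)
    p <- tryCatch(
      stats::oneway.test(vals[ok] ~ grp[ok], var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    pvals[s$id] <- p
    if (!is.na(p) && p < alpha) keep[[s$id]] <- s
  }
  list(signals = keep, pvalues = pvals, skipped = skipped)
}

#' z-score a vector
#'
#' Centers to zero mean and scales to unit (sample) standard deviation;
#' invariant under positive affine transforms of the input.
#'
#' @param values numeric vector with positive SD.
#' @return transformed vector.
#' @export
zscore <- function(values) {
  s <- stats::sd(values)
  if (is.na(s) || s == 0)
    stop("zscore undefined for constant input (sd = 0)")
  (values - mean(values)) / s
}

#' k-means clustering of signal matrices
#'
#' Thin deterministic wrapper around [stats::kmeans()] (squared
#' Euclidean distance, best of `restarts` random initializations).  An
#' initialization that produces an empty cluster is retried with a
#' shifted seed, with a message.
#'
#' @param data numeric matrix, one row per signal (typically z-scored).
#' @param k number of clusters (`<= nrow(data)`).
#' @param seed integer seed.
#' @param restarts number of random starts.
#' @return list of class `tc_cluster`: `assignments` (named integer
#'   vector), `centroids` (`k x n`), `k`, `inertia` (total
#'   within-cluster sum of squares).
#' @export
kmeans_signals <- function(data, k, seed = 1L, restarts = 25L) {
  data <- as.matrix(data)
  if (k > nrow(data)) stop("k exceeds the number of signals")
  if (k == nrow(data)) {
    assignments <- seq_len(nrow(data))
    names(assignments) <- rownames(data)
    return(structure(list(assignments = assignments, centroids = data,
                          k = k, inertia = 0),
                     class = "tc_cluster"))
  }
  km <- NULL
  for (attempt in 0:4) {
    set.seed(as.integer(seed) + attempt)
    km <- tryCatch(
      stats::kmeans(data, centers = k, nstart = restarts, iter.max = 100L),
      error = function(e) NULL)
    if (!is.null(km)) break
    message("k-means produced an empty cluster; re-seeding (attempt ",
            attempt + 1L, ")")
  }
  if (is.null(km)) stop("k-means failed after repeated re-seeding")
  assignments <- km$cluster
  names(assignments) <- rownames(data)
  structure(list(assignments = assignments, centroids = km$centers,
                 k = k, inertia = km$tot.withinss),
            class = "tc_cluster")
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log within-cluster dispersion of the data to that of
#' `n_refs` uniform reference datasets drawn over the per-feature ranges
#' of the data.  The optimal `k` is the smallest with
#' `Gap(k) >= Gap(k+1) - s_{k+1}`.
#'
#' @param data numeric matrix (rows = signals).
#' @param k_range candidate cluster numbers (increasing).
#' @param n_refs number of reference datasets (`> 0`).
#' @param seed integer seed.
#' @param restarts k-means restarts per fit.
#' @return list with `optimal_k` and a data frame `table` (`k`, `logW`,
#'   `E_logW`, `gap`, `s`).
#' @export
gap_statistic <- function(data, k_range = 1:6, n_refs = 50L, seed = 1L,
                          restarts = 10L) {
  if (n_refs < 1L) stop("n_refs must be positive")
  data <- as.matrix(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(data)) stop("k_range exceeds the number of rows")
  logW <- function(mat, k, sd)
    log(kmeans_signals(mat, k, seed = sd, restarts = restarts)$inertia)
  lw <- vapply(k_range, function(k) logW(data, k, seed), 0)
  lo <- apply(data, 2L, min)
  hi <- apply(data, 2L, max)
  set.seed(as.integer(seed))
  ref_lw <- matrix(NA_real_, n_refs, length(k_range))
  for (b in seq_len(n_refs)) {
    ref <- matrix(stats::runif(length(data)), nrow(data), ncol(data))
    ref <- sweep(sweep(ref, 2L, hi - lo, `*`), 2L, lo, `+`)
    ref_lw[b, ] <- vapply(k_range, function(k) logW(ref, k, seed + b), 0)
  }
  gap <- colMeans(ref_lw) - lw
  s <- apply(ref_lw, 2L, stats::sd) * sqrt(1 + 1 / n_refs)
  opt <- length(k_range)
  for (j in seq_len(length(k_range) - 1L)) {
    if (gap[j] >= gap[j + 1L] - s[j + 1L]) { opt <- j; break }
  }
  list(optimal_k = k_range[opt],
       table = data.frame(k = k_range, logW = lw, E_logW = colMeans(ref_lw),
                          gap = gap, s = s))
}

#' Per-signal cluster fidelity diagnostics
#'
#' How faithfully does a cluster centroid represent its members?  For
#' each signal: the number of its time points falling outside the
#' cluster mean's pointwise 95% normal-theory prediction interval
#' (centroid +/- t-quantile * within-cluster SD * sqrt(1 + 1/m)), and
#' its R-squared to the centroid.
#'
#' @param result a `tc_cluster` from [kmeans_signals()].
#' @param data the matrix that was clustered.
#' @param r2_mode `"pearson"` (squared correlation with the centroid,
#'   default) or `"regression"` (`1 - SSE/SST` against the centroid).
#' @return list with `per_signal` (data frame `id`, `cluster`,
#'   `n_outside_pi`, `r2`) and `per_cluster` (data frame `cluster`,
#'   `size`, `share_outside` = share of members with at least one point
#'   outside the PI, `share_low_r2` = share with R-squared below 0.8);
#'   clusters with fewer than 3 members have undefined PIs and are
#'   flagged with `NA`.
#' @export
cluster_fidelity <- function(result, data,
                             r2_mode = c("pearson", "regression")) {
  r2_mode <- match.arg(r2_mode)
  data <- as.matrix(data)
  ids <- rownames(data)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(data)))
  per <- data.frame(id = ids, cluster = as.integer(result$assignments),
                    n_outside_pi = NA_integer_, r2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (cl in seq_len(result$k)) {
    rows <- which(per$cluster == cl)
    m <- length(rows)
    cen <- result$centroids[cl, ]
    sub <- data[rows, , drop = FALSE]
    if (m >= 3L) {
      sds <- apply(sub, 2L, stats::sd)
      half <- stats::qt(0.975, df = m - 1L) * sds * sqrt(1 + 1 / m)
      lowb <- cen - half
      upb <- cen + half
      per$n_outside_pi[rows] <- apply(sub, 1L, function(x)
        sum(x < lowb | x > upb))
    }
    per$r2[rows] <- apply(sub, 1L, function(x) {
      if (r2_mode == "pearson") {
        if (stats::sd(cen) == 0 || stats::sd(x) == 0) return(NA_real_)
        stats::cor(x, cen)^2
      } else {
        sst <- sum((x - mean(x))^2)
        if (sst == 0) return(NA_real_)
        1 - sum((x - cen)^2) / sst
      }
    })
  }
  agg <- lapply(split(per, per$cluster), function(d) data.frame(
    cluster = d$cluster[1L], size = nrow(d),
    share_outside = mean(d$n_outside_pi > 0),
    share_low_r2 = mean(d$r2 < 0.8, na.rm = TRUE)))
  list(per_signal = per, per_cluster = do.call(rbind, agg))
}
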