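#' Construct a replicate time-series signal
#'
#' A signal is one molecule's (protein, transcript, metabolite) replicate
#' time course: a strictly increasing time vector and an `n x r` matrix of
#' replicate measurements, from which per-time-point means and standard
#' deviations are derived.  Missing replicate cells (`NA`) are allowed as
#' long as every time point retains at least one measurement.
#'
#' @param id character scalar identifying the signal.
#' @param times numeric vector of time coordinates, strictly increasing,
#'   length at least 4 (the method is intended for 4-12 time points).
#' @param replicates numeric matrix with `length(times)` rows, one column
#'   per replicate.  `NA` cells are ignored when computing means and SDs.
#' @return An object of class `tc_signal` with elements `id`, `times`,
#'   `replicates`, `means`, `sds` and `n_obs` (non-missing replicates per
#'   time point).  Time points with a single replicate get `sds = NA` and
#'   are flagged via `n_obs`, never silently treated as zero-variance.
#' @examples
#' s <- signal("P1", 0:3, matrix(rnorm(12), 4, 3))
#' s$means
#' @export
signal <- function(id, times, replicates) {
  times <- as.numeric(times)
  n <- length(times)
  if (n < 4L)
    stop("signal '", id, "': need at least 4 time points, got ", n)
  if (any(diff(times) <= 0))
    stop("signal '", id, "': times must be strictly increasing")
  replicates <- as.matrix(replicates)
  if (nrow(replicates) != n)
    stop("signal '", id, "': replicate matrix must have one row per time point")
  n_obs <- rowSums(!is.na(replicates))
  if (any(n_obs == 0L))
    stop("signal '", id, "': time point(s) ",
         paste(which(n_obs == 0L), collapse = ", "),
         " have no non-missing replicate")
  means <- rowMeans(replicates, na.rm = TRUE)
  sds <- apply(replicates, 1L, stats::sd, na.rm = TRUE)
  structure(
    list(id = as.character(id), times = times, replicates = replicates,
         means = unname(means), sds = unname(sds), n_obs = unname(n_obs)),
    class = "tc_signal")
}

#' @export
print.tc_signal <- function(x, ...) {
  cat("<tc_signal> ", x$id, ": ", length(x$times), " time points, ",
      ncol(x$replicates), " replicates\n", sep = "")
  invisible(x)
}

#' Interval widths between measuring time points
#'
#' @param times strictly increasing numeric vector.
#' @return numeric vector `h` of length `length(times) - 1` with
#'   `h[i] = times[i+1] - times[i]`.
#' @examples
#' interval_widths(c(0, 0.5, 1, 2, 4, 8, 16, 24))
#' @export
interval_widths <- function(times) {
  h <- diff(as.numeric(times))
  if (length(h) == 0L || any(h <= 0))
    stop("times must be strictly increasing with at least 2 entries")
  h
}

#' Read signals from a tabular file
#'
#' Supports two dialects.  Long format has columns `id`, `time`,
#' `replicate`, `value` (one measurement per row).  Wide format has an
#' `id` column followed by one column per time x replicate combination,
#' named `<time>_<replicate>` (e.g. `0.5_2`).  The field separator is
#' auto-detected from the extension (`.csv` = comma, otherwise tab)
#' unless given explicitly.
#'
#' @param path file path.
#' @param format `"auto"`, `"long"` or `"wide"`.  `"auto"` picks long when
#'   the header contains `id`, `time`, `replicate`, `value`.
#' @param sep field separator; `NULL` to auto-detect from the extension.
#' @return list of [signal()] objects, in first-appearance order of the
#'   ids.  Signals with fewer than 4 time points are skipped with a
#'   warning.
#' @export
read_signals <- function(path, format = c("auto", "long", "wide"), sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  long_cols <- c("id", "time", "replicate", "value")
  if (format == "auto")
    format <- if (all(long_cols %in% names(df))) "long" else "wide"

  if (format == "long") {
    miss <- setdiff(long_cols, names(df))
    if (length(miss))
      stop("long format requires columns: ", paste(miss, collapse = ", "))
    for (col in c("time", "value")) {
      v <- df[[col]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop("non-numeric '", col, "' value in row ", bad[1L], ": ",
             v[bad[1L]])
      df[[col]] <- num
    }
    key <- paste(df$id, df$time, df$replicate, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (id, time, replicate) entry: ",
           gsub("\r", "/", key[which(duplicated(key))[1L]]))
    ids <- unique(df$id)
    out <- list()
    for (i in ids) {
      d <- df[df$id == i, , drop = FALSE]
      times <- sort(unique(d$time))
      if (length(times) < 4L) {
        warning("signal '", i, "' skipped: fewer than 4 time points")
        next
      }
      reps <- sort(unique(d$replicate))
      mat <- matrix(NA_real_, length(times), length(reps),
                    dimnames = list(NULL, reps))
      mat[cbind(match(d$time, times), match(d$replicate, reps))] <- d$value
      out[[i]] <- signal(i, times, mat)
    }
  } else {
    if (!"id" %in% names(df)) stop("wide format requires an 'id' column")
    meas <- setdiff(names(df), "id")
    parts <- regmatches(meas, regexec("^(.+)_([^_]+)$", meas))
    bad <- which(vapply(parts, length, 1L) != 3L)
    if (length(bad))
      stop("wide column name not of the form <time>_<replicate>: ",
           meas[bad[1L]])
    tvals <- as.numeric(vapply(parts, `[`, "", 2L))
    if (anyNA(tvals))
      stop("non-numeric time in wide column name: ",
           meas[which(is.na(tvals))[1L]])
    rvals <- vapply(parts, `[`, "", 3L)
    times <- sort(unique(tvals))
    reps <- unique(rvals)
    out <- list()
    for (r in seq_len(nrow(df))) {
      i <- df$id[r]
      mat <- matrix(NA_real_, length(times), length(reps),
                    dimnames = list(NULL, reps))
      vals <- suppressWarnings(as.numeric(df[r, meas]))
      orig <- unlist(df[r, meas], use.names = FALSE)
      nn <- which(!is.na(orig) & is.na(vals))
      if (length(nn))
        stop("non-numeric value for id '", i, "', column ", meas[nn[1L]])
      mat[cbind(match(tvals, times), match(rvals, reps))] <- vals
      if (length(times) < 4L) {
        warning("signal '", i, "' skipped: fewer than 4 time points")
        next
      }
      out[[i]] <- signal(i, times, mat)
    }
  }
  out
}

#' Write per-signal fit reports to a TSV table
#'
#' One row per signal with columns `id`, `class_label`, `lambda`, `aicc`,
#' `n_extrema`, `knot_values`, `knot_curvatures` (JSON arrays) and
#' `extrema` (JSON list of `{time, value, type, nearest_knot}`).
#'
#' @param fits list of fit reports from [select_model()].
#' @param path output file path.
#' @param trace_path optional path for a JSON sidecar holding the full
#'   per-parent-shape selection trace.
#' @return `path`, invisibly.
#' @export
write_results <- function(fits, path, trace_path = NULL) {
  rows <- lapply(fits, function(f) {
    ex <- f$extrema
    exj <- if (is.null(ex) || nrow(ex) == 0L) "[]" else
      as.character(jsonlite::toJSON(
        ex[, c("time", "value", "type", "nearest_knot")],
        digits = I(12), dataframe = "rows"))
    data.frame(
      id = f$id,
      class_label = f$label,
      lambda = f$selected$lambda,
      aicc = f$selected$aicc,
      n_extrema = if (is.null(ex)) 0L else nrow(ex),
      knot_values = as.character(jsonlite::toJSON(f$selected$model$a,
                                                  digits = I(12))),
      knot_curvatures = as.character(jsonlite::toJSON(f$selected$model$c,
                                                      digits = I(12))),
      extrema = exj,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), class_label = character(),
               lambda = numeric(), aicc = numeric(), n_extrema = integer(),
               knot_values = character(), knot_curvatures = character(),
               extrema = character(), stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e)))
  if (!is.null(trace_path)) {
    trace <- lapply(fits, function(f) {
      lapply(f$candidates, function(cd) list(
        parent = parent_shape_id(cd$shape$parent),
        extremum_intervals = cd$shape$extremum_intervals,
        lambda = cd$lambda, mgcv = cd$mgcv,
        weighted_rss = cd$weighted_rss, aicc = cd$aicc))
    })
    names(trace) <- vapply(fits, `[[`, "", "id")
    jsonlite::write_json(trace, trace_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV file path.
#' @return data frame with JSON columns parsed back into list columns
#'   `knot_values`, `knot_curvatures` and `extrema`.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c(id = "character",
                                         class_label = "character"))
  df$knot_values <- lapply(df$knot_values, jsonlite::fromJSON)
  df$knot_curvatures <- lapply(df$knot_curvatures, jsonlite::fromJSON)
  df$extrema <- lapply(df$extrema, function(x)
    jsonlite::fromJSON(x, simplifyDataFrame = TRUE))
  df
}
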