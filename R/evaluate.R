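#' Align an estimated angle series with a ground-truth trace
#'
#' Each estimate is paired with the truth sample nearest in time; pairs
#' farther apart than `max_gap` (default 0.2 s, two periods at the nominal
#' ~10 Hz rate) are dropped, and the number dropped is recorded in the
#' `"n_dropped"` attribute.
#'
#' @param estimates an `angle_series` data frame (needs `timestamp_s`,
#'   `theta_deg`).
#' @param truth data frame with `timestamp_s`, `angle_deg`.
#' @param max_gap maximum allowed timestamp difference, seconds.
#' @return data frame (`aligned_pairs`) with `estimate_deg`, `truth_deg`,
#'   `timestamp_s`.
#' @export
align_series <- function(estimates, truth, max_gap = 0.2) {
  if (nrow(estimates) == 0L || nrow(truth) == 0L) {
    stop("cannot align empty series", call. = FALSE)
  }
  if (min(estimates$timestamp_s) > max(truth$timestamp_s) + max_gap ||
      max(estimates$timestamp_s) < min(truth$timestamp_s) - max_gap) {
    stop("estimate and truth time ranges do not overlap", call. = FALSE)
  }
  truth <- truth[order(truth$timestamp_s), , drop = FALSE]
  tt <- truth$timestamp_s
  idx <- vapply(estimates$timestamp_s,
                function(t) which.min(abs(tt - t)), integer(1))
  gap <- abs(tt[idx] - estimates$timestamp_s)
  keep <- gap <= max_gap
  out <- data.frame(estimate_deg = estimates$theta_deg[keep],
                    truth_deg = truth$angle_deg[idx[keep]],
                    timestamp_s = estimates$timestamp_s[keep])
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("aligned_pairs", "data.frame")
  out
}

#' Error metrics between estimated and reference angle series
#'
#' With errors \eqn{e_i = \hat\theta_i - \theta_i}:
#' MAE = mean |e|; RMSE = sqrt(mean e^2); MAPE = 100 mean |e/theta| over
#' pairs with nonzero truth (zero-truth pairs are excluded and counted in
#' `mape_excluded` -- percentage error is unstable near 0 degrees);
#' NRMSE = RMSE normalized by the truth range (or mean, via `nrmse_norm`);
#' STD = sample (n-1) standard deviation of the errors; and
#' R2 = 1 - sum(e^2) / sum((theta - mean theta)^2). On a constant truth
#' series NRMSE and R2 are undefined and reported as `NA`, not as errors.
#'
#' @param pairs an [align_series()] result (or any data frame with
#'   `estimate_deg`, `truth_deg`), at least 2 rows.
#' @param nrmse_norm `"range"` (default) or `"mean"` normalizer.
#' @return a `metrics_report` list: `mae`, `rmse`, `mape`, `nrmse`, `std`,
#'   `r_squared`, `n`, `mape_excluded`.
#' @export
compute_metrics <- function(pairs, nrmse_norm = c("range", "mean")) {
  nrmse_norm <- match.arg(nrmse_norm)
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  e <- pairs$estimate_deg - pairs$truth_deg
  truth <- pairs$truth_deg
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  nz <- truth != 0
  mape <- if (any(nz)) 100 * mean(abs(e[nz] / truth[nz])) else NA_real_
  denom <- switch(nrmse_norm,
                  range = max(truth) - min(truth),
                  mean = mean(truth))
  nrmse <- if (is.finite(denom) && denom != 0) rmse / denom else NA_real_
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot > 0) 1 - sum(e^2) / ss_tot else NA_real_
  structure(
    list(mae = mae, rmse = rmse, mape = mape, nrmse = nrmse,
         std = stats::sd(e), r_squared = r2, n = n,
         mape_excluded = sum(!nz)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "angle metrics (n = %d):\n  MAE  %7.3f deg\n  RMSE %7.3f deg\n  MAPE %7.3f %%\n  NRMSE %6.4f\n  STD  %7.3f deg\n  R^2  %7.4f\n",
    x$n, x$mae, x$rmse, x$mape, x$nrmse, x$std, x$r_squared))
  if (x$mape_excluded > 0) {
    cat(sprintf("  (%d zero-truth pair(s) excluded from MAPE)\n",
                x$mape_excluded))
  }
  invisible(x)
}

#' Write a metrics report to JSON or CSV
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  vals <- report[c("mae", "rmse", "mape", "nrmse", "std", "r_squared",
                   "n", "mape_excluded")]
  if (format == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(vals), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Summarize metric reports across experimental conditions
#'
#' Builds a long-format table with one row per (exercise, view, distance,
#' method) condition; duplicate conditions are aggregated by the mean of
#' each metric, with a count column.
#'
#' @param runs list of lists, each with `exercise`, `view`, `distance`,
#'   `method` and `metrics` (a `metrics_report`).
#' @param path optional CSV output path.
#' @return the summary data frame (invisibly written to `path` if given).
#' @export
summarize_runs <- function(runs, path = NULL) {
  if (length(runs) == 0L) stop("no runs to summarize", call. = FALSE)
  rows <- do.call(rbind, lapply(runs, function(r) {
    m <- r$metrics
    data.frame(exercise = r$exercise, view = r$view,
               distance = r$distance, method = r$method,
               mae = m$mae, rmse = m$rmse, mape = m$mape, nrmse = m$nrmse,
               std = m$std, r_squared = m$r_squared, n = m$n,
               stringsAsFactors = FALSE)
  }))
  keys <- c("exercise", "view", "distance", "method")
  mets <- c("mae", "rmse", "mape", "nrmse", "std", "r_squared")
  agg <- stats::aggregate(rows[mets], by = rows[keys], FUN = mean)
  cnt <- stats::aggregate(list(n_runs = rows$mae), by = rows[keys],
                          FUN = length)
  out <- merge(agg, cnt, by = keys, sort = TRUE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}
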