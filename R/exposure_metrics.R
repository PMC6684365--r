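#' Summary statistics for a PM2.5 series
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator), maximum
#' and the count of observed minutes. Missing minutes are excluded from
#' every statistic and from all denominators.
#'
#' @param pm a [pm_series()].
#' @return A list of class `area_summary_core` with elements
#'   `duration_minutes`, `mean`, `sd`, `maximum`.
#' @export
summarize_series <- function(pm) {
  stopifnot(inherits(pm, "pm_series"))
  x <- pm$pm25[!is.na(pm$pm25)]
  if (length(x) == 0L) stop("no observed minutes in PM series")
  structure(list(
    source_id = attr(pm, "source_id"),
    duration_minutes = length(x),
    mean = mean(x),
    sd = if (length(x) > 1L) stats::sd(x) else 0,
    maximum = max(x)
  ), class = "area_summary_core")
}

#' @export
print.area_summary_core <- function(x, ...) {
  cat(sprintf("%s: %d observed minutes, mean %.1f (SD %.1f), max %.1f ug/m3\n",
              x$source_id, x$duration_minutes, x$mean, x$sd, x$maximum))
  invisible(x)
}

#' Threshold exceedance fractions
#'
#' For each benchmark concentration, the percentage of observed 1-minute
#' measurements strictly above it. Thresholds must be increasing, so the
#' returned fractions are non-increasing.
#'
#' @param pm a [pm_series()].
#' @param thresholds increasing benchmark concentrations (ug/m3); defaults
#'   to the WHO annual (10) and 24-h (25) indoor-air guideline values plus
#'   the 246 ug/m3 pre-ban bar average.
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
exceedance_fractions <- function(pm, thresholds = c(10, 25, 246)) {
  stopifnot(inherits(pm, "pm_series"))
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  x <- pm$pm25[!is.na(pm$pm25)]
  if (length(x) == 0L) stop("no observed minutes in PM series")
  out <- vapply(thresholds, function(th) 100 * mean(x > th), 0)
  names(out) <- paste0("pct_gt", thresholds)
  out
}

#' Day-time and night-time median concentrations
#'
#' Classifies each observed minute by wall-clock time: minutes in the
#' half-open window `[start, end)` are "day", all others "night", so the
#' two classes tile the 24-h clock exactly. Medians are over observed
#' minutes only. If the series never enters one class the corresponding
#' median is `NA`.
#'
#' @param pm a [pm_series()] spanning at least one full day.
#' @param window length-2 character vector of clock times `"HH:MM"`;
#'   default 07:00-23:00, the hours of prisoner activity.
#' @return Named numeric vector `c(day = ..., night = ...)`.
#' @export
day_night_medians <- function(pm, window = c("07:00", "23:00")) {
  stopifnot(inherits(pm, "pm_series"))
  span_h <- as.numeric(difftime(max(pm$time), min(pm$time), units = "hours"))
  if (span_h < 23) stop("series must span at least one full day")
  w <- parse_clock(window)
  lt <- as.POSIXlt(pm$time)
  clock_min <- lt$hour * 60 + lt$min
  is_day <- clock_min >= w[1] & clock_min < w[2]
  obs <- !is.na(pm$pm25)
  med <- function(sel) if (any(sel & obs)) stats::median(pm$pm25[sel & obs]) else NA_real_
  c(day = med(is_day), night = med(!is_day))
}

#' Column-wise cross-prison medians
#'
#' Pools per-prison summary rows into the overall-median row of the area
#' results table: for every numeric column, the median across prisons
#' (mean of the two central order statistics for even counts).
#'
#' @param summaries a data frame with one row per prison and numeric
#'   summary columns (non-numeric columns are ignored).
#' @return Named numeric vector of column medians.
#' @export
pool_across_prisons <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  num <- vapply(summaries, is.numeric, TRUE)
  vapply(summaries[num], function(col) stats::median(col, na.rm = TRUE), 0)
}

#' Mobile location/activity vocabulary
#' @export
mobile_categories <- function() {
  c("reception", "teaching", "healthcare_gym", "outdoor", "staff_office",
    "workshop", "corridor_landing", "cell_unlock", "cell_search",
    "recreation", "cell_maintenance")
}

#' Summarise mobile (short-duration) PM2.5 measurements
#'
#' Pools 30-minute walk-through measurements across prisons into a
#' per-location/activity table — n, minimum, maximum, mean, SD, median and
#' inter-quartile range of the per-measurement mean concentrations —
#' ordered by median, plus pooled geometric statistics over all
#' measurements.
#'
#' @param measurements data frame with columns `prison_id`, `category`
#'   (from [mobile_categories()]), `duration_minutes` (> 0) and
#'   `mean_pm25` (ug/m3).
#' @return A list of class `mobile_summary`: `by_category` data frame and
#'   `pooled` with `n`, `gm`, `gsd`, `min`, `max`.
#' @export
summarize_mobile <- function(measurements) {
  need <- c("prison_id", "category", "duration_minutes", "mean_pm25")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(measurements$category), mobile_categories())
  if (length(bad)) stop("unknown location/activity categories: ", paste(bad, collapse = ", "))
  if (any(measurements$duration_minutes <= 0)) stop("durations must be positive")
  if (any(measurements$mean_pm25 <= 0)) {
    stop("non-positive mean concentration: geometric statistics undefined")
  }
  by_cat <- do.call(rbind, lapply(split(measurements, measurements$category), function(g) {
    q <- stats::quantile(g$mean_pm25, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = g$category[1], n = nrow(g),
               min = min(g$mean_pm25), max = max(g$mean_pm25),
               mean = mean(g$mean_pm25),
               sd = if (nrow(g) > 1L) stats::sd(g$mean_pm25) else 0,
               p25 = q[1], median = q[2], p75 = q[3])
  }))
  by_cat <- by_cat[order(by_cat$median), , drop = FALSE]
  rownames(by_cat) <- NULL
  gs <- geometric_stats(measurements$mean_pm25)
  structure(list(
    by_category = by_cat,
    pooled = list(n = nrow(measurements), gm = gs[["gm"]], gsd = gs[["gsd"]],
                  min = min(measurements$mean_pm25), max = max(measurements$mean_pm25))
  ), class = "mobile_summary")
}

#' @export
print.mobile_summary <- function(x, ...) {
  cat(sprintf("Mobile PM2.5 summary: %d measurements, GM %.1f ug/m3 (GSD %.1f)\n",
              x$pooled$n, x$pooled$gm, x$pooled$gsd))
  print(x$by_category, digits = 3)
  invisible(x)
}

#' Area-monitoring summary for one prison
#'
#' Convenience wrapper chaining [summarize_series()],
#' [exceedance_fractions()] and [day_night_medians()] into one row of the
#' per-prison area results table.
#'
#' @param pm a [pm_series()].
#' @param config a [study_config()].
#' @param prison_id label for the row.
#' @return A one-row data frame.
#' @export
area_summary <- function(pm, config = study_config(),
                         prison_id = attr(pm, "source_id")) {
  core <- summarize_series(pm)
  exc <- exceedance_fractions(pm, config$pm_thresholds)
  dn <- tryCatch(day_night_medians(pm, config$day_window),
                 error = function(e) c(day = NA_real_, night = NA_real_))
  out <- data.frame(prison_id = prison_id,
                    duration_minutes = core$duration_minutes,
                    t(exc),
                    maximum = core$maximum, pm_mean = core$mean, pm_sd = core$sd,
                    day_median = dn[["day"]], night_median = dn[["night"]])
  rownames(out) <- NULL
  out
}
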