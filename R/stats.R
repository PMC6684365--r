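#' Coefficient of determination of a simple linear fit
#'
#' R-squared of the ordinary least-squares regression of `y` on `x` —
#' equivalently the squared Pearson correlation — used to quantify the
#' agreement between the co-located PM2.5 and airborne-nicotine
#' measurements.
#'
#' @param x,y paired concentrations, length >= 3.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("x is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)  # constant y is fitted exactly by the intercept
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Geometric mean and geometric standard deviation
#'
#' The occupational-hygiene summary for right-skewed exposure data:
#' GM = exp(mean of log values), GSD = exp(sample SD (n-1) of log values).
#'
#' @param values strictly positive numeric vector.
#' @return Named numeric vector `c(gm = ..., gsd = ...)`; GSD is 1 for a
#'   single value.
#' @export
geometric_stats <- function(values) {
  if (any(is.na(values)) || any(values <= 0)) {
    stop("geometric statistics need strictly positive values")
  }
  lv <- log(values)
  c(gm = exp(mean(lv)),
    gsd = if (length(lv) > 1L) exp(stats::sd(lv)) else 1)
}

#' Compare in-prison PM2.5 with matched ambient concentrations
#'
#' For each prison, restricts the ambient station series to the wall-clock
#' span of the in-prison measurement before averaging, so the outdoor
#' contribution is assessed over the same period, then pools the ambient
#' means across prisons by the overall-median rule.
#'
#' @param prison_series named list of in-prison [pm_series()] (one per
#'   prison).
#' @param ambient_series named list of matched ambient [pm_series()] (same
#'   names), at the station's native resolution.
#' @return A list of class `ambient_comparison`: `by_prison` data frame
#'   (prison_id, prison_mean, ambient_mean) and `medians` (cross-prison
#'   medians of both columns).
#' @export
ambient_comparison <- function(prison_series, ambient_series) {
  if (!identical(sort(names(prison_series)), sort(names(ambient_series)))) {
    stop("prison and ambient series lists must share names")
  }
  rows <- lapply(names(prison_series), function(id) {
    pr <- prison_series[[id]]; am <- ambient_series[[id]]
    span <- range(pr$time)
    sel <- am$time >= span[1] & am$time <= span[2]
    if (!any(sel)) stop("no temporal overlap between prison and ambient series for ", id)
    data.frame(prison_id = id,
               prison_mean = mean(pr$pm25, na.rm = TRUE),
               ambient_mean = mean(am$pm25[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  by_prison <- do.call(rbind, rows)
  structure(list(
    by_prison = by_prison,
    medians = c(prison = stats::median(by_prison$prison_mean),
                ambient = stats::median(by_prison$ambient_mean))
  ), class = "ambient_comparison")
}

#' @export
print.ambient_comparison <- function(x, ...) {
  cat(sprintf("In-prison vs ambient PM2.5 over matched periods (%d prisons)\n",
              nrow(x$by_prison)))
  cat(sprintf("  cross-prison medians: prison %.1f, ambient %.1f ug/m3\n",
              x$medians[["prison"]], x$medians[["ambient"]]))
  invisible(x)
}

#' Pair area PM2.5 means with processed nicotine values
#'
#' Builds the contemporaneous paired data set used for the PM-nicotine
#' agreement analysis: one row per prison with its multi-day area PM2.5
#' mean and its processed nicotine concentration, restricted (by default)
#' to prisons where the two monitors ran contemporaneously.
#'
#' @param area data frame with columns `prison_id` and `pm_mean`.
#' @param nicotine the `by_prison` element of a [process_nicotine()]
#'   result (or any data frame with `prison_id`, `concentration`,
#'   `contemporaneous`).
#' @param contemporaneous_only drop non-contemporaneous pairs.
#' @return Data frame `prison_id`, `pm_mean`, `nicotine`,
#'   `contemporaneous`.
#' @export
pair_pm_nicotine <- function(area, nicotine, contemporaneous_only = TRUE) {
  m <- merge(area[, c("prison_id", "pm_mean")],
             nicotine[, c("prison_id", "concentration", "contemporaneous")],
             by = "prison_id")
  names(m)[names(m) == "concentration"] <- "nicotine"
  if (contemporaneous_only) m <- m[m$contemporaneous, , drop = FALSE]
  rownames(m) <- NULL
  m
}
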