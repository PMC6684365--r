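#' Substitute half the detection limit for censored values
#'
#' Standard half-LOD substitution for summary statistics of censored
#' environmental data: below-LOD entries are replaced by the configured
#' half-LOD value; detects are returned unchanged.
#'
#' @param values numeric concentrations (`NA` where censored).
#' @param censored logical vector marking below-LOD entries.
#' @param half_lod substitution value (> 0).
#' @return numeric vector with no missing values among censored entries.
#' @export
impute_below_lod <- function(values, censored, half_lod = 0.016) {
  if (half_lod <= 0) stop("half_lod must be positive")
  if (length(censored) != length(values)) stop("values and censored differ in length")
  values[censored] <- half_lod
  values
}

#' Merge a duplicate passive-monitor pair
#'
#' Two co-located monitors at one site are merged to their arithmetic mean;
#' the percent deviation of each member from that mean reports the
#' agreement of the duplicate deployment.
#'
#' @param a,b the two uncensored concentrations (ug/m3) from one prison.
#' @return A list with `mean` and `deviation_pct` (identical for the two
#'   members of a pair).
#' @export
merge_duplicates <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L) stop("merge_duplicates expects a single pair")
  if (is.na(a) || is.na(b)) stop("duplicate members must be uncensored values")
  m <- (a + b) / 2
  list(mean = m, deviation_pct = abs(a - m) / m * 100)
}

#' Quality-control screening of passive nicotine monitors
#'
#' Applies the study QC rules: tampered monitors are excluded with a
#' logged reason; field blanks never contribute a prison-level value and
#' raise a contamination warning if any blank is above the LOD; the
#' remaining monitors are returned as the analysis set with their
#' contemporaneity labels intact.
#'
#' @param measurements a `nicotine_measurements` data frame (see
#'   [read_nicotine_table()]).
#' @return A list of class `nicotine_qc`: `analysis` (retained
#'   measurements), `exclusions` (data frame of monitor, reason),
#'   `blanks` (the field-blank rows) and `blank_contamination` (logical).
#' @export
qc_exclude <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  blanks <- measurements[measurements$field_blank, , drop = FALSE]
  contaminated <- any(!blanks$censored & !is.na(blanks$concentration))
  if (contaminated) {
    warning("field blank above the LOD: possible contamination during transport/storage")
  }
  rest <- measurements[!measurements$field_blank, , drop = FALSE]
  tampered <- rest$tampered
  exclusions <- data.frame(
    monitor_id = rest$monitor_id[tampered],
    prison_id = rest$prison_id[tampered],
    reason = rep("tampered", sum(tampered)),
    stringsAsFactors = FALSE
  )
  structure(list(
    analysis = rest[!tampered, , drop = FALSE],
    exclusions = exclusions,
    blanks = blanks,
    blank_contamination = contaminated
  ), class = "nicotine_qc")
}

#' @export
print.nicotine_qc <- function(x, ...) {
  cat(sprintf("Nicotine QC: %d monitors retained, %d excluded, %d field blanks%s\n",
              nrow(x$analysis), nrow(x$exclusions), nrow(x$blanks),
              if (x$blank_contamination) " [CONTAMINATION WARNING]" else ""))
  if (nrow(x$exclusions)) print(x$exclusions)
  invisible(x)
}

#' Process passive nicotine monitors to one value per prison
#'
#' Full monitor-to-prison chain: QC exclusion ([qc_exclude()]), duplicate
#' merging to the pair mean ([merge_duplicates()]) and half-LOD
#' substitution for censored filters ([impute_below_lod()]). At most one
#' duplicate pair is defined per site; more than two monitors at a prison
#' is an error.
#'
#' @param measurements a `nicotine_measurements` data frame.
#' @param config a [study_config()] supplying the half-LOD value.
#' @return A list of class `nicotine_result`: `by_prison` data frame
#'   (prison_id, concentration, censored_any, duplicate_deviation_pct,
#'   contemporaneous), `qc` (the [qc_exclude()] output) and `median`.
#' @export
process_nicotine <- function(measurements, config = study_config()) {
  qc <- qc_exclude(measurements)
  an <- qc$analysis
  rows <- lapply(split(an, an$prison_id), function(g) {
    if (nrow(g) > 2L) {
      stop("more than two monitors at ", g$prison_id[1],
           ": only duplicate pairs are defined")
    }
    dev <- NA_real_
    if (nrow(g) == 2L) {
      merged <- merge_duplicates(g$concentration[1], g$concentration[2])
      conc <- merged$mean
      dev <- merged$deviation_pct
      cens <- FALSE
    } else {
      conc <- impute_below_lod(g$concentration, g$censored, config$nicotine_half_lod)
      cens <- g$censored
    }
    data.frame(prison_id = g$prison_id[1], concentration = conc,
               censored_any = any(cens), duplicate_deviation_pct = dev,
               contemporaneous = all(g$contemporaneous),
               stringsAsFactors = FALSE)
  })
  by_prison <- do.call(rbind, rows)
  rownames(by_prison) <- NULL
  structure(list(by_prison = by_prison, qc = qc,
                 median = stats::median(by_prison$concentration)),
            class = "nicotine_result")
}

#' @export
print.nicotine_result <- function(x, ...) {
  cat(sprintf("Airborne nicotine: %d prison-level values, median %.2f ug/m3\n",
              nrow(x$by_prison), x$median))
  print(x$by_prison, digits = 3)
  invisible(x)
}

#' Cross-prison median airborne nicotine concentration
#'
#' Median over one processed value per prison (duplicates merged, censored
#' filters at half-LOD); invariant to the order values are supplied.
#'
#' @param values numeric prison-level concentrations (ug/m3).
#' @return The median (ug/m3).
#' @export
nicotine_median <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  stats::median(values)
}
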