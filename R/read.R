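#' Read a Dylos particle-counter log
#'
#' Parses the comma-separated export of the Dylos Logger software: one row
#' per minute with a timestamp and the two channel counts (>0.5 um then
#' >2.5 um, per 0.01 cubic foot). A header line is detected and skipped
#' automatically. Gaps in the minute grid are preserved as gaps — nothing
#' is interpolated.
#'
#' @param path path to the log file.
#' @param device_id device label attached to the series.
#' @param time_format `strptime` format of the timestamp column.
#' @return A [particle_count_series()].
#' @export
read_dylos_log <- function(path, device_id = "dylos",
                           time_format = "%Y-%m-%d %H:%M") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty Dylos log: ", path)
  first_fields <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- length(first_fields) >= 3 &&
    (is.na(suppressWarnings(as.numeric(trimws(first_fields[2])))) &&
       is.na(as.POSIXct(trimws(first_fields[1]), format = time_format, tz = "")))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop("Dylos log has a header but no data rows: ", path)
  rows <- lines[start:length(lines)]
  parts <- strsplit(rows, ",", fixed = TRUE)
  n_fields <- vapply(parts, length, 1L)
  bad <- which(n_fields != 3L)
  if (length(bad)) {
    stop(sprintf("line %d of %s: expected 3 comma-separated fields, found %d",
                 bad[1] + start - 1L, path, n_fields[bad[1]]))
  }
  ts_txt <- trimws(vapply(parts, `[`, "", 1L))
  time <- as.POSIXct(ts_txt, format = time_format, tz = "")
  if (anyNA(time)) {
    bad <- which(is.na(time))[1]
    stop(sprintf("line %d of %s: unparseable timestamp '%s'",
                 bad + start - 1L, path, ts_txt[bad]))
  }
  parse_count <- function(col, nm) {
    txt <- trimws(vapply(parts, `[`, "", col))
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop(sprintf("line %d of %s: %s count '%s' is not a non-negative integer",
                   bad[1] + start - 1L, path, nm, txt[bad[1]]))
    }
    as.integer(v)
  }
  small <- parse_count(2L, "small-channel")
  large <- parse_count(3L, "large-channel")
  if (anyDuplicated(as.numeric(time))) {
    bad <- which(duplicated(as.numeric(time)))[1]
    stop(sprintf("line %d of %s: duplicate timestamp '%s'",
                 bad + start - 1L, path, ts_txt[bad]))
  }
  particle_count_series(time, small, large, device_id = device_id)
}

#' @rdname read_dylos_log
#' @param series a [particle_count_series()] to write.
#' @param header write a header line.
#' @export
write_dylos_log <- function(series, path, time_format = "%Y-%m-%d %H:%M",
                            header = TRUE) {
  stopifnot(inherits(series, "particle_count_series"))
  out <- sprintf("%s,%d,%d", format(series$time, time_format),
                 series$small, series$large)
  if (header) out <- c("timestamp,small,large", out)
  writeLines(out, path)
  invisible(path)
}

#' Read an ambient monitoring-station PM2.5 export
#'
#' Expects a CSV with a timestamp column and a PM2.5 concentration column
#' (ug/m3); a header is detected automatically. Missing-value tokens
#' (empty, `NA`, `-`, `n/a`) are kept as missing observations, never
#' coerced to zero. The returned series is labelled `"ambient"` with no
#' calibration applied.
#'
#' @param path file path.
#' @param time_format `strptime` format of the timestamp column.
#' @return A [pm_series()] with `source_id = "ambient"`.
#' @export
read_ambient_csv <- function(path, time_format = "%Y-%m-%d %H:%M") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ambient file: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  ts_try <- as.POSIXct(trimws(vapply(parts, `[`, "", 1L)),
                       format = time_format, tz = "")
  start <- if (is.na(ts_try[1])) 2L else 1L
  if (start > length(lines)) stop("no parseable rows in ambient file: ", path)
  keep <- start:length(lines)
  time <- ts_try[keep]
  if (anyNA(time)) {
    bad <- which(is.na(time))[1]
    stop(sprintf("line %d of %s: unparseable timestamp", keep[bad], path))
  }
  val_txt <- trimws(vapply(parts[keep], function(p) if (length(p) >= 2) p[2] else "", ""))
  missing_tok <- val_txt %in% c("", "NA", "na", "n/a", "-", "NaN")
  pm <- suppressWarnings(as.numeric(val_txt))
  pm[missing_tok] <- NA_real_
  bad <- which(!missing_tok & is.na(pm))
  if (length(bad)) {
    stop(sprintf("line %d of %s: unparseable concentration '%s'",
                 keep[bad[1]], path, val_txt[bad[1]]))
  }
  if (any(pm < 0, na.rm = TRUE)) {
    bad <- which(!is.na(pm) & pm < 0)[1]
    stop(sprintf("line %d of %s: negative concentration", keep[bad], path))
  }
  if (all(is.na(pm))) stop("no observed concentrations in ambient file: ", path)
  pm_series(time, pm, source_id = "ambient", calibration_ref = "none")
}

#' @rdname read_ambient_csv
#' @param pm a [pm_series()] to write.
#' @export
write_ambient_csv <- function(pm, path, time_format = "%Y-%m-%d %H:%M") {
  stopifnot(inherits(pm, "pm_series"))
  val <- ifelse(is.na(pm$pm25), "NA", format(pm$pm25, trim = TRUE, digits = 10))
  writeLines(c("timestamp,pm25", sprintf("%s,%s", format(pm$time, time_format), val)),
             path)
  invisible(path)
}

#' Read a pre/post-shift salivary cotinine table
#'
#' One row per participant with pre- and post-shift sample times and
#' concentrations plus the eligibility-questionnaire flags. Below-LOD
#' results are written as the token `<LOD` and kept as censored status
#' (numeric value `NA`, censored flag `TRUE`) rather than being replaced by
#' a number at read time. A record whose post-shift time does not follow
#' its pre-shift time is flagged invalid (`valid_times = FALSE`), not
#' dropped.
#'
#' Expected columns: `participant_id, prison_id, pre_time, pre_value,
#' post_time, post_value, smoker, nicotine_product_user, smoking_cohabitant,
#' smoking_vehicle, valid_pre, valid_post`.
#'
#' @param path file path.
#' @param time_format `strptime` format of the sample-time columns.
#' @return A data frame of class `cotinine_records` with numeric
#'   `pre_value`/`post_value`, logical `pre_censored`/`post_censored`,
#'   the questionnaire/validity flags and a derived `valid_times` flag.
#' @export
read_cotinine_table <- function(path, time_format = "%Y-%m-%d %H:%M") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "prison_id", "pre_time", "pre_value",
            "post_time", "post_value", "smoker", "nicotine_product_user",
            "smoking_cohabitant", "smoking_vehicle", "valid_pre", "valid_post")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stop("cotinine table missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  n <- nrow(df)
  parse_conc <- function(txt, col) {
    txt <- trimws(txt)
    cens <- grepl("^<", txt)
    v <- suppressWarnings(as.numeric(txt))
    v[cens] <- NA_real_
    bad <- which(!cens & (is.na(v) | v < 0) & nzchar(txt))
    if (length(bad)) {
      stop(sprintf("line %d of %s: malformed %s '%s'",
                   bad[1] + 1L, path, col, txt[bad[1]]))
    }
    list(value = v, censored = cens)
  }
  pre <- parse_conc(df$pre_value, "pre_value")
  post <- parse_conc(df$post_value, "post_value")
  parse_flag <- function(txt, col) {
    v <- tolower(trimws(txt)) %in% c("true", "t", "1", "yes", "y")
    v
  }
  pre_time <- as.POSIXct(trimws(df$pre_time), format = time_format, tz = "")
  post_time <- as.POSIXct(trimws(df$post_time), format = time_format, tz = "")
  bad <- which(is.na(pre_time) & nzchar(trimws(df$pre_time)))
  if (length(bad)) stop(sprintf("line %d of %s: unparseable pre_time", bad[1] + 1L, path))
  bad <- which(is.na(post_time) & nzchar(trimws(df$post_time)))
  if (length(bad)) stop(sprintf("line %d of %s: unparseable post_time", bad[1] + 1L, path))
  valid_times <- !is.na(pre_time) & !is.na(post_time) & post_time > pre_time
  structure(data.frame(
    participant_id = df$participant_id,
    prison_id = df$prison_id,
    pre_time = pre_time, post_time = post_time,
    pre_value = pre$value, pre_censored = pre$censored,
    post_value = post$value, post_censored = post$censored,
    smoker = parse_flag(df$smoker),
    nicotine_product_user = parse_flag(df$nicotine_product_user),
    smoking_cohabitant = parse_flag(df$smoking_cohabitant),
    smoking_vehicle = parse_flag(df$smoking_vehicle),
    valid_pre = parse_flag(df$valid_pre),
    valid_post = parse_flag(df$valid_post),
    valid_times = valid_times,
    stringsAsFactors = FALSE
  ), class = c("cotinine_records", "data.frame"))
}

#' @rdname read_cotinine_table
#' @param records a `cotinine_records` data frame to write.
#' @export
write_cotinine_table <- function(records, path, time_format = "%Y-%m-%d %H:%M") {
  fmt_conc <- function(v, cens) ifelse(cens, "<LOD", format(v, trim = TRUE, digits = 10))
  out <- data.frame(
    participant_id = records$participant_id,
    prison_id = records$prison_id,
    pre_time = format(records$pre_time, time_format),
    pre_value = fmt_conc(records$pre_value, records$pre_censored),
    post_time = format(records$post_time, time_format),
    post_value = fmt_conc(records$post_value, records$post_censored),
    smoker = records$smoker,
    nicotine_product_user = records$nicotine_product_user,
    smoking_cohabitant = records$smoking_cohabitant,
    smoking_vehicle = records$smoking_vehicle,
    valid_pre = records$valid_pre,
    valid_post = records$valid_post
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a passive-monitor airborne nicotine table
#'
#' One row per passive diffusion monitor: prison, monitor id, measured
#' concentration (ug/m3) or the `<LOD` token, deployment duration and the
#' QC flags (field blank, duplicate pairing, tampering, whether the
#' deployment was contemporaneous with the PM monitoring).
#'
#' @param path file path.
#' @return A data frame of class `nicotine_measurements` with numeric
#'   `concentration` (`NA` when censored or unusable), logical `censored`,
#'   and the QC flag columns.
#' @export
read_nicotine_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("prison_id", "monitor_id", "concentration", "duration_minutes",
            "field_blank", "duplicate_of", "tampered", "contemporaneous")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) stop("nicotine table missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  txt <- trimws(df$concentration)
  cens <- grepl("^<", txt)
  conc <- suppressWarnings(as.numeric(txt))
  conc[cens] <- NA_real_
  bad <- which(!cens & is.na(conc) & nzchar(txt))
  if (length(bad)) stop(sprintf("line %d of %s: malformed concentration '%s'",
                                bad[1] + 1L, path, txt[bad[1]]))
  if (any(conc < 0, na.rm = TRUE)) stop("negative nicotine concentration in ", path)
  flag <- function(x) tolower(trimws(x)) %in% c("true", "t", "1", "yes", "y")
  structure(data.frame(
    prison_id = df$prison_id,
    monitor_id = df$monitor_id,
    concentration = conc,
    censored = cens,
    duration_minutes = as.numeric(df$duration_minutes),
    field_blank = flag(df$field_blank),
    duplicate_of = ifelse(nzchar(trimws(df$duplicate_of)), trimws(df$duplicate_of), NA_character_),
    tampered = flag(df$tampered),
    contemporaneous = flag(df$contemporaneous),
    stringsAsFactors = FALSE
  ), class = c("nicotine_measurements", "data.frame"))
}

#' Bundled study measurement tables
#'
#' Plain-text copies of the published per-prison monitoring results shipped
#' with the package: `shs_area_table()` returns the per-prison 6-day area
#' PM2.5 summary (durations, exceedance percentages, maxima, mean/SD,
#' matched ambient mean/SD); `shs_nicotine_monitors()` the monitor-level
#' passive nicotine results including duplicate pairs, the tampered monitor
#' and the field blanks; `shs_postshift_table()` the per-prison post-shift
#' salivary cotinine summary.
#'
#' @return A data frame (`shs_nicotine_monitors()` returns a
#'   `nicotine_measurements` object).
#' @export
shs_area_table <- function() {
  path <- system.file("extdata", "area_table.csv", package = "shsexposure",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname shs_area_table
#' @export
shs_nicotine_monitors <- function() {
  path <- system.file("extdata", "nicotine_monitors.csv", package = "shsexposure",
                      mustWork = TRUE)
  read_nicotine_table(path)
}

#' @rdname shs_area_table
#' @export
shs_postshift_table <- function() {
  path <- system.file("extdata", "cotinine_postshift.csv", package = "shsexposure",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
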