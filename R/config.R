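#' Study configuration
#'
#' Bundles every cross-module constant of the exposure-assessment pipeline in
#' one auditable place: PM2.5 benchmark thresholds, the day-time clock window,
#' analytical limits of detection and their half-LOD substitution values, the
#' salivary-cotinine smoker cut-off, the particle-count calibration model, the
#' cotinine elimination toxicokinetics and the cotinine-to-PM dosimetry chain.
#'
#' Defaults correspond to the study conventions: WHO indoor-air guideline
#' values of 10 (annual) and 25 (24-h) ug/m3 plus the 246 ug/m3 pre-ban
#' Scottish bar average as exceedance benchmarks; a 07:00-23:00 day window;
#' a passive-monitor nicotine LOD of 0.031 ug/m3 over a 6-day deployment,
#' substituted at the reported half-LOD of 0.016 ug/m3; a salivary cotinine
#' LOD of 0.1 ng/ml substituted at 0.05 ng/ml; and a 5 ng/ml cut-off above
#' which a participant is treated as a likely smoker.
#'
#' Note the nicotine half-LOD default is the reported rounded value 0.016,
#' not 0.031/2 exactly; the validator therefore allows half-LOD values to
#' differ from half the LOD by up to one half-unit in the last printed digit.
#'
#' @param pm_thresholds strictly increasing positive benchmark concentrations
#'   (ug/m3) used for exceedance fractions.
#' @param day_window length-2 character vector of clock times "HH:MM"; the
#'   day-time class is the half-open interval `[start, end)`.
#' @param nicotine_lod,nicotine_half_lod airborne nicotine LOD and the value
#'   substituted for censored filters (ug/m3).
#' @param cotinine_lod,cotinine_half_lod salivary cotinine LOD and
#'   substitution value (ng/ml).
#' @param smoker_cutoff cotinine concentration (ng/ml) above which (strictly)
#'   a pre- or post-shift sample flags the participant as a likely smoker.
#' @param calibration a [calibration_model()].
#' @param tk a [tk_params()].
#' @param rosetta a [rosetta_params()].
#' @param seed integer seed used by the simulation helpers when none is given.
#' @return An object of class `study_config` (a named list).
#' @seealso [read_study_config()], [calibration_model()], [rosetta_params()]
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$pm_thresholds
study_config <- function(pm_thresholds = c(10, 25, 246),
                         day_window = c("07:00", "23:00"),
                         nicotine_lod = 0.031,
                         nicotine_half_lod = 0.016,
                         cotinine_lod = 0.1,
                         cotinine_half_lod = 0.05,
                         smoker_cutoff = 5.0,
                         calibration = calibration_model(),
                         tk = tk_params(),
                         rosetta = rosetta_params(),
                         seed = 1L) {
  cfg <- structure(list(
    pm_thresholds = as.numeric(pm_thresholds),
    day_window = as.character(day_window),
    nicotine_lod = nicotine_lod,
    nicotine_half_lod = nicotine_half_lod,
    cotinine_lod = cotinine_lod,
    cotinine_half_lod = cotinine_half_lod,
    smoker_cutoff = smoker_cutoff,
    calibration = calibration,
    tk = tk,
    rosetta = rosetta,
    seed = as.integer(seed)
  ), class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  th <- cfg$pm_thresholds
  if (length(th) < 1L || any(th <= 0) || any(diff(th) <= 0)) {
    stop("pm_thresholds must be positive and strictly increasing")
  }
  dw <- parse_clock(cfg$day_window)
  if (dw[1] >= dw[2]) stop("day_window start must precede end")
  # half-LOD must equal half the LOD up to rounding of the quoted value
  check_half <- function(half, lod, what) {
    if (half <= 0 || abs(half / (lod / 2) - 1) > 0.05) {
      stop(sprintf("%s half-LOD (%g) is not half the LOD (%g)", what, half, lod))
    }
  }
  check_half(cfg$nicotine_half_lod, cfg$nicotine_lod, "nicotine")
  check_half(cfg$cotinine_half_lod, cfg$cotinine_lod, "cotinine")
  if (cfg$smoker_cutoff <= 0) stop("smoker_cutoff must be positive")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat("  PM2.5 thresholds (ug/m3): ", paste(x$pm_thresholds, collapse = ", "), "\n")
  cat("  day window: [", x$day_window[1], ", ", x$day_window[2], ")\n", sep = "")
  cat("  nicotine LOD / half-LOD (ug/m3): ", x$nicotine_lod, " / ",
      x$nicotine_half_lod, "\n", sep = "")
  cat("  cotinine LOD / half-LOD (ng/ml): ", x$cotinine_lod, " / ",
      x$cotinine_half_lod, "\n", sep = "")
  cat("  smoker cut-off (ng/ml): >", x$smoker_cutoff, "\n", sep = "")
  cat("  cotinine half-life (h): ", x$tk$half_life, "\n", sep = "")
  cat("  PM:nicotine ratio: ", x$rosetta$pm_to_nicotine_ratio, "\n", sep = "")
  invisible(x)
}

#' Cotinine elimination toxicokinetics
#'
#' First-order elimination parameters for salivary cotinine in the general
#' non-smoking population. The default half-life of 16 hours is the
#' population value used throughout the shift back-calculation.
#'
#' @param half_life elimination half-life in hours (> 0).
#' @param source_note free-text provenance note.
#' @return An object of class `tk_params`.
#' @export
tk_params <- function(half_life = 16,
                      source_note = "population salivary cotinine elimination") {
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0) {
    stop("half_life must be a single positive number (hours)")
  }
  structure(list(half_life = as.numeric(half_life), source_note = source_note),
            class = "tk_params")
}

#' Cotinine-to-air dosimetry ('Rosetta Stone') parameters
#'
#' Constants linking a work-shift salivary cotinine increment (ng/ml) to the
#' shift-average airborne nicotine concentration (ug/m3) that would produce
#' it, and onward to an SHS-PM2.5 equivalent. The chain is the standard
#' passive-smoking dosimetry model: nicotine inhaled at breathing rate
#' `breathing_rate` (m3/h) is absorbed with fraction `absorption_fraction`,
#' metabolised to cotinine with fraction `cotinine_conversion`, distributed
#' over `distribution_volume_l` litres, and read in saliva at
#' `saliva_plasma_ratio` times the plasma concentration. SHS-PM2.5 is taken
#' as `pm_to_nicotine_ratio` times the airborne nicotine concentration.
#'
#' The composed uptake coefficient (see [cotinine_uptake_rate()]) is about
#' 0.00696 ng/ml of salivary cotinine per ug/m3 of airborne nicotine per
#' hour of exposure.
#'
#' @param breathing_rate ventilation rate at light work, m3/h.
#' @param absorption_fraction fraction of inhaled nicotine absorbed.
#' @param cotinine_conversion fraction of absorbed nicotine metabolised to
#'   cotinine.
#' @param distribution_volume_l cotinine volume of distribution, litres
#'   (0.9 l/kg for a 70 kg adult).
#' @param saliva_plasma_ratio saliva:plasma cotinine concentration ratio.
#' @param shift_hours representative shift duration used for cohort-level
#'   conversions, hours.
#' @param pm_to_nicotine_ratio SHS-PM2.5 to airborne-nicotine concentration
#'   ratio (dimensionless, ~10 where SHS is the dominant particle source).
#' @return An object of class `rosetta_params`.
#' @seealso [delta_to_pm_equivalent()]
#' @export
rosetta_params <- function(breathing_rate = 0.72,
                           absorption_fraction = 0.71,
                           cotinine_conversion = 0.78,
                           distribution_volume_l = 63,
                           saliva_plasma_ratio = 1.1,
                           shift_hours = 8,
                           pm_to_nicotine_ratio = 10) {
  p <- structure(list(
    breathing_rate = breathing_rate,
    absorption_fraction = absorption_fraction,
    cotinine_conversion = cotinine_conversion,
    distribution_volume_l = distribution_volume_l,
    saliva_plasma_ratio = saliva_plasma_ratio,
    shift_hours = shift_hours,
    pm_to_nicotine_ratio = pm_to_nicotine_ratio
  ), class = "rosetta_params")
  if (any(unlist(p) <= 0)) stop("all rosetta parameters must be positive")
  p
}

#' Salivary-cotinine uptake rate implied by the dosimetry chain
#'
#' The increase in salivary cotinine (ng/ml) produced by one hour of exposure
#' to 1 ug/m3 of airborne nicotine, composed from the dosimetry constants.
#'
#' @param rosetta a [rosetta_params()].
#' @return ng/ml per (ug/m3 airborne nicotine x hour).
#' @export
cotinine_uptake_rate <- function(rosetta = rosetta_params()) {
  with(rosetta,
       breathing_rate * absorption_fraction * cotinine_conversion *
         saliva_plasma_ratio / distribution_volume_l)
}

#' Read or write a study configuration file
#'
#' Configuration files are YAML with the same field names as
#' [study_config()]; nested sections `calibration`, `tk` and `rosetta` map to
#' their constructors. Any field omitted keeps its default, so a file only
#' needs to carry overrides.
#'
#' @param path file path.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("calibration", "tk", "rosetta"))]
  if (!is.null(raw$calibration)) args$calibration <- do.call(calibration_model, raw$calibration)
  if (!is.null(raw$tk)) args$tk <- do.call(tk_params, raw$tk)
  if (!is.null(raw$rosetta)) args$rosetta <- do.call(rosetta_params, raw$rosetta)
  do.call(study_config, args)
}

#' @rdname read_study_config
#' @param config a `study_config` to serialise.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- unclass(config)
  out$calibration <- unclass(out$calibration)
  out$calibration$knots_y <- NULL  # derived; recomputed by the constructor
  out$tk <- unclass(out$tk)
  out$rosetta <- unclass(out$rosetta)
  yaml::write_yaml(out, path)
  invisible(path)
}

# "HH:MM" -> minutes from midnight
parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("clock times must be 'HH:MM': ", paste(x[bad], collapse = ", "))
  hh <- as.integer(vapply(m, `[`, "", 2L))
  mm <- as.integer(vapply(m, `[`, "", 3L))
  if (any(hh > 24 | mm > 59)) stop("invalid clock time")
  hh * 60L + mm
}
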