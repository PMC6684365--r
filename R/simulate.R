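#' Simulation scenario for the synthetic study
#'
#' Defines the forward model the synthetic-data generator draws from: a
#' diurnal smoking-event process over an ambient baseline for the area PM
#' series, a proportional (roughly 10:1 PM:nicotine) passive-sampler
#' model, and a cotinine cohort driven by first-order elimination plus
#' exposure-dependent uptake with assay-LOD censoring.
#'
#' Indoor PM2.5 is `ambient_baseline` plus the superposition of smoking
#' events arriving as a Poisson process with a higher intensity during the
#' 07:00-23:00 day window (`day_event_rate`) than at night
#' (`night_event_rate`); each event contributes a log-normal peak
#' increment that decays exponentially at `decay_rate` (air exchange), and
#' Gaussian observation noise floored at zero is added. Defaults give a
#' 6-day mean around 25-30 ug/m3 — within the 10-140 ug/m3 range typical
#' of the prisons monitored — with day medians well above night medians.
#'
#' @param n_days length of the area deployment, days.
#' @param ambient_baseline outdoor/background PM2.5, ug/m3.
#' @param day_event_rate,night_event_rate smoking events per hour inside
#'   and outside the day window.
#' @param event_mass_gm,event_mass_gsd geometric mean / GSD of the peak
#'   PM2.5 increment per event, ug/m3.
#' @param decay_rate exponential decay of each event's contribution, per
#'   hour.
#' @param obs_noise_sd SD of the observation noise, ug/m3.
#' @param nicotine_ratio PM:nicotine concentration ratio.
#' @param nicotine_noise_sd SD of the passive-sampler error, ug/m3.
#' @param day_window day-time clock window, `"HH:MM"` pair.
#' @param cohort list overriding any of: `n_workers`, `pre_gm`, `pre_gsd`
#'   (pre-shift cotinine distribution, ng/ml), `uptake_coefficient`
#'   (ng/ml salivary cotinine per ug/m3 SHS-PM per hour; `NULL` derives
#'   the exact inverse of the configured dosimetry chain so pipeline
#'   recovery is well-posed), `assay_noise_sd` (ng/ml), `shift_hours`.
#' @param config a [study_config()] supplying LODs, calibration and
#'   dosimetry constants.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_days = 6,
                         ambient_baseline = 6.6,
                         day_event_rate = 3,
                         night_event_rate = 0.3,
                         event_mass_gm = 12,
                         event_mass_gsd = 2,
                         decay_rate = 1.5,
                         obs_noise_sd = 2,
                         nicotine_ratio = 10,
                         nicotine_noise_sd = 0.02,
                         day_window = c("07:00", "23:00"),
                         cohort = list(),
                         config = study_config()) {
  co <- utils::modifyList(list(
    n_workers = 407L,
    pre_gm = 0.10, pre_gsd = 2.5,
    uptake_coefficient = NULL,
    assay_noise_sd = 0.05,
    shift_hours = 8
  ), cohort)
  if (is.null(co$uptake_coefficient)) {
    co$uptake_coefficient <- cotinine_uptake_rate(config$rosetta) /
      config$rosetta$pm_to_nicotine_ratio
  }
  s <- structure(list(
    n_days = n_days, ambient_baseline = ambient_baseline,
    day_event_rate = day_event_rate, night_event_rate = night_event_rate,
    event_mass_gm = event_mass_gm, event_mass_gsd = event_mass_gsd,
    decay_rate = decay_rate, obs_noise_sd = obs_noise_sd,
    nicotine_ratio = nicotine_ratio, nicotine_noise_sd = nicotine_noise_sd,
    day_window = day_window, cohort = co, config = config
  ), class = "sim_scenario")
  with(s, stopifnot(n_days > 0, ambient_baseline >= 0,
                    day_event_rate >= 0, night_event_rate >= 0,
                    event_mass_gm > 0, event_mass_gsd >= 1,
                    decay_rate > 0, obs_noise_sd >= 0, nicotine_ratio > 0))
  stopifnot(co$n_workers >= 1, co$pre_gm > 0, co$pre_gsd >= 1,
            co$uptake_coefficient > 0, co$assay_noise_sd >= 0,
            co$shift_hours > 0)
  s
}

# run expr with a deterministic RNG stream, restoring global state after
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a multi-day area PM2.5 deployment
#'
#' Draws a minute-resolution indoor PM2.5 series from the scenario's
#' smoking-event model and derives the matching two-channel particle-count
#' log by inverting the configured count-to-mass calibration and
#' quantising to whole counts (the coarse channel is a small Poisson
#' fraction of the fine-band count). Identical `(scenario, seed)` give
#' bit-identical output.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param start first timestamp of the deployment.
#' @param device_id device label for the count series.
#' @return A list with elements `pm` (the noiseless-truth-plus-noise
#'   [pm_series()]) and `counts` (the [particle_count_series()]).
#' @export
simulate_area_pm <- function(scenario, seed = 1L,
                             start = as.POSIXct("2016-10-03 00:00:00", tz = ""),
                             device_id = "dylos-sim") {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_sim_seed(seed, {
    n <- as.integer(scenario$n_days * 24 * 60)
    time <- start + 60 * (seq_len(n) - 1L)
    lt <- as.POSIXlt(time)
    clock_min <- lt$hour * 60 + lt$min
    w <- parse_clock(scenario$day_window)
    is_day <- clock_min >= w[1] & clock_min < w[2]
    rate_min <- ifelse(is_day, scenario$day_event_rate, scenario$night_event_rate) / 60
    n_events <- stats::rpois(n, rate_min)
    impulse <- numeric(n)
    idx <- which(n_events > 0)
    if (length(idx)) {
      mass <- stats::rlnorm(sum(n_events[idx]),
                            meanlog = log(scenario$event_mass_gm),
                            sdlog = log(scenario$event_mass_gsd))
      impulse[idx] <- vapply(split(mass, rep(seq_along(idx), n_events[idx])), sum, 0)
    }
    a <- exp(-scenario$decay_rate / 60)
    shs <- as.numeric(stats::filter(impulse, a, method = "recursive"))
    noise <- pmax(stats::rnorm(n, 0, scenario$obs_noise_sd), 0)
    pm_true <- scenario$ambient_baseline + shs + noise
    calib <- scenario$config$calibration
    diff_counts <- round(invert_calibration(calib, pm_true / calib$device_factor))
    large <- stats::rpois(n, 0.03 * diff_counts)
    counts <- particle_count_series(time, small = diff_counts + large,
                                    large = large, device_id = device_id)
    list(pm = pm_series(time, pm_true, source_id = device_id,
                        calibration_ref = "simulated-truth"),
         counts = counts)
  })
}

#' Simulate an ambient monitoring-station series
#'
#' Hourly outdoor PM2.5 at the scenario baseline with Gaussian variation
#' floored at zero.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param start first timestamp.
#' @param sd hour-to-hour SD, ug/m3.
#' @return A [pm_series()] labelled `"ambient"`.
#' @export
simulate_ambient <- function(scenario, seed = 1L,
                             start = as.POSIXct("2016-10-03 00:00:00", tz = ""),
                             sd = 1.5) {
  with_sim_seed(seed, {
    n <- as.integer(scenario$n_days * 24)
    time <- start + 3600 * (seq_len(n) - 1L)
    pm <- pmax(stats::rnorm(n, scenario$ambient_baseline, sd), 0)
    pm_series(time, pm, source_id = "ambient", calibration_ref = "none")
  })
}

#' Simulate a passive nicotine monitor co-located with a PM series
#'
#' The time-averaged SHS component of the PM series (mean above the
#' ambient baseline) divided by the PM:nicotine ratio, plus sampler noise,
#' censored at the passive-monitor LOD.
#'
#' @param pm a [pm_series()] from [simulate_area_pm()].
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param prison_id,monitor_id labels for the returned row.
#' @return A one-row `nicotine_measurements` data frame.
#' @export
simulate_nicotine <- function(pm, scenario, seed = 1L,
                              prison_id = "P1", monitor_id = "M1") {
  stopifnot(inherits(pm, "pm_series"), inherits(scenario, "sim_scenario"))
  with_sim_seed(seed, {
    shs_mean <- mean(pmax(pm$pm25 - scenario$ambient_baseline, 0), na.rm = TRUE)
    conc <- shs_mean / scenario$nicotine_ratio +
      stats::rnorm(1, 0, scenario$nicotine_noise_sd)
    lod <- scenario$config$nicotine_lod
    cens <- conc < lod
    structure(data.frame(
      prison_id = prison_id, monitor_id = monitor_id,
      concentration = if (cens) NA_real_ else conc,
      censored = cens,
      duration_minutes = sum(!is.na(pm$pm25)),
      field_blank = FALSE, duplicate_of = NA_character_,
      tampered = FALSE, contemporaneous = TRUE,
      stringsAsFactors = FALSE
    ), class = c("nicotine_measurements", "data.frame"))
  })
}

#' Simulate a pre/post-shift cotinine cohort
#'
#' Draws pre-shift salivary cotinine from the scenario's log-normal
#' distribution, then generates the measured post-shift value by the same
#' forward model the pipeline inverts: first-order elimination of the
#' pre-shift level over the shift plus uptake proportional to the worker's
#' SHS-PM exposure and shift length, with Gaussian assay noise, floored at
#' zero and censored below the assay LOD. The default uptake coefficient
#' is the exact inverse of the configured dosimetry chain, so running the
#' cohort through [cotinine_exposure()] recovers the input exposure.
#'
#' @param scenario a [sim_scenario()].
#' @param exposure shift-average SHS-PM2.5 per worker, ug/m3 (scalar or
#'   length `n_workers`).
#' @param seed integer seed.
#' @param date sampling day for the timestamps.
#' @return A `cotinine_records` data frame of `n_workers` rows.
#' @export
simulate_cotinine_cohort <- function(scenario, exposure = 25, seed = 1L,
                                     date = "2016-11-14") {
  stopifnot(inherits(scenario, "sim_scenario"))
  co <- scenario$cohort
  cfg <- scenario$config
  with_sim_seed(seed, {
    n <- as.integer(co$n_workers)
    exposure <- rep_len(exposure, n)
    pre_true <- stats::rlnorm(n, log(co$pre_gm), log(co$pre_gsd))
    pre_time <- as.POSIXct(paste(date, "07:30"), tz = "") +
      60 * (sample.int(31L, n, replace = TRUE) - 1L)
    post_time <- pre_time + co$shift_hours * 3600
    eliminated <- predict_post_shift(pre_true, co$shift_hours, cfg$tk)
    uptake <- co$uptake_coefficient * exposure * co$shift_hours
    post_true <- pmax(eliminated + uptake +
                        stats::rnorm(n, 0, co$assay_noise_sd), 0)
    lod <- cfg$cotinine_lod
    pre_cens <- pre_true < lod
    post_cens <- post_true < lod
    structure(data.frame(
      participant_id = sprintf("W%04d", seq_len(n)),
      prison_id = sprintf("P%d", 1L + (seq_len(n) - 1L) %% 15L),
      pre_time = pre_time, post_time = post_time,
      pre_value = ifelse(pre_cens, NA_real_, pre_true),
      pre_censored = pre_cens,
      post_value = ifelse(post_cens, NA_real_, post_true),
      post_censored = post_cens,
      smoker = FALSE, nicotine_product_user = FALSE,
      smoking_cohabitant = FALSE, smoking_vehicle = FALSE,
      valid_pre = TRUE, valid_post = TRUE, valid_times = TRUE,
      stringsAsFactors = FALSE
    ), class = c("cotinine_records", "data.frame"))
  })
}

#' Write a complete synthetic study to disk
#'
#' Generates `n_prisons` area deployments (Dylos-format count logs), one
#' ambient station export, the passive-nicotine monitor table and a
#' cotinine cohort, all under one seed, in the formats the package
#' readers consume.
#'
#' @param scenario a [sim_scenario()].
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_prisons number of area deployments.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_study <- function(scenario, dir, seed = 1L, n_prisons = 15L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(dylos = character(0))
  nic <- NULL
  for (i in seq_len(n_prisons)) {
    sim <- simulate_area_pm(scenario, seed = seed + i,
                            device_id = sprintf("P%d", i))
    p <- file.path(dir, sprintf("dylos_P%d.csv", i))
    write_dylos_log(sim$counts, p)
    paths$dylos <- c(paths$dylos, p)
    nic <- rbind(nic, simulate_nicotine(sim$pm, scenario, seed = seed + i,
                                        prison_id = sprintf("P%d", i),
                                        monitor_id = sprintf("M%d", i)))
  }
  paths$ambient <- file.path(dir, "ambient.csv")
  write_ambient_csv(simulate_ambient(scenario, seed = seed), paths$ambient)
  paths$nicotine <- file.path(dir, "nicotine.csv")
  nic_out <- nic
  nic_out$concentration <- ifelse(nic_out$censored, "<LOD",
                                  format(nic_out$concentration, trim = TRUE,
                                         digits = 10))
  nic_out$censored <- NULL
  nic_out$duplicate_of[is.na(nic_out$duplicate_of)] <- ""
  utils::write.csv(nic_out, paths$nicotine, row.names = FALSE, quote = FALSE)
  paths$cotinine <- file.path(dir, "cotinine.csv")
  write_cotinine_table(simulate_cotinine_cohort(scenario, seed = seed),
                       paths$cotinine)
  invisible(paths)
}
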