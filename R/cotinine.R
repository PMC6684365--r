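#' Eligibility and smoker-exclusion filter for cotinine records
#'
#' Applies the cohort inclusion rules in order: (1) drop participants
#' failing a questionnaire flag (current smoker, nicotine-product user,
#' smoking cohabitant, or smoking during travel to work); (2) drop
#' participants without a valid pre- and post-shift sample (including
#' records whose post-shift time does not follow the pre-shift time);
#' (3) drop likely smokers, i.e. a pre- or post-shift value strictly above
#' the cut-off (default 5 ng/ml). Each exclusion is tallied under its
#' first applicable reason, so the tallies plus the retained count always
#' sum to the input count.
#'
#' @param records a `cotinine_records` data frame (see
#'   [read_cotinine_table()]).
#' @param config a [study_config()].
#' @return A list of class `eligibility_result`: `analysis` (retained
#'   records), `tally` (named integer vector: questionnaire,
#'   invalid_sample, over_cutoff, retained).
#' @export
eligibility_filter <- function(records, config = study_config()) {
  n <- nrow(records)
  if (n == 0L) {
    return(structure(list(analysis = records,
                          tally = c(questionnaire = 0L, invalid_sample = 0L,
                                    over_cutoff = 0L, retained = 0L)),
                     class = "eligibility_result"))
  }
  quest <- records$smoker | records$nicotine_product_user |
    records$smoking_cohabitant | records$smoking_vehicle
  invalid <- !quest & (!records$valid_pre | !records$valid_post | !records$valid_times)
  over <- !quest & !invalid &
    ((!records$pre_censored & !is.na(records$pre_value) &
        records$pre_value > config$smoker_cutoff) |
       (!records$post_censored & !is.na(records$post_value) &
          records$post_value > config$smoker_cutoff))
  keep <- !quest & !invalid & !over
  structure(list(
    analysis = records[keep, , drop = FALSE],
    tally = c(questionnaire = sum(quest), invalid_sample = sum(invalid),
              over_cutoff = sum(over), retained = sum(keep))
  ), class = "eligibility_result")
}

#' @export
print.eligibility_result <- function(x, ...) {
  t <- x$tally
  cat(sprintf("Cotinine eligibility: %d retained (excluded: %d questionnaire, %d invalid sample, %d above smoker cut-off)\n",
              t[["retained"]], t[["questionnaire"]], t[["invalid_sample"]],
              t[["over_cutoff"]]))
  invisible(x)
}

#' Half-LOD substitution for censored cotinine values
#'
#' @param values numeric cotinine concentrations, ng/ml (`NA` where
#'   censored).
#' @param censored logical below-LOD indicator.
#' @param half_lod substitution value, ng/ml (default 0.05).
#' @return numeric vector.
#' @export
impute_cotinine_lod <- function(values, censored, half_lod = 0.05) {
  impute_below_lod(values, censored, half_lod)
}

#' Project a pre-shift cotinine value forward under elimination
#'
#' First-order elimination of salivary cotinine: the hypothetical
#' post-shift concentration a worker would show after `elapsed` hours with
#' zero nicotine intake is `pre * 2^(-elapsed / half_life)`. The
#' projection is a semigroup in elapsed time: projecting t1 then t2 equals
#' projecting t1 + t2.
#'
#' @param pre pre-shift concentration, ng/ml (>= 0).
#' @param elapsed hours between the two samples (>= 0).
#' @param tk a [tk_params()].
#' @return predicted zero-exposure post-shift concentration, ng/ml.
#' @export
predict_post_shift <- function(pre, elapsed, tk = tk_params()) {
  if (any(elapsed < 0)) stop("elapsed time must be non-negative")
  if (any(pre < 0, na.rm = TRUE)) stop("pre-shift concentration must be non-negative")
  pre * 2^(-elapsed / tk$half_life)
}

#' Shift cotinine increment
#'
#' Difference between the measured post-shift concentration and the
#' zero-exposure projection; positive values indicate nicotine intake —
#' i.e. SHS exposure — during the shift. The sign is preserved.
#'
#' @param measured_post measured post-shift concentration, ng/ml.
#' @param predicted_post output of [predict_post_shift()], ng/ml.
#' @return increment, ng/ml (may be negative).
#' @export
cotinine_delta <- function(measured_post, predicted_post) {
  measured_post - predicted_post
}

#' Select the change-sensitive sub-sample
#'
#' Restricts to participants able to express a measurable shift change:
#' the pre-shift sample must be above the LOD and the zero-exposure
#' projected post-shift value must also exceed the LOD. Records failing
#' either rule carry no usable increment information.
#'
#' @param records data frame with logical `pre_censored` and numeric
#'   `predicted_post` columns.
#' @param cotinine_lod assay LOD, ng/ml.
#' @return The qualifying rows of `records`.
#' @export
select_subsample <- function(records, cotinine_lod = 0.1) {
  keep <- !records$pre_censored & records$predicted_post > cotinine_lod
  records[keep, , drop = FALSE]
}

#' Convert a cotinine increment to a shift-average SHS-PM2.5 equivalent
#'
#' Inverts the dosimetry chain of [rosetta_params()]: an increment `delta`
#' accrued over `elapsed` hours implies a shift-average airborne nicotine
#' concentration `delta / (k * elapsed)`, where `k` is the composed
#' salivary-cotinine uptake rate ([cotinine_uptake_rate()]); multiplying
#' by the PM:nicotine ratio gives the SHS-PM2.5 equivalent. The map is
#' linear in `delta` and sends zero to zero.
#'
#' @param delta cotinine increment, ng/ml.
#' @param elapsed exposure duration, hours (> 0); defaults to the
#'   representative shift duration in `rosetta`.
#' @param rosetta a [rosetta_params()].
#' @return SHS-PM2.5 equivalent concentration, ug/m3.
#' @export
#' @examples
#' delta_to_pm_equivalent(0.138)  # cohort-median increment over an 8-h shift
delta_to_pm_equivalent <- function(delta, elapsed = rosetta$shift_hours,
                                   rosetta = rosetta_params()) {
  if (any(elapsed <= 0)) stop("elapsed time must be positive")
  k <- cotinine_uptake_rate(rosetta)
  nicotine <- delta / (k * elapsed)
  rosetta$pm_to_nicotine_ratio * nicotine
}

#' Post-shift cohort summary table
#'
#' Per-prison and overall summaries of post-shift salivary cotinine on
#' half-LOD-imputed values: n, n below LOD, 25th/75th percentiles and
#' median per prison plus an "All" row, with pooled geometric mean and
#' GSD.
#'
#' @param records data frame with `prison_id`, numeric `post_value` and
#'   logical `post_censored`.
#' @param config a [study_config()].
#' @return A list of class `cotinine_cohort_summary`: `by_prison` data
#'   frame (last row "All"), `gm`, `gsd`.
#' @export
cohort_summaries <- function(records, config = study_config()) {
  post <- impute_cotinine_lod(records$post_value, records$post_censored,
                              config$cotinine_half_lod)
  one <- function(id, v, cens) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(prison_id = id, n = length(v), n_below_lod = sum(cens),
               p25 = q[1], p75 = q[3], median = q[2], stringsAsFactors = FALSE)
  }
  rows <- lapply(split(seq_len(nrow(records)), records$prison_id), function(i) {
    one(records$prison_id[i[1]], post[i], records$post_censored[i])
  })
  by_prison <- do.call(rbind, c(rows, list(one("All", post, records$post_censored))))
  rownames(by_prison) <- NULL
  gs <- geometric_stats(post)
  structure(list(by_prison = by_prison, gm = gs[["gm"]], gsd = gs[["gsd"]]),
            class = "cotinine_cohort_summary")
}

#' @export
print.cotinine_cohort_summary <- function(x, ...) {
  cat(sprintf("Post-shift salivary cotinine: GM %.3f ng/ml (GSD %.2f)\n", x$gm, x$gsd))
  print(x$by_prison, digits = 3)
  invisible(x)
}

#' Estimate shift SHS exposure from pre/post salivary cotinine
#'
#' The package's central estimator. Starting from raw participant records
#' it (1) applies the eligibility and smoker-exclusion rules
#' ([eligibility_filter()]); (2) computes each participant's elapsed time
#' from the recorded sample timestamps; (3) projects the pre-shift value
#' forward under first-order elimination to the hypothetical zero-exposure
#' post-shift value ([predict_post_shift()]); (4) forms the shift
#' increment ([cotinine_delta()]), using the measured post-shift value
#' (half-LOD substituted when censored); (5) restricts to the
#' change-sensitive sub-sample ([select_subsample()]); and (6) converts
#' increments to shift-average SHS-PM2.5 equivalents through the dosimetry
#' chain ([delta_to_pm_equivalent()]). The cohort-level PM equivalent is
#' the conversion of the sub-sample median increment at the representative
#' shift duration.
#'
#' @param records a `cotinine_records` data frame.
#' @param config a [study_config()].
#' @return An object of class `cotinine_exposure` with elements
#'   `analysis` (eligible records augmented with `elapsed_h`,
#'   `predicted_post`, `delta`), `subsample` (qualifying rows with
#'   `pm_equivalent`), `tally`, `summaries`
#'   ([cohort_summaries()] of the analysis set) and `coefficients`
#'   (`median_delta`, `pm_equivalent`). Supports `print()`, `summary()`,
#'   `coef()`, `predict()` and `residuals()`.
#' @export
#' @examples
#' scen <- sim_scenario(cohort = list(n_workers = 50))
#' rec <- simulate_cotinine_cohort(scen, exposure = 25, seed = 1)
#' fit <- cotinine_exposure(rec)
#' coef(fit)
cotinine_exposure <- function(records, config = study_config()) {
  elig <- eligibility_filter(records, config)
  an <- elig$analysis
  if (nrow(an) == 0L) stop("no eligible records")
  an$elapsed_h <- as.numeric(difftime(an$post_time, an$pre_time, units = "hours"))
  pre_imp <- impute_cotinine_lod(an$pre_value, an$pre_censored,
                                 config$cotinine_half_lod)
  post_imp <- impute_cotinine_lod(an$post_value, an$post_censored,
                                  config$cotinine_half_lod)
  an$predicted_post <- predict_post_shift(pre_imp, an$elapsed_h, config$tk)
  an$delta <- cotinine_delta(post_imp, an$predicted_post)
  sub <- select_subsample(an, config$cotinine_lod)
  sub$pm_equivalent <- delta_to_pm_equivalent(sub$delta, sub$elapsed_h,
                                              config$rosetta)
  median_delta <- stats::median(sub$delta)
  structure(list(
    analysis = an,
    subsample = sub,
    tally = elig$tally,
    summaries = cohort_summaries(an, config),
    coefficients = c(
      median_delta = median_delta,
      pm_equivalent = delta_to_pm_equivalent(median_delta,
                                             config$rosetta$shift_hours,
                                             config$rosetta)
    ),
    n_positive = sum(sub$delta > 0),
    config = config,
    call = match.call()
  ), class = "cotinine_exposure")
}

#' @export
print.cotinine_exposure <- function(x, ...) {
  cat("Shift SHS exposure from salivary cotinine\n")
  t <- x$tally
  cat(sprintf("  cohort: %d eligible of %d records\n", t[["retained"]], sum(t)))
  cat(sprintf("  sub-sample: %d participants (%d with positive increment)\n",
              nrow(x$subsample), x$n_positive))
  cat(sprintf("  median increment: %+.3f ng/ml\n",
              x$coefficients[["median_delta"]]))
  cat(sprintf("  shift-average SHS-PM2.5 equivalent: %.1f ug/m3\n",
              x$coefficients[["pm_equivalent"]]))
  invisible(x)
}

#' @export
coef.cotinine_exposure <- function(object, ...) object$coefficients

#' @export
residuals.cotinine_exposure <- function(object, ...) object$analysis$delta

#' @export
summary.cotinine_exposure <- function(object, ...) {
  out <- list(tally = object$tally,
              n_subsample = nrow(object$subsample),
              n_positive = object$n_positive,
              delta_quartiles = stats::quantile(object$subsample$delta,
                                                c(0.25, 0.5, 0.75)),
              delta_range = range(object$subsample$delta),
              coefficients = object$coefficients,
              cohort = object$summaries)
  class(out) <- "summary.cotinine_exposure"
  out
}

#' @export
print.summary.cotinine_exposure <- function(x, ...) {
  t <- x$tally
  cat("Shift SHS exposure from salivary cotinine\n")
  cat(sprintf("  records: %d; excluded %d (questionnaire), %d (invalid sample), %d (smoker cut-off); analysed %d\n",
              sum(t), t[["questionnaire"]], t[["invalid_sample"]],
              t[["over_cutoff"]], t[["retained"]]))
  cat(sprintf("  sub-sample n = %d, positive increments = %d\n",
              x$n_subsample, x$n_positive))
  cat(sprintf("  increment: median %+.3f ng/ml (IQR %+.3f to %+.3f; range %+.3f to %+.3f)\n",
              x$delta_quartiles[[2]], x$delta_quartiles[[1]],
              x$delta_quartiles[[3]], x$delta_range[1], x$delta_range[2]))
  cat(sprintf("  cohort shift-average SHS-PM2.5 equivalent: %.1f ug/m3\n",
              x$coefficients[["pm_equivalent"]]))
  cat("\nPost-shift cotinine summary:\n")
  print(x$cohort)
  invisible(x)
}

#' @export
#' @rdname cotinine_exposure
#' @param object a fitted `cotinine_exposure`.
#' @param newdata optional `cotinine_records` to score with the fitted
#'   configuration; defaults to the analysis set.
#' @param ... unused.
predict.cotinine_exposure <- function(object, newdata = NULL, ...) {
  cfg <- object$config
  if (is.null(newdata)) return(object$analysis$predicted_post)
  elapsed <- as.numeric(difftime(newdata$post_time, newdata$pre_time,
                                 units = "hours"))
  pre <- impute_cotinine_lod(newdata$pre_value, newdata$pre_censored,
                             cfg$cotinine_half_lod)
  predict_post_shift(pre, elapsed, cfg$tk)
}
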