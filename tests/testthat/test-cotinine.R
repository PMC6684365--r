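test_that("eligibility filter reproduces the cohort arithmetic and tallies", {
  # 422 records: 3 without valid samples, 12 above the smoker cut-off
  scen <- sim_scenario(cohort = list(n_workers = 422))
  rec <- simulate_cotinine_cohort(scen, exposure = 25, seed = 2)
  rec$valid_post[1:3] <- FALSE
  rec$post_value[4:15] <- 6.2
  rec$post_censored[4:15] <- FALSE
  out <- eligibility_filter(rec)
  expect_equal(out$tally[["invalid_sample"]], 3L)
  expect_equal(out$tally[["over_cutoff"]], 12L)
  expect_equal(out$tally[["retained"]], 407L)
  expect_equal(sum(out$tally), 422L)
  expect_equal(nrow(out$analysis), 407L)

  empty <- rec[0, ]
  out0 <- eligibility_filter(empty)
  expect_equal(sum(out0$tally), 0L)
  expect_equal(nrow(out0$analysis), 0L)
})

test_that("smoker cut-off is strict: exactly 5.0 ng/ml is retained", {
  at_cut <- make_record(post = 5.0)
  above <- make_record(id = "W2", post = 5.0001)
  out <- eligibility_filter(bind_records(at_cut, above))
  expect_equal(out$analysis$participant_id, "W1")
  expect_equal(out$tally[["over_cutoff"]], 1L)
})

test_that("questionnaire flags exclude with their own tally", {
  recs <- bind_records(
    make_record(id = "W1", smoker = TRUE),
    make_record(id = "W2", cohabitant = TRUE),
    make_record(id = "W3")
  )
  out <- eligibility_filter(recs)
  expect_equal(out$tally[["questionnaire"]], 2L)
  expect_equal(out$analysis$participant_id, "W3")
})

test_that("cotinine half-LOD substitution is 0.05 and leaves detects alone", {
  expect_equal(impute_cotinine_lod(NA_real_, TRUE), 0.05)
  expect_equal(impute_cotinine_lod(0.155, FALSE), 0.155)
  cens <- rep(c(TRUE, FALSE), c(139, 268))
  vals <- c(rep(NA_real_, 139), rlnorm(268, log(0.2), 0.5))
  out <- impute_cotinine_lod(vals, cens)
  expect_equal(sum(out == 0.05), 139L)
})

test_that("elimination projection follows first-order kinetics", {
  expect_equal(predict_post_shift(0.7, 0), 0.7)
  expect_equal(predict_post_shift(1.0, 16), 0.5)  # one default half-life
  expect_equal(predict_post_shift(0.4, 8), 0.4 * 2^(-0.5))
  expect_equal(predict_post_shift(0.4, 8, tk_params(half_life = 16)),
               0.2828427, tolerance = 1e-6)
  expect_error(predict_post_shift(0.4, -1), "non-negative")
})

test_that("elimination projection is a semigroup in elapsed time", {
  set.seed(21)
  tk <- tk_params(half_life = 16)
  for (i in 1:20) {
    pre <- runif(1, 0.05, 3)
    t1 <- runif(1, 0, 12); t2 <- runif(1, 0, 12)
    expect_equal(predict_post_shift(predict_post_shift(pre, t1, tk), t2, tk),
                 predict_post_shift(pre, t1 + t2, tk))
  }
})

test_that("the shift increment preserves sign", {
  expect_equal(cotinine_delta(0.5, 0.362), 0.138)
  expect_equal(cotinine_delta(0.4, 0.4), 0)
  expect_equal(cotinine_delta(0.1, 0.975), -0.875)
})

test_that("sub-sample selection requires detectable pre and projected post", {
  recs <- bind_records(
    make_record(id = "A", pre = 0.5, pre_cens = TRUE),   # rule 1
    make_record(id = "B", pre = 0.11),                   # projected 0.078 < LOD
    make_record(id = "C", pre = 0.3)                     # projected 0.21 > LOD
  )
  recs$predicted_post <- predict_post_shift(
    impute_cotinine_lod(recs$pre_value, recs$pre_censored), 8)
  sub <- select_subsample(recs)
  expect_equal(sub$participant_id, "C")
})

test_that("increment-to-PM conversion is linear and reproduces the dosimetry chain", {
  expect_equal(delta_to_pm_equivalent(0), 0)
  expect_equal(delta_to_pm_equivalent(2 * 0.07), 2 * delta_to_pm_equivalent(0.07))
  # hand computation through the chain: delta / (k * t) * ratio with
  # k = 0.72 * 0.71 * 0.78 * 1.1 / 63
  k <- 0.72 * 0.71 * 0.78 * 1.1 / 63
  expect_equal(delta_to_pm_equivalent(0.1, elapsed = 6),
               10 * 0.1 / (k * 6))
  # negative increments map to negative equivalents (sign preserved)
  expect_lt(delta_to_pm_equivalent(-0.1), 0)
  expect_error(delta_to_pm_equivalent(0.1, elapsed = 0), "positive")
})

test_that("cohort summaries produce the table shape with GM/GSD", {
  recs <- bind_records(
    make_record(id = "W1", prison = "P1", post = 0.5, post_cens = TRUE),
    make_record(id = "W2", prison = "P1", post = 0.5, post_cens = TRUE),
    make_record(id = "W3", prison = "P2", post = 0.3)
  )
  cs <- cohort_summaries(recs)
  p1 <- cs$by_prison[cs$by_prison$prison_id == "P1", ]
  expect_equal(p1$median, 0.05)          # all-censored prison sits at half-LOD
  expect_equal(p1$n_below_lod, 2L)
  p2 <- cs$by_prison[cs$by_prison$prison_id == "P2", ]
  expect_equal(p2$p25, 0.3)              # singleton: all quantiles equal
  expect_equal(p2$p75, 0.3)
  expect_equal(cs$by_prison$prison_id[nrow(cs$by_prison)], "All")
  expect_equal(cs$by_prison$n[nrow(cs$by_prison)], 3L)
})

test_that("cohort GM/GSD are recovered from a synthetic log-normal cohort", {
  # n = 407 draws from GM 0.145, GSD 2.48; the sampling-error envelope for
  # log GM at this n is log(GSD)/sqrt(n) ~ 0.045, so 3 SE ~ 15% on GM
  set.seed(8)
  post <- rlnorm(407, log(0.145), log(2.48))
  recs <- make_record()[rep(1, 407), ]
  recs$participant_id <- sprintf("W%03d", 1:407)
  recs$post_value <- post
  recs$post_censored <- FALSE
  cs <- cohort_summaries(structure(recs, class = c("cotinine_records", "data.frame")))
  expect_lt(abs(cs$gm / 0.145 - 1), 3 * log(2.48) / sqrt(407))
  expect_lt(abs(log(cs$gsd) / log(2.48) - 1), 0.15)
})

test_that("the fitted estimator is internally consistent end to end", {
  scen <- sim_scenario(cohort = list(n_workers = 300))
  rec <- simulate_cotinine_cohort(scen, exposure = 25, seed = 5)
  fit <- cotinine_exposure(rec)
  expect_s3_class(fit, "cotinine_exposure")
  # tallies account for every input record
  expect_equal(sum(fit$tally), 300L)
  # sub-sample members obey both selection rules
  expect_true(all(!fit$subsample$pre_censored))
  expect_true(all(fit$subsample$predicted_post > 0.1))
  # coef/residuals/predict wire through
  expect_named(coef(fit), c("median_delta", "pm_equivalent"))
  expect_equal(residuals(fit), fit$analysis$delta)
  expect_equal(predict(fit), fit$analysis$predicted_post)
  expect_equal(predict(fit, newdata = rec[1:5, ]),
               predict_post_shift(
                 impute_cotinine_lod(rec$pre_value[1:5], rec$pre_censored[1:5]),
                 as.numeric(difftime(rec$post_time[1:5], rec$pre_time[1:5],
                                     units = "hours"))))
  expect_output(print(fit), "sub-sample")
  expect_output(print(summary(fit)), "increment")
})

test_that("zero exposure with no noise gives exactly zero increments", {
  scen <- sim_scenario(cohort = list(n_workers = 100, pre_gm = 0.4,
                                     assay_noise_sd = 0))
  rec <- simulate_cotinine_cohort(scen, exposure = 0, seed = 9)
  fit <- cotinine_exposure(rec)
  expect_true(all(abs(fit$subsample$delta) < 1e-12))
  expect_equal(coef(fit)[["pm_equivalent"]], 0)
})

test_that("zero-exposure cohorts with assay noise have increments centred on 0", {
  # pre-shift GM well above the LOD so censoring cannot shift the median;
  # 400 cohorts of 150 workers
  scen <- sim_scenario(cohort = list(n_workers = 150, pre_gm = 0.4,
                                     assay_noise_sd = 0.05))
  meds <- vapply(1:400, function(s) {
    fit <- cotinine_exposure(simulate_cotinine_cohort(scen, exposure = 0,
                                                      seed = s))
    stats::median(fit$subsample$delta)
  }, 0)
  mc_se <- stats::sd(meds) / sqrt(length(meds))
  expect_lt(abs(stats::median(meds)), 2 * mc_se)
})

test_that("the pipeline recovers constant exposures through the forward model", {
  scen <- sim_scenario()  # study-scale cohort of 407
  for (C in c(10, 25, 50)) {
    meds <- vapply(1:100, function(s) {
      fit <- cotinine_exposure(simulate_cotinine_cohort(scen, exposure = C,
                                                        seed = 7000 + s))
      coef(fit)[["pm_equivalent"]]
    }, 0)
    expect_lt(abs(stats::median(meds) / C - 1), 0.15)
  }
})
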