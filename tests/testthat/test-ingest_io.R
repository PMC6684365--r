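test_that("a minimal Dylos log parses with the nominal minute interval", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2016-10-03 00:00,120,15",
               "2016-10-03 00:01,130,12",
               "2016-10-03 00:02,110,18"), path)
  s <- read_dylos_log(path, device_id = "D1")
  expect_s3_class(s, "particle_count_series")
  expect_equal(nrow(s), 3L)
  expect_equal(attr(s, "interval_s"), 60)
  expect_equal(s$small, c(120L, 130L, 110L))
})

test_that("Dylos reader rejects malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,small,large",
               "2016-10-03 00:00,120,15",
               "2016-10-03 00:01,-5,12"), path)
  expect_error(read_dylos_log(path), "line 3.*non-negative integer")

  writeLines(c("2016-10-03 00:00,120,15",
               "2016-10-03 00:00,130,12"), path)
  expect_error(read_dylos_log(path), "line 2.*duplicate timestamp")

  writeLines(c("2016-10-03 00:00,120,15",
               "not-a-time,130,12"), path)
  expect_error(read_dylos_log(path), "line 2.*timestamp")

  writeLines(character(0), path)
  expect_error(read_dylos_log(path), "empty")
})

test_that("a simulated 6-day log round-trips write -> read losslessly", {
  sim <- simulate_area_pm(sim_scenario(), seed = 11, device_id = "D6")
  expect_equal(nrow(sim$counts), 6 * 24 * 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dylos_log(sim$counts, path)
  back <- read_dylos_log(path, device_id = "D6")
  expect_equal(back$small, sim$counts$small)
  expect_equal(back$large, sim$counts$large)
  expect_equal(as.numeric(back$time), as.numeric(sim$counts$time))
  expect_equal(attr(back, "device_id"), "D6")
})

test_that("ambient reader keeps missing tokens missing and rejects bad values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,pm25",
               sprintf("2016-10-03 %02d:00,6.6", 0:23)), path)
  s <- read_ambient_csv(path)
  expect_equal(attr(s, "source_id"), "ambient")
  expect_equal(mean(s$pm25), 6.6)

  writeLines(c("2016-10-03 00:00,6.6",
               "2016-10-03 01:00,NA",
               "2016-10-03 02:00,7.0"), path)
  s <- read_ambient_csv(path)
  expect_true(is.na(s$pm25[2]))
  expect_equal(sum(!is.na(s$pm25)), 2L)

  writeLines("2016-10-03 00:00,-3", path)
  expect_error(read_ambient_csv(path), "negative")
  writeLines(c("timestamp,pm25", "2016-10-03 00:00,NA"), path)
  expect_error(read_ambient_csv(path), "no observed")
})

test_that("simulated ambient file mean matches the configured baseline", {
  scen <- sim_scenario(n_days = 30)
  amb <- simulate_ambient(scen, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ambient_csv(amb, path)
  back <- read_ambient_csv(path)
  se <- sd(back$pm25) / sqrt(nrow(back))
  expect_lt(abs(mean(back$pm25) - scen$ambient_baseline), 2 * se)
})

test_that("cotinine table preserves censoring and flags inverted times", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,prison_id,pre_time,pre_value,post_time,post_value,smoker,nicotine_product_user,smoking_cohabitant,smoking_vehicle,valid_pre,valid_post",
               "W1,P1,2016-11-14 07:30,<LOD,2016-11-14 15:30,0.2,false,false,false,false,true,true",
               "W2,P1,2016-11-14 15:30,0.3,2016-11-14 07:30,0.2,false,false,false,false,true,true"),
             path)
  rec <- read_cotinine_table(path)
  expect_true(rec$pre_censored[1])
  expect_true(is.na(rec$pre_value[1]))
  expect_false(rec$valid_times[2])   # post before pre: flagged, not dropped
  expect_equal(nrow(rec), 2L)

  writeLines(c("participant_id,prison_id,pre_time,pre_value,post_time,post_value,smoker,nicotine_product_user,smoking_cohabitant,smoking_vehicle,valid_pre,valid_post",
               "W1,P1,2016-11-14 07:30,oops,2016-11-14 15:30,0.2,false,false,false,false,true,true"),
             path)
  expect_error(read_cotinine_table(path), "line 2.*pre_value")
})

test_that("a simulated cohort round-trips through the cotinine table format", {
  scen <- sim_scenario(cohort = list(n_workers = 422))
  rec <- simulate_cotinine_cohort(scen, exposure = 25, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cotinine_table(rec, path)
  back <- read_cotinine_table(path)
  expect_equal(nrow(back), 422L)
  expect_equal(back$pre_censored, rec$pre_censored)
  expect_equal(back$post_censored, rec$post_censored)
  expect_equal(back$pre_value, rec$pre_value, tolerance = 1e-8)
  expect_equal(as.numeric(back$pre_time), as.numeric(rec$pre_time))
  expect_equal(as.numeric(back$post_time), as.numeric(rec$post_time))
})

test_that("study configuration validates its invariants and round-trips YAML", {
  expect_error(study_config(pm_thresholds = c(25, 10)), "increasing")
  expect_error(study_config(nicotine_half_lod = 0.02), "half the LOD")
  expect_error(study_config(day_window = c("23:00", "07:00")), "precede")
  cfg <- study_config(smoker_cutoff = 4, tk = tk_params(half_life = 18))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$smoker_cutoff, 4)
  expect_equal(back$tk$half_life, 18)
  expect_equal(back$pm_thresholds, cfg$pm_thresholds)
  expect_equal(back$rosetta$pm_to_nicotine_ratio,
               cfg$rosetta$pm_to_nicotine_ratio)
})
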