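test_that("series summaries report mean, n-1 SD, maximum and observed minutes", {
  s <- summarize_series(tiny_pm(rep(30, 10)))
  expect_equal(s$mean, 30)
  expect_equal(s$sd, 0)
  expect_equal(s$maximum, 30)
  expect_equal(s$duration_minutes, 10L)

  s <- summarize_series(tiny_pm(c(10, 20, 30)))
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(s$maximum, 30)

  # missing minutes drop out of every denominator
  s <- summarize_series(tiny_pm(c(10, NA, 30)))
  expect_equal(s$duration_minutes, 2L)
  expect_equal(s$mean, 20)
  expect_error(summarize_series(tiny_pm(rep(NA_real_, 3))), "no observed")
})

test_that("exceedance uses strict inequality over observed minutes", {
  th <- c(10, 25, 246)
  expect_equal(unname(exceedance_fractions(tiny_pm(rep(5, 4)), th)), c(0, 0, 0))
  expect_equal(unname(exceedance_fractions(tiny_pm(rep(30, 4)), th)), c(100, 100, 0))
  expect_equal(unname(exceedance_fractions(tiny_pm(c(5, 15, 30, 300)), th)),
               c(75, 50, 25))
  # boundary value is not an exceedance
  expect_equal(unname(exceedance_fractions(tiny_pm(rep(10, 4)), th)), c(0, 0, 0))
  expect_error(exceedance_fractions(tiny_pm(1:3), c(25, 10)), "increasing")
})

test_that("exceedance is monotone in thresholds and in the series", {
  set.seed(7)
  for (i in 1:20) {
    x <- rlnorm(500, log(20), 1)
    pm <- tiny_pm(x)
    th <- sort(runif(4, 1, 300))
    f <- unname(exceedance_fractions(pm, th))
    expect_true(all(diff(f) <= 0))          # larger threshold never increases
    f_up <- unname(exceedance_fractions(tiny_pm(x + 5), th))
    expect_true(all(f_up >= f))             # raising every value raises fractions
  }
})

test_that("day/night partition tiles the clock and medians follow the window", {
  n <- 2 * 24 * 60
  lt <- as.POSIXlt(minute_times(n))
  is_day <- (lt$hour * 60 + lt$min) >= 420 & (lt$hour * 60 + lt$min) < 1380
  expect_equal(sum(is_day) + sum(!is_day), n)  # every minute in exactly one class

  x <- ifelse(is_day, 40, 10)
  dn <- day_night_medians(tiny_pm(x))
  expect_equal(unname(dn), c(40, 10))

  dn <- day_night_medians(tiny_pm(rep(17, n)))
  expect_equal(unname(dn), c(17, 17))

  expect_error(day_night_medians(tiny_pm(1:10)), "full day")
})

test_that("published per-prison durations pool to the reported totals", {
  area <- shs_area_table()
  expect_equal(sum(area$duration_minutes), 128431)
  expect_equal(round(mean(area$duration_minutes)), 8562)
})

test_that("cross-prison pooling matches a brute-force sort-based median oracle", {
  oracle_median <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  set.seed(13)
  for (i in 1:25) {
    n <- sample(1:20, 1)
    df <- data.frame(a = runif(n, 0, 100), b = rlnorm(n), id = letters[1:n][1:n])
    pooled <- pool_across_prisons(df)
    expect_equal(pooled[["a"]], oracle_median(df$a))
    expect_equal(pooled[["b"]], oracle_median(df$b))
  }
})

test_that("mobile summaries handle singletons, pairs, and recover a known GM", {
  one <- data.frame(prison_id = "P1", category = "reception",
                    duration_minutes = 30, mean_pm25 = 2.4)
  ms <- summarize_mobile(one)
  expect_equal(ms$by_category$median, 2.4)
  expect_equal(ms$by_category$mean, 2.4)
  expect_equal(ms$by_category$p25, ms$by_category$p75)

  two <- data.frame(prison_id = c("P1", "P2"), category = "reception",
                    duration_minutes = 30, mean_pm25 = c(1.0, 4.1))
  ms <- summarize_mobile(two)
  expect_equal(ms$by_category$min, 1.0)
  expect_equal(ms$by_category$max, 4.1)
  expect_equal(ms$by_category$mean, 2.55)

  expect_error(summarize_mobile(data.frame(prison_id = "P1", category = "lobby",
                                           duration_minutes = 30, mean_pm25 = 1)),
               "unknown location")
  expect_error(summarize_mobile(transform(one, mean_pm25 = 0)), "non-positive")

  # 86 log-normal measurements with GM 24, GSD 4: pooled GM within the
  # 25% sampling-error envelope at this n (fixed seed)
  set.seed(1)
  vals <- rlnorm(86, log(24), log(4))
  cats <- sample(mobile_categories(), 86, replace = TRUE)
  ms <- summarize_mobile(data.frame(prison_id = "P1", category = cats,
                                    duration_minutes = 30, mean_pm25 = vals))
  expect_lt(abs(ms$pooled$gm / 24 - 1), 0.25)
  expect_equal(ms$pooled$n, 86)
  # table ordered by median
  expect_true(!is.unsorted(ms$by_category$median))
})
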