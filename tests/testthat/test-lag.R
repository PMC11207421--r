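test_that("the lagged-Pearson profile equals a naive per-shift loop", {
  set.seed(42)
  for (i in 1:3) {
    t <- seq(-100, 900, by = 2)
    ta <- ts_series(t, cumsum(rnorm(length(t))))
    tday <- seq(0, 900, by = 2)
    tc <- ts_series(tday, cumsum(rnorm(length(tday))))
    est <- lag_cross_correlation(tc, ta, max_lag = 100)
    expect_equal(est$profile$score, naive_pearson_profile(tc, ta, 100),
                 tolerance = 1e-12)
  }
})

test_that("cross-correlation recovers exact delays and the zero-lag identity", {
  day <- generate_meteo_day(quiet_config(), seed = 51)
  tc0 <- exact_delay_tc(day, 0)
  e0 <- lag_cross_correlation(tc0, day$Ta, 120)
  expect_equal(e0$tau, 0)
  expect_equal(e0$score, 1, tolerance = 1e-12)

  tc <- exact_delay_tc(day, 44)
  e <- lag_cross_correlation(tc, day$Ta, 120)
  expect_equal(e$tau, 44)
  expect_equal(e$score, 1, tolerance = 1e-12)
})

test_that("cross-correlation tolerates moderate canopy noise", {
  errs <- sapply(1:5, function(s) {
    day <- generate_meteo_day(meteo_config(), seed = 60 + s)
    tc <- exact_delay_tc(day, 44, noise_sd = 0.3, seed = 160 + s)
    estimate_lag(tc, day$Ta, "cross_correlation")$tau - 44
  })
  expect_lte(median(abs(errs)), 6)
})

test_that("mutual information matches entropy for self-pairs and detects independence", {
  set.seed(7)
  x <- rnorm(2000)
  bins <- ceiling(log2(2000)) + 1
  expect_equal(mutual_information(x, x), binned_entropy(x, bins),
               tolerance = 1e-12)

  y <- runif(2000)
  x2 <- runif(2000)
  mi_obs <- mutual_information(x2, y)
  null <- replicate(200, mutual_information(x2, sample(y)))
  expect_lt(mi_obs, quantile(null, 0.95))

  # binning on each variable's own range: scale invariance
  expect_equal(mutual_information(x2, y), mutual_information(x2, 2 * y),
               tolerance = 1e-12)
})

test_that("mutual information input contracts hold", {
  expect_error(mutual_information(1:100, 1:99), "equal length")
  expect_error(mutual_information(1:30, 1:30), "at least 50")
  expect_error(mutual_information(1:100, 1:100, bins = 1), "bins")
})

test_that("MI bias on independent series shrinks with sample size", {
  set.seed(13)
  mi_at_n <- function(n) mean(replicate(8,
    mutual_information(rnorm(n), rnorm(n), bins = 8)))
  expect_lt(mi_at_n(2000), mi_at_n(200))
})

test_that("lagged MI finds exact delays, even under monotone distortion", {
  day <- generate_meteo_day(quiet_config(), seed = 52)
  tc <- exact_delay_tc(day, 44)
  expect_equal(lag_mutual_information(tc, day$Ta, 120)$tau, 44)
  expect_equal(lag_mutual_information(exact_delay_tc(day, 0), day$Ta, 120)$tau, 0)

  # monotone invariance holds up to binning: the cubed marginal is strongly
  # concentrated, so a finer grid than Sturges is needed to resolve it
  cubed <- ts_series(tc$t, (tc$v - mean(tc$v))^3, tc$unit)
  expect_equal(lag_mutual_information(cubed, day$Ta, 120, bins = 16)$tau, 44)
})

test_that("grey relational grade reproduces the hand-computed example", {
  g <- gray_relational_grade(c(0, 1, 2), c(0, 1, 3), rho = 0.5)
  expect_equal(g$grade, 7 / 9, tolerance = 1e-12)
  expect_equal(g$zeta, c(1, 1, 1 / 3), tolerance = 1e-12)
  expect_true(all(g$zeta > 0 & g$zeta <= 1))

  # zero-distance degenerate rule
  same <- gray_relational_grade(1:5, 1:5)
  expect_equal(same$grade, 1)
})

test_that("grey relational lag profiles peak at the true shift", {
  day <- generate_meteo_day(quiet_config(), seed = 53)
  tc <- exact_delay_tc(day, 60)
  e <- lag_gray_relational(tc, day$Ta, 150)
  expect_equal(e$tau, 60)
  expect_equal(e$score, 1, tolerance = 1e-12)
  expect_true(all(e$profile$score > 0 & e$profile$score <= 1))
  expect_equal(lag_gray_relational(exact_delay_tc(day, 0), day$Ta, 150)$tau, 0)
})

test_that("grey relational estimation tolerates moderate noise", {
  errs <- sapply(1:5, function(s) {
    day <- generate_meteo_day(meteo_config(), seed = 70 + s)
    tc <- exact_delay_tc(day, 60, noise_sd = 0.3, seed = 170 + s)
    estimate_lag(tc, day$Ta, "gray_relational")$tau - 60
  })
  expect_lte(median(abs(errs)), 10)
})

test_that("all profile methods report lags on the sampling grid", {
  day <- generate_meteo_day(meteo_config(), seed = 54)
  tc <- exact_delay_tc(day, 58, noise_sd = 0.2, seed = 55)
  for (m in c("cross_correlation", "mutual_information", "gray_relational")) {
    e <- estimate_lag(tc, day$Ta, m, max_lag = 150)
    expect_equal(e$tau %% 2, 0)
    expect_true(all(diff(e$profile$lag) > 0))
    expect_equal(e$score, max(e$profile$score))
    expect_true(e$tau %in% e$profile$lag)
  }
})

test_that("insufficient overlap and degenerate windows raise errors", {
  t <- seq(0, 200, by = 2)
  set.seed(5)
  a <- ts_series(t, rnorm(length(t)))
  b <- ts_series(t, rnorm(length(t)))
  expect_error(lag_cross_correlation(a, b, max_lag = 150), "insufficient overlap")
  expect_error(lag_cross_correlation(a, ts_series(t, rep(1, length(t))),
                                     max_lag = 20), "degenerate")
})
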