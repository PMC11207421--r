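test_that("simple-regression R2 behaves like R2", {
  x <- seq(1, 20)
  expect_equal(r_squared_linear(x, 3 - 2 * x)$r2, 1, tolerance = 1e-12)

  set.seed(6)
  x2 <- rnorm(200); y2 <- sample(x2)
  obs <- r_squared_linear(x2, y2)$r2
  null <- replicate(200, r_squared_linear(x2, sample(y2))$r2)
  expect_lt(obs, quantile(null, 0.95))

  expect_equal(r_squared_linear(10 * x2 + 3, -2 * y2)$r2, obs, tolerance = 1e-12)
  expect_error(r_squared_linear(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(r_squared_linear(1:2, 1:2), "at least 3")
})

test_that("zero true lag makes corrected and uncorrected cells identical", {
  camp <- simulate_campaign(n_days = 3,
                            true_lag = c(T1 = 0, T2 = 0, T3 = 0, T4 = 0),
                            tc_noise_sd = 0,
                            config = quiet_config(), seed = 19)
  lags <- estimate_campaign_lags(camp, "cross_correlation", days = 1)
  expect_true(all(vapply(lags, `[[`, 0, "cross_correlation") == 0))
  tab <- before_after_comparison(camp, lags, models = "empirical")
  for (p in c("Pn", "Tr", "gs")) {
    r_none <- tab$r2[tab$lag_method == "none" & tab$parameter == p]
    r_corr <- tab$r2[tab$lag_method == "cross_correlation" & tab$parameter == p]
    expect_equal(r_none, r_corr, tolerance = 1e-12)
  }
})

test_that("lag correction improves the empirical CWSI-gs relation", {
  camp <- simulate_campaign(n_days = 8,
                            true_lag = c(T1 = 60, T2 = 60, T3 = 60, T4 = 60),
                            seed = 23)
  lags <- estimate_campaign_lags(camp, "cross_correlation")
  tab <- before_after_comparison(camp, lags, models = "empirical")
  d <- attr(tab, "delta")
  expect_gt(d$delta_r2[d$parameter == "gs"], 0)
  # stressed canopies are warmer while gas exchange falls: negative slopes
  strong <- tab$r2 > 0.2
  expect_true(all(tab$slope_sign[strong] == -1))
  # sensitivity ordering built into the generator carries into the table
  corr <- tab[tab$lag_method == "cross_correlation", ]
  expect_gte(corr$r2[corr$parameter == "gs"], corr$r2[corr$parameter == "Pn"])
})

test_that("the uncorrected column ignores the lag estimates entirely", {
  camp <- simulate_campaign(n_days = 3,
                            true_lag = c(T1 = 40, T2 = 40, T3 = 40, T4 = 40),
                            seed = 29)
  mk <- function(tau) lapply(camp$scenarios, function(s) c(cross_correlation = tau))
  t1 <- before_after_comparison(camp, mk(40), models = "empirical")
  t2 <- before_after_comparison(camp, mk(100), models = "empirical")
  expect_equal(t1$r2[t1$lag_method == "none"], t2$r2[t2$lag_method == "none"],
               tolerance = 1e-12)
  # while the corrected column does react
  expect_false(isTRUE(all.equal(
    t1$r2[t1$lag_method == "cross_correlation"],
    t2$r2[t2$lag_method == "cross_correlation"])))
})

test_that("both CWSI models produce full correlation tables", {
  camp <- simulate_campaign(n_days = 4,
                            true_lag = c(T1 = 60, T2 = 60, T3 = 60, T4 = 60),
                            seed = 31)
  lags <- estimate_campaign_lags(camp, "cross_correlation", days = 1:2)
  tab <- before_after_comparison(camp, lags)
  expect_setequal(unique(tab$model), c("empirical", "theoretical"))
  expect_equal(nrow(tab), 2 * 2 * 3)  # 2 models x {none, cc} x 3 parameters
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_true(all(tab$n == nrow(camp$photos)))
})
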