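test_that("meteo generation is seed-deterministic and honors its contracts", {
  cfg <- meteo_config()
  d1 <- generate_meteo_day(cfg, seed = 7)
  d2 <- generate_meteo_day(cfg, seed = 7)
  expect_identical(d1$Ta$v, d2$Ta$v)
  expect_identical(d1$u$v, d2$u$v)

  # noise off: the Ta maximum sits exactly at the configured peak time
  quiet <- generate_meteo_day(quiet_config(peak_time = 852), seed = 1)
  expect_equal(quiet$Ta$t[which.max(quiet$Ta$v)], 852)

  for (s in 1:5) {
    d <- generate_meteo_day(cfg, seed = s)
    expect_gte(min(d$RH$v), 5)
    expect_lte(max(d$RH$v), 100)
    expect_true(all(d$u$v >= 0))
    expect_true(all(d$Rn$v >= 0))
  }
})

test_that("invalid meteorology configurations are rejected", {
  expect_error(meteo_config(t_min = 20, t_max = 15), "t_max")
  expect_error(meteo_config(peak_time = 1500), "peak_time")
  expect_error(meteo_config(noise_sd = list(Ta = -1, RH = 0, Rn = 0)), "noise")
  expect_error(meteo_config(ta_width = 0), "ta_width")
})

test_that("pure-delay canopy temperature reduces to Ta in the identity configuration", {
  day <- generate_meteo_day(quiet_config(), seed = 3)
  tc <- generate_canopy_temperature(day, 0, stress_scenario("T1", 0),
                                    baseline = nwsb_baseline(0, 0),
                                    noise_sd = 0, seed = 1)
  expect_equal(tc$v, day$Ta$v[day$t >= 0], tolerance = 1e-12)
})

test_that("brute-force Pearson recovers the imposed pure delay", {
  day <- generate_meteo_day(quiet_config(), seed = 5)
  tc <- exact_delay_tc(day, 44)
  prof <- naive_pearson_profile(tc, day$Ta, 120)
  lags <- seq(0, 120, by = 2)
  expect_equal(lags[which.max(prof)], 44)
})

test_that("stress raises the canopy-air difference monotonically", {
  day <- generate_meteo_day(quiet_config(), seed = 2)
  ctd_means <- sapply(c(0, 0.3, 0.6, 0.9), function(s) {
    tc <- generate_canopy_temperature(day, 60, stress_scenario("x", s),
                                      noise_sd = 0)
    mean(tc$v - day$Ta$v[day$t >= 0])
  })
  expect_true(all(diff(ctd_means) > 0))
})

test_that("canopy generation rejects impossible lags and modes", {
  day <- generate_meteo_day(meteo_config(padding = 60), seed = 1)
  sc <- stress_scenario("T1", 0)
  expect_error(generate_canopy_temperature(day, 120, sc), "padding")
  expect_error(generate_canopy_temperature(day, 3, sc), "multiple")
  expect_error(generate_canopy_temperature(day, 60, sc, mode = "magic"))
})

test_that("first-order response mode lags the target by roughly its time constant", {
  day <- generate_meteo_day(quiet_config(), seed = 4)
  tc <- generate_canopy_temperature(day, 40, stress_scenario("T1", 0),
                                    mode = "first_order",
                                    baseline = nwsb_baseline(0, 0),
                                    noise_sd = 0)
  est <- lag_cross_correlation(tc, day$Ta, 120)$tau
  expect_gt(est, 10)
  expect_lt(est, 80)
})

test_that("photosynthesis declines with stress and drops at the severe threshold", {
  cfg0 <- photo_config(cv = 0)
  base <- generate_photosynthesis(list(stress_scenario("T1", 0)), cfg0)
  expect_equal(unlist(base[, c("Pn", "Tr", "gs")]),
               c(Pn = 25, Tr = 6, gs = 0.5))

  stresses <- seq(0, 1, by = 0.1)
  scen <- lapply(stresses, function(s) stress_scenario(paste0("s", s), s))
  obs <- generate_photosynthesis(scen, cfg0)
  for (p in c("Pn", "Tr", "gs"))
    expect_true(all(diff(obs[[p]]) <= 1e-12))

  below <- generate_photosynthesis(list(stress_scenario("a", 0.749)), cfg0)
  above <- generate_photosynthesis(list(stress_scenario("b", 0.751)), cfg0)
  # the configured 30% drop, on top of the small linear decline
  expect_equal(above$Pn / below$Pn, 0.7, tolerance = 1e-2)

  expect_error(photo_config(Pn0 = -1), "baseline")
  expect_error(photo_config(k = c(Pn = -0.1, Tr = 0.1, gs = 0.1)), "rates")
})

test_that("campaigns regenerate identically from (config, seed)", {
  c1 <- simulate_campaign(n_days = 2, seed = 11)
  c2 <- simulate_campaign(n_days = 2, seed = 11)
  expect_identical(c1$photos, c2$photos)
  expect_identical(c1$tc[[2]]$T3$v, c2$tc[[2]]$T3$v)
  expect_identical(c1$days[[1]]$Ta$v, c2$days[[1]]$Ta$v)
  # canopy grid is a subset of the meteorology grid
  expect_true(all(c1$tc[[1]]$T1$t %in% c1$days[[1]]$t))
})

test_that("the embedded baseline is recoverable by regression (Idso linearity)", {
  day <- generate_meteo_day(quiet_config(), seed = 9)
  tc <- generate_canopy_temperature(day, 30, stress_scenario("T1", 0),
                                    baseline = nwsb_baseline(-2, 2.5),
                                    noise_sd = 0)
  pr <- apply_time_lag(tc, day, 30)
  fit <- stats::lm(I(Tc - Ta) ~ I(vpd(Ta, RH)), data = pr)
  expect_equal(unname(coef(fit)), c(2.5, -2), tolerance = 1e-9)
})
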