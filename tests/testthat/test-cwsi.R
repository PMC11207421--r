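test_that("psychrometric coefficient follows the barometric scaling", {
  expect_equal(psychrometric_gamma(0), 0.665 * 101.3, tolerance = 1e-12)
  expect_equal(psychrometric_gamma(1000), 59.9, tolerance = 1e-2)
  z <- seq(0, 4000, by = 500)
  expect_true(all(diff(psychrometric_gamma(z)) < 0))
  expect_error(psychrometric_gamma(-5), "non-negative")
})

test_that("saturation-curve slope matches its cubic and the Tetens derivative", {
  expect_equal(delta_slope(20, 20),
               45.03 + 3.014 * 20 + 0.05345 * 400 + 0.00224 * 8000,
               tolerance = 1e-12)
  # depends only on the canopy-air mean
  expect_equal(delta_slope(22, 18), delta_slope(20, 20))
  T <- seq(0, 40, by = 1)
  expect_true(all(diff(delta_slope(T, T)) > 0))
  # independent oracle: centred finite difference of the Tetens curve (Pa/degC)
  Tm <- seq(5, 35, by = 0.5)
  dnum <- (saturation_vapor_pressure(Tm + 0.005) -
           saturation_vapor_pressure(Tm - 0.005)) / 0.01 * 1000
  expect_lt(max(abs(delta_slope(Tm, Tm) - dnum) / dnum), 0.02)
  expect_warning(delta_slope(60, 60), "extrapolated")
})

test_that("aerodynamic resistance matches hand evaluation and decreases with wind", {
  hand <- function(u, h, z) 4.72 * log((z - 0.63 * h) / (0.13 * h))^2 / (1 + 0.54 * u)
  expect_equal(aerodynamic_resistance(2, 1, 2), hand(2, 1, 2), tolerance = 1e-12)
  expect_equal(aerodynamic_resistance(0, 1, 2), hand(0, 1, 2), tolerance = 1e-12)
  u <- seq(0, 10, by = 1)
  expect_true(all(diff(aerodynamic_resistance(u, 1, 2)) < 0))
  expect_error(aerodynamic_resistance(2, 4, 2), "z > d")
})

test_that("vapor pressure terms honor their limits", {
  expect_equal(vpd(25, 50), 3.160 / 2, tolerance = 1e-3)
  expect_equal(vpd(25, 100), 0)
  expect_equal(vpd(25, 0), saturation_vapor_pressure(25))
  expect_error(vpd(25, 150), "humidity")

  expect_equal(vpg(25, 0), 0)
  expect_equal(vpg(25, 2.5), -0.5015, tolerance = 1e-3)
  expect_lt(vpg(20, 3), 0)
  expect_gt(vpg(20, -3), 0)
})

test_that("the non-water-stressed baseline is recovered by OLS", {
  v <- seq(0.5, 3, length.out = 61)
  ctd <- -2 * v + 2.5
  b <- fit_nwsb(ctd, v, time = seq(780, 900, by = 2))
  expect_equal(unname(coef(b)), c(-2, 2.5), tolerance = 1e-12)
  expect_equal(b$r2, 1, tolerance = 1e-12)

  # noisy recovery: the true slope lies inside the OLS 95% CI
  set.seed(3)
  noisy <- ctd + rnorm(61, 0, 0.3)
  fit <- stats::lm(noisy ~ v)
  ci <- stats::confint(fit)[2, ]
  expect_gte(-2, ci[1])
  expect_lte(-2, ci[2])

  expect_error(fit_nwsb(ctd, rep(1, 61), time = seq(780, 900, by = 2)),
               "degenerate")
  expect_error(fit_nwsb(ctd, v, time = seq(0, 120, by = 2)), "window")
})

test_that("empirical CWSI hits its endpoints exactly", {
  b <- nwsb_baseline(-2, 2.5)
  ta <- 25; rh <- 40
  nwsb <- -2 * vpd(ta, rh) + 2.5
  ntb <- -2 * vpg(ta, 2.5) + 2.5
  at <- function(ctd) cwsi_empirical(ta + ctd, ta, rh, b)$cwsi_raw
  expect_equal(at(nwsb), 0, tolerance = 1e-12)
  expect_equal(at(ntb), 1, tolerance = 1e-12)
  expect_equal(at((nwsb + ntb) / 2), 0.5, tolerance = 1e-12)

  degenerate <- nwsb_baseline(0, 0)
  expect_error(cwsi_empirical(26, 25, 40, degenerate), "degenerate bounds")
})

test_that("energy-balance inversion round-trips the canopy resistance", {
  gamma <- psychrometric_gamma(0)
  ra <- aerodynamic_resistance(2, 1, 2)
  delta <- delta_slope(20, 20)
  for (rc in c(13.01, 26.02, 130.1)) {
    ctd <- energy_balance_ctd(rc, 600, 60, ra, 1500, delta, gamma)
    inv <- canopy_resistance_inversion(ctd, 600, 60, ra, 1500, delta, gamma)
    expect_equal(inv$rc, rc, tolerance = 1e-9)
    expect_equal(inv$flag, "ok")
  }
  # algebraic limit: VPD = 0 and ctd = 0 implies rc = -ra, floored
  inv0 <- canopy_resistance_inversion(0, 600, 60, ra, 0, delta, gamma)
  expect_equal(inv0$rc, 0)
  expect_equal(inv0$flag, "floored")
  # monotone in ctd below the limit
  R <- ra * (600 - 60) / (1.20 * 1013)
  ctds <- seq(-3, R - 0.5, length.out = 10)
  rcs <- canopy_resistance_inversion(ctds, 600, 60, ra, 1500, delta, gamma)$rc
  expect_true(all(diff(rcs) > 0))
  expect_error(canopy_resistance_inversion(R + 1, 600, 60, ra, 1500, delta,
                                           gamma), "upper limit")
})

test_that("theoretical CWSI spans 0 at potential transpiration to 1 without it", {
  p <- theoretical_params(Z = 0, h = 1, z = 2)
  ra <- aerodynamic_resistance(2, p$h, p$z)
  gamma <- psychrometric_gamma(p$Z)
  ta <- 20; rh <- 50; rn <- 600; g <- 60
  vp <- vpd(ta, rh) * 1000
  tc_for <- function(rc) {
    ctd <- 0
    for (i in 1:60)
      ctd <- energy_balance_ctd(rc, rn, g, ra, vp, delta_slope(ta + ctd, ta), gamma)
    ta + ctd
  }
  rcp <- p$rcp_table[["regreening-jointing"]]
  r0 <- cwsi_theoretical(tc_for(rcp), ta, rh, rn, g, 2, p)
  expect_equal(r0$cwsi_raw, 0, tolerance = 1e-6)
  r1 <- cwsi_theoretical(tc_for(1e6), ta, rh, rn, g, 2, p)
  expect_gt(r1$cwsi_raw, 0.999)

  # closed-form spot check at rc = 2 * rcp with fixed components
  q <- gamma * (1 + 2 * rcp / ra)
  gs <- gamma * (1 + rcp / ra)
  delta <- delta_slope(tc_for(2 * rcp), ta)
  r2 <- cwsi_theoretical(tc_for(2 * rcp), ta, rh, rn, g, 2, p)
  expect_equal(r2$cwsi_raw, (q - gs) / (delta + q), tolerance = 1e-6)

  # non-decreasing in canopy temperature
  tcs <- seq(ta - 2, ta + 2.2, by = 0.2)
  vals <- cwsi_theoretical(tcs, ta, rh, rn, g, 2, p)$cwsi_raw
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("CWSI records are internally consistent", {
  day <- generate_meteo_day(meteo_config(), seed = 77)
  tc <- generate_canopy_temperature(day, 60, stress_scenario("T3", 0.6),
                                    seed = 78)
  pr <- apply_time_lag(tc, day, 60)
  emp <- cwsi_empirical(pr$Tc, pr$Ta, pr$RH, nwsb_baseline(-2, 2.5),
                        time = pr$time, lag_applied = 60)
  expect_equal(emp$cwsi_raw, (emp$ctd - emp$nwsb) / (emp$ntb - emp$nwsb),
               tolerance = 1e-12)
  th <- cwsi_theoretical(pr$Tc, pr$Ta, pr$RH, pr$Rn, pr$G, pr$u,
                         time = pr$time, lag_applied = 60)
  ok <- th$flag == "ok"
  q <- th$gamma * (1 + th$rc / th$ra)
  expect_equal(th$cwsi_raw[ok], ((q - th$gamma_star) / (th$delta + q))[ok],
               tolerance = 1e-12)
})

test_that("lag re-pairing is exact, invertible bookkeeping", {
  day <- generate_meteo_day(meteo_config(), seed = 91)
  tc <- generate_canopy_temperature(day, 44, stress_scenario("T1", 0), seed = 92)
  p0 <- apply_time_lag(tc, day, 0)
  expect_equal(p0$Ta, day$Ta$v[day$t >= 0])

  p44 <- apply_time_lag(tc, day, 44)
  i <- match(p44$time - 44, day$t)
  expect_equal(p44$Ta, day$Ta$v[i])
  expect_equal(p44$RH, day$RH$v[i])
  # contemporaneous channels unshifted
  expect_equal(p44$Rn, day$Rn$v[match(p44$time, day$t)])
  # shifting back restores the original alignment on the common support
  keep <- p0$time %in% p44$time
  expect_equal(p44$Ta, day$Ta$v[match(p44$time, day$t) - 22])
  expect_equal(p0$Tc[keep], p44$Tc)

  expect_error(apply_time_lag(tc, day, 43), "multiple")
})
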