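# Crop Water Stress Index models.
#
# Empirical (Idso): CWSI = (CTD - NWSB) / (NTB - NWSB) with the
# non-water-stressed baseline NWSB = a*VPD + b and the non-transpiring bound
# NTB = a*VPG + b, VPG = es(Ta) - es(Ta + b).
#
# Theoretical (Jackson, canopy energy balance):
# CWSI = (gamma*(1 + rc/ra) - gamma_star) / (Delta + gamma*(1 + rc/ra)),
# with gamma_star = gamma*(1 + rcp/ra) built from the minimum (potential)
# canopy resistance rcp, and the actual canopy resistance rc inverted from
# the observed canopy-air temperature difference through the energy balance.
# Internal unit canon: temperatures degC, resistances s/m, pressures Pa
# (kPa only at the empirical-model boundary).

#' Psychrometric coefficient from altitude
#'
#' `gamma = 0.665 * 101.3 * ((293 - 0.0065 Z) / 293)^5.26` in Pa per degC,
#' i.e. the sea-level value 67.36 scaled by the barometric pressure ratio.
#'
#' @param Z altitude above sea level (m), non-negative.
#' @return Psychrometric coefficient (Pa/degC); vectorized.
#' @export
psychrometric_gamma <- function(Z) {
  if (any(Z < 0)) stop("altitude must be non-negative", call. = FALSE)
  if (any(Z >= 293 / 0.0065))
    stop("altitude outside the validity of the barometric formula", call. = FALSE)
  0.665 * 101.3 * ((293 - 0.0065 * Z) / 293)^5.26
}

#' Slope of the saturation vapor pressure curve
#'
#' Cubic approximation `Delta = 45.03 + 3.014 T + 0.05345 T^2 + 0.00224 T^3`
#' (Pa/degC) evaluated at the canopy-air mean temperature `T = (Tc + Ta)/2`.
#'
#' @param tc,ta canopy and air temperature (degC); vectorized.
#' @return Slope Delta (Pa/degC). Means outside -10..50 degC trigger a
#'   warning but still return the polynomial value.
#' @export
delta_slope <- function(tc, ta) {
  T <- (tc + ta) / 2
  if (any(T < -10 | T > 50))
    warning("mean temperature outside -10..50 degC; slope extrapolated")
  45.03 + 3.014 * T + 0.05345 * T^2 + 0.00224 * T^3
}

#' Aerodynamic resistance over a crop canopy
#'
#' `ra = 4.72 [ln((z - d)/z0)]^2 / (1 + 0.54 u)` with zero-plane displacement
#' `d = 0.63 h` and roughness length `z0 = 0.13 h`.
#'
#' @param u wind speed at reference height (m/s), non-negative; vectorized.
#' @param h crop height (m), positive.
#' @param z reference height (m), default 2.
#' @return Aerodynamic resistance (s/m).
#' @export
aerodynamic_resistance <- function(u, h, z = 2) {
  if (h <= 0) stop("crop height h must be positive", call. = FALSE)
  d <- 0.63 * h; z0 <- 0.13 * h
  if (z <= d) stop("geometry violated: need z > d = 0.63*h", call. = FALSE)
  if ((z - d) / z0 <= 1)
    stop("geometry violated: need (z - d)/z0 > 1", call. = FALSE)
  if (any(u < 0)) stop("wind speed must be non-negative", call. = FALSE)
  4.72 * log((z - d) / z0)^2 / (1 + 0.54 * u)
}

#' Saturation vapor pressure (Tetens form)
#'
#' `es(T) = 0.6108 exp(17.27 T / (T + 237.7))` in kPa.
#' @param ta temperature (degC); vectorized.
#' @return Saturation vapor pressure (kPa).
#' @export
saturation_vapor_pressure <- function(ta) {
  0.6108 * exp(17.27 * ta / (ta + 237.7))
}

#' Vapor pressure deficit
#'
#' `VPD = es(Ta) * (100 - RH)/100` in kPa.
#' @param ta air temperature (degC).
#' @param rh relative humidity (%), in `[0, 100]`.
#' @return VPD (kPa); vectorized.
#' @export
vpd <- function(ta, rh) {
  if (any(rh < 0 | rh > 100))
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  saturation_vapor_pressure(ta) * (100 - rh) / 100
}

#' Vapor pressure gradient for the non-transpiring baseline
#'
#' `VPG = es(Ta) - es(Ta + b)`, the saturation-pressure change across the
#' baseline intercept `b`; negative for `b > 0`.
#' @param ta air temperature (degC).
#' @param b baseline intercept (degC).
#' @return VPG (kPa); vectorized.
#' @export
vpg <- function(ta, b) {
  saturation_vapor_pressure(ta) - saturation_vapor_pressure(ta + b)
}

#' Non-water-stressed baseline object
#'
#' Holds the Idso baseline slope/intercept `CTD = a * VPD + b` for a
#' well-watered canopy; constructed directly or fitted with [fit_nwsb()].
#'
#' @param a slope (degC/kPa).
#' @param b intercept (degC).
#' @param r2,n,fit_window fit metadata (filled by [fit_nwsb()]).
#' @return An object of class `nwsb_baseline`.
#' @export
nwsb_baseline <- function(a, b, r2 = NA_real_, n = 0L,
                          fit_window = c(NA_real_, NA_real_)) {
  structure(list(a = a, b = b, r2 = r2, n = n, fit_window = fit_window),
            class = "nwsb_baseline")
}

#' @export
print.nwsb_baseline <- function(x, ...) {
  cat(sprintf("<nwsb_baseline> CTD = %.4f * VPD + %.4f", x$a, x$b))
  if (!is.na(x$r2)) cat(sprintf("  (R2 = %.4f, n = %d)", x$r2, x$n))
  cat("\n")
  invisible(x)
}

#' @export
coef.nwsb_baseline <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.nwsb_baseline <- function(object, newdata, ...) {
  object$a * newdata + object$b
}

#' Fit the non-water-stressed baseline by OLS
#'
#' Ordinary least squares of the canopy-air temperature difference on the
#' vapor pressure deficit over an early-afternoon window (default
#' 13:00-15:00, when the CTD-VPD relation is most distinct), on well-watered
#' data.
#'
#' @param ctd canopy-air temperature difference (degC).
#' @param vpd_kpa vapor pressure deficit (kPa).
#' @param time optional timestamps (min); needed if `window` is used.
#' @param window two-vector window (min), default `c(780, 900)`; `NULL` uses
#'   all points.
#' @return An `nwsb_baseline` with slope, intercept, `r2` and `n`.
#' @export
fit_nwsb <- function(ctd, vpd_kpa, time = NULL, window = c(780, 900)) {
  if (length(ctd) != length(vpd_kpa))
    stop("ctd and vpd must have equal length", call. = FALSE)
  keep <- rep(TRUE, length(ctd))
  if (!is.null(window)) {
    if (is.null(time))
      stop("a fit window needs timestamps", call. = FALSE)
    keep <- time >= window[1] & time <= window[2]
  }
  x <- vpd_kpa[keep]; y <- ctd[keep]
  if (length(x) < 2) stop("empty window: fewer than 2 points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate VPD: zero variance in the fit window", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  nwsb_baseline(a = unname(stats::coef(fit)[2]),
                b = unname(stats::coef(fit)[1]),
                r2 = r2, n = length(x),
                fit_window = if (is.null(window)) c(NA_real_, NA_real_) else window)
}

#' Empirical (baseline) Crop Water Stress Index
#'
#' `CWSI = (CTD - NWSB) / (NTB - NWSB)` with the lower bound evaluated at
#' the current VPD and the upper bound at the current VPG. The raw value is
#' kept alongside a `[0, 1]`-clamped companion; the raw value may
#' legitimately leave that range under measurement noise.
#'
#' @param tc,ta,rh canopy temperature, air temperature (degC) and relative
#'   humidity (%); vectorized.
#' @param baseline an [nwsb_baseline()].
#' @param time optional timestamps (min) carried into the record.
#' @param lag_applied lag (min) already applied to the (ta, rh) inputs; 0 =
#'   uncorrected. Bookkeeping only.
#' @return A data frame of class `cwsi_record`: `time`, `model`,
#'   `lag_applied`, `cwsi_raw`, `cwsi`, `ctd`, `vpd`, `nwsb`, `ntb`.
#' @export
cwsi_empirical <- function(tc, ta, rh, baseline, time = NULL, lag_applied = 0) {
  stopifnot(inherits(baseline, "nwsb_baseline"))
  ctd <- tc - ta
  v <- vpd(ta, rh)
  g <- vpg(ta, baseline$b)
  nwsb <- baseline$a * v + baseline$b
  ntb <- baseline$a * g + baseline$b
  denom <- ntb - nwsb
  if (any(abs(denom) < 1e-9))
    stop("degenerate bounds: |NTB - NWSB| < 1e-9", call. = FALSE)
  raw <- (ctd - nwsb) / denom
  out <- data.frame(time = if (is.null(time)) NA_real_ else time,
                    model = "empirical", lag_applied = lag_applied,
                    cwsi_raw = raw, cwsi = pmin(1, pmax(0, raw)),
                    ctd = ctd, vpd = v, nwsb = nwsb, ntb = ntb)
  class(out) <- c("cwsi_record", "data.frame")
  out
}

#' Parameters of the theoretical CWSI model
#'
#' @param Z altitude (m).
#' @param h crop height (m).
#' @param z reference height (m), default 2; must exceed `0.63 h`.
#' @param rcp_table named vector of minimum (potential) canopy resistance
#'   (s/m) by growth stage.
#' @param rho_air air density (kg/m3).
#' @param cp_air specific heat of air (J/kg/K).
#' @return A list of class `theoretical_params`.
#' @export
theoretical_params <- function(Z = 526, h = 0.6, z = 2,
                               rcp_table = c("regreening-jointing" = 13.01,
                                             "jointing-tasseling" = 18.03,
                                             "tasseling-filling" = 26.85),
                               rho_air = 1.20, cp_air = 1013) {
  if (h <= 0) stop("crop height must be positive", call. = FALSE)
  if (z <= 0.63 * h)
    stop("reference height must exceed the zero-plane displacement 0.63*h",
         call. = FALSE)
  if (any(rcp_table <= 0))
    stop("minimum canopy resistances must be positive", call. = FALSE)
  structure(list(Z = Z, h = h, z = z, rcp_table = rcp_table,
                 rho_air = rho_air, cp_air = cp_air),
            class = "theoretical_params")
}

#' Invert the canopy energy balance for actual canopy resistance
#'
#' Given the observed canopy-air temperature difference and the available
#' energy, solves the Jackson energy balance for the bulk canopy resistance:
#' with `R = ra (Rn - G) / (rho cp)` (degC), `Y = (ctd * Delta + VPD_Pa) /
#' (R - ctd)` and `rc = ra (Y / gamma - 1)`. Negative solutions are floored
#' at 0 (flag `"floored"`); observations warmer than the no-transpiration
#' limit (`R <= ctd`) either error (`strict = TRUE`) or return `rc = Inf`
#' with flag `"above_upper_limit"`.
#'
#' @param ctd canopy-air temperature difference (degC).
#' @param rn,g net radiation and soil heat flux (W/m2).
#' @param ra aerodynamic resistance (s/m).
#' @param vpd_pa vapor pressure deficit (Pa).
#' @param delta slope of the saturation curve (Pa/degC).
#' @param gamma psychrometric coefficient (Pa/degC).
#' @param rho_air,cp_air air density (kg/m3) and specific heat (J/kg/K).
#' @param strict error on `R <= ctd` instead of flagging.
#' @return A data frame with `rc` (s/m) and `flag`; vectorized.
#' @export
canopy_resistance_inversion <- function(ctd, rn, g, ra, vpd_pa, delta, gamma,
                                        rho_air = 1.20, cp_air = 1013,
                                        strict = TRUE) {
  R <- ra * (rn - g) / (rho_air * cp_air)
  over <- R <= ctd
  if (strict && any(over))
    stop("above upper limit: available-energy warming R <= observed CTD; ",
         "no finite canopy resistance exists", call. = FALSE)
  Y <- (ctd * delta + vpd_pa) / (R - ctd)
  rc <- ra * (Y / gamma - 1)
  flag <- rep("ok", length(rc))
  floor_it <- !over & rc < 0
  rc[floor_it] <- 0
  flag[floor_it] <- "floored"
  rc[over] <- Inf
  flag[over] <- "above_upper_limit"
  data.frame(rc = rc, flag = flag)
}

#' Theoretical (energy-balance) Crop Water Stress Index
#'
#' Builds every component from the meteorology at each timestamp — the
#' psychrometric coefficient from altitude, the saturation-curve slope at the
#' canopy-air mean temperature, the aerodynamic resistance from wind speed
#' and canopy geometry, the actual canopy resistance by energy-balance
#' inversion — and evaluates
#' `CWSI = (gamma (1 + rc/ra) - gamma_star) / (Delta + gamma (1 + rc/ra))`
#' with `gamma_star = gamma (1 + rcp/ra)` from the growth stage's minimum
#' canopy resistance. The index is 0 at potential transpiration (`rc = rcp`)
#' and tends to 1 as the canopy stops transpiring (`rc -> Inf`).
#'
#' @param tc,ta,rh,rn,g,u meteorology at each timestamp (degC, degC, %,
#'   W/m2, W/m2, m/s); vectorized.
#' @param params a [theoretical_params()].
#' @param stage growth stage selecting the minimum canopy resistance.
#' @param time optional timestamps (min).
#' @param lag_applied bookkeeping: lag (min) already applied to (ta, rh).
#' @return A data frame of class `cwsi_record` with components `gamma`,
#'   `gamma_star`, `delta`, `ra`, `rc`, `flag` alongside `cwsi_raw`, `cwsi`,
#'   `ctd`, `vpd`.
#' @export
cwsi_theoretical <- function(tc, ta, rh, rn, g, u,
                             params = theoretical_params(),
                             stage = "regreening-jointing",
                             time = NULL, lag_applied = 0) {
  stopifnot(inherits(params, "theoretical_params"))
  if (!stage %in% names(params$rcp_table))
    stop("unknown growth stage: ", stage, call. = FALSE)
  rcp <- params$rcp_table[[stage]]
  gamma <- psychrometric_gamma(params$Z)
  delta <- delta_slope(tc, ta)
  ra <- aerodynamic_resistance(u, params$h, params$z)
  vpd_pa <- vpd(ta, rh) * 1000
  ctd <- tc - ta
  inv <- canopy_resistance_inversion(ctd, rn, g, ra, vpd_pa, delta, gamma,
                                     rho_air = params$rho_air,
                                     cp_air = params$cp_air, strict = FALSE)
  gamma_star <- gamma * (1 + rcp / ra)
  q <- gamma * (1 + inv$rc / ra)
  raw <- (q - gamma_star) / (delta + q)
  raw[inv$flag == "above_upper_limit"] <- 1
  out <- data.frame(time = if (is.null(time)) NA_real_ else time,
                    model = "theoretical", lag_applied = lag_applied,
                    cwsi_raw = raw, cwsi = pmin(1, pmax(0, raw)),
                    ctd = ctd, vpd = vpd_pa / 1000,
                    gamma = gamma, gamma_star = gamma_star, delta = delta,
                    ra = ra, rc = inv$rc, flag = inv$flag)
  class(out) <- c("cwsi_record", "data.frame")
  out
}

#' Forward energy-balance canopy-air temperature difference
#'
#' The inverse of [canopy_resistance_inversion()]: the CTD a canopy with
#' resistance `rc` would show. Used to build ground-truth inputs for the
#' theoretical model.
#'
#' @inheritParams canopy_resistance_inversion
#' @param rc canopy resistance (s/m).
#' @return CTD (degC); vectorized.
#' @export
energy_balance_ctd <- function(rc, rn, g, ra, vpd_pa, delta, gamma,
                               rho_air = 1.20, cp_air = 1013) {
  R <- ra * (rn - g) / (rho_air * cp_air)
  q <- gamma * (1 + rc / ra)
  (R * q - vpd_pa) / (delta + q)
}

#' Re-pair canopy temperature with lag-shifted meteorology
#'
#' Pairs `Tc(t)` with `Ta(t - tau)` and `RH(t - tau)` (shifted jointly so
#' VPD stays thermodynamically consistent) while keeping radiation, soil
#' heat flux and wind contemporaneous. The result feeds either CWSI model
#' unchanged; `tau = 0` reproduces the uncorrected pairing.
#'
#' @param tc canopy-temperature [ts_series()].
#' @param meteo a [generate_meteo_day()]-shaped `meteo_day` (or any list
#'   with `Ta`, `RH`, `Rn`, `G`, `u` [ts_series()] on one grid).
#' @param tau lag (min): non-negative multiple of the grid step.
#' @return A data frame with columns `time`, `Tc`, `Ta`, `RH`, `Rn`, `G`,
#'   `u` and attribute `lag_applied`; rows without full history are dropped
#'   with a message.
#' @export
apply_time_lag <- function(tc, meteo, tau) {
  stopifnot(inherits(tc, "ts_series"))
  step <- ts_step(tc)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (abs(tau / step - round(tau / step)) > 1e-8)
    stop("tau must be a multiple of the grid step", call. = FALSE)
  pa <- pair_at_lag(tc, meteo$Ta, tau)
  ph <- pair_at_lag(tc, meteo$RH, tau)
  dropped <- length(tc$t) - pa$n
  if (dropped > 0)
    message(sprintf("apply_time_lag: %d sample(s) dropped for lack of history",
                    dropped))
  keep <- tc$t %in% pa$t
  contemp <- function(s) {
    j <- round((pa$t - s$t[1L]) / step) + 1L
    s$v[j]
  }
  out <- data.frame(time = pa$t, Tc = tc$v[keep], Ta = pa$y, RH = ph$y,
                    Rn = contemp(meteo$Rn), G = contemp(meteo$G),
                    u = contemp(meteo$u))
  attr(out, "lag_applied") <- tau
  out
}
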