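#' Configuration for one synthetic diurnal meteorology day
#'
#' Defaults emulate a clear early-spring day over a winter-wheat canopy in a
#' semi-humid temperate climate: a skewed single-peak air temperature curve
#' (slow pre-noon rise, slower evening decay), relative humidity moving
#' opposite to temperature, a half-sine shortwave/net-radiation course over
#' daylight, soil heat flux as a fixed fraction of net radiation, and gently
#' autocorrelated wind.
#'
#' @param step sampling step (min).
#' @param padding pre-midnight margin (min); must cover the largest lag ever
#'   applied so shifted lookups `Ta(t - tau)` never wrap.
#' @param t_min,t_max daily minimum / maximum air temperature (degC).
#' @param peak_time time of the Ta maximum (min from midnight); the skewed
#'   bump is positioned so its argmax lands exactly here.
#' @param ta_width width (min) of the Ta bump.
#' @param ta_skew skewness of the Ta bump (Gram-Charlier third-order
#'   coefficient; positive = earlier crest, longer evening tail).
#' @param rh_min,rh_max relative-humidity range (%); RH is affine-decreasing
#'   in Ta between these, then clipped to `[5, 100]`.
#' @param rn_peak peak net radiation (W m-2).
#' @param daylight two-vector, start/end of the daylight half-sine (min).
#' @param rn_night night-time radiation baseline (W m-2).
#' @param g_frac soil heat flux as a fraction of net radiation.
#' @param u_mean mean wind speed (m s-1).
#' @param u_ar1,u_sd AR(1) coefficient and innovation SD of the wind
#'   perturbation.
#' @param noise_sd named list of additive Gaussian noise SDs for `Ta` (degC),
#'   `RH` (%) and `Rn` (W m-2).
#' @return A list of class `meteo_config`.
#' @export
meteo_config <- function(step = 2, padding = 240,
                         t_min = 8, t_max = 24, peak_time = 840,
                         ta_width = 220, ta_skew = 0.3,
                         rh_min = 40, rh_max = 90,
                         rn_peak = 650, daylight = c(360, 1140), rn_night = 0,
                         g_frac = 0.1,
                         u_mean = 1.5, u_ar1 = 0.8, u_sd = 0.3,
                         noise_sd = list(Ta = 0.2, RH = 1.5, Rn = 10)) {
  if (t_max <= t_min)
    stop("invalid config: t_max must exceed t_min", call. = FALSE)
  if (peak_time < 0 || peak_time > 1440)
    stop("invalid config: peak_time must lie within the day (0-1440 min)",
         call. = FALSE)
  ns <- lapply(noise_sd, as.numeric)
  if (any(unlist(ns) < 0))
    stop("invalid config: noise SDs must be non-negative", call. = FALSE)
  if (ta_width <= 0)
    stop("invalid config: ta_width must be positive", call. = FALSE)
  if (step <= 0 || padding < 0)
    stop("invalid config: step must be positive and padding non-negative",
         call. = FALSE)
  structure(list(step = step, padding = padding, t_min = t_min, t_max = t_max,
                 peak_time = peak_time, ta_width = ta_width,
                 ta_skew = ta_skew, rh_min = rh_min, rh_max = rh_max,
                 rn_peak = rn_peak, daylight = daylight, rn_night = rn_night,
                 g_frac = g_frac, u_mean = u_mean, u_ar1 = u_ar1, u_sd = u_sd,
                 noise_sd = ns),
            class = "meteo_config")
}

# Skewed single-peak bump: Gaussian core with a Gram-Charlier third-order
# (skewness) correction, shifted so its argmax sits exactly at `peak` and
# scaled to max 1.
gc_bump <- function(t, peak, w, a3) {
  shape <- function(z)
    (1 + (a3 / 6) * z * (z^2 - 3) +
       (10 * a3^2 / 720) * (z^6 - 15 * z^4 + 45 * z^2 - 15)) * exp(-0.5 * z^2)
  z_star <- if (a3 == 0) 0 else
    stats::optimize(shape, c(-2, 2), maximum = TRUE)$maximum
  f <- shape((t - peak) / w + z_star)
  f / shape(z_star)
}

#' Generate one synthetic meteorology day
#'
#' Produces air temperature, relative humidity, net radiation, soil heat flux
#' and wind speed on one uniform minute grid that starts `padding` minutes
#' before midnight, so that lagged lookups up to `padding` minutes have real
#' history.
#'
#' @param config a [meteo_config()].
#' @param seed integer seed for the noise draws, or `NULL` to consume the
#'   current RNG stream.
#' @return A list of class `meteo_day` with fields `t` (grid) and
#'   [ts_series()] members `Ta`, `RH`, `Rn`, `G`, `u`.
#' @examples
#' day <- generate_meteo_day(meteo_config(), seed = 1)
#' range(day$RH$v)
#' @export
generate_meteo_day <- function(config = meteo_config(), seed = NULL) {
  stopifnot(inherits(config, "meteo_config"))
  with_seed(seed, {
    t <- seq(-config$padding, 1440 - config$step, by = config$step)
    n <- length(t)
    bump <- gc_bump(t, config$peak_time, config$ta_width, config$ta_skew)
    ta_clean <- config$t_min + (config$t_max - config$t_min) * bump
    ta <- ta_clean + stats::rnorm(n, 0, config$noise_sd$Ta)

    rh_clean <- config$rh_max - (config$rh_max - config$rh_min) *
      (ta - config$t_min) / (config$t_max - config$t_min)
    rh <- pmin(100, pmax(5, rh_clean + stats::rnorm(n, 0, config$noise_sd$RH)))

    day <- t >= config$daylight[1L] & t <= config$daylight[2L]
    rn <- rep(config$rn_night, n)
    rn[day] <- config$rn_night + config$rn_peak *
      sin(pi * (t[day] - config$daylight[1L]) / diff(config$daylight))
    rn[day] <- pmax(0, rn[day] + stats::rnorm(sum(day), 0, config$noise_sd$Rn))

    g <- config$g_frac * rn

    e <- numeric(n)
    innov <- stats::rnorm(n, 0, config$u_sd)
    for (i in 2:n) e[i] <- config$u_ar1 * e[i - 1L] + innov[i]
    u <- pmax(0, config$u_mean + e)

    structure(list(t = t,
                   Ta = ts_series(t, ta, "degC"),
                   RH = ts_series(t, rh, "%"),
                   Rn = ts_series(t, rn, "W/m2"),
                   G  = ts_series(t, g, "W/m2"),
                   u  = ts_series(t, u, "m/s"),
                   config = config),
              class = "meteo_day")
  })
}

#' @export
print.meteo_day <- function(x, ...) {
  cat(sprintf("<meteo_day> %d samples, step %g min, t in [%g, %g]\n",
              length(x$t), x$t[2] - x$t[1], x$t[1], x$t[length(x$t)]))
  cat(sprintf("  Ta [%.1f, %.1f] degC; RH [%.0f, %.0f] %%; Rn max %.0f W/m2; u mean %.2f m/s\n",
              min(x$Ta$v), max(x$Ta$v), min(x$RH$v), max(x$RH$v),
              max(x$Rn$v), mean(x$u$v)))
  invisible(x)
}

#' Water-stress scenario (irrigation treatment)
#'
#' @param label treatment id, e.g. `"T1"`.
#' @param stress dimensionless severity in `[0, 1]`; 0 = fully irrigated.
#' @param fc_fraction percent of field water-holding capacity, label only.
#' @return A list of class `stress_scenario`.
#' @export
stress_scenario <- function(label, stress, fc_fraction = NA_real_) {
  if (stress < 0 || stress > 1)
    stop("stress severity must lie in [0, 1]", call. = FALSE)
  structure(list(label = label, stress = stress, fc_fraction = fc_fraction),
            class = "stress_scenario")
}

#' Default four-treatment stress ladder
#'
#' Four irrigation treatments from fully irrigated to severe stress,
#' labelled T1-T4 and keyed to upper irrigation limits of 95/80/65/50 % of
#' field water-holding capacity; the dimensionless severity maps that range
#' linearly onto 0-0.9.
#' @return A named list of [stress_scenario()] objects.
#' @export
default_scenarios <- function() {
  fc <- c(T1 = 95, T2 = 80, T3 = 65, T4 = 50)
  out <- lapply(names(fc), function(nm)
    stress_scenario(nm, stress = (95 - fc[[nm]]) / 50, fc_fraction = fc[[nm]]))
  names(out) <- names(fc)
  out
}

#' Generate canopy temperature responding to air temperature with a lag
#'
#' In `pure_delay` mode the canopy tracks a delayed copy of the air
#' temperature plus the non-water-stressed canopy-air difference evaluated at
#' the delayed meteorology, a stress offset and white noise:
#' `Tc(t) = Ta(t - tau) + a * VPD(t - tau) + b + stress * dt_stress + eps(t)`.
#' VPD is computed from the jointly shifted Ta and RH so the embedded Idso
#' baseline is exact. In `first_order` mode the canopy obeys a discrete
#' first-order relaxation toward the same target with time constant `tau`
#' (the recovered lag then only approximates `tau`).
#'
#' @param meteo a [generate_meteo_day()] result.
#' @param tau imposed lag (min); non-negative grid multiple, at most the
#'   padding margin.
#' @param scenario a [stress_scenario()].
#' @param mode `"pure_delay"` or `"first_order"`.
#' @param baseline an [nwsb_baseline()] carrying the stress-free slope `a`
#'   (degC kPa-1) and intercept `b` (degC).
#' @param dt_stress canopy-air temperature offset (degC) at severity 1.
#' @param noise_sd white-noise SD on Tc (degC).
#' @param seed integer seed or `NULL`.
#' @return A [ts_series()] of canopy temperature on the day-proper grid
#'   (`t >= 0`), with attributes `true_lag`, `scenario` and `mode`.
#' @examples
#' day <- generate_meteo_day(meteo_config(), seed = 1)
#' tc <- generate_canopy_temperature(day, tau = 44,
#'   scenario = stress_scenario("T1", 0), noise_sd = 0, seed = 1)
#' @export
generate_canopy_temperature <- function(meteo, tau, scenario,
                                        mode = c("pure_delay", "first_order"),
                                        baseline = nwsb_baseline(-2, 2.5),
                                        dt_stress = 3, noise_sd = 0.15,
                                        seed = NULL) {
  stopifnot(inherits(meteo, "meteo_day"), inherits(scenario, "stress_scenario"))
  mode <- match.arg(mode)
  step <- ts_step(meteo$Ta)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (abs(tau / step - round(tau / step)) > 1e-8)
    stop("tau must be a multiple of the sampling step", call. = FALSE)
  if (tau > -meteo$t[1L])
    stop("insufficient history: tau exceeds the pre-midnight padding margin",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  a <- baseline$a; b <- baseline$b

  with_seed(seed, {
    day_idx <- meteo$t >= 0
    t_day <- meteo$t[day_idx]
    if (mode == "pure_delay") {
      k <- round(tau / step)
      i_day <- which(day_idx)
      ta_sh <- meteo$Ta$v[i_day - k]
      rh_sh <- meteo$RH$v[i_day - k]
      target <- ta_sh + a * vpd(ta_sh, rh_sh) + b + scenario$stress * dt_stress
      tc <- target + stats::rnorm(length(t_day), 0, noise_sd)
    } else {
      if (tau < step)
        stop("first_order mode needs tau >= one sampling step", call. = FALSE)
      tgt <- meteo$Ta$v + a * vpd(meteo$Ta$v, meteo$RH$v) + b +
        scenario$stress * dt_stress
      tc_full <- numeric(length(meteo$t))
      tc_full[1L] <- tgt[1L]
      for (i in seq_len(length(tgt) - 1L))
        tc_full[i + 1L] <- tc_full[i] + (step / tau) * (tgt[i] - tc_full[i])
      tc <- tc_full[day_idx] + stats::rnorm(length(t_day), 0, noise_sd)
    }
    out <- ts_series(t_day, tc, "degC")
    attr(out, "true_lag") <- tau
    attr(out, "scenario") <- scenario$label
    attr(out, "mode") <- mode
    out
  })
}

#' Configuration for synthetic leaf gas-exchange observations
#'
#' Midday observations decline linearly with stress severity and collapse by
#' a further fraction once severity crosses a severe-stress threshold,
#' mimicking stomatal closure at the soil-moisture threshold. Default
#' sensitivities order stomatal conductance > transpiration > net
#' photosynthesis.
#'
#' @param Pn0,Tr0,gs0 unstressed baselines (umol m-2 s-1, mmol m-2 s-1,
#'   mol m-2 s-1).
#' @param k named decline rates per unit severity for `Pn`, `Tr`, `gs`.
#' @param s_thr severity threshold of the severe-stress drop.
#' @param drop fractional drop applied at and beyond `s_thr`.
#' @param cv noise coefficient of variation (fraction of the baseline).
#' @param obs_time observation time (min from midnight; 840 = 14:00).
#' @return A list of class `photo_config`.
#' @export
photo_config <- function(Pn0 = 25, Tr0 = 6, gs0 = 0.5,
                         k = c(Pn = 0.5, Tr = 0.65, gs = 0.8),
                         s_thr = 0.75, drop = 0.3, cv = 0.05, obs_time = 840) {
  if (Pn0 < 0 || Tr0 < 0 || gs0 < 0)
    stop("invalid config: baselines must be non-negative", call. = FALSE)
  if (any(k < 0) || drop < 0 || cv < 0)
    stop("invalid config: rates, drop and cv must be non-negative", call. = FALSE)
  structure(list(Pn0 = Pn0, Tr0 = Tr0, gs0 = gs0, k = k, s_thr = s_thr,
                 drop = drop, cv = cv, obs_time = obs_time),
            class = "photo_config")
}

#' Generate midday photosynthesis observations per stress scenario
#'
#' @param scenarios list of [stress_scenario()] objects.
#' @param config a [photo_config()].
#' @param seed integer seed or `NULL`.
#' @return A data frame with one row per scenario: `scenario`, `stress`,
#'   `Pn`, `Tr`, `gs`, `obs_time`.
#' @examples
#' generate_photosynthesis(default_scenarios(), photo_config(cv = 0), seed = 1)
#' @export
generate_photosynthesis <- function(scenarios, config = photo_config(),
                                    seed = NULL) {
  stopifnot(inherits(config, "photo_config"))
  with_seed(seed, {
    rows <- lapply(scenarios, function(sc) {
      s <- sc$stress
      sev <- 1 - config$drop * (s >= config$s_thr)
      base <- c(Pn = config$Pn0, Tr = config$Tr0, gs = config$gs0)
      val <- base * (1 - config$k[c("Pn", "Tr", "gs")] * s) * sev
      val <- val + stats::rnorm(3, 0, config$cv * base)
      val[val < 0] <- 0
      data.frame(scenario = sc$label, stress = s,
                 Pn = val[["Pn"]], Tr = val[["Tr"]], gs = val[["gs"]],
                 obs_time = config$obs_time)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a multi-day, multi-treatment campaign with known lags
#'
#' Generates `n_days` meteorology days (with day-to-day variation in the
#' temperature range, peak time and radiation), canopy temperature per
#' (day x scenario) with the scenario's true lag imposed, and midday
#' gas-exchange observations per (day x scenario). All randomness flows from
#' one seed; the same (configuration, seed) pair is bit-reproducible.
#'
#' @param n_days number of days.
#' @param scenarios named list of [stress_scenario()] objects.
#' @param true_lag named lag (min) per scenario; grid multiples.
#' @param config a [meteo_config()] for the typical day.
#' @param pconfig a [photo_config()].
#' @param baseline [nwsb_baseline()] used inside the generator.
#' @param dt_stress stress CTD offset at severity 1 (degC).
#' @param tc_noise_sd canopy-temperature noise SD (degC).
#' @param mode lag mechanism passed to [generate_canopy_temperature()].
#' @param day_jitter named SDs of the day-to-day variation of `t_max`,
#'   `t_min`, `peak_time` and `rn_peak`.
#' @param seed integer seed.
#' @return A list of class `cwsi_campaign` with fields `days` (list of
#'   [generate_meteo_day()] results), `tc` (list, `tc[[day]][[scenario]]`),
#'   `photos` (data frame with a `day` column), `true_lag`, `scenarios`,
#'   `baseline`, `seed`.
#' @examples
#' camp <- simulate_campaign(n_days = 2, seed = 1)
#' camp$true_lag
#' @export
simulate_campaign <- function(n_days = 12,
                              scenarios = default_scenarios(),
                              true_lag = c(T1 = 97, T2 = 92, T3 = 98, T4 = 76),
                              config = meteo_config(),
                              pconfig = photo_config(),
                              baseline = nwsb_baseline(-2, 2.5),
                              dt_stress = 3,
                              tc_noise_sd = 0.15,
                              mode = "pure_delay",
                              day_jitter = c(t_max = 2, t_min = 1,
                                             peak_time = 20, rn_peak = 50),
                              seed = 1) {
  # lags are forced onto the sampling grid so pure delays are exact shifts
  true_lag <- round(true_lag / config$step) * config$step
  missing_lag <- setdiff(names(scenarios), names(true_lag))
  if (length(missing_lag))
    stop("true_lag missing for scenario(s): ",
         paste(missing_lag, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    days <- vector("list", n_days)
    tc <- vector("list", n_days)
    photos <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      cfg_d <- config
      cfg_d$t_max <- config$t_max + stats::rnorm(1, 0, day_jitter[["t_max"]])
      cfg_d$t_min <- config$t_min + stats::rnorm(1, 0, day_jitter[["t_min"]])
      if (cfg_d$t_max <= cfg_d$t_min + 2) cfg_d$t_max <- cfg_d$t_min + 2
      cfg_d$peak_time <- min(1440, max(0, config$peak_time +
        stats::rnorm(1, 0, day_jitter[["peak_time"]])))
      cfg_d$rn_peak <- max(100, config$rn_peak +
        stats::rnorm(1, 0, day_jitter[["rn_peak"]]))
      days[[d]] <- generate_meteo_day(cfg_d, seed = NULL)
      tc[[d]] <- lapply(scenarios, function(sc)
        generate_canopy_temperature(days[[d]], tau = true_lag[[sc$label]],
                                    scenario = sc, mode = mode,
                                    baseline = baseline,
                                    dt_stress = dt_stress,
                                    noise_sd = tc_noise_sd, seed = NULL))
      ph <- generate_photosynthesis(scenarios, pconfig, seed = NULL)
      ph$day <- d
      photos[[d]] <- ph
    }
    structure(list(days = days, tc = tc,
                   photos = do.call(rbind, photos),
                   true_lag = true_lag, scenarios = scenarios,
                   baseline = baseline, dt_stress = dt_stress,
                   mode = mode, seed = seed, config = config,
                   pconfig = pconfig),
              class = "cwsi_campaign")
  })
}

#' @export
print.cwsi_campaign <- function(x, ...) {
  cat(sprintf("<cwsi_campaign> %d days x %d scenarios, seed %d, mode %s\n",
              length(x$days), length(x$scenarios), x$seed, x$mode))
  cat("  true lags (min):",
      paste(names(x$true_lag), x$true_lag, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
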