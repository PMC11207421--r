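# Shared fixtures: noise-free configurations and exact-delay canopy series.

quiet_config <- function(...) {
  meteo_config(noise_sd = list(Ta = 0, RH = 0, Rn = 0), u_sd = 0, ...)
}

# Canopy temperature as an exact delayed copy of Ta (zero baseline, zero
# stress), optionally with white noise.
exact_delay_tc <- function(day, tau, noise_sd = 0, seed = NULL) {
  generate_canopy_temperature(day, tau, stress_scenario("ref", 0),
                              baseline = nwsb_baseline(0, 0),
                              noise_sd = noise_sd, seed = seed)
}

# Naive per-shift Pearson profile: independent oracle computing each
# correlation from explicit sums, pairing by index arithmetic.
naive_pearson_profile <- function(tc, ta, max_lag) {
  step <- tc$t[2] - tc$t[1]
  lags <- seq(0, max_lag, by = step)
  sapply(lags, function(tau) {
    k <- round(tau / step)
    j <- round((tc$t - tau - ta$t[1]) / step) + 1
    ok <- j >= 1 & j <= length(ta$t)
    x <- tc$v[ok]; y <- ta$v[j[ok]]
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- sum(x * y) - sx * sy / n
    den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
    num / den
  })
}

# Binned Shannon entropy (nats) matching the MI estimator's binning rule.
binned_entropy <- function(v, bins) {
  r <- range(v)
  i <- pmin(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1, bins)
  p <- tabulate(i, bins) / length(v)
  p <- p[p > 0]
  -sum(p * log(p))
}
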