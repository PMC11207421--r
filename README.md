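# cwsilag

Canopy temperature (Tc) responds to air temperature (Ta) with a delay of
tens of minutes — the canopy's thermal mass and stomatal dynamics act as a
low-pass filter. The Crop Water Stress Index (CWSI), the standard
thermal-infrared indicator of crop water status, is built from the
canopy–air temperature difference CTD = Tc − Ta, so pairing Tc with the
*contemporaneous* Ta contaminates the stress signal with thermal inertia.
`cwsilag` is for agronomists and crop-stress researchers working with
continuously logged canopy/micro-meteorology series (infrared thermometry +
weather station, ~2-min sampling). It:

- estimates the Tc–Ta time lag τ by four methods — **peak-seeking**
  (asymmetric diurnal curve fits to each series, τ = difference of fitted
  peak times), **lagged Pearson correlation**, **lagged mutual
  information**, and **grey relational analysis** (all profile methods scan
  τ on the sampling grid over truncated overlaps);
- computes both standard CWSI formulations, uncorrected and lag-corrected
  (Tc(t) paired with Ta(t − τ), RH(t − τ)):
  - *empirical (Idso)*: CWSI = (CTD − NWSB)/(NTB − NWSB), with the
    non-water-stressed baseline NWSB = a·VPD + b fitted by OLS on
    well-watered 13:00–15:00 data and the non-transpiring bound
    NTB = a·VPG + b, VPG = e_s(Ta) − e_s(Ta + b);
  - *theoretical (Jackson energy balance)*:
    CWSI = (γ(1 + r_c/r_a) − γ\*)/(Δ + γ(1 + r_c/r_a)), with
    γ\* = γ(1 + r_cp/r_a) from the growth stage's minimum canopy resistance
    and the actual r_c inverted from the observed CTD through the canopy
    energy balance;
- quantifies what the correction buys: R² of Pn, Tr and gs (midday gas
  exchange) against every (model × lag method × corrected/uncorrected)
  CWSI variant;
- ships a synthetic diurnal generator with a *known imposed lag* and an
  embedded baseline, so every stage is testable against ground truth
  without field data.

## Worked example

Estimate a known 60-min lag on a noisy synthetic day, then measure the
before/after effect on the CWSI–gas-exchange correlation:

```r
library(cwsilag)

day <- generate_meteo_day(meteo_config(), seed = 2)
tc  <- generate_canopy_temperature(day, tau = 60,
                                   scenario = stress_scenario("T2", 0.3),
                                   noise_sd = 0.3, seed = 2)
for (m in c("cross_correlation", "mutual_information",
            "gray_relational", "peak_seeking")) {
  e <- estimate_lag(tc, day$Ta, m)
  cat(sprintf("%-20s tau = %3g min  (score %.4f)\n", m, e$tau, e$score))
}
#> cross_correlation    tau =  60 min  (score 0.9984)
#> mutual_information   tau =  62 min  (score 1.7909)
#> gray_relational      tau =  60 min  (score 0.9182)
#> peak_seeking         tau =  64 min  (score 0.9996)
```

All four estimators land on the imposed 60 min to within a few grid steps;
the scores are each method's peak statistic (Pearson r, MI in nats, grey
relational grade, and the worse of the two curve-fit R²).

```r
camp <- simulate_campaign(n_days = 6,
                          true_lag = c(T1 = 60, T2 = 60, T3 = 60, T4 = 60),
                          seed = 42)
lags <- estimate_campaign_lags(camp, "cross_correlation")
tab  <- before_after_comparison(camp, lags, models = "empirical")
tab
#> CWSI vs photosynthetic parameters (R2 per model x lag method):
#>
#>   empirical model:
#>         lag_method    Pn    Tr    gs
#>               none 0.843 0.846 0.857
#>  cross_correlation 0.912 0.911 0.942
```

Correcting the pairing by the estimated per-treatment lags raises R²
against stomatal conductance from 0.86 to 0.94 (`attr(tab, "delta")` holds
the per-cell differences); slopes are negative, as they must be — stressed
canopies are warmer while gas exchange falls.

`run_pipeline(pipeline_config(seed = 1), "out/")` executes the whole chain
(simulate → smooth → estimate lags → CWSI → compare) and writes every
artifact — campaign CSVs, lag profiles and estimates, correlation and delta
tables, the effective configuration and a run log — into `out/`.

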