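---
title: "Time-lag aware CWSI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lag aware CWSI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cwsilag)
```

## The problem

A crop canopy does not track air temperature instantaneously: heat storage in
the canopy and the stomatal response to atmospheric demand delay the canopy
temperature (Tc) behind the air temperature (Ta) by tens of minutes. The Crop
Water Stress Index (CWSI) is built from the canopy–air temperature difference
(CTD = Tc − Ta), so pairing Tc with the *contemporaneous* Ta mixes the water
stress signal with this thermal inertia. This package (i) estimates the lag
τ between diurnal Tc and Ta series, (ii) recomputes both standard CWSI
formulations with Tc(t) paired against Ta(t − τ) and RH(t − τ), and (iii)
measures whether that correction strengthens the relation between CWSI and
midday leaf gas exchange (net photosynthesis Pn, transpiration Tr, stomatal
conductance gs).

All series are assumed to be uniformly sampled (default 2-min step) single
days; series generated by the package carry a pre-midnight padding margin so
that lagged lookups never wrap around.

## Lag estimators

Four estimators are provided. The sign convention is uniform: τ ≥ 0 means Tc
lags behind Ta. The profile methods scan candidate lags τ = 0, δ, 2δ, …,
`max_lag` on the sampling grid δ (default grid 0–180 min, which covers
field-scale lags of 30–100 min with margin), pair Tc(t) with Ta(t − τ) over
the truncated overlap — no wraparound, and at least 50 % of the day must
remain — and return the argmax, ties going to the smallest lag.

**Peak-seeking.** Both series are smoothed (Savitzky–Golay), each is fitted
with a single-peak diurnal curve by multi-start Levenberg–Marquardt, and τ is
the difference of the fitted peak times. Canopy days use a composite
asymmetric peak (Gaussian core plus a sigmoid-gated one-sided exponential
shoulder):

y = y0 + A·(exp(−z²/2w) + (1 − ½(1 − tanh(k₂(x − xc₂))))·B·exp(−½k₃(|x − xc₃| + (x − xc₃)))), z = x − xc₁.

The switch uses `tanh`: a `tan` in that position is unbounded and periodic
and cannot act as a smooth gate (the literal form is available via
`literal_tan = TRUE` for comparability). Air days use a Gaussian core with
Gram–Charlier/Edgeworth corrections carrying skewness a₃ and kurtosis a₄,
with the Hermite polynomials He₃(z) = z³ − 3z, He₄(z) = z⁴ − 6z² + 3 and
He₆(z). Because the composite peaks need not sit at the location parameters
xc₁/xc, the peak time is the argmax of the fitted curve on a dense 1-min
grid (ties to the earlier time), never a coefficient read-out. The
optimization runs one heuristic start plus 12 (CCE) or 5 (ECS) jittered
starts; the canopy equation in particular is multi-modal, and the starts
must explore gate positions well before the peak and shoulder weights up to
a few times the core, otherwise near-identical residuals hide peak-time
errors of tens of minutes. Convergence tolerances are 1e-10 (relative
residual), at most 5000 function evaluations per start; the best
finite-residual start wins, and `w > 0` is enforced by bounds.

**Lagged Pearson correlation.** `lag_cross_correlation()` computes Pearson r
per candidate lag. It is affine-invariant, so Z-scoring the inputs is
optional.

**Lagged mutual information.** A plug-in histogram estimator on equal-width
bins spanning each variable's own observed range (hence scale-invariant),
natural logarithm, 0·log 0 ≡ 0. The bin count defaults to the Sturges rule
⌈log₂ n⌉ + 1 on each overlap; a deterministic rule keeps runs reproducible.
The plug-in estimator is biased upward at small n (the bias shrinks as n
grows, which the tests check), and its monotone-transform invariance holds
only up to binning: strongly concentrated marginals (e.g. a cubed series)
need a finer grid than Sturges to resolve.

**Grey relational analysis.** Pointwise coefficients
ζ(k) = (Δmin + ρ·Δmax)/(Δ(k) + ρ·Δmax) with Δ(k) = |x(k) − y(k)|, resolution
factor ρ = 0.5, averaged into the grade γ; the extremes Δmin/Δmax are taken
jointly over *all* candidate lags and positions, as the double min/max in
the definition requires; if Δmax = 0 every coefficient is 1. Grades are not
scale-invariant, so the inputs must be standardized — and here a design
choice was genuinely open. Z-scoring each full series once breaks the
anchor property "an exact delayed copy scores γ = 1 at the true shift"
whenever the two series have different supports (canopy series are
day-only; air series carry pre-midnight padding, so the shifted segment has
a different mean and SD than the full series). We therefore standardize
each overlapping segment pair (mean 0, population SD) immediately before
the distances are taken. This keeps the grade scale-free and restores the
exact-copy anchor regardless of padding.

## CWSI models

Internal unit canon: temperatures in °C, resistances in s·m⁻¹, pressures in
Pa — except the empirical model boundary, where VPD is in kPa as its formula
emits.

**Empirical (baseline) model.** CWSI = (CTD − NWSB)/(NTB − NWSB). The lower,
non-water-stressed baseline is the Idso line NWSB = a·VPD + b, fitted by OLS
over the 13:00–15:00 window (when the CTD–VPD relation is most distinct) on
well-watered data; the upper, non-transpiring bound is NTB = a·VPG + b with
VPG = es(Ta) − es(Ta + b) and es the Tetens saturation curve
0.6108·exp(17.27 T/(T + 237.7)) kPa. The raw index is *not* clamped by
default — correlation analyses may legitimately use out-of-range values — but
a `[0, 1]`-clamped companion column is always stored.

**Theoretical (energy-balance) model.** CWSI = (γ(1 + rc/ra) − γ*)/(Δ +
γ(1 + rc/ra)), with the psychrometric coefficient γ(Z) = 0.665·101.3·((293 −
0.0065Z)/293)^5.26 Pa·°C⁻¹, the saturation-slope cubic Δ(T) at the canopy–air
mean temperature, and the aerodynamic resistance ra = 4.72[ln((z − d)/z₀)]²/
(1 + 0.54u) with d = 0.63h, z₀ = 0.13h. Two resistances play distinct roles:
γ* = γ(1 + r_cp/ra) uses the *minimum* (potential-transpiration) canopy
resistance r_cp of the growth stage (13.01/18.03/26.85 s·m⁻¹ from regreening
through filling), while the *actual* resistance rc is inverted from the
observed CTD through the energy balance: with R = ra(Rn − G)/(ρ c_p) °C,
rc = ra·(Y/γ − 1), Y = (CTD·Δ + VPD_Pa)/(R − CTD). A formulation in which
γ* were built from the same rc as the numerator would make the index
identically zero — only the two-resistance reading yields an index that is 0
at potential transpiration and approaches 1 as rc → ∞. Negative inversions
are floored at 0 and flagged; observations warmer than the no-transpiration
limit (R ≤ CTD) are flagged and reported as CWSI = 1. Air density (1.20
kg·m⁻³) and specific heat (1013 J·kg⁻¹·K⁻¹) are configurable constants of
`theoretical_params()`.

**Lag correction.** `apply_time_lag()` re-pairs Tc(t) with Ta(t − τ) *and*
RH(t − τ): humidity is shifted jointly with temperature so the VPD entering
either model stays thermodynamically consistent (shifting Ta alone would
evaluate the saturation curve at one time and the humidity at another).
Radiation, soil heat flux and wind stay contemporaneous — they act on the
canopy through the instantaneous energy balance, not through the lagged
thermal coupling. τ = 0 reproduces the uncorrected pairing exactly, and
records carry `lag_applied` for bookkeeping.

**Before/after comparison.** `before_after_comparison()` evaluates each
(model × lag method) variant's CWSI at every midday observation (nearest
grid sample within ±2 min of 14:00), pools scenarios and days, and reports
the R² of each gas-exchange parameter regressed on CWSI, plus
corrected-minus-uncorrected deltas. For the empirical model the baseline is
refitted on the least-stressed treatment *under the same pairing* as the
variant being scored, so every column is self-consistent; the uncorrected
column never touches the lag estimates.

## The synthetic generator

Since continuous field series of this kind are rarely distributed, the
generator provides ground truth: every downstream claim is validated against
data whose lag, baseline and stress structure are known exactly.

The day is built as follows, each default chosen once to be realistic for a
clear early-spring day over winter wheat:

- **Ta**: a skewed single-peak bump — a Gaussian core with a Gram–Charlier
  third-order (skewness) correction — positioned so its argmax sits exactly
  at the configured peak time (default 14:00), riding on the daily minimum.
  Defaults: 8–24 °C range, width 220 min, skewness 0.3, Gaussian noise
  SD 0.2 °C.
- **RH**: affine-decreasing in Ta (90 % at the minimum to 40 % at the
  maximum), noise SD 1.5 %, clipped to [5, 100] %.
- **Rn**: half-sine over 06:00–19:00 peaking at 650 W·m⁻², zero at night;
  **G** = 0.1·Rn; **u**: mean 1.5 m·s⁻¹ with AR(1) perturbation (φ = 0.8,
  innovation SD 0.3), floored at 0.
- **Tc** (pure-delay mode): Tc(t) = Ta(t − τ) + a·VPD(t − τ) + b +
  s·ΔT_stress + ε, with the Idso baseline (a = −2 °C·kPa⁻¹, b = 2.5 °C)
  evaluated at the *shifted* meteorology, so the baseline relation is
  embedded exactly and `fit_nwsb()` must recover (a, b) to machine precision
  on noise-free data. The stress severity s ∈ [0, 1] adds up to
  ΔT_stress = 3 °C; the four default treatments map irrigation limits of
  95/80/65/50 % field capacity onto s = 0/0.3/0.6/0.9. A first-order
  relaxation mode is also provided; its recovered lag only approximates the
  time constant.
- **Gas exchange**: Pn/Tr/gs = baseline·(1 − k·s), with a further 30 % drop
  once s ≥ 0.75 (the soil-moisture threshold at which stomata close
  abruptly), truncated at 0, noise CV 5 %. Baselines 25 µmol·m⁻²·s⁻¹ /
  6 mmol·m⁻²·s⁻¹ / 0.5 mol·m⁻²·s⁻¹ and sensitivities k = 0.5/0.65/0.8 order
  the responses gs > Tr > Pn.
- **Campaigns** draw day-to-day variation (Tmax SD 2 °C, Tmin SD 1 °C, peak
  time SD 20 min, Rn peak SD 50 W·m⁻²) so that pooled multi-day regressions
  face realistic between-day variance. Default true lags are 97/92/98/76 min
  for T1–T4, mirroring field-scale magnitudes; every lag is snapped to the
  sampling grid so pure delays are exact shifts. Each day carries a 4-h
  pre-midnight padding margin — larger than any candidate lag — so shifted
  lookups never alias.

All randomness flows from one seed passed down explicitly; regenerating with
the same configuration and seed is bit-identical.

**What the generator does *not* emulate** — and hence what passing tests do
not demonstrate about field data: cloud passages and radiation intermittency,
advection, multi-day weather autocorrelation, a soil-water balance (stress is
an imposed severity, not a prognostic water budget), canopy cover changes,
or sensor drift. Two consequences deserve emphasis. First, in pure-delay
mode the lag is exact and common to the whole day, so all estimators agree
at the truth on clean data; estimator spreads like those seen on field data
arise only from noise and shape distortion. Second, the Ta bump is drawn
from the same curve family the air-temperature fit equation assumes, which
makes the peak-seeking method look its best; on real data its bias depends
entirely on how well those equations track the observed diurnal shape —
the flatness of the diurnal peak means a curve fit with R² ≈ 0.9999 can
still misplace the peak by tens of minutes under shape mismatch.

## Numerical choices

- **Smoothing**: Savitzky–Golay window 31 samples (62 min) and order 3 —
  wide enough to suppress 2-min sensor noise, narrow enough to preserve a
  single diurnal peak; both are arguments everywhere they matter. Boundary
  samples are the evaluations of the boundary polynomial fits.
- **Z-scoring** uses the population SD (divisor n); every downstream
  estimator is invariant to the convention, it is fixed for reproducibility.
  Constant series raise an error rather than returning NaN.
- **Degenerate rules**: zero-variance overlap windows error; empirical
  bounds closer than 1e-9 error; Δmax = 0 in GRA gives grade 1; the
  observation matcher skips cells with no grid sample within ±2 min.
- **Ties**: profile argmaxes take the smallest lag; dense-grid curve peaks
  take the earliest time.
- **Validation problem sizes**: single days of 720–840 samples; noise
  studies use 20 seeds; the end-to-end improvement study uses campaigns of
  12 days × 4 treatments × 20 seeds, which keeps the full suite comfortably
  within a desktop run while leaving the improvement signal (mean ΔR² ≈
  0.06–0.08 for gs) far from its decision boundary.

## A compact example

```{r example, fig.width = 6, fig.height = 4}
day <- generate_meteo_day(meteo_config(), seed = 2)
tc  <- generate_canopy_temperature(day, tau = 60,
                                   scenario = stress_scenario("T2", 0.3),
                                   noise_sd = 0.3, seed = 2)
est <- estimate_lag(tc, day$Ta, "cross_correlation")
est
plot(est)
```

```{r campaign}
camp <- simulate_campaign(n_days = 6,
                          true_lag = c(T1 = 60, T2 = 60, T3 = 60, T4 = 60),
                          seed = 42)
lags <- estimate_campaign_lags(camp, "cross_correlation")
tab <- before_after_comparison(camp, lags, models = "empirical")
tab
attr(tab, "delta")
```

## Known limitations

- Single-day, single-lag structure: one τ per treatment and day; slowly
  drifting lags within a day are outside the model.
- The theoretical model omits atmospheric stability corrections to ra and
  any two-source (soil + canopy) partitioning.
- The MI estimator is the plug-in histogram; kernel or k-NN estimators may
  behave differently near the peak on short windows.
- Growth stage is user input; the package does not detect it.
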