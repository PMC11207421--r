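Package: cwsilag
Title: Time-Lag Aware Crop Water Stress Index for Canopy Temperature Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the delay with which crop canopy temperature responds
    to air temperature and propagates that delay into the Crop Water Stress
    Index (CWSI). Provides four lag estimators over diurnal series
    (peak-seeking via asymmetric diurnal curve fits, lagged Pearson
    correlation, lagged mutual information, and grey relational analysis),
    the Idso empirical and Jackson energy-balance CWSI models with
    lag-corrected variants, a synthetic diurnal micro-meteorology generator
    with a known imposed lag for validation, and tooling to compare the
    correlation of corrected and uncorrected CWSI with leaf gas-exchange
    measurements (net photosynthesis, transpiration, stomatal conductance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
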