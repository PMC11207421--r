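# CSV ingestion and export.  One file per scalar series with header
# `time_min,value`; meteorology days as `time_min,Ta,RH,Rn,G,u`; campaign
# manifests as YAML.

validate_time_grid <- function(t, what = "time_min") {
  if (anyNA(t) || !is.numeric(t))
    stop("non-numeric or missing timestamps in column ", what, call. = FALSE)
  if (any(diff(t) <= 0))
    stop("non-monotonic time: ", what, " must be strictly increasing",
         call. = FALSE)
}

# Regularize a (t, v) pair onto the modal step; interpolate gaps of at most
# two missing samples, error on larger ones.  Returns list(t, v, n_filled).
regularize_series <- function(t, v) {
  d <- diff(t)
  step <- min(d)
  ratio <- d / step
  if (any(abs(ratio - round(ratio)) > 1e-6))
    stop("irregular step: timestamps are not multiples of the base step ",
         step, call. = FALSE)
  if (any(round(ratio) > 3))
    stop("gap larger than 2 missing samples; refusing to interpolate",
         call. = FALSE)
  full_t <- seq(t[1], t[length(t)], by = step)
  n_filled <- length(full_t) - length(t)
  if (n_filled > 0) {
    v <- stats::approx(t, v, xout = full_t)$y
    message(sprintf("interpolated %d missing sample(s)", n_filled))
    t <- full_t
  }
  list(t = t, v = v, n_filled = n_filled)
}

#' Read a single time series from CSV
#'
#' Expects a header with a time column (numeric minutes) and a value column.
#' Gaps of up to two missing samples are linearly interpolated (with a
#' message); larger gaps are an error.
#'
#' @param path CSV file path.
#' @param time_col,value_col column names (defaults `time_min`, `value`).
#' @param unit unit tag for the resulting series.
#' @return A [ts_series()].
#' @export
read_timeseries_csv <- function(path, time_col = "time_min",
                                value_col = "value", unit = "") {
  df <- utils::read.csv(path)
  for (col in c(time_col, value_col))
    if (!col %in% names(df))
      stop("missing column \"", col, "\" in ", path, call. = FALSE)
  validate_time_grid(df[[time_col]], time_col)
  reg <- regularize_series(df[[time_col]], df[[value_col]])
  ts_series(reg$t, reg$v, unit)
}

#' Write a time series to CSV
#' @param series a [ts_series()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a meteorology day from CSV
#'
#' Expects columns `time_min, Ta, RH, Rn, G, u` on a uniform grid.
#' @param path CSV file path.
#' @return A `meteo_day` (without generator config).
#' @export
read_meteo_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("time_min", "Ta", "RH", "Rn", "G", "u")
  for (col in needed)
    if (!col %in% names(df))
      stop("missing column \"", col, "\" in ", path, call. = FALSE)
  validate_time_grid(df$time_min)
  units <- c(Ta = "degC", RH = "%", Rn = "W/m2", G = "W/m2", u = "m/s")
  series <- lapply(names(units), function(nm) {
    reg <- regularize_series(df$time_min, df[[nm]])
    ts_series(reg$t, reg$v, units[[nm]])
  })
  names(series) <- names(units)
  structure(c(list(t = series$Ta$t), series, list(config = NULL)),
            class = "meteo_day")
}

#' Write a meteorology day to CSV
#' @param meteo a `meteo_day`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_meteo_csv <- function(meteo, path) {
  utils::write.csv(data.frame(time_min = meteo$t, Ta = meteo$Ta$v,
                              RH = meteo$RH$v, Rn = meteo$Rn$v,
                              G = meteo$G$v, u = meteo$u$v),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic campaign to a directory
#'
#' Writes one meteorology CSV per day, one canopy-temperature CSV per
#' (day x scenario), the gas-exchange table, and a YAML manifest recording
#' scenarios, seeds and true lags.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "cwsi_campaign"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in seq_along(campaign$days)) {
    write_meteo_csv(campaign$days[[d]],
                    file.path(dir, sprintf("meteo_day%02d.csv", d)))
    for (sc in names(campaign$scenarios))
      write_timeseries_csv(campaign$tc[[d]][[sc]],
                           file.path(dir, sprintf("tc_day%02d_%s.csv", d, sc)))
  }
  utils::write.csv(campaign$photos, file.path(dir, "photosynthesis.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = campaign$seed,
    n_days = length(campaign$days),
    mode = campaign$mode,
    true_lag_min = as.list(campaign$true_lag),
    scenarios = lapply(campaign$scenarios, function(s)
      list(label = s$label, stress = s$stress, fc_fraction = s$fc_fraction)),
    baseline = list(a = campaign$baseline$a, b = campaign$baseline$b),
    dt_stress = campaign$dt_stress)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
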