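#' Savitzky-Golay smoothing of a diurnal series
#'
#' Local least-squares polynomial smoothing on the series' own grid. The
#' filter reproduces any polynomial of degree at most `polyorder` exactly
#' (including at the boundaries, where the fitted boundary polynomials are
#' evaluated rather than the signal padded), which is why it preserves the
#' shape and peak position of smooth diurnal curves while suppressing
#' high-frequency sensor noise.
#'
#' @param series a [ts_series()].
#' @param window odd window length in samples (default 31 samples = 62 min on
#'   the 2-min grid).
#' @param polyorder polynomial degree, strictly smaller than `window`.
#' @return A smoothed [ts_series()] on the same grid and unit.
#' @examples
#' t <- seq(0, 1438, by = 2)
#' noisy <- ts_series(t, sin(t / 200) + rnorm(length(t), 0, 0.1))
#' sm <- savgol_smooth(noisy)
#' @export
savgol_smooth <- function(series, window = 31, polyorder = 3) {
  stopifnot(inherits(series, "ts_series"))
  if (window %% 2 != 1)
    stop("invalid argument: window must be odd", call. = FALSE)
  if (polyorder >= window)
    stop("invalid argument: polyorder must be smaller than window", call. = FALSE)
  if (window > length(series$v))
    stop("invalid argument: window exceeds the series length", call. = FALSE)
  sm <- signal::sgolayfilt(series$v, p = polyorder, n = window)
  ts_series(series$t, sm, series$unit)
}

#' Z-score standardization of a series
#'
#' Centers and scales to sample mean 0 and population standard deviation 1
#' (divisor n, not n-1; any consistent convention leaves the downstream lag
#' estimators unchanged). The result is dimensionless.
#'
#' @param series a [ts_series()].
#' @return A standardized [ts_series()].
#' @export
zscore <- function(series) {
  stopifnot(inherits(series, "ts_series"))
  m <- mean(series$v)
  s <- sqrt(mean((series$v - m)^2))
  if (s <= .Machine$double.eps * max(1, abs(m)))
    stop("degenerate series: zero variance, cannot Z-score", call. = FALSE)
  ts_series(series$t, (series$v - m) / s, "")
}
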