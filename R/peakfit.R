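# Diurnal peak-curve models and the peak-seeking lag.
#
# Canopy temperature days are fitted with a composite asymmetric peak (a
# Gaussian core plus a sigmoid-gated one-sided exponential shoulder, a
# Chesler-Cram-type shape, here called CCE); air temperature days with a
# Gaussian-core Edgeworth/Gram-Charlier series (ECS) whose Hermite terms
# carry skewness (a3) and kurtosis (a4).  The lag is the difference of the
# two fitted peak times.

cce_curve <- function(x, p, literal_tan = FALSE) {
  z <- x - p[["xc1"]]
  sw <- if (literal_tan) tan(p[["k2"]] * (x - p[["xc2"]]))
        else             tanh(p[["k2"]] * (x - p[["xc2"]]))
  p[["y0"]] + p[["A"]] * (exp(-z * z / (2 * p[["w"]])) +
    (1 - 0.5 * (1 - sw)) * p[["B"]] *
      exp(-0.5 * p[["k3"]] * (abs(x - p[["xc3"]]) + (x - p[["xc3"]]))))
}

ecs_curve <- function(x, p) {
  z <- (x - p[["xc"]]) / p[["w"]]
  core <- exp(-0.5 * z^2)
  herm <- 1 +
    (p[["a3"]] / 6) * z * (z^2 - 3) +
    (p[["a4"]] / 24) * (z^4 - 6 * z^2 + 3) +
    (10 * p[["a3"]]^2 / 720) * (z^6 - 15 * z^4 + 45 * z^2 - 15)
  p[["y0"]] + p[["A"]] / (p[["w"]] * sqrt(2 * pi)) * core * herm
}

# Multi-start Levenberg-Marquardt driver.  `starts` is a list of named
# parameter vectors; returns the converged fit with the lowest SSE.
fit_peak_curve <- function(t, v, fun, starts, lower, upper) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000,
                                     ftol = 1e-10, ptol = 1e-10)
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) v - fun(t, p),
                         lower = lower[names(p0)], upper = upper[names(p0)],
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    if (!is.finite(sse)) next
    if (is.null(best) || sse < best$sse)
      best <- list(par = res$par, sse = sse)
  }
  if (is.null(best))
    stop("fit failure: no start converged to a finite residual", call. = FALSE)
  best
}

make_peak_fit <- function(equation, par, t, v, fun) {
  fitted <- fun(t, par)
  sst <- sum((v - mean(v))^2)
  r2 <- 1 - sum((v - fitted)^2) / sst
  dense <- seq(min(t), max(t), by = 1)
  yd <- fun(dense, par)
  peak_time <- dense[which.max(yd)]  # which.max: earliest index wins ties
  structure(list(equation = equation, params = unlist(par), r2 = r2,
                 peak_time = peak_time, t = t, v = v,
                 fitted.values = fitted, curve = fun),
            class = "peak_fit")
}

#' Fit the composite canopy-temperature peak curve
#'
#' Fits `y = y0 + A * (exp(-z^2 / (2 w)) + s(x) * B * exp(-0.5 k3 (|x - xc3| +
#' (x - xc3))))` with `z = x - xc1` and gate `s(x) = 1 - 0.5 (1 - tanh(k2 (x -
#' xc2)))` to a smoothed single-peak day of canopy temperature by multi-start
#' nonlinear least squares. The peak time is extracted as the argmax of the
#' fitted curve on a dense 1-min grid (the composite peak need not sit at
#' `xc1`); ties go to the earlier time.
#'
#' @param series a smoothed single-day [ts_series()].
#' @param literal_tan use the periodic `tan` gate instead of the bounded
#'   `tanh` switch (not recommended; kept for comparability with the printed
#'   form of the equation).
#' @param n_starts number of jittered multi-starts beyond the heuristic one.
#' @return An object of class `peak_fit` with fields `params`, `r2`,
#'   `peak_time` and methods `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `print`.
#' @seealso [fit_ecs()], [lag_peak_seeking()]
#' @export
fit_cce <- function(series, literal_tan = FALSE, n_starts = 12) {
  stopifnot(inherits(series, "ts_series"))
  t <- series$t; v <- series$v
  span <- diff(range(t))
  xc0 <- t[which.max(v)]
  base <- c(y0 = min(v), A = diff(range(v)), w = (span / 6)^2,
            B = 0.1, xc1 = xc0, xc2 = xc0, xc3 = xc0, k2 = 0.01, k3 = 0.01)
  # the composite surface is multi-modal; starts must explore gate locations
  # well before the peak and shoulder weights up to a few times the core
  starts <- c(list(base), with_seed(20240101L, lapply(seq_len(n_starts), function(i) {
    s <- base
    s[["xc1"]] <- s[["xc1"]] + stats::rnorm(1, 0, 80)
    s[["xc2"]] <- s[["xc2"]] + stats::rnorm(1, -200, 150)
    s[["xc3"]] <- s[["xc3"]] + stats::rnorm(1, -100, 200)
    s[["w"]] <- s[["w"]] * stats::runif(1, 0.2, 3)
    s[["A"]] <- s[["A"]] * stats::runif(1, 0.5, 1.5)
    s[["B"]] <- stats::runif(1, 0.05, 3)
    s[["k2"]] <- stats::runif(1, 0.001, 0.05)
    s[["k3"]] <- stats::runif(1, 0.001, 0.05)
    s
  })))
  lower <- c(y0 = -Inf, A = 0, w = 1e-4, B = 0, xc1 = -Inf, xc2 = -Inf,
             xc3 = -Inf, k2 = -Inf, k3 = 0)
  upper <- c(y0 = Inf, A = Inf, w = Inf, B = Inf, xc1 = Inf, xc2 = Inf,
             xc3 = Inf, k2 = Inf, k3 = Inf)
  fun <- function(x, p) cce_curve(x, p, literal_tan = literal_tan)
  best <- fit_peak_curve(t, v, fun, starts, lower, upper)
  make_peak_fit("CCE", best$par, t, v, fun)
}

#' Fit the Edgeworth-series air-temperature peak curve
#'
#' Fits `y = y0 + A / (w sqrt(2 pi)) exp(-0.5 z^2) (1 + (a3/6) He3(z) +
#' (a4/24) He4(z) + (10 a3^2 / 720) He6(z))` with `z = (x - xc) / w`, i.e. a
#' Gaussian core with Hermite-polynomial skewness/kurtosis corrections, to a
#' smoothed single-peak day of air temperature. Same return contract as
#' [fit_cce()]; with `a3 = a4 = 0` the fitted peak time equals `xc`.
#'
#' @inheritParams fit_cce
#' @return An object of class `peak_fit`.
#' @export
fit_ecs <- function(series, n_starts = 5) {
  stopifnot(inherits(series, "ts_series"))
  t <- series$t; v <- series$v
  span <- diff(range(t))
  xc0 <- t[which.max(v)]
  w0 <- span / 6
  base <- c(y0 = min(v), A = diff(range(v)) * w0 * sqrt(2 * pi),
            w = w0, xc = xc0, a3 = 0, a4 = 0)
  starts <- c(list(base), with_seed(20240102L, lapply(seq_len(n_starts), function(i) {
    s <- base
    s[["xc"]] <- s[["xc"]] + stats::rnorm(1, 0, 40)
    s[["w"]] <- s[["w"]] * stats::runif(1, 0.4, 2.5)
    s[["A"]] <- s[["A"]] * stats::runif(1, 0.5, 2)
    s[["a3"]] <- stats::rnorm(1, 0, 0.3)
    s[["a4"]] <- stats::rnorm(1, 0, 0.3)
    s
  })))
  lower <- c(y0 = -Inf, A = 0, w = 1, xc = -Inf, a3 = -Inf, a4 = -Inf)
  upper <- c(y0 = Inf, A = Inf, w = Inf, xc = Inf, a3 = Inf, a4 = Inf)
  best <- fit_peak_curve(t, v, ecs_curve, starts, lower, upper)
  make_peak_fit("ECS", best$par, t, v, ecs_curve)
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit: %s> R2 = %.4f, peak at %.0f min (%02d:%02d)\n",
              x$equation, x$r2, x$peak_time,
              floor(x$peak_time / 60) %% 24, round(x$peak_time %% 60)))
  cat("  coefficients:\n")
  print(round(x$params, 5))
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) object$params

#' @export
fitted.peak_fit <- function(object, ...) object$fitted.values

#' @export
residuals.peak_fit <- function(object, ...) object$v - object$fitted.values

#' @export
predict.peak_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$fitted.values)
  object$curve(newtimes, object$params)
}

#' @export
plot.peak_fit <- function(x, ...) {
  graphics::plot(x$t, x$v, pch = 16, cex = 0.3, col = "grey50",
                 xlab = "time (min from midnight)", ylab = "value",
                 main = sprintf("%s fit (R2 = %.3f)", x$equation, x$r2), ...)
  dense <- seq(min(x$t), max(x$t), by = 1)
  graphics::lines(dense, x$curve(dense, x$params), col = "firebrick", lwd = 2)
  graphics::abline(v = x$peak_time, lty = 2)
  invisible(x)
}

#' Peak-seeking lag between canopy and air temperature
#'
#' Fits the composite peak curve to the (smoothed) canopy temperature and the
#' Edgeworth-series curve to the (smoothed) air temperature over their common
#' day window, and reports the lag as the difference of the fitted peak
#' times. Positive lags mean the canopy peaks after the air.
#'
#' @param tc smoothed canopy-temperature [ts_series()].
#' @param ta smoothed air-temperature [ts_series()].
#' @param ... passed to [fit_cce()] / [fit_ecs()].
#' @return A [`lag_estimate`][estimate_lag] with `method = "peak_seeking"`
#'   and the two `peak_fit` objects attached as `fits`.
#' @export
lag_peak_seeking <- function(tc, ta, ...) {
  stopifnot(inherits(tc, "ts_series"), inherits(ta, "ts_series"))
  lo <- max(min(tc$t), min(ta$t))
  hi <- min(max(tc$t), max(ta$t))
  fit_tc <- fit_cce(ts_window(tc, lo, hi), ...)
  fit_ta <- fit_ecs(ts_window(ta, lo, hi))
  new_lag_estimate(tau = fit_tc$peak_time - fit_ta$peak_time,
                   score = min(fit_tc$r2, fit_ta$r2),
                   method = "peak_seeking", profile = NULL,
                   fits = list(tc = fit_tc, ta = fit_ta))
}
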