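# Profile-based lag estimators: lagged Pearson correlation, lagged mutual
# information, grey time-lag relational analysis.  All three scan a candidate
# grid tau = 0, step, 2*step, ..., max_lag, pair Tc(t) with Ta(t - tau) over
# the truncated overlap (no wraparound), score each candidate, and return the
# argmax; ties go to the smallest lag.

new_lag_estimate <- function(tau, score, method, profile = NULL, fits = NULL) {
  structure(list(tau = tau, score = score, method = method,
                 profile = profile, fits = fits),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> method = %s: tau = %g min (score = %.4f)\n",
              x$method, x$tau, x$score))
  if (!is.null(x$profile) && x$tau %in% range(x$profile$lag)[c(1, 2)])
    cat("  note: estimate sits on the candidate-grid boundary\n")
  invisible(x)
}

#' @export
plot.lag_estimate <- function(x, ...) {
  if (is.null(x$profile))
    stop("no profile attached (peak-seeking estimates carry fits instead)",
         call. = FALSE)
  graphics::plot(x$profile$lag, x$profile$score, type = "l",
                 xlab = "candidate lag (min)", ylab = "score",
                 main = sprintf("%s lag profile", x$method), ...)
  graphics::abline(v = x$tau, lty = 2, col = "firebrick")
  invisible(x)
}

candidate_lags <- function(tc, ta, max_lag, min_lag = 0) {
  step <- ts_step(tc)
  if (abs(ts_step(ta) - step) > 1e-8)
    stop("series must share one sampling step", call. = FALSE)
  if (max_lag < min_lag) stop("max_lag must be >= min_lag", call. = FALSE)
  seq(ceiling(min_lag / step) * step, floor(max_lag / step) * step, by = step)
}

check_overlap <- function(n, n_day) {
  if (n < 0.5 * n_day)
    stop("insufficient overlap: fewer than 50% of the day's samples remain ",
         "at a candidate lag; reduce max_lag or supply padded history",
         call. = FALSE)
}

#' Lag estimation by sliding Pearson correlation
#'
#' Computes the Pearson correlation between `Tc(t)` and `Ta(t - tau)` for
#' every candidate lag on the sampling grid and reports the lag maximising
#' it, together with that maximum. Pearson correlation is affine-invariant,
#' so raw or Z-scored inputs give identical profiles.
#'
#' @param tc canopy-temperature [ts_series()].
#' @param ta air-temperature [ts_series()] (may include pre-midnight padding;
#'   pairing is by timestamp with truncation, never wraparound).
#' @param max_lag largest candidate lag (min).
#' @param min_lag smallest candidate lag (min, default 0; negative values
#'   probe the canopy leading the air).
#' @return A `lag_estimate` with the full profile attached
#'   (`profile$lag`, `profile$score`, `profile$n_overlap`).
#' @examples
#' day <- generate_meteo_day(meteo_config(), seed = 1)
#' tc <- generate_canopy_temperature(day, 44, stress_scenario("T1", 0),
#'                                   noise_sd = 0, seed = 1)
#' lag_cross_correlation(tc, day$Ta, max_lag = 120)$tau
#' @export
lag_cross_correlation <- function(tc, ta, max_lag = 180, min_lag = 0) {
  stopifnot(inherits(tc, "ts_series"), inherits(ta, "ts_series"))
  lags <- candidate_lags(tc, ta, max_lag, min_lag)
  n_day <- length(tc$v)
  score <- n_overlap <- numeric(length(lags))
  for (i in seq_along(lags)) {
    p <- pair_at_lag(tc, ta, lags[i])
    check_overlap(p$n, n_day)
    if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0)
      stop("degenerate series: zero variance in an overlap window", call. = FALSE)
    score[i] <- stats::cor(p$x, p$y)
    n_overlap[i] <- p$n
  }
  best <- which.max(score)
  new_lag_estimate(lags[best], score[best], "cross_correlation",
                   data.frame(lag = lags, score = score, n_overlap = n_overlap))
}

#' Plug-in mutual information between two equal-length samples
#'
#' Histogram (plug-in) estimate of `I(X; Y) = sum p(x, y) log(p(x, y) /
#' (p(x) p(y)))` in nats, on equal-width bins spanning each variable's own
#' observed range (`0 log 0 = 0`). Binning on each variable's own range makes
#' the estimate invariant to affine rescaling of either input.
#'
#' @param x,y numeric vectors (or [ts_series()]) of equal length, at least 50
#'   samples.
#' @param bins number of bins per axis (`>= 2`); default is the Sturges rule
#'   `ceiling(log2(n)) + 1`.
#' @return Mutual information in nats (non-negative).
#' @examples
#' set.seed(1); x <- rnorm(500)
#' mutual_information(x, x) # = entropy of the binned marginal
#' @export
mutual_information <- function(x, y, bins = NULL) {
  if (inherits(x, "ts_series")) x <- x$v
  if (inherits(y, "ts_series")) y <- y$v
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 50)
    stop("mutual information needs at least 50 samples", call. = FALSE)
  if (is.null(bins)) bins <- ceiling(log2(n)) + 1
  if (bins < 2) stop("bins must be at least 2", call. = FALSE)
  bx <- bin_index(x, bins)
  by <- bin_index(y, bins)
  joint <- table(factor(bx, levels = 1:bins), factor(by, levels = 1:bins)) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

bin_index <- function(v, bins) {
  r <- range(v)
  if (r[2] <= r[1]) return(rep(1L, length(v)))
  i <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(i, bins)
}

#' Lag estimation by sliding mutual information
#'
#' Scores each candidate lag by the mutual information between `Tc(t)` and
#' `Ta(t - tau)` over the truncated overlap and returns the lag at the MI
#' peak. Because MI is invariant to monotone transforms (up to binning), this
#' captures nonlinear as well as linear coupling.
#'
#' @inheritParams lag_cross_correlation
#' @param bins bins per axis; default Sturges on each overlap.
#' @return A `lag_estimate` with profile.
#' @export
lag_mutual_information <- function(tc, ta, max_lag = 180, min_lag = 0,
                                   bins = NULL) {
  stopifnot(inherits(tc, "ts_series"), inherits(ta, "ts_series"))
  lags <- candidate_lags(tc, ta, max_lag, min_lag)
  n_day <- length(tc$v)
  score <- n_overlap <- numeric(length(lags))
  for (i in seq_along(lags)) {
    p <- pair_at_lag(tc, ta, lags[i])
    check_overlap(p$n, n_day)
    score[i] <- mutual_information(p$x, p$y, bins)
    n_overlap[i] <- p$n
  }
  best <- which.max(score)
  new_lag_estimate(lags[best], score[best], "mutual_information",
                   data.frame(lag = lags, score = score, n_overlap = n_overlap))
}

#' Grey relational grade between two aligned sequences
#'
#' Pointwise grey relational coefficients `zeta(k) = (D_min + rho * D_max) /
#' (D(k) + rho * D_max)` with `D(k) = |x(k) - y(k)|`, averaged into the grade
#' `gamma = mean(zeta)`. `D_min`/`D_max` default to the extremes of this pair
#' but can be supplied externally — the lag-profile scan passes the global
#' extremes over all candidate shifts and positions, as the double min/max in
#' the definition requires. If `D_max = 0` the sequences coincide and every
#' coefficient is 1.
#'
#' @param x,y numeric vectors of equal length (dimensionless; Z-score first).
#' @param rho resolution factor, default 0.5.
#' @param delta_min,delta_max global extremes of `|x - y|`; `NULL` = use this
#'   pair's own.
#' @return A list with `grade` and the coefficient vector `zeta`.
#' @examples
#' gray_relational_grade(c(0, 1, 2), c(0, 1, 3))$grade # 7/9
#' @export
gray_relational_grade <- function(x, y, rho = 0.5,
                                  delta_min = NULL, delta_max = NULL) {
  if (inherits(x, "ts_series")) x <- x$v
  if (inherits(y, "ts_series")) y <- y$v
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  d <- abs(x - y)
  if (is.null(delta_min)) delta_min <- min(d)
  if (is.null(delta_max)) delta_max <- max(d)
  if (delta_max == 0) {
    zeta <- rep(1, length(d))
  } else {
    zeta <- (delta_min + rho * delta_max) / (d + rho * delta_max)
  }
  list(grade = mean(zeta), zeta = zeta)
}

#' Lag estimation by grey time-lag relational analysis
#'
#' Scores each candidate lag by the grey relational grade between `Tc(t)`
#' and `Ta(t - tau)`, with the distance extremes `D_min`/`D_max` taken
#' jointly over all candidate lags and positions. Grey relational grades are
#' not scale-invariant, so each overlapping segment pair is standardized
#' (mean 0, population SD 1) before the pointwise distances are taken; an
#' exact delayed copy then attains grade 1 at the true shift regardless of
#' how much padding either series carries. The lag with the highest grade is
#' returned.
#'
#' @inheritParams lag_cross_correlation
#' @param rho resolution factor, default 0.5.
#' @return A `lag_estimate` with profile (scores in `(0, 1]`).
#' @export
lag_gray_relational <- function(tc, ta, max_lag = 180, min_lag = 0, rho = 0.5) {
  stopifnot(inherits(tc, "ts_series"), inherits(ta, "ts_series"))
  lags <- candidate_lags(tc, ta, max_lag, min_lag)
  n_day <- length(tc$v)
  std <- function(v) {
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    if (s == 0)
      stop("degenerate series: zero variance in an overlap window", call. = FALSE)
    (v - m) / s
  }
  pairs <- vector("list", length(lags))
  for (i in seq_along(lags)) {
    p <- pair_at_lag(tc, ta, lags[i])
    check_overlap(p$n, n_day)
    pairs[[i]] <- abs(std(p$x) - std(p$y))
  }
  dmin <- min(vapply(pairs, min, 0))
  dmax <- max(vapply(pairs, max, 0))
  score <- vapply(seq_along(lags), function(i) {
    d <- pairs[[i]]
    if (dmax == 0) 1 else mean((dmin + rho * dmax) / (d + rho * dmax))
  }, 0)
  best <- which.max(score)
  new_lag_estimate(lags[best], score[best], "gray_relational",
                   data.frame(lag = lags, score = score,
                              n_overlap = lengths(pairs)))
}

#' Estimate the canopy-air temperature lag by one of four methods
#'
#' Convenience front end applying the standard preprocessing (Savitzky-Golay
#' smoothing, then Z-scoring for the profile methods) before dispatching to
#' the requested estimator. Positive lags mean the canopy temperature lags
#' behind the air temperature.
#'
#' @param tc,ta canopy / air temperature [ts_series()].
#' @param method one of `"cross_correlation"`, `"mutual_information"`,
#'   `"gray_relational"`, `"peak_seeking"`.
#' @param max_lag candidate-grid upper bound (min).
#' @param smooth apply [savgol_smooth()] first (default `TRUE`).
#' @param window,polyorder smoothing parameters.
#' @param ... passed to the method-specific estimator.
#' @return A `lag_estimate`.
#' @examples
#' day <- generate_meteo_day(meteo_config(), seed = 2)
#' tc <- generate_canopy_temperature(day, 60, stress_scenario("T2", 0.3),
#'                                   noise_sd = 0.3, seed = 2)
#' estimate_lag(tc, day$Ta, "cross_correlation")$tau
#' @export
estimate_lag <- function(tc, ta,
                         method = c("cross_correlation", "mutual_information",
                                    "gray_relational", "peak_seeking"),
                         max_lag = 180, smooth = TRUE,
                         window = 31, polyorder = 3, ...) {
  method <- match.arg(method)
  if (smooth) {
    tc <- savgol_smooth(tc, window, polyorder)
    ta <- savgol_smooth(ta, window, polyorder)
  }
  switch(method,
    cross_correlation = lag_cross_correlation(zscore(tc), zscore(ta),
                                              max_lag = max_lag, ...),
    mutual_information = lag_mutual_information(zscore(tc), zscore(ta),
                                                max_lag = max_lag, ...),
    gray_relational = lag_gray_relational(tc, ta, max_lag = max_lag, ...),
    peak_seeking = lag_peak_seeking(tc, ta, ...))
}
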