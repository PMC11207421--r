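#' Uniformly sampled time series
#'
#' Light container for a scalar diurnal signal on a uniform minute grid:
#' canopy temperature, air temperature, relative humidity, radiation, soil
#' heat flux or wind speed. Time is minutes from midnight; negative times are
#' the pre-midnight padding that shifted lookups `v(t - tau)` need.
#'
#' @param t numeric vector of timestamps (minutes), strictly increasing with
#'   a constant step.
#' @param v numeric vector of values, same length as `t`, no missing values.
#' @param unit character unit tag (e.g. `"degC"`, `"%"`, `"W/m2"`, `""`).
#' @return An object of class `ts_series` with fields `t`, `v`, `unit`.
#' @examples
#' x <- ts_series(seq(0, 100, by = 2), sin(seq(0, 100, by = 2) / 20), "degC")
#' ts_step(x)
#' @export
ts_series <- function(t, v, unit = "") {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v))
    stop("`t` and `v` must have the same length", call. = FALSE)
  if (length(t) < 2L)
    stop("a time series needs at least 2 samples", call. = FALSE)
  if (anyNA(t) || anyNA(v))
    stop("missing values are not allowed in a ts_series", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  step <- dt[1L]
  if (any(abs(dt - step) > 1e-8 * max(1, step)))
    stop("timestamps must lie on a uniform grid", call. = FALSE)
  structure(list(t = t, v = v, unit = as.character(unit)[1L]),
            class = "ts_series")
}

#' @export
print.ts_series <- function(x, ...) {
  cat(sprintf("<ts_series> n = %d, step = %g min, t in [%g, %g]%s\n",
              length(x$t), ts_step(x), x$t[1L], x$t[length(x$t)],
              if (nzchar(x$unit)) paste0(", unit = ", x$unit) else ""))
  cat(sprintf("  values: [%.4g, %.4g]\n", min(x$v), max(x$v)))
  invisible(x)
}

#' @export
length.ts_series <- function(x) length(x$t)

#' @export
as.data.frame.ts_series <- function(x, ...) {
  data.frame(time_min = x$t, value = x$v)
}

#' Sampling step of a time series
#' @param x a [ts_series()].
#' @return The grid step in minutes.
#' @export
ts_step <- function(x) {
  stopifnot(inherits(x, "ts_series"))
  x$t[2L] - x$t[1L]
}

#' Restrict a time series to a time window
#' @param x a [ts_series()].
#' @param from,to window bounds in minutes (inclusive).
#' @return A [ts_series()] on the sub-grid.
#' @export
ts_window <- function(x, from = -Inf, to = Inf) {
  keep <- x$t >= from & x$t <= to
  if (sum(keep) < 2L) stop("window retains fewer than 2 samples", call. = FALSE)
  ts_series(x$t[keep], x$v[keep], x$unit)
}

# Pair x(t) with y(t - tau) over the overlapping support (truncation, no
# wraparound).  Both series must share one step; tau must be a grid multiple.
pair_at_lag <- function(x, y, tau) {
  step <- ts_step(x)
  if (abs(ts_step(y) - step) > 1e-8)
    stop("series must share one sampling step", call. = FALSE)
  k <- tau / step
  if (abs(k - round(k)) > 1e-8)
    stop("lag must be a multiple of the sampling step", call. = FALSE)
  j <- round((x$t - tau - y$t[1L]) / step) + 1L
  ok <- j >= 1L & j <= length(y$t)
  list(x = x$v[ok], y = y$v[j[ok]], t = x$t[ok], n = sum(ok))
}

# Evaluate code with a temporary RNG seed, restoring global state after.
# seed = NULL means "use the current stream" (caller manages seeding).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
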