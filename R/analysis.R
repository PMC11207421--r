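# Before/after comparison: does lag-correcting the CWSI strengthen its
# relation with midday leaf gas exchange (Pn, Tr, gs)?

#' Coefficient of determination of a simple linear regression
#'
#' @param x predictor (here: CWSI values), variance > 0, n >= 3.
#' @param y response (here: a photosynthetic parameter).
#' @return A list with `r2`, `slope` and `n`.
#' @export
r_squared_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must match in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate predictor: zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(r2 = r2, slope = unname(stats::coef(fit)[2]), n = length(x))
}

#' Estimate per-treatment lags across a campaign
#'
#' Runs one or more lag estimators per (scenario x day) and aggregates each
#' scenario's estimate as the across-day median, snapped to the sampling
#' grid. The heavier peak-seeking fits may be restricted to the first few
#' days.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param methods character vector of estimator names (see [estimate_lag()]).
#' @param days day indices to use (default: all; peak-seeking defaults to
#'   the first day only via `peak_days`).
#' @param peak_days day indices for the peak-seeking method.
#' @param max_lag candidate-grid bound (min).
#' @param ... passed to [estimate_lag()].
#' @return Named list: scenario label -> named numeric vector of lags (min)
#'   per method.
#' @export
estimate_campaign_lags <- function(campaign,
                                   methods = c("cross_correlation",
                                               "mutual_information",
                                               "gray_relational"),
                                   days = NULL, peak_days = 1,
                                   max_lag = 180, ...) {
  stopifnot(inherits(campaign, "cwsi_campaign"))
  if (is.null(days)) days <- seq_along(campaign$days)
  step <- campaign$config$step
  out <- lapply(names(campaign$scenarios), function(sc) {
    est <- vapply(methods, function(m) {
      use <- if (m == "peak_seeking") peak_days else days
      taus <- vapply(use, function(d)
        estimate_lag(campaign$tc[[d]][[sc]], campaign$days[[d]]$Ta,
                     method = m, max_lag = max_lag, ...)$tau, 0)
      round(stats::median(taus) / step) * step
    }, 0)
    names(est) <- methods
    est
  })
  names(out) <- names(campaign$scenarios)
  out
}

# CWSI (raw) at each (day x scenario) observation time for one model under
# one per-scenario lag assignment.  Returns a data frame aligned with
# campaign$photos rows (NA where no grid sample falls within 2 min).
campaign_cwsi_at_obs <- function(campaign, taus, model,
                                 params = theoretical_params(),
                                 stage = "regreening-jointing",
                                 baseline_window = c(780, 900)) {
  scen <- names(campaign$scenarios)
  baseline <- NULL
  if (model == "empirical") {
    # NWSB is by definition the non-water-stressed baseline: fit it on the
    # least-stressed scenario, pooled over days, under the same pairing
    # (lag) as the variant being evaluated.
    stress <- vapply(campaign$scenarios, `[[`, 0, "stress")
    ref <- scen[which.min(stress)]
    pooled <- do.call(rbind, lapply(seq_along(campaign$days), function(d)
      apply_time_lag(campaign$tc[[d]][[ref]], campaign$days[[d]],
                     taus[[ref]])))
    baseline <- fit_nwsb(pooled$Tc - pooled$Ta, vpd(pooled$Ta, pooled$RH),
                         time = pooled$time, window = baseline_window)
  }
  rows <- lapply(seq_len(nrow(campaign$photos)), function(i) {
    ph <- campaign$photos[i, ]
    d <- ph$day; sc <- ph$scenario
    pairs <- apply_time_lag(campaign$tc[[d]][[sc]], campaign$days[[d]],
                            taus[[sc]])
    j <- which.min(abs(pairs$time - ph$obs_time))
    if (abs(pairs$time[j] - ph$obs_time) > 2) return(NA_real_)
    p <- pairs[j, ]
    if (model == "empirical") {
      cwsi_empirical(p$Tc, p$Ta, p$RH, baseline)$cwsi_raw
    } else {
      cwsi_theoretical(p$Tc, p$Ta, p$RH, p$Rn, p$G, p$u,
                       params = params, stage = stage)$cwsi_raw
    }
  })
  cbind(campaign$photos, cwsi = unlist(rows))
}

#' Correlation of CWSI with photosynthetic parameters, before and after
#' lag correction
#'
#' For every (model x lag method x parameter) cell: computes the CWSI at
#' each midday observation across all scenarios and days — uncorrected
#' (`lag_method = "none"`) or with each scenario's estimated lag applied —
#' and regresses the photosynthetic parameter on the CWSI. For the empirical
#' model the non-water-stressed baseline is refitted under each variant's
#' pairing on the least-stressed treatment.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param lag_estimates per-scenario named lag vectors, as produced by
#'   [estimate_campaign_lags()].
#' @param models which CWSI models to evaluate.
#' @param params,stage theoretical-model settings.
#' @param baseline_window empirical baseline fit window (min).
#' @return A long data frame of class `cwsi_correlation_table` with columns
#'   `model`, `lag_method`, `parameter`, `r2`, `slope_sign`, `n`, plus an
#'   attribute `delta` holding corrected-minus-uncorrected R2 per cell.
#' @examples
#' \donttest{
#' camp <- simulate_campaign(n_days = 4, true_lag = c(T1 = 60, T2 = 60,
#'   T3 = 60, T4 = 60), seed = 3)
#' lags <- estimate_campaign_lags(camp, "cross_correlation", days = 1)
#' before_after_comparison(camp, lags, models = "empirical")
#' }
#' @export
before_after_comparison <- function(campaign, lag_estimates,
                                    models = c("empirical", "theoretical"),
                                    params = theoretical_params(),
                                    stage = "regreening-jointing",
                                    baseline_window = c(780, 900)) {
  stopifnot(inherits(campaign, "cwsi_campaign"))
  models <- match.arg(models, several.ok = TRUE)
  scen <- names(campaign$scenarios)
  methods <- names(lag_estimates[[scen[1]]])
  pars <- c("Pn", "Tr", "gs")
  rows <- list()
  for (model in models) {
    for (m in c("none", methods)) {
      taus <- if (m == "none") {
        stats::setNames(rep(0, length(scen)), scen)
      } else {
        stats::setNames(vapply(scen, function(s) lag_estimates[[s]][[m]], 0),
                        scen)
      }
      obs <- campaign_cwsi_at_obs(campaign, as.list(taus), model,
                                  params = params, stage = stage,
                                  baseline_window = baseline_window)
      ok <- !is.na(obs$cwsi)
      if (sum(ok) < 3) {
        warning(sprintf("cell skipped (model %s, method %s): <3 usable obs",
                        model, m))
        next
      }
      for (p in pars) {
        r <- r_squared_linear(obs$cwsi[ok], obs[[p]][ok])
        rows[[length(rows) + 1L]] <-
          data.frame(model = model, lag_method = m, parameter = p,
                     r2 = r$r2, slope_sign = sign(r$slope), n = r$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  base <- out[out$lag_method == "none", c("model", "parameter", "r2")]
  names(base)[3] <- "r2_uncorrected"
  delta <- merge(out[out$lag_method != "none", ], base,
                 by = c("model", "parameter"), sort = FALSE)
  delta$delta_r2 <- delta$r2 - delta$r2_uncorrected
  attr(out, "delta") <- delta[, c("model", "lag_method", "parameter",
                                  "r2", "r2_uncorrected", "delta_r2")]
  class(out) <- c("cwsi_correlation_table", "data.frame")
  out
}

#' @export
print.cwsi_correlation_table <- function(x, ...) {
  cat("CWSI vs photosynthetic parameters (R2 per model x lag method):\n")
  for (model in unique(x$model)) {
    sub <- x[x$model == model, ]
    wide <- stats::reshape(sub[, c("lag_method", "parameter", "r2")],
                           idvar = "lag_method", timevar = "parameter",
                           direction = "wide")
    names(wide) <- sub("^r2\\.", "", names(wide))
    cat(sprintf("\n  %s model:\n", model))
    print(format(wide, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Heat map of a CWSI correlation table
#'
#' @param x a `cwsi_correlation_table`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cwsi_correlation_table <- function(x, ...) {
  cells <- unique(x[, c("model", "lag_method")])
  labs <- paste(cells$model, cells$lag_method, sep = ":")
  pars <- unique(x$parameter)
  z <- matrix(NA_real_, nrow(cells), length(pars),
              dimnames = list(labs, pars))
  for (i in seq_len(nrow(x)))
    z[paste(x$model[i], x$lag_method[i], sep = ":"), x$parameter[i]] <- x$r2[i]
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(pars), seq_len(nrow(z)), t(z),
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "CWSI vs gas exchange: R2", ...)
  graphics::axis(1, seq_along(pars), pars)
  graphics::axis(2, seq_len(nrow(z)), rownames(z), las = 2, cex.axis = 0.7)
  for (i in seq_along(pars)) for (j in seq_len(nrow(z)))
    graphics::text(i, j, sprintf("%.2f", z[j, i]), cex = 0.7)
  invisible(x)
}
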