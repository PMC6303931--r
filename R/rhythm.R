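# --- rhythm quantification: LOWESS, fixed-24-h sinusoid, AUC, strength, Vmax

check_ts <- function(data, min_points = 2) {
  stopifnot(all(c("time_hct", "value") %in% names(data)))
  if (nrow(data) < min_points) {
    abort(sprintf("need at least %d points.", min_points),
          class = "chronocope_insufficient_data")
  }
  if (is.unsorted(data$time_hct, strictly = TRUE)) {
    abort("`time_hct` must be strictly increasing.",
          class = "chronocope_input_error")
  }
  invisible(data)
}

#' LOWESS-smooth a time series
#'
#' Locally weighted linear regression with tricube weights and no robustness
#' iterations, evaluated at the input times. The span is
#' `min(1, window_points / n)`, i.e. each local fit uses the
#' `window_points` nearest neighbours (the classic "5-point window").
#'
#' @param data Tibble with columns `time_hct` (strictly increasing) and
#'   `value`.
#' @param window_points Number of points in the local window (>= 3).
#' @return The input tibble with `value` replaced by the smoothed values.
#' @examples
#' ts <- tibble::tibble(time_hct = c(1, 7, 13, 15, 19, 23),
#'                      value = c(10, 14, 10, 8, 6, 8))
#' lowess_smooth(ts)
#' @export
lowess_smooth <- function(data, window_points = 5) {
  check_ts(data, min_points = 3)
  if (window_points < 3) {
    abort("`window_points` must be >= 3.",
          class = "chronocope_config_error")
  }
  n <- nrow(data)
  f <- min(1, window_points / n)
  sm <- lowess(data$time_hct, data$value, f = f, iter = 0, delta = 0)
  out <- data
  out$value <- sm$y
  as_tibble(out)
}

#' Fit a fixed-period 24-hour sinusoid
#'
#' Ordinary least squares on the harmonic basis
#' \{1, cos(2 pi t / 24), sin(2 pi t / 24)\} -- the single-component cosinor
#' model with the period fixed at 24 h. The fit is closed-form; no iterative
#' optimiser is involved. Times are used as given (hCT hours, possibly
#' spanning several days); the basis is itself 24-h periodic.
#'
#' Conventions: `mesor` is the intercept; `amplitude = sqrt(a^2 + b^2) >= 0`;
#' `acrophase` is the clock time of the fitted peak in `[0, 24)`; a
#' zero-variance (constant) input yields `amplitude = 0` and
#' `r_squared = 0`.
#'
#' @param data Tibble with columns `time_hct` and `value`; at least 4 points
#'   and at least 3 distinct times modulo 24.
#' @return Object of class `sine_fit` with elements `mesor`, `amplitude`,
#'   `acrophase`, `r_squared`, `n`, `coefficients` and `data`. Supports
#'   [tidy()], [glance()], [predict()][predict.sine_fit] and
#'   [autoplot()][autoplot.sine_fit].
#' @examples
#' ts <- tibble::tibble(time_hct = c(1, 7, 13, 15, 19, 23),
#'                      value = c(10, 14, 10, 8, 6, 8))
#' fit_sine24(ts)
#' @export
fit_sine24 <- function(data) {
  check_ts(data, min_points = 4)
  t <- data$time_hct
  v <- data$value
  if (length(unique(round(t %% 24, 9))) < 3) {
    abort("degenerate design: need >= 3 distinct times modulo 24.",
          class = "chronocope_singular_design")
  }
  w <- 2 * pi / 24
  X <- cbind(`(Intercept)` = 1, cos24 = cos(w * t), sin24 = sin(w * t))
  fit <- lm.fit(X, v)
  cf <- coef(fit)
  mesor <- unname(cf[1])
  a <- unname(cf[2])
  b <- unname(cf[3])
  amplitude <- sqrt(a^2 + b^2)
  # v = M + A cos(w (t - phi)) with w phi = atan2(b, a)
  acrophase <- (atan2(b, a) / w) %% 24
  if (amplitude == 0) acrophase <- 0
  tss <- sum((v - mean(v))^2)
  rss <- sum(fit$residuals^2)
  r_squared <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0
  structure(list(mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase, r_squared = r_squared,
                 n = length(v), coefficients = c(mesor = mesor, a = a, b = b),
                 data = as_tibble(data)),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "<sine_fit> 24-h cosinor: mesor %.4g, amplitude %.4g, acrophase %.4g hCT, R^2 %.3f (n = %d)\n",
    x$mesor, x$amplitude, x$acrophase, x$r_squared, x$n))
  invisible(x)
}

#' Predict from a fitted 24-hour sinusoid
#'
#' @param object A `sine_fit`.
#' @param newdata Optional tibble with a `time_hct` column; defaults to the
#'   fitted times.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.sine_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_hct else newdata$time_hct
  w <- 2 * pi / 24
  cf <- object$coefficients
  unname(cf["mesor"] + cf["a"] * cos(w * t) + cf["b"] * sin(w * t))
}

#' @method tidy sine_fit
#' @export
tidy.sine_fit <- function(x, ...) {
  tibble(term = c("mesor", "amplitude", "acrophase"),
         estimate = c(x$mesor, x$amplitude, x$acrophase))
}

#' @method glance sine_fit
#' @export
glance.sine_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n)
}

#' Area under the smoothed time course
#'
#' Trapezoidal integral of the LOWESS-smoothed curve over the observation
#' window `[t_first, t_last]` (value x hours). Used as the proxy for net
#' transcriptional, secretory or locomotor output. The integral is taken on
#' the smoothed curve rather than on the fitted sinusoid, whose full-period
#' integral would collapse to `24 * mesor` and discard the curve's shape.
#'
#' @inheritParams lowess_smooth
#' @param smooth Apply LOWESS smoothing first (skipped automatically for
#'   series of fewer than 3 points, where the local line reproduces the
#'   data).
#' @return The integral, a single number.
#' @examples
#' compute_auc(tibble::tibble(time_hct = c(0, 24), value = c(5, 5)))
#' @export
compute_auc <- function(data, window_points = 5, smooth = TRUE) {
  check_ts(data, min_points = 2)
  v <- if (smooth && nrow(data) >= 3) {
    lowess_smooth(data, window_points)$value
  } else data$value
  t <- data$time_hct
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Rhythm strength of the 24-hour component
#'
#' Fraction of variance explained (R-squared) by the fixed-24-h harmonic
#' regression on the raw series: a dimensionless measure in `[0, 1]` of how
#' much of the signal's variance is carried by its 24-h component. It is
#' invariant under affine rescaling of the values, so it compares fairly
#' across individuals with different overall activity levels.
#'
#' @param data Tibble with `time_hct` and `value`; at least 8 points
#'   spanning at least 48 h, with non-zero variance.
#' @return Rhythm strength in `[0, 1]`.
#' @examples
#' t <- seq(0, 71.5, by = 0.5)
#' rhythm_strength_24h(tibble::tibble(time_hct = t,
#'                                    value = cos(2 * pi * t / 24)))
#' @export
rhythm_strength_24h <- function(data) {
  check_ts(data, min_points = 8)
  if (diff(range(data$time_hct)) < 48 - 1e-9) {
    abort("series must span at least 48 h.",
          class = "chronocope_insufficient_data")
  }
  if (var(data$value) == 0) {
    abort("rhythm strength undefined for a zero-variance series.",
          class = "chronocope_undefined_strength")
  }
  fit_sine24(data)$r_squared
}

#' Maximum velocity over the first days of recording
#'
#' Mean of the per-24-h-window maxima over the first `n_days` windows,
#' counted from the first observation. Used on light-dark days as a proxy
#' for absolute locomotor capacity.
#'
#' @inheritParams lowess_smooth
#' @param n_days Number of 24-h windows to average (default 3).
#' @return The mean daily maximum.
#' @examples
#' t <- seq(0, 71, by = 1)
#' vmax(tibble::tibble(time_hct = t, value = rep(7, length(t))))
#' @export
vmax <- function(data, n_days = 3) {
  check_ts(data, min_points = 2)
  t0 <- data$time_hct[1]
  win <- floor((data$time_hct - t0) / 24) + 1
  if (sum(tabulate(win[win <= n_days]) > 0) < n_days) {
    abort(sprintf("series must cover %d full 24-h windows.", n_days),
          class = "chronocope_insufficient_data")
  }
  keep <- win <= n_days
  daily_max <- tapply(data$value[keep], win[keep], max)
  mean(daily_max)
}

#' Per-individual rhythm metrics for a tidy series table
#'
#' Applies the full quantification chain -- LOWESS smoothing, fixed-24-h
#' sinusoid fit, AUC, rhythm strength and (for multi-day series) Vmax -- to
#' every `(individual_id, channel, regime)` series in a tidy table.
#' Rhythm strength requires at least 8 points spanning 48 h and Vmax a
#' 3-day span; both are `NA` where the series is too short (the 6-timepoint
#' gene and hormone designs).
#'
#' @param data Tidy tibble with columns `individual_id`, `channel`,
#'   `regime`, `time_hct`, `value`.
#' @param window_points LOWESS window passed to [lowess_smooth()].
#' @param vmax_days Windows averaged by [vmax()].
#' @return Tibble with one row per series: `individual_id`, `channel`,
#'   `regime`, `n`, `mesor`, `amplitude`, `acrophase`, `auc`,
#'   `rhythm_strength`, `vmax`.
#' @examples
#' cfg <- cohort_config(n_groups = 1, group_size = 2, seed = 1)
#' co <- generate_cohort(cfg)
#' rhythm_metrics(simulate_channel_timeseries(co, cfg, "cortisol"))
#' @export
rhythm_metrics <- function(data, window_points = 5, vmax_days = 3) {
  stopifnot(all(c("individual_id", "channel", "regime", "time_hct",
                  "value") %in% names(data)))
  data |>
    dplyr::group_by(.data$individual_id, .data$channel, .data$regime) |>
    dplyr::arrange(.data$time_hct, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_sine24(d)
      span <- diff(range(d$time_hct))
      rs <- if (nrow(d) >= 8 && span >= 48 - 1e-9 && var(d$value) > 0) {
        fit$r_squared
      } else NA_real_
      vm <- if (span >= vmax_days * 24 - 1) {
        tryCatch(vmax(d, n_days = vmax_days), error = function(e) NA_real_)
      } else NA_real_
      tibble(n = nrow(d), mesor = fit$mesor, amplitude = fit$amplitude,
             acrophase = fit$acrophase,
             auc = compute_auc(d, window_points),
             rhythm_strength = rs, vmax = vm)
    }) |>
    dplyr::ungroup()
}
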