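# --- diagnostic figures (ggplot2)

#' @describeIn fit_sine24 Plot the observations, LOWESS curve and fitted
#'   sinusoid.
#' @param object A `sine_fit`.
#' @param ... Unused.
#' @method autoplot sine_fit
#' @export
autoplot.sine_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time_hct = seq(min(d$time_hct), max(d$time_hct),
                                length.out = 200))
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_hct, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "#2166ac") +
    ggplot2::labs(x = "time (hCT)", y = "value",
                  subtitle = sprintf(
                    "mesor %.3g, amplitude %.3g, acrophase %.3g hCT, R² %.2f",
                    object$mesor, object$amplitude, object$acrophase,
                    object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Actogram-style activity plot
#'
#' Day-by-day line plot of a binned activity trace for one or a few fish,
#' with the constant-light segment shaded.
#'
#' @param activity Tibble from [simulate_activity()].
#' @param ids Fish to show (default: first two).
#' @return A ggplot object.
#' @export
plot_actogram <- function(activity, ids = NULL) {
  if (is.null(ids)) ids <- head(unique(activity$individual_id), 2)
  d <- activity[activity$individual_id %in% ids, ]
  d$day <- floor((d$time_hct - min(d$time_hct)) / 24) + 1
  d$tod <- (d$time_hct - min(d$time_hct)) %% 24
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tod, y = .data$value,
                                  colour = .data$individual_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(day ~ regime) +
    ggplot2::labs(x = "hours into recording day",
                  y = "V (mm s⁻¹)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_full_study Dot plot of the rank-correlation battery.
#' @param object A `chrono_study`.
#' @param ... Unused.
#' @method autoplot chrono_study
#' @export
autoplot.chrono_study <- function(object, ...) {
  d <- object$correlations
  d$sig <- d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho,
                                  y = paste(.data$channel, .data$metric),
                                  shape = .data$sig,
                                  colour = .data$regime)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "p < 0.05") +
    ggplot2::labs(x = "Spearman ρ (vs emergence rank)", y = NULL) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Metric versus emergence rank scatter
#'
#' @param metrics Tibble from [rhythm_metrics()] joined with a `rank`
#'   column, or a `chrono_study`.
#' @param channel,metric Which channel and metric to display.
#' @return A ggplot object.
#' @export
plot_rank_metric <- function(metrics, channel, metric = "amplitude") {
  if (inherits(metrics, "chrono_study")) {
    metrics <- dplyr::inner_join(metrics$metrics,
                                 metrics$ranks[c("individual_id", "rank")],
                                 by = "individual_id")
  }
  d <- metrics[metrics$channel == channel, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b", linewidth = 0.5) +
    ggplot2::facet_wrap(~regime, scales = "free_y") +
    ggplot2::labs(x = "emergence rank (1 = EE)", y = metric,
                  title = channel) +
    ggplot2::theme_minimal()
}
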