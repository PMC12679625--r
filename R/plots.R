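#' Diagnostic plots
#'
#' `autoplot()` methods for the pipeline's intermediate and result objects,
#' plus a cohort-level metric plot in the violin-and-box style conventional
#' for group comparisons of stability metrics.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gaitlf-plots
NULL

#' @rdname gaitlf-plots
#' @export
autoplot.scalar_traj <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "M/L displacement (m)",
                  title = sprintf("stage: %s", signal_stage(object)))
  b <- trial_boundaries(object)
  if (length(b) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$time[b],
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' @rdname gaitlf-plots
#' @export
autoplot.phase_traj <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y, y = .data$ydot)) +
    ggplot2::geom_path(linewidth = 0.2, alpha = 0.7) +
    ggplot2::labs(x = "Y (m)", y = "dY/dt (m/s)",
                  title = "phase-space trajectory")
}

#' @rdname gaitlf-plots
#' @export
autoplot.gait_monodromy <- function(object, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  circle <- tibble(x = cos(th), y = sin(th))
  ev <- tidy(object)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circle, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey60") +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(x = .data$multiplier_re,
                                     y = .data$multiplier_im),
                        size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re(FM)", y = "Im(FM)",
                  title = "Floquet multipliers vs the unit circle")
}

#' @rdname gaitlf-plots
#' @export
autoplot.gait_rosenstein <- function(object, ...) {
  curve <- object$curve
  win <- object$fit_window
  fit_pts <- curve[curve$time <= win[2], ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time,
                                      y = .data$mean_log_divergence)) +
    ggplot2::annotate("rect", xmin = win[1], xmax = win[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(data = fit_pts, method = "lm", formula = y ~ x,
                         se = FALSE, colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = "time (s)", y = "<ln divergence>",
                  title = sprintf("Rosenstein divergence curve (slope %.3f 1/s)",
                                  object$max_le_s))
}

#' @rdname gaitlf-plots
#' @param table A cohort metrics table with a `group` column.
#' @param metric Metric column to display.
#' @export
plot_cohort_metric <- function(table, metric = "mean_FM") {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$group,
                                      y = .data[[metric]],
                                      fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, alpha = 0.8) +
    ggplot2::geom_jitter(width = 0.05, size = 0.8, alpha = 0.6) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = metric)
}
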