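#' Plot a lesion error curve
#'
#' Mean absolute heading error against deactivation probability, with
#' normal-approximation confidence band.
#'
#' @param object A [lesion_error_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lesion_curve <- function(object, ...) {
  s <- lesion_error_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$p, y = .data$mean_error_deg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "MST deactivation probability",
                  y = "Mean absolute heading error (deg)",
                  title = "Simulated cell loss vs. heading error") +
    ggplot2::theme_minimal()
}

#' Plot baseline response strategies
#'
#' @param table Output of [baseline_table()].
#' @return A ggplot object.
#' @export
plot_baselines <- function(table) {
  long <- tidyr::pivot_longer(table, c("mean_error_deg", "closed_form_deg"),
                              names_to = "kind", values_to = "error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$error,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Mean absolute heading error (deg)",
                  fill = NULL,
                  title = "Chance-performance baselines") +
    ggplot2::theme_minimal()
}

#' Plot heading error by dot density
#'
#' One panel per presentation time, error by number of dots and group —
#' the standard accuracy summary of the behavioral experiments.
#'
#' @param condition_stats Output of [condition_summary()].
#' @return A ggplot object.
#' @export
plot_heading_error <- function(condition_stats) {
  ggplot2::ggplot(condition_stats,
                  ggplot2::aes(x = factor(.data$n_dots),
                               y = .data$mean_abs_error,
                               colour = .data$group,
                               group = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_abs_error - .data$standard_error,
      ymax = .data$mean_abs_error + .data$standard_error
    )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~duration, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Dots in display", y = "Heading error (deg)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot per-heading precision
#'
#' @param precision Per-group output of [precision_by_heading()] (a
#'   `group` column is optional).
#' @return A ggplot object.
#' @export
plot_precision <- function(precision) {
  aes <- if ("group" %in% names(precision)) {
    ggplot2::aes(x = .data$true_heading, y = .data$sd_deg,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$true_heading, y = .data$sd_deg)
  }
  ggplot2::ggplot(precision, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Presented heading (deg)",
                  y = "SD of perceived heading (deg)",
                  colour = "Group",
                  title = "Precision by heading") +
    ggplot2::theme_minimal()
}

#' Plot perceived vs. true heading with the regression line
#'
#' @param trials Trial tibble for one condition.
#' @return A ggplot object.
#' @export
plot_regression <- function(trials) {
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$true_heading,
                                       y = .data$response)) +
    ggplot2::geom_jitter(width = 0.4, alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "True heading (deg)", y = "Perceived heading (deg)") +
    ggplot2::theme_minimal()
}
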