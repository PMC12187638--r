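#' Plot a fitted thermal performance curve
#'
#' Combined activity curve over temperature with the peak and the optimal
#' window marked, in the style of a thermal performance plot.
#'
#' @param object a `hurdle_curve`.
#' @param fraction optimal-window fraction for the annotation (default 0.90).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hurdle_curve <- function(object, fraction = 0.90, ...) {
  pred <- predict(object)
  pk <- find_peak(object)
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data$surface_temp,
                                          y = .data$combined)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = pk$peak_temp, linetype = "dashed") +
    ggplot2::labs(x = "Surface temperature (°C)",
                  y = "Expected workers on trail",
                  title = sprintf("Thermal performance curve (%s mode)",
                                  object$mode)) +
    ggplot2::theme_minimal()
  if (!pk$boundary) {
    ow <- optimal_window(object, fraction)
    p <- p + ggplot2::annotate("rect", xmin = ow$optimal_lo,
                               xmax = ow$optimal_hi, ymin = -Inf, ymax = Inf,
                               alpha = 0.12)
  }
  p
}

#' Plot daily available activity hours
#'
#' Open-circle daily hours per nest over time with a loess guide line,
#' mirroring a logger-derived activity-budget panel.
#'
#' @param budgets output of [available_hours()].
#' @param complete_only drop incomplete logger days (default TRUE).
#' @return a ggplot object.
#' @export
plot_activity_budget <- function(budgets, complete_only = TRUE) {
  if (complete_only) budgets <- budgets[budgets$complete, ]
  ggplot2::ggplot(budgets, ggplot2::aes(x = .data$date, y = .data$hours)) +
    ggplot2::geom_point(shape = 1, alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.7, span = 0.3) +
    ggplot2::facet_wrap(~nest_id) +
    ggplot2::labs(x = NULL, y = "Available hours per day") +
    ggplot2::theme_minimal()
}

#' Plot longitudinal nest-size trajectories
#'
#' Annual entrance-hole counts per nest with the best-supported growth
#' model's fitted trend.
#'
#' @param surveys survey table (`nest_id`, `year`, `entrance_holes`).
#' @param growth output of [fit_growth_models()] (used to pick each nest's
#'   best model); optional.
#' @return a ggplot object.
#' @export
plot_growth_trajectories <- function(surveys, growth = NULL) {
  p <- ggplot2::ggplot(surveys, ggplot2::aes(x = .data$year,
                                             y = .data$entrance_holes)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~nest_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Nest size (entrance holes)") +
    ggplot2::theme_minimal()
  if (!is.null(growth)) {
    best <- growth |>
      dplyr::group_by(.data$nest_id) |>
      dplyr::slice_min(.data$aicc, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    fits <- purrr::map_dfr(seq_len(nrow(best)), function(i) {
      d <- surveys[surveys$nest_id == best$nest_id[i], ]
      d$yr <- d$year - min(d$year)
      f <- switch(best$model[i],
                  intercept = stats::lm(entrance_holes ~ 1, data = d),
                  linear = stats::lm(entrance_holes ~ yr, data = d),
                  quadratic = stats::lm(entrance_holes ~ yr + I(yr^2), data = d))
      tibble::tibble(nest_id = d$nest_id, year = d$year,
                     fitted = stats::fitted(f))
    })
    p <- p + ggplot2::geom_line(data = fits,
                                ggplot2::aes(y = .data$fitted),
                                linetype = "dashed")
  }
  p
}

#' Plot the emergence-threshold posterior
#'
#' Posterior density of the population lower emergence threshold with the
#' 95% credible interval shaded.
#'
#' @param object an `emergence_changepoint`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.emergence_changepoint <- function(object, ...) {
  draws <- do.call(rbind, object$draws)[, "mu_tau"]
  pt <- object$population_threshold
  ggplot2::ggplot(data.frame(mu_tau = draws), ggplot2::aes(x = .data$mu_tau)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = c(pt$ci_lo, pt$mean, pt$ci_hi),
                        linetype = c("dotted", "solid", "dotted")) +
    ggplot2::labs(x = "Population emergence threshold (°C)",
                  y = "Posterior density") +
    ggplot2::theme_minimal()
}
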