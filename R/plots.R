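#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a seasonal occupancy trajectory
#'
#' Point estimates with 95% credible-interval bars per season, the
#' standard way seasonal occupancy estimates are displayed.
#'
#' @param trajectory A tibble from [occupancy_trajectory()] (or the
#'   `occupancy` element of a `species_report`).
#' @param species Optional label used in the title.
#' @return A ggplot object.
#' @export
plot_occupancy_trajectory <- function(trajectory, species = NULL) {
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = factor(.data$season,
                                          levels = .data$season),
                               y = .data$estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Season", y = "Occupancy probability",
                  title = species) +
    ggplot2::theme_minimal()
}

#' Plot coefficient estimates with credible intervals
#'
#' @param tidied A tibble with `term` (or `covariate`), `estimate`,
#'   `conf.low`, `conf.high` — e.g. from [tidy.occu_fit()] or a
#'   `species_report`'s `coefficients`.
#' @return A ggplot object.
#' @export
plot_coefficients <- function(tidied) {
  if (!"term" %in% names(tidied) && "covariate" %in% names(tidied)) {
    tidied$term <- paste(tidied$parameter, tidied$covariate)
  }
  ggplot2::ggplot(tidied, ggplot2::aes(x = .data$estimate,
                                       y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Coefficient (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.occu_fit <- function(object, ...) {
  plot_coefficients(tidy(object))
}

#' @export
autoplot.averaged_posterior <- function(object, ...) {
  plot_coefficients(object$summary)
}

#' @export
autoplot.species_report <- function(object, ...) {
  plot_occupancy_trajectory(object$occupancy, species = object$species)
}

#' @export
autoplot.detection_history <- function(object, ...) {
  long <- history_to_long(object)
  long$season <- factor(long$season,
                        levels = object$design$seasons$label)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$occasion, y = .data$site,
                                     fill = factor(.data$y))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~season, nrow = 1) +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey90", `1` = "steelblue"),
      na.value = "white", name = "Detected"
    ) +
    ggplot2::labs(x = "Occasion", y = "Site") +
    ggplot2::theme_minimal()
}
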