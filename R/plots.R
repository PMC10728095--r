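#' Plot a trajectory
#'
#' Cell counts of the three compartments over time on a log scale.
#'
#' @param object a `ctl_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ctl_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", "N", "M", "T")],
    -"time",
    names_to = "compartment", values_to = "cells"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$time, pmax(.data$cells, 1),
    colour = .data$compartment
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (days)", y = "cells",
      title = paste0("checkpoint ", attr(object, "mode"))
    )
}

#' Plot a (p1, p2) response grid
#'
#' Bubble-style view of a [grid_response()] table: circle area encodes tumor
#' volume, colour the low-antigen fraction, faceted by day and mode.
#'
#' @param grid a `ctl_grid` tibble.
#' @return A ggplot.
#' @export
plot_grid_response <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(.data$p1, .data$p2)) +
    ggplot2::geom_point(ggplot2::aes(
      size = .data$volume_mm3,
      colour = .data$low_antigen_fraction
    )) +
    ggplot2::scale_colour_gradient(
      low = "blue", high = "red",
      limits = c(0, 1)
    ) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::facet_grid(mode ~ day, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "p1 (fast-kill probability, high antigen)",
      y = "p2 (fast-kill probability, low antigen)",
      colour = "low-antigen\nfraction", size = "volume (mm^3)"
    )
}

#' Plot cohort outcome probabilities
#'
#' Stacked bars of clinical outcome probabilities per mode and day.
#'
#' @param probs tibble from [outcome_probabilities()].
#' @return A ggplot.
#' @export
plot_outcome_probabilities <- function(probs) {
  ggplot2::ggplot(probs, ggplot2::aes(
    factor(.data$day), .data$p,
    fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "day", y = "probability", fill = "outcome")
}

#' Plot binned outcome rates
#'
#' Stacked bars of outcome probability across bins of one parameter.
#'
#' @param rates tibble from [binned_outcome_rates()].
#' @return A ggplot.
#' @export
plot_binned_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(
    factor(.data$bin), .data$p,
    fill = .data$outcome
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = paste0(rates$parameter[1], " bin"), y = "probability",
      fill = "outcome"
    )
}

#' Plot a sensitivity report
#'
#' @param object a `ctl_sensitivity` object.
#' @param ... unused.
#' @return A ggplot of PRCC values, significant bars filled.
#' @export
autoplot.ctl_sensitivity <- function(object, ...) {
  df <- tidy.ctl_sensitivity(object)
  df <- df[!is.na(df$prcc), ]
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$parameter, abs(.data$prcc)),
    .data$prcc,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "PRCC",
      title = paste0(
        attr(object, "metric"), ", checkpoint ",
        attr(object, "mode")
      )
    )
}

#' Plot a bifurcation sweep
#'
#' Region map of outcome sets over the swept parameter plane.
#'
#' @param sweep a `ctl_sweep` tibble.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  gg <- ggplot2::ggplot(sweep, ggplot2::aes(
    .data$value1, .data$value2,
    fill = .data$outcome_set
  )) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = sweep$param1[1], y = sweep$param2[1], fill = "outcomes")
  if (!all(is.na(sweep$slice))) {
    gg <- gg + ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both)
  }
  gg
}
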