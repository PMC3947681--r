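# ggplot2 display methods for result objects.

#' Plot an event-count distribution
#'
#' Marginal probability per event as a column chart (joint distributions
#' are marginalised per event for display).
#'
#' @param object an `event_dist` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot event_dist
#' @export
autoplot.event_dist <- function(object, ...) {
  ev <- setdiff(names(object), "probability")
  long <- tidyr::pivot_longer(object, dplyr::all_of(ev),
                              names_to = "event", values_to = "count")
  marg <- dplyr::summarise(
    dplyr::group_by(long, .data$event, .data$count),
    probability = sum(.data$probability), .groups = "drop")
  ggplot2::ggplot(marg, ggplot2::aes(x = .data$count, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~event, scales = "free_x") +
    ggplot2::labs(x = "event count", y = "probability",
                  title = sprintf("event-count marginals at t = %.3g",
                                  attr(object, "t")))
}

#' Plot a simulated trajectory
#'
#' Population numbers over time as a step plot.
#'
#' @param object a `trajectory_sample` tibble.
#' @param what `"populations"` (default) or `"events"` (cumulative
#'   counts).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot trajectory_sample
#' @export
autoplot.trajectory_sample <- function(object,
                                       what = c("populations", "events"),
                                       ...) {
  what <- match.arg(what)
  scheme <- attr(object, "scheme")
  sel <- if (what == "events") attr(object, "event_names")
         else attr(object, "pop_names")
  long <- tidyr::pivot_longer(object[, c("time", sel)], -"time",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = what,
                  title = paste("trajectory,", scheme, "scheme"))
}

#' Plot a convergence-order test
#'
#' One-step total-variation error against step size on log-log axes,
#' with the fitted slope in the title.
#'
#' @param object an `order_test` from [order_of_accuracy()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot order_test
#' @export
autoplot.order_test <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$h, y = .data$tv_error)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step size h", y = "one-step TV error",
                  title = sprintf("%s scheme: observed order %.2f",
                                  object$scheme, object$slope))
}

#' Plot stage-occupancy curves
#'
#' @param lambda,mu length-4 rate vectors, as in [stage_occupancy()].
#' @param t_max plot horizon.
#' @param n_points grid resolution.
#' @return A ggplot object.
#' @export
plot_stage_occupancy <- function(lambda, mu, t_max, n_points = 200) {
  df <- stage_occupancy(lambda, mu, seq(0, t_max, length.out = n_points))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$probability,
                                   colour = factor(.data$stage))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "P(still in stage)", colour = "stage")
}
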