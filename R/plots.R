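#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Space-time plot of an event schedule
#'
#' The diagnostic view in which the crossing model is visible by eye:
#' plotting event time against the position projected onto the edge normal,
#' events generated by a constant-velocity straight edge lie on a straight
#' line whose slope is the inverse normal speed.
#'
#' @param object An `sbf_schedule`.
#' @param projection_deg Orientation (deg) onto whose normal positions are
#'   projected; default 90 projects onto x (a vertical edge moving
#'   horizontally).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sbf_schedule <- function(object, projection_deg = 90, ...) {
  th <- projection_deg * pi / 180
  df <- dplyr::mutate(tibble::as_tibble(object),
                      proj_deg = sin(th) * .data$x_deg -
                        cos(th) * .data$y_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proj_deg, y = .data$time_ms,
                                   colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position along edge normal (deg)", y = "time (ms)",
                  colour = "event") +
    ggplot2::theme_minimal()
}

#' Plot size-perception accuracy against mean illusory-strength rating
#'
#' One point per (speed x spacing) cell; a monotone relationship indicates
#' concordance of the objective and subjective measures.
#'
#' @param object An `sbf_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sbf_analysis <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$mean_rating, y = .data$slope,
                               colour = factor(.data$spacing_deg),
                               shape = factor(.data$speed_deg_s))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean illusory-strength rating",
                  y = "size perception accuracy (slope)",
                  colour = "spacing (deg)", shape = "speed (deg/s)") +
    ggplot2::theme_minimal()
}

#' Plot ratings (or accuracy) as a function of SOA, colored by EOD
#'
#' @param timing_table Output of [replot_by_timing()].
#' @param y One of `"mean_rating"`, `"prop_correct_width"`.
#' @return A ggplot with the 76 ms point marked.
#' @export
plot_rating_by_timing <- function(timing_table, y = "mean_rating") {
  ggplot2::ggplot(timing_table,
                  ggplot2::aes(x = .data$soa_bin_ms, y = .data[[y]],
                               colour = .data$eod_bin_ms,
                               group = .data$eod_bin_ms)) +
    ggplot2::geom_vline(xintercept = 76, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SOA (ms)", y = y, colour = "EOD (ms)") +
    ggplot2::theme_minimal()
}

#' Plot the slope-vs-SOA step with an estimated change point
#'
#' @param analysis An `sbf_analysis`.
#' @return A ggplot of per-cell slopes against SOA with the change-point
#'   estimate from [estimate_soa_threshold()] marked.
#' @export
plot_slope_by_soa <- function(analysis) {
  tau <- estimate_soa_threshold(analysis)
  ggplot2::ggplot(analysis$cells,
                  ggplot2::aes(x = .data$soa_ms, y = .data$slope)) +
    ggplot2::geom_vline(xintercept = tau, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SOA (ms)", y = "size perception accuracy (slope)") +
    ggplot2::theme_minimal()
}
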