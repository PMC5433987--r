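#' Plot a matched bird track with its behavioural classification
#'
#' Track map coloured by fix class: out of range, in attraction range, and
#' attendance; vessel grid points are drawn in grey underneath.
#'
#' @param matched Output of [match_locations()] (one or a few trips).
#' @param vessel_tracks Interpolated vessel tracks (optional).
#' @return A ggplot object.
#' @export
plot_matched_track <- function(matched, vessel_tracks = NULL) {
  matched <- mutate(matched, class = factor(
    ifelse(.data$is_attendance, "attendance",
           ifelse(.data$in_attraction, "in range", "out of range")),
    levels = c("out of range", "in range", "attendance")
  ))
  p <- ggplot2::ggplot()
  if (!is.null(vessel_tracks) && nrow(vessel_tracks)) {
    p <- p + ggplot2::geom_path(
      data = vessel_tracks,
      ggplot2::aes(.data$lon, .data$lat, group = .data$vessel_id),
      colour = "grey70"
    )
  }
  p +
    ggplot2::geom_path(
      data = matched,
      ggplot2::aes(.data$lon, .data$lat, group = .data$trip_id),
      colour = "grey40", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = matched,
      ggplot2::aes(.data$lon, .data$lat, colour = .data$class),
      size = 1
    ) +
    ggplot2::scale_colour_manual(values = c(
      "out of range" = "grey55", "in range" = "purple3",
      "attendance" = "goldenrod2"
    )) +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Per-encounter attendance probability (or any other sweep statistic)
#' against the attraction radius, one line per time-to-return allowance.
#'
#' @param object A tibble from [sweep_thresholds()].
#' @param stat Name of the column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vb_sweep <- function(object, stat = "p_attend", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$attraction_km, .data[[stat]],
    colour = factor(.data$time_to_return_hr),
    group = factor(.data$time_to_return_hr)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Attraction radius (km)", y = stat,
                  colour = "Time-to-return (hr)") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted response model
#'
#' Fixed-effect estimates with approximate 95 percent intervals.
#'
#' @param object A `vb_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vb_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "Estimate", y = NULL,
                  title = object$name) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
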