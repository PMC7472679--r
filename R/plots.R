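#' Plot the mean +- SD band of normalized pressor responses
#'
#' One panel per pressure: the across-segment mean as a line, +- one SD as a
#' shaded band, on the normalized time axis (midpoint at t = 0).
#'
#' @param band Output of [summarize_band()].
#' @return A ggplot object.
#' @export
plot_response_band <- function(band) {
  ggplot2::ggplot(band, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "grey70"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "#2c5aa0") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pressure)) +
    ggplot2::labs(
      x = "time relative to response midpoint (s)",
      y = "normalized pressure (mmHg)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a histogram of per-bolus MAP changes
#'
#' @param hist Output of [delta_histogram()].
#' @return A ggplot object.
#' @export
plot_delta_histogram <- function(hist) {
  ggplot2::ggplot(hist) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$bin_lo, xmax = .data$bin_hi,
                   ymin = 0, ymax = .data$count),
      fill = "#2c5aa0", colour = "white"
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta * "MAP (mmHg)"), y = "boluses") +
    ggplot2::theme_minimal()
}

#' Plot any stretch of a recording with beat annotations
#'
#' @param recording A recording tibble.
#' @param from,to Time range (s); defaults to the full recording.
#' @param beats Optional beat table from [detect_beats()]; systolic peaks are
#'   marked when given.
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, from = NULL, to = NULL, beats = NULL) {
  from <- from %||% recording$time_s[1]
  to <- to %||% recording$time_s[nrow(recording)]
  sub <- recording[recording$time_s >= from & recording$time_s <= to, ]
  p <- ggplot2::ggplot(sub, ggplot2::aes(.data$time_s, .data$aortic_pressure)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "aortic pressure (mmHg)") +
    ggplot2::theme_minimal()
  if (!is.null(beats) && nrow(beats) > 0) {
    rate <- recording_rate(recording)
    hemo <- beat_pressures(recording, beats)
    hemo <- hemo[hemo$beat_time_s >= from & hemo$beat_time_s <= to, ]
    p <- p + ggplot2::geom_point(
      data = hemo, ggplot2::aes(.data$beat_time_s, .data$AoS),
      colour = "#c03a2b", size = 0.8
    )
  }
  p
}

#' @export
autoplot.bolus_comparison <- function(object, bin_width = 2, ...) {
  deltas <- object$per_segment$MAP_delta
  plot_delta_histogram(delta_histogram(deltas[is.finite(deltas)], bin_width))
}
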