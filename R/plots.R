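#' Plot eye, head and gaze traces
#'
#' Stacked traces of mean eye position, head yaw and gaze over a time
#' window, the standard view of the saccade-and-fixate pattern: gaze is
#' piecewise constant while the head keeps moving.
#'
#' @param kin Kinematic tibble with `t`, `mean_eye`, `yaw_unwrapped` (or
#'   `yaw`) and `gaze` columns (see [add_gaze_channels()]).
#' @param from,to Time window in seconds (defaults to the whole series).
#' @return A ggplot object.
#' @export
plot_gaze_trace <- function(kin, from = NULL, to = NULL) {
  yaw_col <- if ("yaw_unwrapped" %in% names(kin)) "yaw_unwrapped" else "yaw"
  d <- tibble::tibble(t = kin$t,
                      `mean eye` = kin$mean_eye,
                      `head yaw` = kin[[yaw_col]],
                      gaze = kin$gaze)
  if (!is.null(from)) d <- d[d$t >= from, ]
  if (!is.null(to)) d <- d[d$t <= to, ]
  d <- tidyr::pivot_longer(d, -"t", names_to = "channel", values_to = "deg")
  d$channel <- factor(d$channel, levels = c("mean eye", "head yaw", "gaze"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$deg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Histogram of gaze velocity with the classification threshold
#'
#' @param gaze_velocity Gaze velocity series, deg/s.
#' @param threshold Saccade threshold, deg/s.
#' @param binwidth Bin width, deg/s.
#' @return A ggplot object.
#' @export
plot_velocity_distribution <- function(gaze_velocity, threshold = 180,
                                       binwidth = 20) {
  d <- tibble::tibble(v = gaze_velocity[!is.na(gaze_velocity)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gaze velocity (deg/s)", y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter of head pitch against vergence with the fitted line
#'
#' @param pitch,vergence Series in degrees.
#' @param fit Optional `pitch_vergence_fit` to draw.
#' @param sample_n Plot at most this many points.
#' @return A ggplot object.
#' @export
plot_pitch_vergence <- function(pitch, vergence, fit = NULL, sample_n = 5000) {
  ok <- !is.na(pitch) & !is.na(vergence)
  d <- tibble::tibble(pitch = pitch[ok], vergence = vergence[ok])
  if (nrow(d) > sample_n) d <- dplyr::slice_sample(d, n = sample_n)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pitch, y = .data$vergence)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::labs(x = "head pitch (deg, nose-up positive)",
                  y = "vergence (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    g <- g + ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                                  colour = "red")
  }
  g
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a lagged cross-correlation
#'
#' @param object A `lag_correlation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lag_correlation
#' @export
autoplot.lag_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "lag (s)", y = "correlation") +
    ggplot2::theme_minimal()
}

#' Autoplot an event-triggered average
#'
#' @param object A `triggered_average` tibble.
#' @param ... Unused.
#' @return A ggplot object with a mean line and +/-1 sem ribbon.
#' @method autoplot triggered_average
#' @export
autoplot.triggered_average <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "mean") +
    ggplot2::theme_minimal()
}

#' Compare per-fixation RMS stabilization of head and gaze
#'
#' @param rms_head,rms_gaze `rms_stabilization` objects for head yaw and
#'   gaze.
#' @param binwidth Histogram bin width, degrees.
#' @return A ggplot object.
#' @export
plot_fixation_rms <- function(rms_head, rms_gaze, binwidth = 0.5) {
  d <- dplyr::bind_rows(
    dplyr::mutate(rms_head$per_fixation, channel = "head yaw"),
    dplyr::mutate(rms_gaze$per_fixation, channel = "gaze")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rms, fill = .data$channel)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.5) +
    ggplot2::labs(x = "RMS deviation within fixation (deg)", y = "count") +
    ggplot2::theme_minimal()
}
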