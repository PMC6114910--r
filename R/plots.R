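#' Plot metric responses of a gain sweep
#'
#' One panel per metric against the percent-of-range gain, mirroring the
#' standard presentation of feedback-response curves (frequency, duty cycle,
#' amplitude, speed, Strouhal number, normalized cost of transport).
#'
#' @param object A [gain_sweep()] table.
#' @param metrics Character vector of metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gain_sweep
#' @export
autoplot.gain_sweep <- function(object,
                                metrics = c("frequency", "duty_cycle",
                                            "amplitude", "speed", "strouhal",
                                            "cot_normalized"),
                                ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::all_of(c("percent_gain", "mode", metrics))),
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$percent_gain, .data$value,
                                   color = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "gain (% of stable range)", y = NULL,
                  color = "feedback") +
    ggplot2::theme_minimal()
}

#' Plot midline snapshots of a kinematics series or trajectory
#'
#' Overlays midlines at evenly spaced times, colored by time, to show the
#' traveling body wave and net progression.
#'
#' @param object A `kinematics_series` (from [make_traveling_wave()]).
#' @param n_frames Number of snapshots (default 9).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinematics_series
#' @export
autoplot.kinematics_series <- function(object, n_frames = 9, ...) {
  idx <- unique(round(seq(1, length(object$time), length.out = n_frames)))
  df <- purrr::map_dfr(idx, function(i) {
    tibble::tibble(t = object$time[i], x = object$x[i, ], y = object$y[i, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$t,
                                   color = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", color = "t (s)") +
    ggplot2::theme_minimal()
}

#' Plot a neuromechanical phase-lag profile
#'
#' @param phi A tibble from [phase_lag_profile()].
#' @return A ggplot object.
#' @export
plot_phase_lag <- function(phi) {
  df <- dplyr::summarise(dplyr::group_by(phi, .data$s, .data$side),
                         phi = mean(.data$phi), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$phi, color = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "body position (fraction of L)",
                  y = "phase lag (cycle fraction)") +
    ggplot2::theme_minimal()
}
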