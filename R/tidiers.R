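#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report into a long tibble
#'
#' @param x A [metrics_report()].
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value`, `unit`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("speed", "amplitude", "frequency", "wavelength", "duty_cycle",
               "strouhal", "activation_wave_speed", "curvature_wave_speed",
               "wavespeed_ratio", "cost_of_transport",
               "cost_of_transport_normalized"),
    value = c(x$speed, x$amplitude, x$frequency, x$wavelength, x$duty_cycle,
              x$strouhal, x$v_a, x$V, x$wavespeed_ratio, x$cot,
              x$cot_normalized),
    unit = c("L/s", "L", "Hz", "L", "fraction", "-", "L/s", "L/s", "-",
             "erg/(s g)", "-")
  )
}

#' One-row summary of a metrics report
#'
#' @param x A [metrics_report()].
#' @param ... Unused.
#' @return A one-row tibble with one column per metric.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(speed = x$speed, amplitude = x$amplitude,
                 frequency = x$frequency, wavelength = x$wavelength,
                 duty_cycle = x$duty_cycle, strouhal = x$strouhal,
                 v_a = x$v_a, V = x$V, wavespeed_ratio = x$wavespeed_ratio,
                 cot = x$cot, cot_normalized = x$cot_normalized)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Swimming metrics (window ",
      sprintf("%.2f-%.2f s", x$window[1], x$window[2]), ")\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$trajectory$meta
  cat(sprintf("Closed-loop run: %s backend, %s feedback (gain %.3g), %g s\n",
              m$backend, m$feedback_mode, m$gain, m$duration))
  print(x$metrics)
  invisible(x)
}
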