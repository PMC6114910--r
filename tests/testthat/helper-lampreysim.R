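# Shared fixtures and memoized closed-loop runs (the desk-scale runs are the
# expensive part of the suite; every test that needs one shares the cache).

desk_cache <- new.env(parent = emptyenv())

# reduced-scale closed-loop run, memoized on (mode, gain, duration)
desk_run <- function(mode = "none", gain = 0, duration = 6) {
  key <- paste(mode, gain, duration, sep = "|")
  if (is.null(desk_cache[[key]])) {
    fb <- if (gain == 0) feedback_config("none") else
      feedback_config(mode, gain = gain)
    desk_cache[[key]] <- run_simulation(reduced_config(fb, duration = duration))
  }
  desk_cache[[key]]
}

# open-loop CPG run driven by prescribed sinusoidal curvature, memoized
driver_run <- function(mode = "none", gain = 0, duration = 5) {
  key <- paste("drv", mode, gain, duration, sep = "|")
  if (is.null(desk_cache[[key]])) {
    p <- cpg_params()
    drv <- make_curvature_driver(wave_spec(duration = duration))
    fb <- if (gain == 0) feedback_config("none") else
      feedback_config(mode, gain = gain)
    desk_cache[[key]] <- run_cpg(p, duration = duration, dt = 1e-3,
                                 feedback_config = fb, kappa_fn = drv)
  }
  desk_cache[[key]]
}

# frequency of a cpg_run from the mean terminal phase velocity (exact for the
# deterministic chains; avoids zero-crossing quantization)
cpg_run_frequency <- function(r, from = 2) {
  n <- length(r$time)
  i0 <- which.min(abs(r$time - from))
  mean((r$theta_left[n, ] - r$theta_left[i0, ]) /
         (r$time[n] - r$time[i0])) / (2 * pi)
}

cpg_run_duty <- function(r) {
  duty_cycle(list(time = r$time, sigma_left = r$sigma_left,
                  sigma_right = r$sigma_right))
}
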