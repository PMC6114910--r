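#' Specification of a synthetic traveling-wave swimmer
#'
#' Describes midline kinematics of the form
#' `y(s, t) = A(s) * sin(2*pi*(f*t - s/lambda))` superposed on a uniform
#' translation, with a linear amplitude envelope from `amp_head` at the head to
#' `amp_tail` at the tail. Defaults mirror the steady control swimmer: 1 Hz
#' tailbeat, body wavelength 0.75 L, tail amplitude 0.12 L, and translation at
#' 0.52 L/s toward -x. Used to test every analysis operation against exact
#' ground truth without running the fluid solver.
#'
#' @param frequency Tailbeat frequency, Hz.
#' @param wavelength Body wavelength, in units of L.
#' @param amp_head,amp_tail Amplitude envelope endpoints, in units of L.
#' @param speed Translation speed, L/s (movement toward -x).
#' @param duration Duration, s.
#' @param dt Sampling interval, s.
#' @param n_s Number of midline samples (default 641).
#' @param L Body length, cm.
#' @param wave_speed Optional wave speed, L/s; must equal
#'   `frequency * wavelength` if supplied.
#' @param noise_sd Std. dev. of optional Gaussian measurement noise added to
#'   the transverse coordinate, cm (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(frequency = 1, wavelength = 0.75,
                      amp_head = 0.02, amp_tail = 0.12,
                      speed = 0.52, duration = 10, dt = 0.01,
                      n_s = 641L, L = 12.56,
                      wave_speed = NULL, noise_sd = 0, seed = NULL) {
  stopifnot(frequency > 0, wavelength > 0, duration > 0, dt > 0,
            n_s >= 5, L > 0, noise_sd >= 0)
  if (!is.null(wave_speed) &&
      abs(wave_speed - frequency * wavelength) > 1e-9) {
    stop("inconsistent wave spec: wave_speed must equal frequency * wavelength",
         call. = FALSE)
  }
  structure(
    list(frequency = frequency, wavelength = wavelength,
         amp_head = amp_head, amp_tail = amp_tail, speed = speed,
         duration = duration, dt = dt, n_s = as.integer(n_s), L = L,
         noise_sd = noise_sd, seed = seed),
    class = "wave_spec"
  )
}

#' Generate traveling-wave midline kinematics with analytic curvature
#'
#' Builds the full midline time series of the spec, with the signed curvature
#' computed analytically from the derivatives of the envelope and phase (so the
#' fixture carries its own exact ground truth). Deterministic given the seed.
#'
#' @param spec A [wave_spec()].
#' @return An object of class `kinematics_series`: `time` (n_t), `s` (cm,
#'   head-to-tail arclength parameter), `x`, `y`, `kappa` (n_t x n_s matrices),
#'   `com` (n_t x 2), `tail_y` (n_t), `L`, and the spec.
#' @export
make_traveling_wave <- function(spec) {
  stopifnot(inherits(spec, "wave_spec"))
  L <- spec$L
  time <- seq(0, spec$duration, by = spec$dt)
  s <- seq(0, 1, length.out = spec$n_s) * L            # cm
  lam <- spec$wavelength * L                            # cm
  A <- (spec$amp_head + (spec$amp_tail - spec$amp_head) * s / L) * L
  dA <- (spec$amp_tail - spec$amp_head)                 # dA/ds, dimensionless
  k <- 2 * pi / lam
  ph <- outer(2 * pi * spec$frequency * time, k * s, "-")  # n_t x n_s
  Am <- matrix(A, length(time), spec$n_s, byrow = TRUE)
  y <- Am * sin(ph)
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    y <- y + matrix(stats::rnorm(length(y), 0, spec$noise_sd),
                    nrow(y), ncol(y))
  }
  x <- outer(-spec$speed * L * time, s, "+")
  kappa <- kappa_wave(spec, s / L, time)
  structure(
    list(time = time, s = s, x = x, y = y, kappa = kappa,
         com = cbind(rowMeans(x), rowMeans(y)),
         tail_y = y[, spec$n_s], L = L, spec = spec),
    class = "kinematics_series"
  )
}

# Analytic signed curvature of the spec's traveling wave at body positions
# s_frac (fraction of L) and times t: kappa = y'' / (1 + y'^2)^(3/2) with
# x parameterized by arclength-at-rest. Returns length(t) x length(s_frac).
kappa_wave <- function(spec, s_frac, t) {
  L <- spec$L
  lam <- spec$wavelength * L
  k <- 2 * pi / lam
  A <- (spec$amp_head + (spec$amp_tail - spec$amp_head) * s_frac) * L
  dA <- (spec$amp_tail - spec$amp_head)
  ph <- outer(2 * pi * spec$frequency * t, k * s_frac * L, "-")
  Am <- matrix(A, length(t), length(s_frac), byrow = TRUE)
  yp <- dA * sin(ph) - Am * k * cos(ph)
  ypp <- -2 * dA * k * cos(ph) - Am * k^2 * sin(ph)
  ypp / (1 + yp^2)^1.5
}

#' Generate a binary activation pattern with a known phase-lag profile
#'
#' Produces a head-to-tail traveling on/off activation wave at the spec's
#' frequency and wavelength, sampled at the oscillator positions of the active
#' body. On the right side, onsets are offset from the local peak of (positive)
#' curvature by `lag_profile(s) * T`; the left side is the same pattern in
#' antiphase (offset from peaks of negative curvature). The measured phase lag
#' of [phase_lag_profile()] on this fixture is `lag_profile(s)` by
#' construction, and the measured duty cycle is `duty`.
#'
#' @param spec A [wave_spec()].
#' @param duty Activation duty cycle, in (0, 1).
#' @param lag_profile Function of body position (fraction of L) returning the
#'   onset lag as a fraction of the cycle; default 0.
#' @param n_osc Number of oscillator positions (default 280).
#' @param n_lateral Lateral segments per side (default 320; sets the passive
#'   head offset).
#' @return An object of class `activation_series`: `time`, `s_frac`
#'   (oscillator positions, fraction of L), `sigma_left`, `sigma_right`
#'   (n_t x n_osc 0/1 matrices), `duty`, and the generating offsets.
#' @export
make_activation_pattern <- function(spec, duty, lag_profile = function(s) 0,
                                    n_osc = 280L, n_lateral = 320L) {
  stopifnot(inherits(spec, "wave_spec"), duty > 0, duty < 1)
  time <- seq(0, spec$duration, by = spec$dt)
  n_head <- n_lateral - n_osc
  s_frac <- (seq_len(n_osc) + n_head - 0.5) / n_lateral
  lag <- vapply(s_frac, lag_profile, numeric(1))
  f <- spec$frequency
  # locate the true peak of +kappa (envelope shifts it off the carrier phase)
  # numerically within one cycle at each oscillator position
  tfine <- seq(0, 1 / f, length.out = 2001L)[-2001L]
  kf <- kappa_wave(spec, s_frac, tfine)
  t_peak <- tfine[apply(kf, 2, which.max)]
  onset_right <- f * t_peak + lag
  cyc <- outer(f * time, rep(1, n_osc)) -
    matrix(onset_right, length(time), n_osc, byrow = TRUE)
  frac <- cyc - floor(cyc)
  sigma_right <- (frac < duty) + 0L
  frac_l <- (cyc + 0.5) - floor(cyc + 0.5)
  sigma_left <- (frac_l < duty) + 0L
  structure(
    list(time = time, s_frac = s_frac,
         sigma_left = sigma_left, sigma_right = sigma_right,
         duty = duty, lag = lag, spec = spec),
    class = "activation_series"
  )
}

#' Prescribed sinusoidal curvature drive for open-loop CPG experiments
#'
#' Returns a function of time giving the per-oscillator curvature of the
#' spec's traveling wave (small-amplitude closed form
#' `kappa(s, t) = -A(s) k^2 sin(2 pi (f t - s/lambda))`), for feeding the CPG's
#' feedback port without any body or fluid mechanics — e.g. to show that
#' magnitude feedback shifts the CPG frequency and directional feedback shifts
#' the duty cycle.
#'
#' @param spec A [wave_spec()].
#' @param n_osc,n_lateral As in [make_activation_pattern()].
#' @return A function `kappa(t)` returning a length-`n_osc` curvature vector
#'   (1/cm), with the oscillator positions attached as attribute `s_frac`.
#' @export
make_curvature_driver <- function(spec, n_osc = 280L, n_lateral = 320L) {
  stopifnot(inherits(spec, "wave_spec"))
  n_head <- n_lateral - n_osc
  s_frac <- (seq_len(n_osc) + n_head - 0.5) / n_lateral
  L <- spec$L
  A <- (spec$amp_head + (spec$amp_tail - spec$amp_head) * s_frac) * L
  k <- 2 * pi / (spec$wavelength * L)
  f <- spec$frequency
  fn <- function(t) {
    -A * k^2 * sin(2 * pi * (f * t - s_frac / spec$wavelength))
  }
  attr(fn, "s_frac") <- s_frac
  fn
}
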