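#' Parameters of the double-chain phase-oscillator CPG
#'
#' The central pattern generator is modeled as two chains (left and right) of
#' `n_seg` phase oscillators. Each oscillator runs at natural frequency `omega`
#' and is pulled by every other oscillator on the same side through a sine
#' coupling whose strength decays exponentially with the number of segments
#' between them: ascending connections (tail-to-head, `i - j < 0`) have
#' amplitude `A_asc` and decay length `lambda_asc`, descending connections
#' amplitude `A_desc` and decay length `lambda_desc`. Left and right oscillators
#' of the same segment are coupled in antiphase with strength `alpha_c`. The
#' chain is tuned with a constant phase shift `psi_bar` between neighboring
#' segments, so the zero-feedback steady state is a traveling wave with one full
#' wave over the `n_seg` active segments.
#'
#' Defaults follow the lamprey model: `omega = 2*pi` rad/s (1 Hz rhythm),
#' `A_asc = 1`, `A_desc = 10` rad/s, `lambda_asc = 40`, `lambda_desc = 5`
#' segments, `alpha_c = 81.87` rad/s (ten times the strongest descending
#' connection), `psi_bar = 2*pi/280`, and `n_seg = 280` active segments per
#' side. The default activation threshold `tau` is calibrated so that a segment
#' is active for 36% of each cycle (see [calibrate_threshold()]).
#'
#' @param omega Natural frequency, rad/s.
#' @param A_asc,A_desc Ascending / descending coupling amplitudes, rad/s.
#' @param lambda_asc,lambda_desc Coupling decay lengths, in segments.
#' @param alpha_c Contralateral coupling strength, rad/s.
#' @param psi_bar Phase shift between neighboring oscillators, rad.
#' @param n_seg Number of oscillators per side.
#' @param tau Activation threshold on `sin(theta)`, in (-1, 1).
#'
#' @return An object of class `cpg_params` (a list with the fields above plus
#'   the precomputed ipsilateral coupling matrix).
#' @export
cpg_params <- function(omega = 2 * pi,
                       A_asc = 1.0, A_desc = 10,
                       lambda_asc = 40, lambda_desc = 5,
                       alpha_c = 81.87,
                       psi_bar = 2 * pi / 280,
                       n_seg = 280,
                       tau = calibrate_threshold(0.36)) {
  stopifnot(omega > 0, n_seg >= 2, lambda_asc > 0, lambda_desc > 0)
  if (!(tau > -1 && tau < 1)) {
    stop("`tau` must lie strictly between -1 and 1.", call. = FALSE)
  }
  p <- structure(
    list(
      omega = omega, A_asc = A_asc, A_desc = A_desc,
      lambda_asc = lambda_asc, lambda_desc = lambda_desc,
      alpha_c = alpha_c, psi_bar = psi_bar,
      n_seg = as.integer(n_seg), tau = tau
    ),
    class = "cpg_params"
  )
  p$coupling <- coupling_matrix(p)
  p
}

#' Ipsilateral coupling strength between two oscillators
#'
#' Exponentially decaying coupling along one chain: for `i - j < 0` (ascending,
#' j posterior to i) the strength is `A_asc * exp(-|i-j|/lambda_asc)`; for
#' `i - j > 0` (descending) it is `A_desc * exp(-|i-j|/lambda_desc)`.
#' Self-coupling is zero.
#'
#' @param i,j Oscillator indices (may be vectors, recycled).
#' @param params A [cpg_params()] object.
#' @return Coupling strength(s), rad/s.
#' @export
coupling_strength <- function(i, j, params) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L | i > params$n_seg | j < 1L | j > params$n_seg)) {
    stop("oscillator indices must be in 1..n_seg", call. = FALSE)
  }
  d <- i - j
  out <- numeric(length(d))
  asc <- d < 0L
  desc <- d > 0L
  out[asc] <- params$A_asc * exp(-abs(d[asc]) / params$lambda_asc)
  out[desc] <- params$A_desc * exp(-abs(d[desc]) / params$lambda_desc)
  out
}

# Full n x n ipsilateral coupling matrix; row i holds the strengths of the
# connections oscillator i receives.
coupling_matrix <- function(params) {
  n <- params$n_seg
  d <- outer(seq_len(n), seq_len(n), "-")
  A <- matrix(0, n, n)
  A[d < 0] <- params$A_asc * exp(-abs(d[d < 0]) / params$lambda_asc)
  A[d > 0] <- params$A_desc * exp(-abs(d[d > 0]) / params$lambda_desc)
  A
}

#' Initialize the CPG phase state
#'
#' The tuned traveling-wave state sets `theta[k, i] = -(i - 1) * psi_bar` on the
#' left chain and the same minus `pi` on the right chain, so that (with zero
#' feedback) every phase advances at exactly `omega`: all ipsilateral sine terms
#' vanish because neighboring phases differ by exactly `psi_bar`, and the
#' contralateral term vanishes at the antiphase offset. Phases are stored
#' unwrapped (monotone in time); wrapping happens only inside sines.
#'
#' @param params A [cpg_params()] object.
#' @param perturb Half-width of a uniform random perturbation (rad) added to
#'   every phase; 0 (default) gives the tuned deterministic start.
#' @param time Initial time, s.
#' @return An object of class `cpg_state`: list with `theta` (2 x n_seg matrix,
#'   row 1 = left, row 2 = right) and `time`.
#' @export
cpg_init <- function(params, perturb = 0, time = 0) {
  i <- seq_len(params$n_seg)
  theta <- rbind(-(i - 1) * params$psi_bar,
                 -(i - 1) * params$psi_bar - pi)
  if (perturb > 0) {
    theta <- theta + matrix(stats::runif(2 * params$n_seg, -perturb, perturb),
                            2, params$n_seg)
  }
  rownames(theta) <- c("left", "right")
  structure(list(theta = theta, time = time), class = "cpg_state")
}

#' Instantaneous phase velocities of the CPG
#'
#' Right-hand side of the oscillator equations:
#' `dtheta[k,i]/dt = omega + sum_j alpha[i,j] * sin(theta[k,j] - theta[k,i] -
#' psi_ij) + alpha_c * sin(theta[k,i] - theta[k*,i]) + feedback[k,i]`,
#' with `psi_ij = (i - j) * psi_bar` and `k*` the opposite side. The feedback
#' term is the additive proprioceptive input port (see [feedback_term()]).
#'
#' The contralateral term vanishes at the antiphase offset and, linearized
#' about it, damps deviations at rate `2 * alpha_c`, so the observed antiphase
#' left-right pattern is an attractor. (Writing the same term with an extra
#' `+pi` inside the sine flips that sign and makes antiphase repelling, which
#' destroys the propagating activation pattern; see the methods vignette.)
#'
#' The ipsilateral sum is evaluated via the identity
#' `theta_j - theta_i - (i-j)*psi_bar = phi_j - phi_i` with
#' `phi_i = theta_i + i*psi_bar`, which reduces it to two matrix-vector
#' products per side.
#'
#' @param state A `cpg_state`.
#' @param feedback 2 x n_seg matrix of additive inputs, rad/s (or a single 0).
#' @param params A [cpg_params()] object.
#' @return 2 x n_seg matrix of phase velocities, rad/s.
#' @export
phase_velocity <- function(state, feedback, params) {
  theta <- state$theta
  n <- params$n_seg
  if (length(feedback) == 1L) feedback <- matrix(feedback, 2, n)
  if (!all(dim(feedback) == dim(theta))) {
    stop("`feedback` must have the same shape as the phase matrix (2 x n_seg).",
         call. = FALSE)
  }
  A <- params$coupling
  phi <- theta + matrix(seq_len(n) * params$psi_bar, 2, n, byrow = TRUE)
  sp <- sin(t(phi)); cp <- cos(t(phi))          # n x 2
  As <- A %*% sp; Ac <- A %*% cp                # n x 2
  ipsi <- t(cp * As - sp * Ac)                  # 2 x n: sum_j a_ij sin(phi_j - phi_i)
  contra <- params$alpha_c * sin(theta - theta[2:1, , drop = FALSE])
  params$omega + ipsi + contra + feedback
}

#' Advance the CPG one time step (classical RK4)
#'
#' The feedback input is held fixed across the step (explicit coupling to the
#' body). Deterministic given state and feedback.
#'
#' @inheritParams phase_velocity
#' @param dt Time step, s (> 0).
#' @return The advanced `cpg_state`.
#' @export
step_cpg <- function(state, feedback, dt, params) {
  stopifnot(dt > 0)
  f <- function(th) {
    phase_velocity(structure(list(theta = th, time = state$time),
                             class = "cpg_state"),
                   feedback, params)
  }
  th <- state$theta
  k1 <- f(th)
  k2 <- f(th + dt / 2 * k1)
  k3 <- f(th + dt / 2 * k2)
  k4 <- f(th + dt * k3)
  th_new <- th + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(th_new))) {
    bad <- which(!is.finite(th_new), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite phase after step at side %d, oscillator %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  structure(list(theta = th_new, time = state$time + dt), class = "cpg_state")
}

#' Binary activation signal from oscillator phases
#'
#' A muscle segment is active when the sine of its oscillator's phase reaches
#' the threshold: `sigma = 1` iff `sin(theta) >= tau` (boundary inclusive).
#'
#' @param state A `cpg_state`.
#' @param tau Activation threshold; defaults to the value stored in `params`.
#' @param params Optional [cpg_params()] supplying `tau`.
#' @return 2 x n_seg binary (0/1) matrix.
#' @export
activation_from_phase <- function(state, tau = NULL, params = NULL) {
  if (is.null(tau)) {
    if (is.null(params)) stop("supply `tau` or `params`", call. = FALSE)
    tau <- params$tau
  }
  (sin(state$theta) >= tau) + 0L
}

#' Activation threshold for a target duty cycle
#'
#' For a phase advancing at a constant rate, `sin(theta) >= tau` holds for the
#' fraction `(pi - 2*asin(tau)) / (2*pi)` of each cycle. Inverting gives the
#' closed form `tau = cos(pi * duty_target)`. The shipped default threshold is
#' `calibrate_threshold(0.36)`, matching the burst proportion of freely
#' swimming lampreys.
#'
#' @param duty_target Target activation fraction, in (0, 1).
#' @return The threshold `tau`.
#' @export
calibrate_threshold <- function(duty_target) {
  if (!(is.numeric(duty_target) && length(duty_target) == 1L &&
        duty_target > 0 && duty_target < 1)) {
    stop("`duty_target` must be a single number in (0, 1).", call. = FALSE)
  }
  cos(pi * duty_target)
}

#' Integrate the CPG alone, optionally with a prescribed curvature drive
#'
#' Runs the oscillator chains open-loop (no body, no fluid). If a curvature
#' driver is supplied, its per-oscillator curvature at the start of each step
#' is mapped through [feedback_term()]; otherwise feedback is zero (the control
#' case). Useful for threshold calibration checks and entrainment experiments.
#'
#' @param params A [cpg_params()] object.
#' @param duration Total integration time, s.
#' @param dt Time step, s.
#' @param feedback_config A [feedback_config()]; default no feedback.
#' @param kappa_fn Optional function of time returning the per-oscillator
#'   curvature vector (1/cm), e.g. from [make_curvature_driver()].
#' @param init A starting `cpg_state`; default tuned state.
#' @param record_every Store every this-many steps (default 1).
#' @return List of class `cpg_run`: `time` (n_t), `theta_left`, `theta_right`,
#'   `sigma_left`, `sigma_right` (n_t x n_seg matrices), plus `params`.
#' @export
run_cpg <- function(params, duration, dt = 1e-3,
                    feedback_config = NULL, kappa_fn = NULL,
                    init = NULL, record_every = 1L) {
  if (is.null(init)) init <- cpg_init(params)
  if (is.null(feedback_config)) feedback_config <- feedback_config("none")
  n_steps <- as.integer(round(duration / dt))
  record_every <- as.integer(record_every)
  n_keep <- length(seq(0L, n_steps, by = record_every))
  n <- params$n_seg
  tL <- matrix(NA_real_, n_keep, n); tR <- tL
  time <- numeric(n_keep)
  state <- init
  row <- 1L
  zero_fb <- matrix(0, 2, n)
  for (s in 0:n_steps) {
    if (s %% record_every == 0L) {
      time[row] <- state$time
      tL[row, ] <- state$theta[1, ]
      tR[row, ] <- state$theta[2, ]
      row <- row + 1L
    }
    if (s == n_steps) break
    fb <- if (is.null(kappa_fn)) zero_fb else
      feedback_term(kappa_fn(state$time), feedback_config)
    state <- step_cpg(state, fb, dt, params)
  }
  structure(
    list(time = time,
         theta_left = tL, theta_right = tR,
         sigma_left = (sin(tL) >= params$tau) + 0L,
         sigma_right = (sin(tR) >= params$tau) + 0L,
         params = params),
    class = "cpg_run"
  )
}
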