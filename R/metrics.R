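#' Mean center-of-mass swimming speed
#'
#' Average instantaneous center-of-mass speed over the analysis window
#' (default t = 6 s to 10 s, the steady portion of a 10 s run), in body lengths
#' per second.
#'
#' @param series A `kinematics_series` (or any list with `time`, `com`, `L`).
#' @param window Length-2 numeric window, s.
#' @return Speed, L/s.
#' @export
swimming_speed <- function(series, window = c(6, 10)) {
  t <- series$time
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9) {
    stop("series does not cover the averaging window", call. = FALSE)
  }
  com <- series$com
  n <- length(t)
  vx <- c(diff(com[, 1]), NA) / c(diff(t), NA)
  vy <- c(diff(com[, 2]), NA) / c(diff(t), NA)
  tm <- (t + c(t[-1], NA)) / 2
  keep <- which(tm >= window[1] & tm <= window[2])
  mean(sqrt(vx[keep]^2 + vy[keep]^2)) / series$L
}

#' Tailbeat amplitude and frequency
#'
#' The tail-tip transverse signal is detrended about its running mean (a
#' centered boxcar one estimated period wide, which removes any linear drift
#' exactly and leaves a sinusoid untouched); frequency is the reciprocal of
#' the mean interval between upward zero crossings, and amplitude is half
#' the peak-to-peak excursion over whole cycles, in body lengths. At least 3
#' full cycles must fall in the window.
#'
#' @param series A `kinematics_series` (needs `time`, `tail_y`, `L`).
#' @param window Analysis window, s; default the final 5 s of the series
#'   (the running-mean detrend consumes half a period at each end).
#' @return Named list: `amplitude` (L), `frequency` (Hz).
#' @export
tailbeat_metrics <- function(series, window = NULL) {
  t <- series$time
  if (is.null(window)) window <- c(max(max(t) - 5, min(t)), max(t))
  keep <- t >= window[1] & t <= window[2]
  tt <- t[keep]
  y_raw <- series$tail_y[keep]
  crossings <- function(y) {
    up <- which(y[-length(y)] < 0 & y[-1] >= 0)
    tt[up] - y[up] * (tt[up + 1] - tt[up]) / (y[up + 1] - y[up])
  }
  # first pass (coarse linear detrend) to estimate the period
  tc0 <- crossings(stats::residuals(stats::lm(y_raw ~ tt)))
  if (length(tc0) < 4) {
    stop("fewer than 3 full tailbeat cycles in the analysis window",
         call. = FALSE)
  }
  period <- mean(diff(tc0))
  half <- max(1L, round(period / mean(diff(tt)) / 2))
  n <- length(y_raw)
  cs <- c(0, cumsum(y_raw))
  valid <- (half + 1):(n - half)               # full boxcar windows only
  rm_mean <- (cs[valid + half + 1] - cs[valid - half]) / (2 * half + 1)
  y <- y_raw[valid] - rm_mean
  tt <- tt[valid]
  tc <- crossings(y)
  if (length(tc) < 4) {
    stop("fewer than 3 full tailbeat cycles in the analysis window",
         call. = FALSE)
  }
  frequency <- 1 / mean(diff(tc))
  span <- tt >= tc[1] & tt <= tc[length(tc)]   # whole cycles only
  amplitude <- (max(y[span]) - min(y[span])) / 2 / series$L
  list(amplitude = amplitude, frequency = frequency)
}

#' Duty cycle of a binary activation signal
#'
#' For each segment (and each side, when both are present) the on-fraction is
#' measured over the final `n_cycles` activation cycles, delimited by 0-to-1
#' onsets; results are averaged over segments and sides. A constant always-on
#' signal has duty cycle 1 by convention; a signal with no activity is an
#' error.
#'
#' @param activation An `activation_series` (or list with `time` and one or
#'   both of `sigma_left`, `sigma_right`).
#' @param n_cycles Number of steady cycles to average over (default 6).
#' @return Mean duty cycle, fraction of the period.
#' @export
duty_cycle <- function(activation, n_cycles = 6) {
  t <- activation$time
  sides <- Filter(Negate(is.null),
                  list(activation$sigma_left, activation$sigma_right))
  if (length(sides) == 0) stop("no activation signals present", call. = FALSE)
  seg_duty <- function(sig) {
    if (all(sig == 1)) return(1)
    if (all(sig == 0)) return(NA_real_)
    on <- which(diff(sig) == 1) + 1L
    if (length(on) < 2) return(NA_real_)
    n_use <- min(n_cycles, length(on) - 1)
    i0 <- on[length(on) - n_use]
    i1 <- on[length(on)]
    mean(sig[i0:(i1 - 1L)])
  }
  vals <- unlist(lapply(sides, function(S) apply(S, 2, seg_duty)))
  if (all(is.na(vals))) stop("no activation activity detected", call. = FALSE)
  mean(vals, na.rm = TRUE)
}

#' Neuromechanical phase lag profile
#'
#' For each body position and each side, pairs every peak of the side's
#' shortening curvature (positive curvature for the right side, negative for
#' the left) with the closest activation onset (0-to-1 transition; ties broken
#' toward the earlier onset) and normalizes the offset by the local activation
#' period: `phi = (t_act - t_curve) / (t_act_next - t_act)`. A positive value
#' means activation onset follows peak curvature (muscle active while
#' shortening). Peaks without a usable partner (no following onset to define
#' the local period, or the nearest onset more than half a period away) are
#' excluded with a warning.
#'
#' @param kappa n_t x n_s matrix of signed curvature at the oscillator
#'   positions.
#' @param activation List with `sigma_left` and/or `sigma_right` (n_t x n_s
#'   0/1 matrices) and `time`.
#' @param time Time vector (defaults to `activation$time`).
#' @param s_frac Body positions (fraction of L) for labeling.
#' @return A tibble with columns `s`, `side`, `cycle`, `phi`.
#' @export
phase_lag_profile <- function(kappa, activation, time = activation$time,
                              s_frac = NULL) {
  n_s <- ncol(kappa)
  if (is.null(s_frac)) s_frac <- seq_len(n_s) / n_s
  dropped <- 0L
  one_side <- function(sig, ksig, side) {
    out <- vector("list", n_s)
    for (j in seq_len(n_s)) {
      pk <- local_maxima(ksig[, j])
      on <- which(diff(sig[, j]) == 1) + 1L
      if (length(on) < 2 || length(pk) == 0) next
      t_on <- time[on]
      rows <- lapply(seq_along(pk), function(ci) {
        tc <- time[pk[ci]]
        dts <- abs(t_on - tc)
        cand <- which(dts == min(dts))
        i <- cand[1]                      # ties toward the earlier onset
        if (i >= length(t_on)) return(NULL)
        Tl <- t_on[i + 1] - t_on[i]
        # a peak whose nearest onset is more than half a period away has no
        # partner in the series (its true onset fell outside the window)
        if (abs(t_on[i] - tc) > 0.5 * Tl) return(NULL)
        data.frame(s = s_frac[j], side = side, cycle = ci,
                   phi = (t_on[i] - tc) / Tl)
      })
      keep <- !vapply(rows, is.null, logical(1))
      dropped <<- dropped + sum(!keep) ## nolint
      out[[j]] <- do.call(rbind, rows[keep])
    }
    do.call(rbind, out)
  }
  res <- list()
  if (!is.null(activation$sigma_left)) {
    res$left <- one_side(activation$sigma_left, -kappa, "left")
  }
  if (!is.null(activation$sigma_right)) {
    res$right <- one_side(activation$sigma_right, kappa, "right")
  }
  if (dropped > 0) {
    warning(dropped, " curvature peak(s) had no paired onset and were excluded")
  }
  tibble::as_tibble(do.call(rbind, res))
}

# indices of strict interior local maxima
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Activation and curvature wave speeds and their ratio
#'
#' The activation (neural) wave speed is `v_a = (d theta/dt) / (d theta/ds)`
#' from the unwrapped oscillator phases; the mechanical wave speed `V` is
#' computed the same way from the curvature phase, obtained as the angle of
#' the analytic signal (Hilbert transform along time at each position).
#' Derivatives are central differences; phase differences are evaluated on the
#' wrapped angles via `Arg(z1 * Conj(z2))`, which avoids global unwrapping.
#' Both speeds are reported as positive head-to-tail propagation speeds (the
#' raw temporal/spatial derivative ratio is negative for a head-to-tail wave
#' under this sign convention; the ratio of wave speeds is unaffected).
#'
#' Averages are taken over the body region `s_range` (fractions of L, default
#' 0.5 to 0.8) and the last `n_beats` tail beats (default 7).
#'
#' @param theta n_t x n_s matrix of unwrapped oscillator phases (one side).
#' @param kappa n_t x n_s matrix of curvature at the same positions.
#' @param time Uniformly spaced time vector, s.
#' @param s_frac Body positions as fractions of L (uniformly spaced).
#' @param L Body length, cm (speeds are returned in L/s).
#' @param s_range Body-fraction averaging window.
#' @param n_beats Number of trailing beats to average over.
#' @param period Beat period, s; estimated from the mean phase velocity if
#'   omitted.
#' @return List: `v_a`, `V` (L/s), `ratio` (`V / v_a`).
#' @export
wave_speeds <- function(theta, kappa, time, s_frac, L = 1,
                        s_range = c(0.5, 0.8), n_beats = 7, period = NULL) {
  dt <- diff(time); ds <- diff(s_frac)
  if (max(dt) - min(dt) > 1e-6 * mean(dt) ||
      max(ds) - min(ds) > 1e-6 * abs(mean(ds))) {
    stop("wave_speeds requires uniform sampling in time and position",
         call. = FALSE)
  }
  dt <- dt[1]; ds <- ds[1] * L                  # cm between samples
  n_t <- nrow(theta); n_s <- ncol(theta)
  ctr_t <- function(M) (M[3:n_t, , drop = FALSE] -
                          M[1:(n_t - 2), , drop = FALSE]) / (2 * dt)
  ctr_s <- function(M) (M[, 3:n_s, drop = FALSE] -
                          M[, 1:(n_s - 2), drop = FALSE]) / (2 * ds)
  trim <- function(M) M[2:(n_t - 1), 2:(n_s - 1), drop = FALSE]

  va_field <- -ctr_t(theta)[, 2:(n_s - 1)] / trim_rows(ctr_s(theta), n_t)
  z <- apply(kappa, 2, analytic_signal)
  dphi_t <- Arg(z[3:n_t, , drop = FALSE] *
                  Conj(z[1:(n_t - 2), , drop = FALSE])) / (2 * dt)
  dphi_s <- Arg(z[, 3:n_s, drop = FALSE] *
                  Conj(z[, 1:(n_s - 2), drop = FALSE])) / (2 * ds)
  V_field <- -dphi_t[, 2:(n_s - 1)] / trim_rows(dphi_s, n_t)

  if (is.null(period)) {
    period <- 2 * pi / mean((theta[n_t, ] - theta[1, ]) /
                              (time[n_t] - time[1]))
  }
  t_mid <- time[2:(n_t - 1)]
  s_mid <- s_frac[2:(n_s - 1)]
  sel_t <- t_mid >= max(time) - n_beats * abs(period)
  sel_s <- s_mid >= s_range[1] & s_mid <= s_range[2]
  va <- mean(va_field[sel_t, sel_s]) / L
  V <- mean(V_field[sel_t, sel_s]) / L
  list(v_a = va, V = V, ratio = V / va)
}

trim_rows <- function(M, n_t) M[2:(n_t - 1), , drop = FALSE]

# analytic signal of a real series via the frequency-domain Hilbert filter
analytic_signal <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Strouhal number
#'
#' `St = 2 f A / U`: the tail's side-to-side speed relative to the forward
#' speed. Units of `A` and `U` must be consistent (both in L or both in cm).
#'
#' @param f Tailbeat frequency, Hz.
#' @param A Tailbeat amplitude.
#' @param U Swimming speed.
#' @return Dimensionless Strouhal number.
#' @export
strouhal <- function(f, A, U) {
  if (any(U == 0)) stop("swimming speed is zero; Strouhal number undefined",
                        call. = FALSE)
  2 * f * A / U
}

#' Reynolds number of a swimmer
#'
#' `Re = rho * U * L / mu` with U in cm/s (a speed given in L/s is multiplied
#' by L).
#'
#' @param speed_L Swimming speed, L/s.
#' @param L Body length, cm.
#' @param rho Fluid density, g/cm^3.
#' @param mu Dynamic viscosity, g/(cm s).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(speed_L, L = 12.56, rho = 1, mu = 0.01) {
  rho * (speed_L * L) * L / mu
}

#' Cost of transport from muscle work
#'
#' Sums the positive mechanical work and a fraction `f_neg` of the absolute
#' value of the negative work done by all muscle segments over one full steady
#' cycle, divided by the cycle period and body mass. Mechanical power of a
#' segment is `-P * vc` (tension times shortening rate; shortening `vc < 0`
#' gives positive power). Optionally normalized by a control-case value.
#'
#' @param power n_t x n_seg matrix of instantaneous muscle power, erg/s
#'   (concatenate sides column-wise), or a list of such matrices.
#' @param time Time vector, s.
#' @param period Cycle period, s; the last full period of the series is used.
#' @param mass Body mass, g.
#' @param f_neg Weight of negative work (default 0.3).
#' @param control Control-case absolute cost of transport for normalization
#'   (optional).
#' @param normalize If `TRUE`, also return the ratio to `control`; an error if
#'   `control` is missing.
#' @return List: `absolute` (erg/(s g), i.e. work per period per unit period
#'   per unit mass) and `normalized` (if requested).
#' @export
cost_of_transport <- function(power, time, period, mass, f_neg = 0.3,
                              control = NULL, normalize = !is.null(control)) {
  if (is.list(power)) power <- do.call(cbind, power)
  keep <- time >= max(time) - period
  if (sum(keep) < 2) stop("series shorter than one cycle", call. = FALSE)
  dt <- diff(time[keep])
  pw <- power[keep, , drop = FALSE]
  pmid <- (pw[-1, , drop = FALSE] + pw[-nrow(pw), , drop = FALSE]) / 2
  Wpos <- sum(dt * rowSums(pmax(pmid, 0)))
  Wneg <- sum(dt * rowSums(pmax(-pmid, 0)))
  absolute <- (Wpos + f_neg * Wneg) / (period * mass)
  out <- list(absolute = absolute)
  if (normalize) {
    if (is.null(control)) {
      stop("control-case cost of transport required for normalized output",
           call. = FALSE)
    }
    out$normalized <- absolute / control
  }
  out
}

#' Body wavelength from curvature zero crossings
#'
#' At each analyzed time the distances between successive zero crossings of
#' the curvature along the body are averaged and doubled (a half-wave lies
#' between successive sign changes); the result is averaged over the window.
#'
#' @param kappa n_t x n_s curvature matrix.
#' @param s_frac Body positions, fraction of L.
#' @param time Time vector, s.
#' @param window Analysis window, s (default last 4 s).
#' @return Wavelength in units of L.
#' @export
body_wavelength <- function(kappa, s_frac, time, window = NULL) {
  if (is.null(window)) window <- c(max(time) - 4, max(time))
  rows <- which(time >= window[1] & time <= window[2])
  wl <- vapply(rows, function(i) {
    k <- kappa[i, ]
    zc <- which(k[-length(k)] * k[-1] < 0)
    if (length(zc) < 2) return(NA_real_)
    scr <- s_frac[zc] - k[zc] * (s_frac[zc + 1] - s_frac[zc]) /
      (k[zc + 1] - k[zc])
    2 * mean(diff(scr))
  }, numeric(1))
  mean(wl, na.rm = TRUE)
}
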