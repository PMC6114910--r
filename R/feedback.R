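#' Configuration of the curvature feedback pathway
#'
#' Proprioceptive stretch receptors (edge cells) sense body curvature and feed
#' an additive term into each oscillator's phase equation. Two functional forms
#' are supported:
#'
#' * `"magnitude"`: `eta(kappa_i) = gain * |kappa_i|`, identical on both sides.
#'   A symmetric excitatory (gain > 0) or inhibitory (gain < 0) drive; it speeds
#'   up or slows down the rhythm without changing left-right phasing. Sustained
#'   periodic swimming is documented for `|gain| < 0.09` cm rad/s.
#' * `"directional"`: `eta(kappa_i) = (-1)^k * gain * kappa_i` with k = 1 on the
#'   left side and k = 2 on the right, so positive curvature (a bend toward the
#'   right) with positive gain excites the right side and inhibits the left.
#'   Documented stable range `|gain| < 20` cm rad/s.
#' * `"none"`: the control case; gain is unused.
#'
#' Curvature is smoothed along the body with a boxcar of half-width
#' `smooth_halfwidth` segments before entering the feedback, and the last
#' `tail_silent_segments` oscillators receive no input.
#'
#' @param mode One of `"none"`, `"magnitude"`, `"directional"`.
#' @param gain Feedback gain, cm rad/s.
#' @param smooth_halfwidth Boxcar half-width, segments (default 5).
#' @param tail_silent_segments Number of tail segments silenced (default 5).
#' @return An object of class `feedback_config`.
#' @export
feedback_config <- function(mode = c("none", "magnitude", "directional"),
                            gain = 0,
                            smooth_halfwidth = 5L,
                            tail_silent_segments = 5L) {
  mode <- match.arg(mode)
  stopifnot(smooth_halfwidth >= 0, tail_silent_segments >= 0)
  structure(
    list(mode = mode, gain = gain,
         smooth_halfwidth = as.integer(smooth_halfwidth),
         tail_silent_segments = as.integer(tail_silent_segments)),
    class = "feedback_config"
  )
}

#' Range of gains with sustained periodic swimming
#'
#' Beyond these magnitudes phase velocities can become too large or (for
#' directional feedback) negative, so that a realistic propagating activation
#' signal is no longer produced.
#'
#' @param mode `"magnitude"` or `"directional"`.
#' @return The gain magnitude bound, cm rad/s (0.09 or 20).
#' @export
feedback_gain_range <- function(mode) {
  switch(mode,
         magnitude = 0.09,
         directional = 20,
         stop("no documented gain range for mode ", mode, call. = FALSE))
}

#' Signed curvature of an ordered 2D midline
#'
#' Computes `kappa = (x' y'' - y' x'') / ((x'^2 + y'^2)^(3/2))` with central
#' finite differences in the ordering parameter (one-sided differences at the
#' two endpoints). The result is parameterization-invariant up to
#' discretization error. Sign convention: with nodes ordered head to tail,
#' positive curvature bends toward the right lateral side, the side reached by
#' rotating the head-to-tail tangent by +90 degrees. For a body laid along +x
#' (head at the origin) with the right side at +y, a bend toward +y has
#' positive curvature.
#'
#' @param points An n x 2 matrix (or data frame with columns x, y) of midline
#'   coordinates in cm, ordered head to tail; n >= 5, consecutive points
#'   distinct.
#' @param presmooth Optional boxcar half-width (in samples) applied to the
#'   coordinates before differencing. Curvature involves second differences,
#'   which amplify sample-scale position noise by 1/h^2; simulated midlines
#'   with hundreds of nodes are therefore pre-smoothed before the per-segment
#'   curvature average. Default 0 (plain central differences).
#' @return An object of class `curvature_field`: list with `kappa` (1/cm, per
#'   sample) and `arclength` (cm, cumulative).
#' @export
midline_curvature <- function(points, presmooth = 0) {
  pts <- as.matrix(points[, 1:2])
  n <- nrow(pts)
  if (presmooth > 0) {
    win <- 2 * as.integer(presmooth) + 1L
    if (n > win + 2) {
      sm <- function(v) {
        cs <- c(0, cumsum(v))
        i <- seq_len(n)
        lo <- pmax(1L, i - as.integer(presmooth))
        hi <- pmin(n, i + as.integer(presmooth))
        (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
      }
      pts <- cbind(sm(pts[, 1]), sm(pts[, 2]))
    }
  }
  if (n < 5) stop("need at least 5 midline points", call. = FALSE)
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg == 0)) stop("coincident consecutive midline points", call. = FALSE)
  x <- pts[, 1]; y <- pts[, 2]
  d1 <- function(v) c(v[2] - v[1], (v[-(1:2)] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  d2 <- function(v) {
    int <- v[-(1:2)] - 2 * v[2:(n - 1)] + v[1:(n - 2)]
    c(int[1], int, int[n - 2])
  }
  xp <- d1(x); yp <- d1(y); xpp <- d2(x); ypp <- d2(y)
  kappa <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  structure(list(kappa = kappa, arclength = c(0, cumsum(seg))),
            class = "curvature_field")
}

#' Map and smooth midline curvature onto the oscillator chain
#'
#' Oscillator i (of `n_osc`, numbered head to tail over the active portion of
#' the body) is assigned the curvature at the midline arclength fraction of the
#' corresponding lateral muscle segment. The active chain starts after the
#' passive head (the first eighth of the lateral filament: `n_head` of
#' `n_lateral` segments). Each value is then replaced by the mean over segments
#' i-h..i+h (h = `config$smooth_halfwidth`), with the window truncated at the
#' anterior boundary, and the final `tail_silent_segments` entries are set to
#' zero.
#'
#' @param field A `curvature_field` from [midline_curvature()], or a bare
#'   numeric vector of per-sample curvature.
#' @param config A [feedback_config()].
#' @param n_osc Number of oscillators (default 280).
#' @param n_lateral Number of lateral muscle segments per side (default 320).
#' @return Numeric vector of length `n_osc`: smoothed per-oscillator curvature.
#' @export
segment_curvature <- function(field, config = feedback_config(),
                              n_osc = 280L, n_lateral = 320L) {
  kappa <- if (inherits(field, "curvature_field")) field$kappa else field
  n_mid <- length(kappa)
  if (n_osc > n_mid) stop("more oscillators than usable midline samples",
                          call. = FALSE)
  n_head <- n_lateral - n_osc
  # midline sample at the center of lateral segment i + n_head
  frac <- (seq_len(n_osc) + n_head - 0.5) / n_lateral
  idx <- pmin(n_mid, pmax(1L, round(1 + frac * (n_mid - 1))))
  k <- kappa[idx]
  h <- config$smooth_halfwidth
  if (h > 0) {
    cs <- c(0, cumsum(k))
    lo <- pmax(1L, seq_len(n_osc) - h)
    hi <- pmin(n_osc, seq_len(n_osc) + h)
    k <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  ts <- config$tail_silent_segments
  if (ts > 0) k[seq(n_osc - ts + 1L, n_osc)] <- 0
  k
}

#' Additive CPG feedback from per-oscillator curvature
#'
#' Applies the configured functional form to the smoothed curvature and returns
#' the per-side additive input for [phase_velocity()]. Magnitude mode returns
#' `gain * |kappa|` on both sides; directional mode returns `(-1)^k * gain *
#' kappa` (k = 1 left, k = 2 right), i.e. `-gain * kappa` on the left row and
#' `+gain * kappa` on the right row, so the directional signal is antisymmetric
#' across the body and sums to zero.
#'
#' @param kappa_i Per-oscillator curvature, 1/cm (length n).
#' @param config A [feedback_config()].
#' @return 2 x n matrix of feedback, rad/s (row 1 = left, row 2 = right).
#' @export
feedback_term <- function(kappa_i, config) {
  n <- length(kappa_i)
  switch(config$mode,
    none = matrix(0, 2, n),
    magnitude = {
      v <- config$gain * abs(kappa_i)
      rbind(v, v, deparse.level = 0)
    },
    directional = rbind(-config$gain * kappa_i,
                        +config$gain * kappa_i, deparse.level = 0),
    stop("unknown feedback mode: ", config$mode, call. = FALSE)
  )
}
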