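#' Parameters of the calcium-gated Hill-type muscle model
#'
#' Each lateral muscle segment carries a kinetic model of calcium release and
#' binding gated by the binary CPG activation signal, a work-dependent
#' deactivation variable, and a Hill-type contractile element (CE) in series
#' with an elastic stretch element (SE).
#'
#' Calcium: free calcium `Cf` is released from the sarcoplasmic reticulum while
#' the segment is active and resequestered while inactive; bound calcium `Cb`
#' (nondimensionalized by the number of binding sites, so `0 <= Cb <= 1`)
#' scales the contractile force. The totals satisfy `Ssites > Ctot > 1` so the
#' muscle can be fully activated and the calcium fully sequestered within a
#' cycle. The rate constants are `k1 = sigma * kbar1`, `k2 = (1 - sigma) *
#' kbar2`, `k3 = kbar3 * m`, `k4 = kbar4 * m`, where `m` tracks the work done
#' in the current cycle (work-dependent deactivation).
#'
#' Force: `Pc = P0 * alpha(vc) * lambda(lc) * Cb`, scaled by the local taper
#' factor. `alpha` is a Hill force-velocity curve (hyperbolic in shortening,
#' shallow linear in lengthening) and `lambda` a quadratic, capped
#' length-tension curve; both are normalized to 1 at `vc = 0`, `lc = lc_rest`.
#' These shapes are re-fitted standard forms, not transcribed from a published
#' table, and are fully configurable here. Sign convention: shortening is
#' `vc < 0` (this makes `m` grow during loaded shortening).
#'
#' The SE transmits the force to the body nodes; its state is the transmitted
#' force `P`, advanced by `dP/dt = k_se * (vl - vc)` where `vl` is the segment
#' elongation rate, with `vc` obtained by inverting the Hill curve at the
#' force the SE currently demands. A skin spring (tension-only) and an optional
#' calcium-dependent passive stiffness act in parallel with the CE/SE pair.
#'
#' @param kbar1,kbar2,kbar3,kbar4 Baseline calcium rate constants, 1/s.
#' @param km1,km2 Work-deactivation rates (1/s; `km1` multiplies normalized
#'   power).
#' @param Ctot Total calcium (dimensionless, > 1).
#' @param Ssites Sequestering sites (dimensionless, > Ctot).
#' @param P0 Maximal tetanic force per segment, dyn.
#' @param vmax_rel Maximal shortening rate of the CE, in CE rest lengths per
#'   second (the CE force reaches 0 at `vc = -vmax_rel * lc0`).
#' @param hill_k Curvature of the shortening branch of the force-velocity
#'   relation (dimensionless; classic a/P0 ratio).
#' @param len_slope Slope of the lengthening branch, per unit relative
#'   velocity.
#' @param alpha_max Cap of the lengthening branch (force enhancement limit).
#' @param lt_beta Curvature of the quadratic length-tension relation.
#' @param k_se SE stiffness, dyn/cm.
#' @param k_skin Skin spring stiffness (tension-only), dyn/cm.
#' @param k_cb Calcium-dependent passive stiffness scale, dyn/cm (force
#'   `k_cb * Cb * (l - l0)`); set 0 to disable.
#' @param k_skin_comp Compression-side skin stiffness, dyn/cm (default 0: the
#'   skin resists extension only; reduced-scale overdamped runs set it equal
#'   to `k_skin` to stabilize lateral-element compression).
#' @param a_floor Activation product `lambda * Cb * taper` below which the CE
#'   is treated as slack (the SE force relaxes to zero); keeps the SE force
#'   dynamics non-stiff as the muscle shuts off.
#' @param p_off_rate Relaxation rate of the transmitted force when the CE is
#'   slack, 1/s.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(kbar1 = 9, kbar2 = 50, kbar3 = 40, kbar4 = 19.4,
                          km1 = 15, km2 = 10,
                          Ctot = 2, Ssites = 6,
                          P0 = 2e5,
                          vmax_rel = 4, hill_k = 0.25,
                          len_slope = 2, alpha_max = 1.5,
                          lt_beta = 4,
                          k_se = 2e7, k_skin = 2e4, k_cb = 2e3,
                          k_skin_comp = 0,
                          a_floor = 0.02, p_off_rate = 200) {
  if (!(Ssites > Ctot && Ctot > 1)) {
    stop("require Ssites > Ctot > 1", call. = FALSE)
  }
  stopifnot(kbar1 >= 0, kbar2 >= 0, kbar3 >= 0, kbar4 >= 0,
            km1 >= 0, km2 >= 0, P0 >= 0, vmax_rel > 0)
  structure(
    list(kbar1 = kbar1, kbar2 = kbar2, kbar3 = kbar3, kbar4 = kbar4,
         km1 = km1, km2 = km2, Ctot = Ctot, Ssites = Ssites,
         P0 = P0, vmax_rel = vmax_rel, hill_k = hill_k,
         len_slope = len_slope, alpha_max = alpha_max, lt_beta = lt_beta,
         k_se = k_se, k_skin = k_skin, k_cb = k_cb,
         k_skin_comp = k_skin_comp, a_floor = a_floor,
         p_off_rate = p_off_rate),
    class = "muscle_params"
  )
}

#' Calcium rate constants gated by activation and work
#'
#' `k1 = sigma * kbar1`, `k2 = (1 - sigma) * kbar2`, `k3 = kbar3 * m`,
#' `k4 = kbar4 * m`. Vectorized over segments.
#'
#' @param sigma Binary activation (0/1), vector.
#' @param m Work-deactivation variable (> 0), vector.
#' @param params A [muscle_params()] object.
#' @return List with components `k1`, `k2`, `k3`, `k4`.
#' @export
rate_constants <- function(sigma, m, params) {
  list(k1 = sigma * params$kbar1,
       k2 = (1 - sigma) * params$kbar2,
       k3 = params$kbar3 * m,
       k4 = params$kbar4 * m)
}

#' Time derivatives of free and bound calcium
#'
#' `dCf/dt = (k4*Cb - k3*Cf)*(1 - Cb) + k1*(C - Cf - Cb) + k2*(Cf*(C - S - Cf -
#' Cb))` and `dCb/dt = -(k4*Cb - k3*Cf)*(1 - Cb)`. With the sarcoplasmic
#' exchange off (`k1 = k2 = 0`) the sum `Cf + Cb` is conserved exactly, and the
#' `(1 - Cb)` factor keeps bound calcium at or below 1.
#'
#' @param Cf,Cb Free and bound calcium, vectors.
#' @param sigma Binary activation, vector.
#' @param m Work variable, vector.
#' @param params A [muscle_params()] object.
#' @return List with components `dCf`, `dCb`.
#' @export
calcium_derivatives <- function(Cf, Cb, sigma, m, params) {
  k <- rate_constants(sigma, m, params)
  ex <- (k$k4 * Cb - k$k3 * Cf) * (1 - Cb)
  dCf <- ex + k$k1 * (params$Ctot - Cf - Cb) +
    k$k2 * (Cf * (params$Ctot - params$Ssites - Cf - Cb))
  list(dCf = dCf, dCb = -ex)
}

#' Work-dependent deactivation dynamics
#'
#' `dm/dt = -km1 * Pc * vc` while shortening (`vc < 0`) and `-km2 * (m - 1)`
#' otherwise, so `m` grows with positive mechanical work and relaxes
#' exponentially back to 1. `Pc` is the CE force normalized by `P0` so that `m`
#' stays O(1).
#'
#' @param m Work variable, vector.
#' @param Pc Normalized contractile force (Pc/P0), vector.
#' @param vc CE velocity, cm/s (shortening negative), vector.
#' @param params A [muscle_params()] object.
#' @return `dm/dt`, vector.
#' @export
work_deactivation_derivative <- function(m, Pc, vc, params) {
  ifelse(vc < 0, -params$km1 * Pc * vc, -params$km2 * (m - 1))
}

#' Hill force-velocity factor alpha(vc)
#'
#' With `v = vc / (vmax_rel * lc0)` the relative CE velocity: hyperbolic in
#' shortening, `alpha = (1 + v) / (1 - v/hill_k)` for `-1 <= v < 0` (zero
#' below), and shallow linear in lengthening, `alpha = 1 + len_slope * v`,
#' capped at `alpha_max`. Continuous and monotone increasing, `alpha(0) = 1`.
#'
#' @param vc CE velocity, cm/s (shortening negative). Vectorized.
#' @param params A [muscle_params()] object.
#' @param lc0 CE rest length, cm.
#' @return Dimensionless force factor.
#' @export
hill_force_velocity <- function(vc, params, lc0) {
  v <- vc / (params$vmax_rel * lc0)
  out <- ifelse(v < 0,
                pmax(0, (1 + v) / (1 - v / params$hill_k)),
                pmin(params$alpha_max, 1 + params$len_slope * v))
  out
}

#' Length-tension factor lambda(lc)
#'
#' Quadratic, capped at zero: `lambda = max(0, 1 - lt_beta * ((lc - lc0)/lc0)^2)`
#' with `lambda(lc0) = 1`.
#'
#' @param lc CE length, cm. Vectorized.
#' @param lc0 CE rest length, cm.
#' @param params A [muscle_params()] object.
#' @return Dimensionless force factor.
#' @export
hill_length_tension <- function(lc, lc0, params) {
  pmax(0, 1 - params$lt_beta * ((lc - lc0) / lc0)^2)
}

#' Contractile force of a muscle segment
#'
#' `Pc = P0 * alpha(vc) * lambda(lc) * Cb`, multiplied by the taper factor
#' (ratio of local to maximal muscle cross-sectional area).
#'
#' @param vc CE velocity, cm/s.
#' @param lc CE length, cm.
#' @param Cb Bound calcium in `[0, 1]`.
#' @param taper Taper factor in (0, 1].
#' @param lc0 CE rest length, cm.
#' @param params A [muscle_params()] object.
#' @return Force, dyn. Vectorized.
#' @export
contractile_force <- function(vc, lc, Cb, taper, lc0, params) {
  stopifnot(all(taper > 0), all(taper <= 1))
  params$P0 * hill_force_velocity(vc, params, lc0) *
    hill_length_tension(lc, lc0, params) * Cb * taper
}

# Invert alpha(vc) = target for the CE velocity demanded by a given normalized
# force. Monotone piecewise closed form; floored at -vmax (free shortening).
# The lengthening branch is deliberately NOT capped: an overloaded or
# deactivating muscle yields quickly, which drives the transmitted SE force
# back toward zero instead of leaving a standing tension.
invert_hill <- function(target, params, lc0) {
  vmax <- params$vmax_rel * lc0
  kh <- params$hill_k
  out <- target * 0
  sh <- target < 1
  # (1 + v) = F (1 - v/kh)  =>  v = (F - 1) / (1 + F/kh), in units of vmax
  out[sh] <- pmax(-1, (target[sh] - 1) / (1 + target[sh] / kh)) * vmax[sh]
  ln <- !sh
  out[ln] <- ((target[ln] - 1) / params$len_slope) * vmax[ln]
  out
}

#' Initialize the per-segment muscle state for one side
#'
#' Segments start with all calcium sequestered (`Cf = Cb = 0` up to a small
#' floor), `m = 1`, CE at rest length, and zero transmitted force.
#'
#' @param n Number of active muscle segments.
#' @param lc0 CE rest lengths, cm (recycled to length n).
#' @return An object of class `muscle_state`: list of vectors `Cf`, `Cb`, `m`,
#'   `lc`, `vc`, `P` plus `lc0`.
#' @export
muscle_init <- function(n, lc0) {
  lc0 <- rep_len(lc0, n)
  structure(
    list(Cf = rep(0, n), Cb = rep(0, n), m = rep(1, n),
         lc = lc0, vc = rep(0, n), P = rep(0, n), lc0 = lc0),
    class = "muscle_state"
  )
}

# Derivatives of the full per-segment muscle state given frozen geometry.
# l, vl: current segment length and elongation rate (cm, cm/s).
muscle_derivs <- function(st, sigma, taper, vl, params) {
  lam <- hill_length_tension(st$lc, st$lc0, params)
  a_eff <- lam * st$Cb * taper
  act <- a_eff >= params$a_floor
  lc0 <- rep_len(st$lc0, length(st$P))
  vmax_abs <- params$vmax_rel * lc0
  vc <- invert_hill(pmax(st$P, 0) / (params$P0 * pmax(a_eff, params$a_floor)),
                    params, lc0)
  # bounded yielding: the CE cannot lengthen faster than a few vmax
  vc <- pmin(vc, 3 * vmax_abs)
  # below the activation floor the CE is slack: it recoils to rest length and
  # the SE force relaxes to zero instead of chasing the Hill inversion
  vc <- ifelse(act, vc, vl)
  dlc <- ifelse(act, vc, params$p_off_rate * (lc0 - st$lc))
  dP <- ifelse(act, params$k_se * (vl - vc), -params$p_off_rate * st$P)
  ca <- calcium_derivatives(st$Cf, st$Cb, sigma, st$m, params)
  Pc_norm <- pmax(st$P, 0) / params$P0
  list(dCf = ca$dCf, dCb = ca$dCb,
       dm = work_deactivation_derivative(st$m, Pc_norm, vc, params),
       dlc = dlc,
       dP = dP,
       vc = vc)
}

#' Advance the muscle states of one side by one time step (RK4)
#'
#' Geometry inputs (segment lengths and elongation rates) and activation are
#' held fixed over the step (explicit coupling to the body). The transmitted
#' force is clamped at zero from below (active muscle cannot push) and bound
#' calcium is clamped to `[0, 1]` against integrator round-off.
#'
#' @param st A `muscle_state`.
#' @param sigma Binary activation per segment.
#' @param taper Taper factors per segment.
#' @param l Segment lengths, cm.
#' @param vl Segment elongation rates, cm/s.
#' @param dt Time step, s.
#' @param params A [muscle_params()] object.
#' @return The advanced `muscle_state`.
#' @export
step_muscle <- function(st, sigma, taper, l, vl, dt, params) {
  take <- function(s, d, h) {
    structure(list(Cf = s$Cf + h * d$dCf, Cb = s$Cb + h * d$dCb,
                   m = s$m + h * d$dm, lc = s$lc + h * d$dlc,
                   vc = d$vc, P = s$P + h * d$dP, lc0 = s$lc0),
              class = "muscle_state")
  }
  k1 <- muscle_derivs(st, sigma, taper, vl, params)
  k2 <- muscle_derivs(take(st, k1, dt / 2), sigma, taper, vl, params)
  k3 <- muscle_derivs(take(st, k2, dt / 2), sigma, taper, vl, params)
  k4 <- muscle_derivs(take(st, k3, dt), sigma, taper, vl, params)
  comb <- function(f) (k1[[f]] + 2 * k2[[f]] + 2 * k3[[f]] + k4[[f]]) / 6
  out <- structure(
    list(Cf = pmax(st$Cf + dt * comb("dCf"), 0),
         Cb = pmin(pmax(st$Cb + dt * comb("dCb"), 0), 1),
         m = pmax(st$m + dt * comb("dm"), 1e-6),
         lc = pmin(pmax(st$lc + dt * comb("dlc"), 0.5 * st$lc0),
                   1.5 * st$lc0),
         vc = k1$vc,
         P = pmin(pmax(st$P + dt * comb("dP"), 0),
                  params$P0 * params$alpha_max),
         lc0 = st$lc0),
    class = "muscle_state"
  )
  if (!all(is.finite(out$P))) {
    stop("non-finite muscle force at segment ",
         which(!is.finite(out$P))[1], call. = FALSE)
  }
  out
}

#' Endpoint forces of the lateral muscle/skin elements
#'
#' Total element tension is the transmitted active force plus the tension-only
#' skin spring (`k_skin * max(0, l - l0)`) plus, when enabled, the
#' calcium-dependent passive stiffness (`k_cb * Cb * (l - l0)`). The force pair
#' is equal and opposite along the segment axis, so each element contributes
#' zero net force and torque.
#'
#' @param st A `muscle_state` (use `NULL` for purely passive segments: skin
#'   only).
#' @param p1,p2 n x 2 matrices of segment endpoint positions (cm), anterior and
#'   posterior.
#' @param l0 Rest lengths, cm.
#' @param params A [muscle_params()] object.
#' @return List with `f1`, `f2` (n x 2 endpoint force matrices, dyn; `f1 + f2 =
#'   0` rowwise) and `tension` (dyn, positive = pulling endpoints together).
#' @export
muscle_segment_force <- function(st, p1, p2, l0, params) {
  d <- p2 - p1
  l <- sqrt(rowSums(d^2))
  if (any(l == 0)) stop("zero-length muscle segment", call. = FALSE)
  u <- d / l
  ext <- l - l0
  tension <- params$k_skin * pmax(0, ext) + params$k_skin_comp * pmin(0, ext)
  if (!is.null(st)) {
    tension <- tension + pmax(st$P, 0) + params$k_cb * st$Cb * ext
  }
  f1 <- u * tension      # pulls p1 toward p2
  list(f1 = f1, f2 = -f1, tension = tension)
}

#' Muscle force taper factor along the body
#'
#' Total muscle force is proportional to physiological cross-sectional area.
#' Assuming elliptical cross-sections out of the plane with both axes
#' proportional to the local body width, area scales as width squared, so the
#' taper factor for lateral segment `i` is `(w_i / max(w))^2` evaluated at the
#' segment midpoint of the width profile.
#'
#' @param index Lateral segment index (1-based, head to tail), vectorized.
#' @param geometry A [build_body()] geometry (uses its `width` profile at
#'   lateral nodes).
#' @return Taper factor(s) in (0, 1].
#' @export
taper_factor <- function(index, geometry) {
  w <- geometry$width
  if (any(index < 1L | index > length(w) - 1L)) {
    stop("lateral segment index out of range", call. = FALSE)
  }
  wm <- (w[index] + w[index + 1L]) / 2
  (wm / max(w))^2
}
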