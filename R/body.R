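#' Build the three-filament discretized lamprey body
#'
#' The body is three filaments: a stiff midline of `n_mid_seg` segments (641
#' nodes by default) and two lateral filaments of `n_lat_seg` segments (321
#' nodes each), laid straight along +x with the head at the origin and the
#' right lateral side at +y. Lateral node j sits at the position of midline
#' node `2j - 1`, offset by half the local body width. The width profile rises
#' as a quarter-ellipse over lateral points 1-20 to its maximum of
#' `w_max_frac * L` (10% of body length) at point 20, then tapers linearly to
#' `w_tail_frac * L` (0.1%) at the last point. The first eighth of the body
#' (lateral segments 1-40 by default) is a passive head with no muscle.
#'
#' Passive elasticity is a network of Hookean springs: midline links between
#' consecutive midline nodes, transverse crosslinks from each lateral node to
#' its midline node, and diagonal crosslinks to the neighboring midline nodes
#' (nearest and next-nearest attachment, so each lateral node is tied to every
#' other midline node). Lateral longitudinal elements are the muscle/skin
#' units handled by [muscle_segment_force()]. Spring constants are a single
#' stiffness scale `k0` times per-class factors, divided by the rest length of
#' each link; `k0` is calibrated (linearly, see
#' [bending_stiffness_check()]) so that the macroscopic bending stiffness of
#' the network matches `E_target` (0.76 MPa by default). `stiffness_scale`
#' rescales the calibrated network afterwards, for reduced-stiffness desk runs.
#'
#' @param L Body length, cm.
#' @param n_mid_seg,n_lat_seg Midline / lateral segment counts.
#' @param E_target Target macroscopic bending stiffness, MPa.
#' @param muscle A [muscle_params()] (its skin spring enters the calibration).
#' @param stiffness_scale Multiplier applied to the calibrated passive spring
#'   constants (1 = full stiffness).
#' @param k_mid_factor,k_cross_factor,k_diag_factor Relative stiffness of the
#'   three passive link classes (midline links much stiffer: near-inextensible).
#' @param w_max_frac,w_tail_frac Maximum and tail width, fractions of L.
#' @param w_bend_floor_frac Width floor (fraction of L) used only for the
#'   bending stiffness profile of the reduced (beam) backend; the geometric
#'   width still tapers to `w_tail_frac`. Default 0 (no floor).
#' @param head_points Lateral points over which the elliptical head widens.
#' @param rho_body Body density, g/cm^3 (neutrally buoyant: 1).
#' @return An object of class `body_geometry`.
#' @export
build_body <- function(L = 12.56, n_mid_seg = 640L, n_lat_seg = 320L,
                       E_target = 0.76, muscle = muscle_params(),
                       stiffness_scale = 1,
                       k_mid_factor = 20, k_cross_factor = 1,
                       k_diag_factor = 1,
                       w_max_frac = 0.1, w_tail_frac = 0.001,
                       w_bend_floor_frac = 0,
                       head_points = 20L, rho_body = 1) {
  stopifnot(L > 0, n_mid_seg %% 2 == 0, n_lat_seg == n_mid_seg / 2)
  n_mid <- n_mid_seg + 1L
  n_lat <- n_lat_seg + 1L

  # width profile at lateral points: quarter-ellipse head, then linear taper
  j <- seq_len(n_lat)
  w_max <- w_max_frac * L
  w_tail <- w_tail_frac * L
  width <- ifelse(
    j <= head_points,
    w_max * sqrt(pmax(0, 1 - ((head_points - j) / (head_points - 1))^2)),
    w_max + (j - head_points) / (n_lat - head_points) * (w_tail - w_max)
  )
  width <- pmax(width, w_tail)   # keep the head tip from degenerating to a point

  s_mid <- (seq_len(n_mid) - 1) * L / n_mid_seg
  mid <- cbind(x = s_mid, y = 0)
  lat_mid_idx <- 2L * j - 1L              # midline node carrying lateral node j
  lat_x <- s_mid[lat_mid_idx]
  right <- cbind(x = lat_x, y = width / 2)
  left <- cbind(x = lat_x, y = -width / 2)

  # global node indexing: midline, then left, then right
  i_mid <- seq_len(n_mid)
  i_left <- n_mid + seq_len(n_lat)
  i_right <- n_mid + n_lat + seq_len(n_lat)
  X0 <- rbind(mid, left, right)

  link <- function(from, to, class) {
    data.frame(from = from, to = to, class = class)
  }
  links <- rbind(
    link(i_mid[-n_mid], i_mid[-1], "mid"),
    # next-nearest midline links: straight at rest, their energy grows with
    # the fourth power of a kink angle, so they guard against local folding
    # without adding linear bending stiffness (the E calibration is unchanged)
    link(i_mid[1:(n_mid - 2L)], i_mid[3:n_mid], "mid2"),
    link(i_left, i_mid[lat_mid_idx], "cross"),
    link(i_right, i_mid[lat_mid_idx], "cross"),
    # diagonals to neighboring attachment points (next-nearest midline nodes)
    link(i_left[j > 1], i_mid[lat_mid_idx[j > 1] - 2L], "diag"),
    link(i_left[j < n_lat], i_mid[lat_mid_idx[j < n_lat] + 2L], "diag"),
    link(i_right[j > 1], i_mid[lat_mid_idx[j > 1] - 2L], "diag"),
    link(i_right[j < n_lat], i_mid[lat_mid_idx[j < n_lat] + 2L], "diag")
  )
  l0 <- sqrt(rowSums((X0[links$to, ] - X0[links$from, ])^2))
  # transverse crosslinks at the head tip can have near-zero rest length;
  # floor at one midline spacing for the 1/l0 stiffness normalization
  l0_eff <- pmax(l0, L / n_mid_seg)
  factor <- c(mid = k_mid_factor, mid2 = k_mid_factor,
              cross = k_cross_factor, diag = k_diag_factor)[links$class]

  geom <- structure(
    list(L = L, n_mid_seg = n_mid_seg, n_lat_seg = n_lat_seg,
         n_nodes = nrow(X0), X0 = X0, width = width,
         i_mid = i_mid, i_left = i_left, i_right = i_right,
         lat_mid_idx = lat_mid_idx,
         links = links, l0 = l0, k_factor_over_l0 = factor / l0_eff,
         k0 = 1,
         head_segments = n_lat_seg / 8L,
         n_active = n_lat_seg - n_lat_seg / 8L,
         # lateral longitudinal (muscle/skin) elements
         lat_l0 = sqrt(diff(lat_x)^2 + (diff(width) / 2)^2),
         w_bend_floor = w_bend_floor_frac * L,
         E_target = E_target,
         mass = rho_body * sum((width[-n_lat] + width[-1]) / 2 *
                                 diff(lat_x))),
    class = "body_geometry"
  )
  geom$taper <- taper_factor(seq_len(n_lat_seg), geom)

  # calibrate k0: network energy under a small imposed bend is linear in k0
  kappa_t <- 0.5 / L
  U_skin <- bent_energy(geom, muscle, kappa_t, passive = FALSE)
  geom$k0 <- 1
  U_net1 <- bent_energy(geom, muscle, kappa_t, skin = FALSE)
  Isum <- second_moment_integral(geom)
  U_target <- 0.5 * (E_target * 1e7) * kappa_t^2 * Isum
  k0 <- (U_target - U_skin) / U_net1
  if (!is.finite(k0) || k0 <= 0) stop("stiffness calibration failed",
                                      call. = FALSE)
  geom$k0 <- k0 * stiffness_scale
  geom$stiffness_scale <- stiffness_scale
  geom
}

# integral of the area moment of inertia I(s) ds over the body, cm^4 * cm.
# Cross-sections are taken circular with diameter equal to the local width
# (the elliptical out-of-plane axis is set equal to the in-plane one).
second_moment_integral <- function(geom) {
  w <- geom$width
  ds <- geom$L / geom$n_lat_seg
  I <- pi / 4 * (w / 2)^4
  sum((I[-length(I)] + I[-1]) / 2) * ds
}

# Map the rest geometry onto a circular arc of curvature kappa (bend toward
# the right, +y) and return the spring-network elastic energy, dyn*cm.
bent_energy <- function(geom, muscle, kappa, passive = TRUE, skin = TRUE) {
  R <- 1 / kappa
  s <- geom$X0[, 1]               # rest arclength coordinate of every node
  off <- geom$X0[, 2]             # signed normal offset (right positive)
  # arc center at (0, R): tangent t(s), inward normal toward center
  Xb <- cbind(x = (R - off) * sin(s / R),
              y = R - (R - off) * cos(s / R))
  U <- 0
  if (passive) {
    d <- Xb[geom$links$to, ] - Xb[geom$links$from, ]
    l <- sqrt(rowSums(d^2))
    U <- U + sum(0.5 * geom$k0 * geom$k_factor_over_l0 * (l - geom$l0)^2)
  }
  if (skin) {
    for (side in list(geom$i_left, geom$i_right)) {
      p <- Xb[side, , drop = FALSE]
      l <- sqrt(rowSums(diff(p)^2))
      ext <- l - geom$lat_l0
      U <- U + sum(0.5 * muscle$k_skin * pmax(0, ext)^2) +
        sum(0.5 * muscle$k_skin_comp * pmin(0, ext)^2)
    }
  }
  U
}

#' Initialize the body state at rest
#'
#' Places the rest geometry at an offset (the swimmer is conventionally started
#' toward the right of the fluid domain, since it swims toward -x), with zero
#' node velocities and all elastic linkages at rest length.
#'
#' @param geometry A [build_body()] geometry.
#' @param origin Length-2 numeric: displacement added to all rest positions, cm.
#' @return An object of class `body_state`: list with `X` (n_nodes x 2
#'   positions, cm) and `V` (velocities, cm/s).
#' @export
body_init <- function(geometry, origin = c(0, 0)) {
  X <- geometry$X0
  X[, 1] <- X[, 1] + origin[1]
  X[, 2] <- X[, 2] + origin[2]
  structure(list(X = X, V = matrix(0, nrow(X), 2)), class = "body_state")
}

#' Passive Hookean forces of the body spring network
#'
#' Linear springs (no damping; the surrounding viscous fluid provides the
#' damping) along the midline links and the transverse/diagonal crosslinks.
#' Skin and muscle forces on the lateral longitudinal elements are handled by
#' [muscle_segment_force()]. Rigid translations and the rest configuration
#' produce zero force.
#'
#' @param state A `body_state`.
#' @param geometry A [build_body()] geometry.
#' @param damping_beta Stiffness-proportional damping time constant, s: each
#'   link adds a tension `beta * k * d(length)/dt` computed from `state$V`.
#'   Default 0 (pure Hookean springs, as in the full-scale model); used as a
#'   numerical stabilizer for the fast constraint modes in reduced-scale runs.
#' @return n_nodes x 2 matrix of node forces, dyn (class `lagrangian_forces`).
#' @export
passive_elastic_forces <- function(state, geometry, damping_beta = 0) {
  lk <- geometry$links
  F <- link_forces_cpp(state$X, lk$from, lk$to,
                       geometry$k0 * geometry$k_factor_over_l0,
                       geometry$l0, geometry$n_nodes,
                       if (damping_beta > 0) state$V else NULL, damping_beta)
  structure(F, class = c("lagrangian_forces", class(F)))
}

# scatter-add v into a length-n accumulator at (possibly repeated) indices
accumulate_at <- function(v, idx, n) {
  accum_cpp(as.integer(idx), as.numeric(v), as.integer(n))
}

#' Sum passive and active Lagrangian forces
#'
#' Elementwise sum of force fields on the same node indexing. Because every
#' elastic and muscular element produces an equal-and-opposite force pair, the
#' assembled field has zero total force and zero total torque (to rounding);
#' both sums are attached as attributes for assertion.
#'
#' @param passive n x 2 force matrix (e.g. from [passive_elastic_forces()]).
#' @param ... Further n x 2 force matrices to add.
#' @param positions Optional n x 2 node positions used for the torque sum.
#' @return n x 2 matrix of class `lagrangian_forces` with attributes
#'   `total_force` (length 2) and `total_torque` (scalar, about the centroid;
#'   `NA` when positions are not supplied).
#' @export
assemble_forces <- function(passive, ..., positions = NULL) {
  F <- passive
  for (extra in list(...)) {
    if (!all(dim(extra) == dim(F))) stop("force field shape mismatch",
                                         call. = FALSE)
    F <- F + extra
  }
  tf <- colSums(F)
  tq <- NA_real_
  if (!is.null(positions)) {
    ctr <- colMeans(positions)
    tq <- sum((positions[, 1] - ctr[1]) * F[, 2] -
                (positions[, 2] - ctr[2]) * F[, 1])
  }
  structure(F, class = c("lagrangian_forces", "matrix", "array"),
            total_force = tf, total_torque = tq)
}

#' Macroscopic bending stiffness of the body network
#'
#' Estimates the effective Young's modulus E by bending the rest geometry onto
#' a circular arc of small curvature, evaluating the spring-network elastic
#' energy U (Hookean links plus the tension-only skin on the stretched side),
#' and identifying it with the linear-beam energy `U = E/2 * kappa^2 *
#' integral(I(s) ds)`, where I(s) is the area moment of the local cross-section
#' (circular with diameter equal to the body width). For a linear network this
#' matches the static end-moment experiment without an iterative solve.
#'
#' @param geometry A [build_body()] geometry.
#' @param muscle A [muscle_params()] (skin stiffness).
#' @param kappa Test curvature, 1/cm (small; default half the body-length
#'   curvature scale).
#' @return Effective bending stiffness, MPa.
#' @export
bending_stiffness_check <- function(geometry, muscle = muscle_params(),
                                    kappa = 0.5 / geometry$L) {
  U <- bent_energy(geometry, muscle, kappa)
  E_cgs <- 2 * U / (kappa^2 * second_moment_integral(geometry))
  E_cgs / 1e7
}

# Geometry of the lateral longitudinal elements on one side: endpoint indices,
# current lengths and elongation rates.
lateral_segments <- function(state, geometry, side = c("left", "right")) {
  side <- match.arg(side)
  idx <- if (side == "left") geometry$i_left else geometry$i_right
  from <- idx[-length(idx)]
  to <- idx[-1]
  d <- state$X[to, , drop = FALSE] - state$X[from, , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  dv <- state$V[to, , drop = FALSE] - state$V[from, , drop = FALSE]
  vl <- rowSums(d * dv) / l
  list(from = from, to = to, l = l, vl = vl,
       p1 = state$X[from, , drop = FALSE], p2 = state$X[to, , drop = FALSE])
}
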