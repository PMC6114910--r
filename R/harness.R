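#' Assemble a full simulation configuration
#'
#' Collects the module configurations and run settings into one validated
#' object. The defaults are the full-fidelity study conditions: 10 s of
#' simulated time, a 7.5 L x 3.0 L fluid domain, water density and viscosity
#' in cgs units, full body stiffness (E = 0.76 MPa), and the control (no
#' feedback) CPG. Feedback gains outside the documented stable ranges are
#' rejected unless `allow_gain_overrange` is set.
#'
#' @param cpg A [cpg_params()].
#' @param feedback A [feedback_config()].
#' @param muscle A [muscle_params()].
#' @param body List of [build_body()] arguments (e.g. `L`, `E_target`,
#'   `stiffness_scale`).
#' @param fluid List: `backend` ("ib" or "resistive"), `nx` (cells across the
#'   domain length), `domain` (extent in body lengths), `rho`, `mu`,
#'   `mu_scale` (viscosity multiplier for reduced-Reynolds demo runs),
#'   `c_drag` (resistive backend tangential drag, dyn s/cm), `c_aniso`
#'   (normal-to-tangential drag ratio; 2 by default, the slender-body value
#'   that lets the resistive backend produce net propulsion).
#' @param run List: `duration` (s), `dt` (s), `record_every` (steps per output
#'   frame), `substeps` (inner body/fluid substeps per neural/muscle step, for
#'   the fast constraint modes of the spring network), `init_perturb` (rad),
#'   `seed`, `start` (body center as fractions of the domain extent).
#' @param allow_gain_overrange Allow feedback gains outside the documented
#'   stable range.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(cpg = cpg_params(),
                              feedback = feedback_config(),
                              muscle = muscle_params(),
                              body = list(),
                              fluid = list(),
                              run = list(),
                              allow_gain_overrange = FALSE) {
  stopifnot(inherits(cpg, "cpg_params"), inherits(feedback, "feedback_config"),
            inherits(muscle, "muscle_params"))
  body <- utils::modifyList(
    list(L = 12.56, E_target = 0.76, stiffness_scale = 1), body)
  fluid <- utils::modifyList(
    list(backend = "ib", nx = 256L, domain = c(7.5, 3.0),
         rho = 1, mu = 0.01, mu_scale = 1, c_drag = 50, c_aniso = 2), fluid)
  run <- utils::modifyList(
    list(duration = 10, dt = 1e-3, record_every = 20L, substeps = 1L,
         init_perturb = 0, seed = NULL, start = c(0.72, 0.5)), run)
  stopifnot(fluid$backend %in% c("ib", "resistive"),
            run$duration > 0, run$dt > 0)
  if (feedback$mode != "none" && !allow_gain_overrange) {
    rng <- feedback_gain_range(feedback$mode)
    if (abs(feedback$gain) >= rng) {
      stop(sprintf(paste0("feedback gain %.3g is outside the documented ",
                          "stable range |gain| < %g for %s feedback ",
                          "(set allow_gain_overrange = TRUE to force)"),
                   feedback$gain, rng, feedback$mode), call. = FALSE)
    }
  }
  structure(list(cpg = cpg, feedback = feedback, muscle = muscle,
                 body = body, fluid = fluid, run = run),
            class = "simulation_config")
}

#' Reduced-scale configuration for desk-top closed-loop runs
#'
#' The full study conditions (an E = 0.76 MPa body in water on an effectively
#' 512-cell Navier-Stokes grid for 10 s) are cluster-scale. This helper
#' returns the package's documented desk-scale regime: the overdamped
#' midline-beam body backend (muscle tensions act as bending-moment couples on
#' a discrete elastic beam that relaxes against a local drag), a softer body
#' (E = 1e-4 MPa), proportionally weaker muscle, a thicker structural tail,
#' and 1 ms time steps. The CPG, curvature feedback and calcium/muscle
#' kinetics run at their full parameters. Neural quantities (tailbeat
#' frequency, duty cycle, and their responses to feedback gain) are robust to
#' this reduction; emergent hydrodynamic magnitudes (speed, amplitude,
#' Strouhal number) are not claimed at this scale.
#'
#' @param feedback A [feedback_config()].
#' @param duration Simulated time, s (default 6).
#' @param backend `"resistive"` (the overdamped beam backend; default) or
#'   `"ib"`.
#' @param nx Fluid cells across the domain length (IB backend only).
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
reduced_config <- function(feedback = feedback_config(), duration = 6,
                           backend = "resistive", nx = 120L, ...) {
  simulation_config(
    feedback = feedback,
    muscle = muscle_params(P0 = 60, k_se = 9000, k_skin = 0, k_cb = 0),
    body = list(E_target = 1e-4, w_tail_frac = 0.02,
                w_bend_floor_frac = 0.05),
    fluid = list(backend = backend, nx = nx, mu_scale = 100, c_drag = 0.03),
    run = list(duration = duration, dt = 1e-3, record_every = 10L,
               substeps = if (backend == "ib") 8L else 1L),
    ...
  )
}

#' Run the closed-loop simulation
#'
#' Executes the feedback loop: per time step, (1) midline curvature is
#' computed from the body state and smoothed onto the oscillators, (2) mapped
#' to additive feedback, (3) the CPG phases advance, (4) activation is
#' thresholded, (5) calcium/muscle states advance and produce forces, (6)
#' passive and active forces are assembled, and (7) the fluid backend turns
#' forces into node motion. The body starts straight at rest in a quiescent
#' fluid with all linkages at rest length.
#'
#' The run aborts with a diagnostic if phase velocities stay negative for more
#' than half a second (feedback gain outside the workable range) or if the
#' state stops being finite (numerical blow-up; the error reports the last
#' completed time).
#'
#' @param config A [simulation_config()].
#' @param verbose Print progress every simulated second.
#' @return A list of class `simulation_result`: `trajectory` (a
#'   [trajectory_record()]) and `metrics` (a [metrics_report()]).
#' @export
run_simulation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  rn <- config$run
  if (!is.null(rn$seed)) set.seed(rn$seed)

  geom <- do.call(build_body, c(config$body, list(muscle = config$muscle)))
  L <- geom$L
  fl <- config$fluid
  use_ib <- fl$backend == "ib"
  nm <- geom$n_mid_seg + 1L
  if (use_ib) {
    grid <- fluid_grid(fl$domain[1] * L, fl$domain[2] * L, fl$nx,
                       rho = fl$rho, mu = fl$mu * fl$mu_scale)
    fluid <- fluid_init(grid)
    origin <- c(rn$start[1] * grid$Lx - L / 2, rn$start[2] * grid$Ly)
  } else {
    origin <- c(0, 0)
    # overdamped midline-beam backend: the midline carries axial springs
    # (E A / l per link) and a discrete bending stiffness B(s) = E I(s);
    # muscle tensions act as bending-moment couples, so the chain cannot be
    # put under axial compression by the muscle (no buckling channel)
    E_cgs <- geom$E_target * 1e7
    w_mid <- stats::approx(seq(1, nm, by = 2), geom$width,
                           xout = seq_len(nm))$y
    l_bar <- L / geom$n_mid_seg
    w_bend <- pmax(w_mid, geom$w_bend_floor)
    B_over_l <- E_cgs * pi / 4 * (w_bend[2:(nm - 1)] / 2)^4 / l_bar
    EA <- E_cgs * pi * (w_mid / 2)^2
    mid_from <- 1:(nm - 1); mid_to <- 2:nm
    k_mid <- (EA[mid_from] + EA[mid_to]) / 2 / l_bar
    mid2_from <- 1:(nm - 2); mid2_to <- 3:nm
    k_mid2 <- EA[2:(nm - 1)] / (2 * l_bar)
    geomO <- list(
      links = list(from = c(mid_from, mid2_from), to = c(mid_to, mid2_to)),
      k0 = 1,
      k_factor_over_l0 = c(k_mid, k_mid2),
      l0 = c(rep(l_bar, nm - 1), rep(2 * l_bar, nm - 2)),
      n_nodes = nm)
    # per-segment moment arms and the (1/4, 1/2, 1/4) spread of each muscle
    # segment's moment onto the midline nodes it straddles
    w_seg <- (geom$width[-length(geom$width)] + geom$width[-1]) / 2
  }
  body <- body_init(geom, origin)
  Xm <- body$X[geom$i_mid, , drop = FALSE]
  cpg <- cpg_init(config$cpg, perturb = rn$init_perturb)
  n_act <- geom$n_active
  act_seg <- geom$head_segments + seq_len(n_act)   # lateral segment indices
  lc0_act <- geom$lat_l0[act_seg]
  mus <- list(left = muscle_init(n_act, lc0_act),
              right = muscle_init(n_act, lc0_act))
  taper_act <- geom$taper[act_seg]
  ds_node <- c(rep(L / geom$n_mid_seg, geom$n_mid_seg + 1),
               rep(L / geom$n_lat_seg, 2 * (geom$n_lat_seg + 1)))

  # lateral node positions; for the beam backend they are reconstructed from
  # the midline (offset w/2 along the node normal, right side at +normal)
  lateral_positions <- function(Xm) {
    m_idx <- geom$lat_mid_idx
    nmn <- nrow(Xm)
    im <- pmin(m_idx + 1L, nmn); il <- pmax(m_idx - 1L, 1L)
    tx <- Xm[im, 1] - Xm[il, 1]; ty <- Xm[im, 2] - Xm[il, 2]
    tl <- sqrt(tx^2 + ty^2)
    nxv <- -ty / tl; nyv <- tx / tl
    half <- geom$width / 2
    list(left = cbind(Xm[m_idx, 1] - nxv * half, Xm[m_idx, 2] - nyv * half),
         right = cbind(Xm[m_idx, 1] + nxv * half, Xm[m_idx, 2] + nyv * half))
  }
  seg_lengths <- function(P) sqrt(rowSums(diff(P)^2))
  lat_prev <- NULL   # previous lateral segment lengths, for elongation rates

  n_steps <- as.integer(round(rn$duration / rn$dt))
  rec_every <- as.integer(rn$record_every)
  n_frames <- length(seq(0L, n_steps, by = rec_every))
  n <- config$cpg$n_seg
  alloc <- function(nc) matrix(NA_real_, n_frames, nc)
  out <- list(time = alloc(1), com = alloc(2), tail_y = alloc(1),
              body_x = alloc(geom$n_nodes), body_y = alloc(geom$n_nodes),
              theta_left = alloc(n), theta_right = alloc(n),
              sigma_left = alloc(n), sigma_right = alloc(n),
              kappa = alloc(n),
              P_left = alloc(n_act), P_right = alloc(n_act),
              vc_left = alloc(n_act), vc_right = alloc(n_act),
              Cb_left = alloc(n_act), Cb_right = alloc(n_act),
              Cf_left = alloc(n_act), Cf_right = alloc(n_act),
              m_left = alloc(n_act), m_right = alloc(n_act))
  od_cache <- new.env(parent = emptyenv())
  od_cache$tol <- 0.05 * L / geom$n_mid_seg   # node motion before J rebuild
  neg_streak <- 0
  row <- 1L
  kappa_i <- numeric(n)
  sigma <- matrix(0L, 2, n)

  record <- function(t) {
    if (use_ib) {
      Xfull <- body$X
    } else {
      lp <- lateral_positions(Xm)
      Xfull <- rbind(Xm, lp$left, lp$right)
    }
    out$time[row, ] <<- t
    out$com[row, ] <<- colMeans(Xfull[geom$i_mid, ])
    out$tail_y[row, ] <<- Xfull[geom$i_mid[nm], 2]
    out$body_x[row, ] <<- Xfull[, 1]
    out$body_y[row, ] <<- Xfull[, 2]
    out$theta_left[row, ] <<- cpg$theta[1, ]
    out$theta_right[row, ] <<- cpg$theta[2, ]
    out$sigma_left[row, ] <<- sigma[1, ]
    out$sigma_right[row, ] <<- sigma[2, ]
    out$kappa[row, ] <<- kappa_i
    for (sd in c("left", "right")) {
      out[[paste0("P_", sd)]][row, ] <<- mus[[sd]]$P
      out[[paste0("vc_", sd)]][row, ] <<- mus[[sd]]$vc
      out[[paste0("Cb_", sd)]][row, ] <<- mus[[sd]]$Cb
      out[[paste0("Cf_", sd)]][row, ] <<- mus[[sd]]$Cf
      out[[paste0("m_", sd)]][row, ] <<- mus[[sd]]$m
    }
    row <<- row + 1L
  }

  for (step in 0:n_steps) {
    # (1) curvature -> oscillators
    Xmid <- if (use_ib) body$X[geom$i_mid, , drop = FALSE] else Xm
    cf <- midline_curvature(Xmid, presmooth = 6)
    kappa_i <- segment_curvature(cf, config$feedback,
                                 n_osc = n, n_lateral = geom$n_lat_seg)
    sigma <- activation_from_phase(cpg, params = config$cpg)
    if (step %% rec_every == 0L) record(step * rn$dt)
    if (step == n_steps) break

    # (2) feedback, (3) CPG
    fb <- feedback_term(kappa_i, config$feedback)
    theta_old <- cpg$theta
    cpg <- step_cpg(cpg, fb, rn$dt, config$cpg)
    if (min(cpg$theta - theta_old) < 0) {
      neg_streak <- neg_streak + 1
      if (neg_streak * rn$dt > 0.5) {
        stop(paste0("sustained negative phase velocities: feedback gain out ",
                    "of the workable range; no realistic activation signal ",
                    "can propagate"), call. = FALSE)
      }
    } else {
      neg_streak <- 0
    }
    sigma <- activation_from_phase(cpg, params = config$cpg)

    # (4)+(5) muscle geometry and state update (geometry frozen over the step)
    if (use_ib) {
      lat_l <- list(left = lateral_segments(body, geom, "left"),
                    right = lateral_segments(body, geom, "right"))
      lens <- list(left = lat_l$left$l, right = lat_l$right$l)
      vls <- list(left = lat_l$left$vl, right = lat_l$right$vl)
    } else {
      lp <- lateral_positions(Xm)
      lens <- list(left = seg_lengths(lp$left), right = seg_lengths(lp$right))
      if (is.null(lat_prev)) lat_prev <- lens
      vls <- list(left = (lens$left - lat_prev$left) / rn$dt,
                  right = (lens$right - lat_prev$right) / rn$dt)
      lat_prev <- lens
    }
    sided <- list()
    for (k in 1:2) {
      sd <- c("left", "right")[k]
      mus[[sd]] <- step_muscle(mus[[sd]], sigma[k, ], taper_act,
                               lens[[sd]][act_seg], vls[[sd]][act_seg],
                               rn$dt, config$muscle)
      full_state <- list(P = numeric(geom$n_lat_seg),
                         Cb = numeric(geom$n_lat_seg))
      full_state$P[act_seg] <- mus[[sd]]$P
      full_state$Cb[act_seg] <- mus[[sd]]$Cb
      sided[[sd]] <- full_state
    }

    # (6)+(7) force assembly and body/fluid advance
    if (use_ib) {
      nsub <- as.integer(rn$substeps)
      dts <- rn$dt / nsub
      for (ss in seq_len(nsub)) {
        F <- unclass(passive_elastic_forces(body, geom))
        for (k in 1:2) {
          sd <- c("left", "right")[k]
          idx <- if (sd == "left") geom$i_left else geom$i_right
          F <- lateral_forces_cpp(F, body$X,
                                  idx[-length(idx)], idx[-1],
                                  sided[[sd]]$P, sided[[sd]]$Cb,
                                  geom$lat_l0, config$muscle$k_skin,
                                  config$muscle$k_cb,
                                  config$muscle$k_skin_comp)
        }
        Xw <- cbind(body$X[, 1] %% grid$Lx, body$X[, 2] %% grid$Ly)
        sp <- spread_forces(F, Xw, grid, ds_node)
        ncfl <- max(1L, ceiling(max(abs(fluid$u), abs(fluid$v), 1e-12) *
                                  dts / (0.5 * grid$h)))
        for (fs in seq_len(ncfl)) {
          fluid <- navier_stokes_step(fluid, sp$fx, sp$fy, dts / ncfl)
        }
        U <- interpolate_velocity(fluid, Xw)
        body$X <- body$X + dts * U
        body$V <- U
      }
      bad <- !all(is.finite(body$X))
    } else {
      # net muscle moment per lateral segment, spread (1/4, 1/2, 1/4) onto the
      # midline nodes the segment straddles
      Mseg <- (sided$right$P - sided$left$P) * w_seg / 2
      M_node <- numeric(nm)
      ctr <- geom$lat_mid_idx[-length(geom$lat_mid_idx)] + 1L   # node 2j
      M_node <- M_node +
        accum_cpp(ctr, Mseg / 2, nm) +
        accum_cpp(ctr - 1L, Mseg / 4, nm) +
        accum_cpp(ctr + 1L, Mseg / 4, nm)
      bend <- bend_forces_cpp(Xm, B_over_l, M_node[2:(nm - 1)], TRUE)
      Fm <- link_forces_cpp(Xm, geomO$links$from, geomO$links$to,
                            geomO$k_factor_over_l0, geomO$l0, nm) + bend$F
      im <- pmin(seq_len(nm) + 1L, nm); il <- pmax(seq_len(nm) - 1L, 1L)
      tgx <- Xm[im, 1] - Xm[il, 1]; tgy <- Xm[im, 2] - Xm[il, 2]
      tgl <- sqrt(tgx^2 + tgy^2)
      U <- overdamped_velocity(Fm, Xm, geomO, fl$c_drag, rn$dt, od_cache,
                               extra_jac = list(i = bend$i, j = bend$j,
                                                x = bend$x),
                               c_aniso = fl$c_aniso,
                               tangents = cbind(tgx / tgl, tgy / tgl))
      Xm <- Xm + rn$dt * U
      bad <- !all(is.finite(Xm))
    }
    if (bad) {
      stop(sprintf("numerical blow-up at t = %.4f s; last recorded frame %d",
                   step * rn$dt, row - 1L), call. = FALSE)
    }
    if (verbose && (step * rn$dt) %% 1 < rn$dt / 2) {
      message(sprintf("t = %.2f s", step * rn$dt))
    }
  }

  meta <- list(L = L, n_nodes = geom$n_nodes, mass = geom$mass,
               dt = rn$dt, record_every = rec_every,
               duration = rn$duration,
               backend = fl$backend, nx = if (use_ib) fl$nx else NA,
               mu = fl$mu * fl$mu_scale,
               reynolds_scale = fl$mu_scale,
               feedback_mode = config$feedback$mode,
               gain = config$feedback$gain,
               n_active = n_act,
               head_segments = geom$head_segments,
               n_lat_seg = geom$n_lat_seg,
               schema_version = TRAJECTORY_SCHEMA_VERSION)
  traj <- trajectory_record(out, meta)
  metrics <- metrics_report(traj)
  structure(list(trajectory = traj, metrics = metrics),
            class = "simulation_result")
}

#' Kinematic and energetic metrics of a trajectory
#'
#' Computes the full report: center-of-mass speed, tailbeat amplitude and
#' frequency, body wavelength, duty cycle, Strouhal number, wave speeds and
#' their ratio, and the (optionally normalized) cost of transport.
#'
#' @param traj A [trajectory_record()].
#' @param window Steady analysis window, s; default the final 4 s.
#' @param control_cot Control-case absolute cost of transport (optional, for
#'   the normalized value).
#' @param f_neg Negative-work weight for the cost of transport.
#' @return An object of class `metrics_report` (also a named list).
#' @export
metrics_report <- function(traj, window = NULL, control_cot = NULL,
                           f_neg = 0.3) {
  t <- traj$time
  if (is.null(window)) window <- c(max(max(t) - 5, min(t)), max(t))
  d <- traj$data
  n_lat <- traj$meta$n_lat_seg
  s_frac <- (seq_len(ncol(d$kappa)) + traj$meta$head_segments - 0.5) / n_lat

  tb <- tryCatch(tailbeat_metrics(traj, window), error = function(e) NULL)
  speed <- swimming_speed(traj, window)
  duty <- tryCatch(duty_cycle(list(time = t, sigma_left = d$sigma_left,
                                   sigma_right = d$sigma_right)),
                   error = function(e) NA_real_)
  wl <- body_wavelength(d$kappa, s_frac, t, window)
  ws <- tryCatch(
    wave_speeds(d$theta_left, d$kappa, t, s_frac, L = 1,
                period = if (!is.null(tb)) 1 / tb$frequency else NULL),
    error = function(e) list(v_a = NA_real_, V = NA_real_, ratio = NA_real_))
  st <- if (!is.null(tb) && is.finite(speed) && speed > 0) {
    strouhal(tb$frequency, tb$amplitude, speed)
  } else NA_real_
  period <- if (!is.null(tb)) 1 / tb$frequency else 1
  power <- cbind(-d$P_left * d$vc_left, -d$P_right * d$vc_right)
  cot <- cost_of_transport(power, t, period, traj$meta$mass, f_neg = f_neg,
                           control = control_cot)
  structure(
    list(speed = speed,
         amplitude = if (is.null(tb)) NA_real_ else tb$amplitude,
         frequency = if (is.null(tb)) NA_real_ else tb$frequency,
         wavelength = wl,
         duty_cycle = duty,
         strouhal = st,
         v_a = ws$v_a, V = ws$V, wavespeed_ratio = ws$ratio,
         cot = cot$absolute,
         cot_normalized = cot$normalized %||% NA_real_,
         window = window),
    class = "metrics_report"
  )
}

#' Sweep a feedback gain across its range
#'
#' Runs one closed-loop simulation per gain (plus the control case at gain 0,
#' which is always included and used to normalize the cost of transport) and
#' returns a tidy table keyed by the percent-of-range gain, one row per run.
#' Individual run failures are recorded (`status` column) and the sweep
#' continues.
#'
#' @param config A baseline [simulation_config()] (its feedback section is
#'   replaced per gain).
#' @param mode `"magnitude"` or `"directional"`.
#' @param gains Numeric vector of gains, cm rad/s.
#' @param verbose Print progress per run.
#' @return A tibble of class `gain_sweep`: columns `mode`, `gain`,
#'   `percent_gain`, `status`, and the metric columns of [metrics_report()].
#' @export
gain_sweep <- function(config, mode, gains, verbose = FALSE) {
  rng <- feedback_gain_range(mode)
  gains <- sort(unique(c(0, gains)))
  control_cot <- NULL
  run_one <- function(g) {
    cfg <- config
    cfg$feedback <- feedback_config(if (g == 0) "none" else mode, gain = g,
                                    smooth_halfwidth = config$feedback$smooth_halfwidth,
                                    tail_silent_segments = config$feedback$tail_silent_segments)
    if (verbose) message(sprintf("gain %.3g (%.0f%%)", g, 100 * g / rng))
    tryCatch({
      res <- run_simulation(cfg)
      m <- res$metrics
      tibble::tibble(mode = mode, gain = g, percent_gain = 100 * g / rng,
                     status = "ok",
                     speed = m$speed, amplitude = m$amplitude,
                     frequency = m$frequency, wavelength = m$wavelength,
                     duty_cycle = m$duty_cycle, strouhal = m$strouhal,
                     wavespeed_ratio = m$wavespeed_ratio, cot = m$cot)
    }, error = function(e) {
      tibble::tibble(mode = mode, gain = g, percent_gain = 100 * g / rng,
                     status = conditionMessage(e),
                     speed = NA_real_, amplitude = NA_real_,
                     frequency = NA_real_, wavelength = NA_real_,
                     duty_cycle = NA_real_, strouhal = NA_real_,
                     wavespeed_ratio = NA_real_, cot = NA_real_)
    })
  }
  tab <- purrr::map_dfr(gains, run_one)
  ctrl <- tab$cot[tab$gain == 0]
  if (length(ctrl) == 1 && is.finite(ctrl) && ctrl > 0) {
    tab$cot_normalized <- tab$cot / ctrl
  } else {
    tab$cot_normalized <- NA_real_
  }
  class(tab) <- c("gain_sweep", class(tab))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
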