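test_that("rate constants are gated by activation and scaled by work", {
  p <- muscle_params()
  k1 <- rate_constants(1, 1, p)
  k0 <- rate_constants(0, 1, p)
  expect_equal(k1$k2, 0)                      # no resequestration while active
  expect_equal(k0$k1, 0)                      # no release while inactive
  k2m <- rate_constants(0, 2, p)
  expect_equal(k2m$k3, 2 * k0$k3)             # k3, k4 linear in m
  expect_equal(k2m$k4, 2 * k0$k4)
})

test_that("calcium derivatives follow the printed kinetics", {
  p <- muscle_params()
  d0 <- calcium_derivatives(0, 0, 0, 1, p)
  expect_equal(d0$dCf, 0)                     # empty inactive muscle is inert
  expect_equal(d0$dCb, 0)
  d1 <- calcium_derivatives(0.4, 1, 1, 1.3, p)
  expect_equal(d1$dCb, 0)                     # (1 - Cb) factor saturates
  # with sarcoplasmic exchange off, Cf + Cb is conserved for any state
  p0 <- muscle_params(kbar1 = 0, kbar2 = 0)
  set.seed(11)
  for (i in 1:25) {
    d <- calcium_derivatives(runif(1, 0, 2), runif(1), sample(0:1, 1),
                             runif(1, 0.5, 2), p0)
    expect_equal(d$dCf + d$dCb, 0, tolerance = 1e-14)
  }
})

test_that("work-dependent deactivation has the printed piecewise form", {
  p <- muscle_params()
  expect_equal(work_deactivation_derivative(1, 0.5, 1, p), 0)
  expect_equal(work_deactivation_derivative(1.5, 0.5, 1, p), -0.5 * p$km2)
  expect_equal(work_deactivation_derivative(1, 0.5, -2, p), p$km1 * 0.5 * 2)
  # relaxation branch decays exponentially toward 1 at rate km2
  m <- 1.8
  dt <- 1e-4
  for (i in 1:5000) m <- m + dt * work_deactivation_derivative(m, 0, 1, p)
  expect_equal(m, 1 + 0.8 * exp(-p$km2 * 0.5), tolerance = 1e-3)
})

test_that("contractile force has the normalized product form", {
  p <- muscle_params()
  lc0 <- 0.04
  expect_equal(contractile_force(0, lc0, 0, 1, lc0, p), 0)   # no calcium
  expect_equal(contractile_force(0, lc0, 0.6, 1, lc0, p), p$P0 * 0.6,
               tolerance = 1e-12)                            # normalization
  expect_equal(contractile_force(0, lc0, 0.6, 0.5, lc0, p),
               contractile_force(0, lc0, 0.6, 1, lc0, p) / 2)  # taper linear
  expect_equal(hill_force_velocity(0, p, lc0), 1)
  expect_equal(hill_length_tension(lc0, lc0, p), 1)
  # force-velocity is monotone increasing and vanishes at -vmax
  v <- seq(-p$vmax_rel * lc0, p$vmax_rel * lc0, length.out = 50)
  a <- hill_force_velocity(v, p, lc0)
  expect_true(all(diff(a) >= 0))
  expect_equal(a[1], 0)
})

test_that("calcium stays bounded and the force transient rises then decays", {
  p <- muscle_params()
  st <- muscle_init(1, lc0 = 0.039)
  P <- Cb <- Cf <- numeric(1500)
  for (i in 1:1500) {
    st <- step_muscle(st, as.integer(i <= 500), 1, 0.039, 0, 1e-3, p)
    P[i] <- st$P; Cb[i] <- st$Cb; Cf[i] <- st$Cf
  }
  expect_true(all(Cb >= 0 & Cb <= 1))
  expect_true(all(Cf >= 0))
  expect_lt(max(P), p$P0 * p$alpha_max + 1e-9)
  expect_gt(max(P[1:500]), 0.5 * p$P0)        # force develops while active
  expect_lt(P[1500], 1e-6 * p$P0)             # and decays to zero after
  expect_gt(P[300], P[50])
})

test_that("work-dependent deactivation reduces the per-cycle force capacity", {
  # identical cyclic loading with deactivation on (km1 > 0) vs the m = 1
  # model (km1 = 0): m grows with the shortening work done and speeds the
  # calcium cycling, which trims the force-time integral of later cycles
  run_m <- function(km1) {
    p <- muscle_params(km1 = km1, km2 = 1)
    st <- muscle_init(1, lc0 = 0.039)
    l <- function(t) 0.039 * (1 + 0.15 * sin(2 * pi * t))
    Pbuf <- numeric(4000)
    m_max <- 1
    for (i in 1:4000) {
      t <- i * 1e-3
      sig <- as.integer(sin(2 * pi * t) > 0.43)
      vl <- (l(t) - l(t - 1e-3)) / 1e-3
      st <- step_muscle(st, sig, 1, l(t), vl, 1e-3, p)
      Pbuf[i] <- st$P
      m_max <- max(m_max, st$m)
    }
    c(impulse = sum(Pbuf[3001:4000]) * 1e-3, m_max = m_max)
  }
  with_d <- run_m(15)
  without <- run_m(0)
  expect_gt(with_d["m_max"], 1.05)          # the work variable engaged
  expect_identical(unname(without["m_max"]), 1)
  expect_lt(with_d["impulse"], without["impulse"])
})

test_that("segment endpoint forces are equal and opposite, skin tension-only", {
  p <- muscle_params()
  # inactive segment at rest length: zero force
  f0 <- muscle_segment_force(NULL, rbind(c(0, 0)), rbind(c(0.039, 0)),
                             l0 = 0.039, p)
  expect_equal(f0$tension, 0)
  # stretched: skin pulls the endpoints together; compressed: nothing
  fs <- muscle_segment_force(NULL, rbind(c(0, 0)), rbind(c(0.05, 0)),
                             l0 = 0.039, p)
  expect_equal(fs$tension, p$k_skin * (0.05 - 0.039), tolerance = 1e-12)
  expect_gt(fs$f1[1, 1], 0)                    # anterior end pulled toward +x
  fc <- muscle_segment_force(NULL, rbind(c(0, 0)), rbind(c(0.02, 0)),
                             l0 = 0.039, p)
  expect_equal(fc$tension, 0)
  # equal-and-opposite contract on a random configuration
  st <- muscle_init(3, 0.039)
  st$P <- c(10, 0, 5)
  set.seed(2)
  p1 <- matrix(rnorm(6), 3, 2); p2 <- p1 + matrix(rnorm(6, 0, 0.1), 3, 2)
  fr <- muscle_segment_force(st, p1, p2, rep(0.039, 3), p)
  expect_equal(fr$f1 + fr$f2, matrix(0, 3, 2))
  expect_error(muscle_segment_force(NULL, p1, p1, rep(0.039, 3), p),
               "zero-length")
})

test_that("taper factor is the squared width ratio", {
  g <- build_body(muscle = muscle_params())
  tf <- taper_factor(seq_len(320), g)
  # evaluated at segment midpoints, so the widest segment sits just under 1
  expect_equal(max(tf), 1, tolerance = 0.01)
  expect_true(all(tf > 0 & tf <= 1))
  # a segment whose width is half the maximum has taper 1/4 (area ~ width^2)
  wm <- (g$width[-321] + g$width[-1]) / 2
  j <- which.min(abs(wm - max(g$width) / 2))
  expect_equal(tf[j], (wm[j] / max(g$width))^2, tolerance = 1e-12)
  expect_equal(tf[j], 0.25, tolerance = 0.02)
  expect_error(taper_factor(321, g), "out of range")
  # invariants of the parameter container
  expect_error(muscle_params(Ctot = 7, Ssites = 6), "Ssites > Ctot")
})
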