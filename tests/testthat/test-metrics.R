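test_that("swimming speed is the windowed center-of-mass speed in L/s", {
  t <- seq(0, 10, by = 0.02)
  L <- 12.56
  still <- list(time = t, com = cbind(3 + 0 * t, 1 + 0 * t), L = L)
  expect_equal(swimming_speed(still), 0)
  drift <- list(time = t, com = cbind(5 - 6.53 * t, 0 * t), L = L)
  expect_equal(swimming_speed(drift), 6.53 / L, tolerance = 1e-10)
  expect_equal(swimming_speed(drift), 0.52, tolerance = 1e-3)
  short <- list(time = seq(0, 4, 0.02), com = cbind(seq(0, 4, 0.02), 0),
                L = L)
  expect_error(swimming_speed(short), "window")
})

test_that("tailbeat metrics recover a sinusoid and ignore linear drift", {
  t <- seq(0, 10, by = 0.005)
  L <- 12.56
  s <- list(time = t, tail_y = 1.5 * sin(2 * pi * 1.3 * t), L = L)
  tb <- tailbeat_metrics(s)
  expect_equal(tb$frequency, 1.3, tolerance = 1e-3)
  expect_equal(tb$amplitude, 1.5 / L, tolerance = 0.01)
  sd <- list(time = t, tail_y = 1.5 * sin(2 * pi * 1.3 * t) + 0.4 * t, L = L)
  expect_equal(tailbeat_metrics(sd)$frequency, 1.3, tolerance = 1e-3)
  # two-harmonic signal: frequency of the fundamental
  s2 <- list(time = t,
             tail_y = sin(2 * pi * t) + 0.3 * sin(2 * pi * 2 * t + 0.4),
             L = L)
  expect_equal(tailbeat_metrics(s2)$frequency, 1, tolerance = 2e-3)
  expect_error(tailbeat_metrics(list(time = t, tail_y = 1.5 * sin(2 * pi *
    0.2 * t), L = L), window = c(0, 4)), "cycles")
})

test_that("duty cycle measures the on-fraction over steady cycles", {
  t <- seq(0, 8, by = 0.002)
  on36 <- ((t %% 1) < 0.36) + 0L
  act <- list(time = t, sigma_left = cbind(on36, on36))
  expect_equal(duty_cycle(act), 0.36, tolerance = 2e-3)
  expect_equal(duty_cycle(list(time = t,
                               sigma_left = cbind(rep(1L, length(t))))), 1)
  expect_error(duty_cycle(list(time = t,
                               sigma_left = cbind(rep(0L, length(t))))),
               "activity")
})

test_that("Strouhal and Reynolds numbers follow their definitions", {
  expect_equal(strouhal(1, 0.12, 0.52), 0.4615, tolerance = 1e-4)
  expect_equal(strouhal(0, 0.12, 0.52), 0)
  expect_equal(strouhal(1, 0.24, 1.04), strouhal(1, 0.12, 0.52))  # homogeneity
  expect_error(strouhal(1, 0.12, 0), "zero")
  expect_equal(reynolds_number(0.52), 1 * (0.52 * 12.56) * 12.56 / 0.01)
})

test_that("wave speeds recover analytic traveling waves via the Hilbert
           transform", {
  t <- seq(0, 10, by = 0.02)
  s <- seq(0, 1, length.out = 121)
  # curvature wave at speed c = f * lambda = 1 * 0.8 L/s
  kap <- outer(t, s, function(t, s) cos(2 * pi * (t - s / 0.8)))
  # activation phase wave with the same geometry
  th <- outer(t, s, function(t, s) 2 * pi * (t - s / 0.8))
  ws <- wave_speeds(th, kap, t, s, L = 1, n_beats = 7)
  expect_equal(ws$v_a, 0.8, tolerance = 1e-6)
  expect_equal(ws$V, 0.8, tolerance = 0.01)
  expect_equal(ws$ratio, 1, tolerance = 0.01)
  # phase-only: rescaling the curvature amplitude leaves V unchanged
  ws2 <- wave_speeds(th, 17 * kap, t, s, L = 1, n_beats = 7)
  expect_equal(ws2$V, ws$V, tolerance = 1e-9)
  # linear phase with different wavelength: v_a = omega * Lambda / (2 pi)
  th2 <- outer(t, s, function(t, s) 2 * pi * 1.5 * t - 2 * pi * s / 0.6)
  ws3 <- wave_speeds(th2, kap, t, s, L = 1, n_beats = 7)
  expect_equal(ws3$v_a, 1.5 * 0.6, tolerance = 1e-6)
  expect_error(wave_speeds(th, kap, t^1.3, s, L = 1), "uniform")
})

test_that("cost of transport weights negative work and normalizes", {
  t <- seq(0, 2, by = 0.001)
  pw <- cbind(1 + 0 * t, 2 + 0 * t)          # constant positive power
  cot <- cost_of_transport(pw, t, period = 1, mass = 5, f_neg = 0.3)
  expect_equal(cot$absolute, 3 / 5, tolerance = 1e-6)
  mixed <- cbind(1 + 0 * t, -2 + 0 * t)
  c0 <- cost_of_transport(mixed, t, 1, 5, f_neg = 0)
  expect_equal(c0$absolute, 1 / 5, tolerance = 1e-6)   # f_neg = 0 drops W-
  c3 <- cost_of_transport(mixed, t, 1, 5, f_neg = 0.3)
  expect_equal(c3$absolute, (1 + 0.3 * 2) / 5, tolerance = 1e-6)
  cn <- cost_of_transport(pw, t, 1, 5, control = cot$absolute)
  expect_equal(cn$normalized, 1, tolerance = 1e-12)    # control against itself
  expect_error(cost_of_transport(pw, t, 1, 5, normalize = TRUE), "control")
})

test_that("phase lag pairs curvature peaks with activation onsets", {
  spec <- wave_spec(duration = 8, dt = 0.005)
  kin <- make_traveling_wave(spec)
  # sample curvature at the oscillator positions used by the activation fixture
  act0 <- make_activation_pattern(spec, duty = 0.36)
  kap <- lampreysim:::kappa_wave(spec, act0$s_frac, kin$time)
  phi0 <- suppressWarnings(
    phase_lag_profile(kap, act0, time = kin$time, s_frac = act0$s_frac))
  expect_lt(max(abs(phi0$phi)), 0.011)                  # onset at the peak
  # uniform lag of +0.1 cycles
  act1 <- make_activation_pattern(spec, 0.36, lag_profile = function(s) 0.1)
  phi1 <- suppressWarnings(
    phase_lag_profile(kap, act1, time = kin$time, s_frac = act1$s_frac))
  expect_equal(mean(phi1$phi), 0.1, tolerance = 0.03)   # sampling quantization
  # linearly position-dependent lag recovered within ~one sample (0.005 cyc)
  lagf <- function(s) 0.15 - 0.25 * s
  act2 <- make_activation_pattern(spec, 0.36, lag_profile = lagf)
  phi2 <- suppressWarnings(
    phase_lag_profile(kap, act2, time = kin$time, s_frac = act2$s_frac))
  prof <- tapply(phi2$phi, phi2$s, mean)
  svals <- as.numeric(names(prof))
  expect_lt(max(abs(as.vector(prof) - lagf(svals))), 0.0075)
})

test_that("body wavelength doubles the curvature zero-crossing spacing", {
  spec <- wave_spec(duration = 6, amp_head = 0.01, amp_tail = 0.02)
  kin <- make_traveling_wave(spec)
  wl <- body_wavelength(kin$kappa, kin$s / kin$L, kin$time)
  expect_equal(wl, 0.75, tolerance = 0.02)
})
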