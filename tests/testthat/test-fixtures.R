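test_that("the traveling-wave fixture round-trips through the metrics", {
  spec <- wave_spec(duration = 10, dt = 0.01)
  kin <- make_traveling_wave(spec)
  tb <- tailbeat_metrics(kin)
  expect_equal(tb$frequency, spec$frequency, tolerance = 0.01)
  expect_equal(tb$amplitude, spec$amp_tail, tolerance = 0.012)
  expect_equal(swimming_speed(kin), spec$speed, tolerance = 0.01)
  # zero-crossing spacing is biased by the strong amplitude envelope (the
  # flat-envelope case is held to 2% in the metrics tests)
  expect_equal(body_wavelength(kin$kappa, kin$s / kin$L, kin$time),
               spec$wavelength, tolerance = 0.08)
  # curvature wave speed ~ f * lambda through the Hilbert pipeline
  th <- outer(2 * pi * spec$frequency * kin$time,
              2 * pi * kin$s / (spec$wavelength * kin$L), "-")
  ws <- wave_speeds(th, kin$kappa, kin$time, kin$s / kin$L, L = 1)
  # the envelope shifts the curvature phase slightly; the pure-wave case is
  # held to 1% in the metrics tests
  expect_equal(ws$V, spec$frequency * spec$wavelength, tolerance = 0.05)
})

test_that("degenerate and scaled specs behave analytically", {
  z <- make_traveling_wave(wave_spec(amp_head = 0, amp_tail = 0,
                                     duration = 2))
  expect_lt(max(abs(z$kappa)), 1e-12)          # straight translating body
  # doubling the wavelength halves the mean curvature magnitude (small amp)
  k1 <- make_traveling_wave(wave_spec(wavelength = 0.5, amp_head = 0.005,
                                      amp_tail = 0.005, duration = 2))
  k2 <- make_traveling_wave(wave_spec(wavelength = 1.0, amp_head = 0.005,
                                      amp_tail = 0.005, duration = 2))
  expect_equal(mean(abs(k1$kappa)) / mean(abs(k2$kappa)), 4, tolerance = 0.05)
  expect_error(wave_spec(wave_speed = 2), "inconsistent")
  expect_silent(wave_spec(frequency = 2, wavelength = 0.5, wave_speed = 1))
})

test_that("fixtures are deterministic given the seed", {
  a <- make_traveling_wave(wave_spec(noise_sd = 0.01, seed = 33, duration = 1))
  b <- make_traveling_wave(wave_spec(noise_sd = 0.01, seed = 33, duration = 1))
  expect_identical(a$y, b$y)
  c2 <- make_traveling_wave(wave_spec(noise_sd = 0.01, seed = 34,
                                      duration = 1))
  expect_false(identical(a$y, c2$y))
})

test_that("the activation fixture has the requested duty cycle", {
  act <- make_activation_pattern(wave_spec(duration = 8, dt = 0.004),
                                 duty = 0.36)
  expect_equal(duty_cycle(act), 0.36, tolerance = 0.005)
  expect_true(all(act$sigma_left %in% 0:1))
  # left and right are in antiphase at every position
  ov <- mean(act$sigma_left * act$sigma_right)
  expect_lt(ov, 0.001)
  expect_error(make_activation_pattern(wave_spec(), duty = 1.2))
})

test_that("the curvature driver entrains the CPG as the feedback predicts", {
  p <- cpg_params()
  # zero-amplitude driver: control behavior at exactly omega
  z <- make_curvature_driver(wave_spec(amp_head = 0, amp_tail = 0))
  rz <- run_cpg(p, duration = 2, dt = 1e-3,
                feedback_config = feedback_config("magnitude", gain = 0.05),
                kappa_fn = z)
  expect_equal(cpg_run_frequency(rz, from = 0.5), 1, tolerance = 1e-9)
  # magnitude mode with positive gain raises the mean phase velocity
  rp <- driver_run("magnitude", 0.0675)
  expect_gt(cpg_run_frequency(rp), 1)
  rn <- driver_run("magnitude", -0.0675)
  expect_lt(cpg_run_frequency(rn), 1)
  # directional feedback leaves the period untouched and shifts both sides'
  # duty cycles together (curvature is antiphase between the sides, so each
  # side sees the same signal relative to its own activation window)
  rd <- driver_run("directional", 15)
  expect_equal(cpg_run_frequency(rd), 1, tolerance = 1e-6)
  dl <- duty_cycle(list(time = rd$time, sigma_left = rd$sigma_left))
  dr <- duty_cycle(list(time = rd$time, sigma_right = rd$sigma_right))
  expect_lt(dl, 0.36)
  expect_equal(dl, dr, tolerance = 0.002)
})
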