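test_that("coupling strengths follow the exponential law and fix alpha_c", {
  p <- cpg_params()
  # descending neighbor: A_d * exp(-1/lambda_d)
  expect_equal(coupling_strength(2, 1, p), 10 * exp(-1 / 5), tolerance = 1e-12)
  expect_equal(coupling_strength(2, 1, p), 8.1873, tolerance = 1e-4)
  # ascending neighbor: A_a * exp(-1/lambda_a)
  expect_equal(coupling_strength(1, 2, p), 1.0 * exp(-1 / 40),
               tolerance = 1e-12)
  expect_equal(coupling_strength(1, 2, p), 0.97531, tolerance = 1e-4)
  # self-coupling is zero; indices out of range error
  expect_identical(coupling_strength(5, 5, p), 0)
  expect_error(coupling_strength(0, 1, p), "indices")
  # contralateral strength is ten times the strongest descending connection
  expect_equal(10 * max(coupling_strength(2:280, 1:279, p)), p$alpha_c,
               tolerance = 1e-3)
})

test_that("phase velocity reproduces the tuned relative equilibrium and
           hand-expanded small chains", {
  p <- cpg_params()
  st <- cpg_init(p)
  pv <- phase_velocity(st, 0, p)
  expect_equal(max(abs(pv - p$omega)), 0, tolerance = 1e-10)

  # additivity of the feedback port
  fb <- matrix(0.37, 2, p$n_seg)
  expect_equal(phase_velocity(st, fb, p), pv + 0.37, tolerance = 1e-12)
  expect_error(phase_velocity(st, matrix(0, 3, 5), p), "shape")

  # brute-force expansion for a 2 x 2 chain with equal phases
  p2 <- cpg_params(n_seg = 2, psi_bar = 0.3, alpha_c = 2)
  st2 <- cpg_init(p2)
  st2$theta <- matrix(0.7, 2, 2)
  pv2 <- phase_velocity(st2, 0, p2)
  a12 <- p2$A_asc * exp(-1 / p2$lambda_asc)   # osc 1 receives from 2 (ascending)
  a21 <- p2$A_desc * exp(-1 / p2$lambda_desc)
  # equal phases: sin(theta_j - theta_i - (i-j)psi) = sin(-(i-j)psi);
  # contralateral term vanishes (equal phases across sides)
  expect_equal(pv2[1, 1], p2$omega + a12 * sin(p2$psi_bar), tolerance = 1e-12)
  expect_equal(pv2[1, 2], p2$omega + a21 * sin(-p2$psi_bar), tolerance = 1e-12)
  expect_equal(pv2[1, ], pv2[2, ], tolerance = 1e-12)
})

test_that("RK4 stepping advances the tuned state at exactly omega", {
  p <- cpg_params()
  st <- cpg_init(p)
  zero <- matrix(0, 2, p$n_seg)
  s1 <- step_cpg(st, zero, 0.01, p)
  expect_equal(unname(s1$theta - st$theta),
               matrix(p$omega * 0.01, 2, p$n_seg), tolerance = 1e-12)
  # one second of integration advances every phase by 2*pi (omega = 2*pi)
  for (i in 1:100) st <- step_cpg(st, zero, 0.01, p)
  expect_equal(unname(st$theta - cpg_init(p)$theta),
               matrix(2 * pi, 2, p$n_seg), tolerance = 1e-9)
  expect_error(step_cpg(st, zero, 0, p))
})

test_that("RK4 agrees with a tiny-step Euler integrator on random phases", {
  # moderate contralateral coupling keeps the forward-Euler reference accurate
  p <- cpg_params(n_seg = 20, alpha_c = 2)
  set.seed(42)
  th0 <- matrix(runif(40, -pi, pi), 2, 20)
  st <- structure(list(theta = th0, time = 0), class = "cpg_state")
  zero <- matrix(0, 2, 20)
  rk <- step_cpg(st, zero, 0.01, p)
  eu <- th0
  for (i in 1:1000) {
    eu <- eu + 1e-5 * phase_velocity(
      structure(list(theta = eu, time = 0), class = "cpg_state"), zero, p)
  }
  expect_equal(unname(rk$theta), unname(eu), tolerance = 1e-4)
})

test_that("activation thresholding is boundary-inclusive", {
  st <- structure(list(theta = matrix(c(asin(0.5), 0, pi / 2, pi), 2, 2),
                       time = 0), class = "cpg_state")
  sig <- activation_from_phase(st, tau = 0.5)
  expect_identical(sig[1, 1], 1L)     # sin(theta) exactly at tau -> active
  expect_identical(sig[2, 1], 0L)     # theta = 0, tau = 0.5 -> inactive
  expect_identical(sig[1, 2], 1L)     # theta = pi/2 -> active for any tau < 1
  expect_true(all(activation_from_phase(st, tau = 0.5) %in% c(0L, 1L)))
})

test_that("threshold calibration inverts the duty relation", {
  expect_equal(calibrate_threshold(0.5), 0, tolerance = 1e-12)
  expect_equal(calibrate_threshold(0.36), 0.42578, tolerance = 1e-5)
  expect_equal(calibrate_threshold(0.999), -1, tolerance = 1e-2)
  expect_error(calibrate_threshold(0))
  expect_error(calibrate_threshold(1.2))
  # numeric verification: fraction of a uniformly advancing cycle above tau
  for (duty in c(0.2, 0.36, 0.7)) {
    tau <- calibrate_threshold(duty)
    th <- seq(0, 2 * pi, length.out = 2e5 + 1)[-1]
    expect_equal(mean(sin(th) >= tau), duty, tolerance = 1e-4)
  }
})

test_that("antiphase and traveling-wave spacing are attractors", {
  p <- cpg_params()
  set.seed(7)
  st <- cpg_init(p, perturb = 0.3)
  zero <- matrix(0, 2, p$n_seg)
  for (i in 1:3000) st <- step_cpg(st, zero, 1e-3, p)
  dphase <- st$theta[1, ] - st$theta[2, ]
  expect_lt(max(abs(sin((dphase - pi) / 2))), 1e-10)     # antiphase restored
  spacing <- diff(st$theta[1, ]) + p$psi_bar
  expect_lt(max(abs(spacing)), 1e-10)                    # psi_bar spacing
  pv <- phase_velocity(st, 0, p)
  expect_equal(max(abs(pv - p$omega)), 0, tolerance = 1e-8)
})

test_that("the emergent control duty cycle matches the analytic value", {
  p <- cpg_params()
  r <- run_cpg(p, duration = 3, dt = 2.5e-4)
  analytic <- (pi - 2 * asin(p$tau)) / (2 * pi)
  expect_equal(cpg_run_duty(r), analytic, tolerance = 1e-3)
  expect_equal(analytic, 0.36, tolerance = 1e-12)
})
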