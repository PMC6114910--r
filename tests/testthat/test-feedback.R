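test_that("midline curvature matches the analytic circle and line", {
  # circle of radius R bending toward the right (+y) side
  R <- 5
  th <- seq(-0.6, 0.6, length.out = 101)
  pts <- cbind(R * sin(th), R * (1 - cos(th)))
  cf <- midline_curvature(pts)
  expect_s3_class(cf, "curvature_field")
  expect_equal(cf$kappa[10:90], rep(1 / R, 81), tolerance = 1e-3)
  # opposite bend flips the sign
  cf2 <- midline_curvature(cbind(R * sin(th), -R * (1 - cos(th))))
  expect_equal(cf2$kappa[10:90], rep(-1 / R, 81), tolerance = 1e-3)
  # collinear points
  line <- cbind(seq(0, 10, length.out = 50), 0.3)
  expect_equal(max(abs(midline_curvature(line)$kappa)), 0)
  # errors
  expect_error(midline_curvature(pts[1:4, ]), "at least 5")
  bad <- pts; bad[11, ] <- bad[10, ]
  expect_error(midline_curvature(bad), "coincident")
})

test_that("curvature is invariant under smooth reparameterization", {
  R <- 4
  th_u <- seq(-0.5, 0.5, length.out = 201)                 # uniform
  th_n <- -0.5 + (seq(0, 1, length.out = 201))^1.3         # stretched
  k_u <- midline_curvature(cbind(R * sin(th_u), R * (1 - cos(th_u))))$kappa
  k_n <- midline_curvature(cbind(R * sin(th_n), R * (1 - cos(th_n))))$kappa
  expect_equal(k_u[20:180], rep(1 / R, 161), tolerance = 5e-3)
  expect_equal(k_n[20:180], rep(1 / R, 161), tolerance = 5e-3)
})

test_that("per-oscillator smoothing is an 11-point boxcar with a silent tail", {
  cfg <- feedback_config()
  # constant field: unchanged except the zeroed tail
  k <- segment_curvature(rep(0.25, 280), cfg, n_osc = 280, n_lateral = 280)
  expect_equal(k[1:275], rep(0.25, 275), tolerance = 1e-12)
  expect_identical(k[276:280], rep(0, 5))
  # unit impulse spreads to value 1/11 over segments i-5..i+5
  imp <- numeric(280); imp[150] <- 1
  ks <- segment_curvature(imp, cfg, n_osc = 280, n_lateral = 280)
  expect_equal(ks[145:155], rep(1 / 11, 11), tolerance = 1e-12)
  expect_equal(sum(ks), 1, tolerance = 1e-12)
  expect_equal(ks[140], 0)
  # zero field stays zero; interior mean is conserved by the boxcar
  expect_identical(segment_curvature(numeric(280), cfg, 280, 280),
                   numeric(280))
  set.seed(1)
  v <- rnorm(280)
  cfg0 <- feedback_config(tail_silent_segments = 0)
  sm <- segment_curvature(v, cfg0, 280, 280)
  expect_equal(mean(sm[6:275]),
               mean(stats::filter(v, rep(1 / 11, 11))[6:275]),
               tolerance = 1e-10)
})

test_that("feedback terms implement the magnitude and directional forms", {
  # magnitude: eta_m |kappa| on both sides
  m <- feedback_term(c(-0.5, 0.2), feedback_config("magnitude", gain = 0.08))
  expect_equal(m[1, ], c(0.04, 0.016), tolerance = 1e-12)
  expect_equal(m[2, ], m[1, ])
  # directional: right side excited by a right bend (positive kappa)
  d <- feedback_term(0.2, feedback_config("directional", gain = 15))
  expect_equal(d[2, 1], 3)       # right
  expect_equal(d[1, 1], -3)      # left
  # zero gain recovers the control case
  z <- feedback_term(runif(10), feedback_config("directional", gain = 0))
  expect_identical(z, matrix(0, 2, 10))
  expect_error(feedback_config("sideways"))
})

test_that("directional feedback is antisymmetric and magnitude symmetric", {
  set.seed(3)
  kap <- rnorm(280, 0, 0.3)
  d <- feedback_term(kap, feedback_config("directional", gain = 12))
  expect_equal(d[1, ], -d[2, ], tolerance = 1e-12)
  expect_equal(colSums(d), numeric(280))
  m <- feedback_term(kap, feedback_config("magnitude", gain = 0.05))
  expect_equal(m[1, ], m[2, ])
  expect_true(all(m >= 0))
})
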