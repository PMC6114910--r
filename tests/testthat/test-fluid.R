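test_that("the 4-point kernel satisfies the discrete moment conditions", {
  set.seed(9)
  for (r in runif(20, -0.5, 0.5)) {
    k <- -3:3
    w <- discrete_delta(r - k)
    expect_equal(sum(w), 1, tolerance = 1e-12)          # zeroth moment
    expect_equal(sum(k * w), r, tolerance = 1e-12)      # first moment
  }
  x <- runif(50, -3, 3)
  expect_equal(discrete_delta(x), discrete_delta(-x))   # even kernel
  expect_true(all(discrete_delta(seq(2, 5, by = 0.1)) == 0))
})

test_that("spreading is conservative and adjoint to interpolation", {
  g <- fluid_grid(10, 10, 32)
  set.seed(2)
  X <- cbind(runif(40, 1, 9), runif(40, 1, 9))
  F <- matrix(rnorm(80), 40, 2)
  sp <- spread_forces(F, X, g, ds = 0.3)
  expect_equal(sum(sp$fx) * g$h^2, sum(F[, 1]) * 0.3, tolerance = 1e-10)
  expect_equal(sum(sp$fy) * g$h^2, sum(F[, 2]) * 0.3, tolerance = 1e-10)
  # zero forces spread to a zero field
  z <- spread_forces(F * 0, X, g, ds = 0.3)
  expect_identical(sum(abs(z$fx)) + sum(abs(z$fy)), 0)
  # adjointness against random fields
  st <- fluid_init(g)
  st$u <- matrix(rnorm(g$nx * g$ny), g$nx)
  st$v <- matrix(rnorm(g$nx * g$ny), g$nx)
  U <- interpolate_velocity(st, X)
  lhs <- sum((U[, 1] * F[, 1] + U[, 2] * F[, 2]) * 0.3)
  rhs <- (sum(st$u * sp$fx) + sum(st$v * sp$fy)) * g$h^2
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # and against the independent pure-R stencil implementation
  cu <- lampreysim:::u_grid_coords(X, g)
  stn <- lampreysim:::ib_stencil(cu$rx, cu$ry, g$nx, g$ny)
  fxR <- matrix(lampreysim:::accumulate_at(
    as.vector(stn$w * (F[, 1] * 0.3 / g$h^2)),
    as.vector(stn$idx), g$nx * g$ny), g$nx, g$ny)
  expect_equal(fxR, sp$fx, tolerance = 1e-12)
  expect_error(spread_forces(F, X * NA, g, 0.3), "non-finite")
})

test_that("interpolation reproduces uniform and linear fields", {
  g <- fluid_grid(10, 10, 64)
  st <- fluid_init(g)
  set.seed(3)
  X <- cbind(runif(30, 2, 8), runif(30, 2, 8))
  expect_equal(unname(interpolate_velocity(st, X)),
               cbind(rep(0, 30), rep(0, 30)))
  st$u[] <- 2.5; st$v[] <- -1.25
  U <- interpolate_velocity(st, X)
  expect_equal(U[, 1], rep(2.5, 30), tolerance = 1e-12)
  expect_equal(U[, 2], rep(-1.25, 30), tolerance = 1e-12)
  # linear shear u = 0.2 * y: interpolation is exact to O(h^2)
  yu <- outer(rep(1, g$nx), (seq_len(g$ny) - 0.5) * g$h)
  st$u <- 0.2 * yu; st$v[] <- 0
  U <- interpolate_velocity(st, X)
  expect_equal(U[, 1], 0.2 * X[, 2], tolerance = 1e-3)
})

test_that("the projection solver reproduces Taylor-Green decay within 1%", {
  g <- fluid_grid(2 * pi, 2 * pi, 64, rho = 1, mu = 0.02)
  st <- fluid_init(g)
  xu <- outer(seq_len(64), rep(1, 64)) * g$h
  yu <- outer(rep(1, 64), seq_len(64) - 0.5) * g$h
  xv <- outer(seq_len(64) - 0.5, rep(1, 64)) * g$h
  yv <- outer(rep(1, 64), seq_len(64)) * g$h
  st$u <- sin(xu) * cos(yu)
  st$v <- -cos(xv) * sin(yv)
  E0 <- sum(st$u^2 + st$v^2)
  for (i in 1:250) st <- navier_stokes_step(st, 0, 0, 0.002)
  expect_equal(sum(st$u^2 + st$v^2) / E0, exp(-4 * 0.02 * 0.5),
               tolerance = 0.01)
  div <- lampreysim:::mac_divergence(st$u, st$v, g$h)
  expect_lt(max(abs(div)), 1e-12)
})

test_that("trivial flows are preserved and CFL violations are caught", {
  g <- fluid_grid(10, 10, 32)
  st <- fluid_init(g)
  s1 <- navier_stokes_step(st, 0, 0, 0.01)
  expect_identical(max(abs(s1$u)) + max(abs(s1$v)), 0)    # rest stays rest
  st$u[] <- 1; st$v[] <- 0.5
  s2 <- navier_stokes_step(st, 0, 0, 0.01)
  expect_equal(max(abs(s2$u - 1)), 0, tolerance = 1e-13)  # Galilean case
  expect_equal(max(abs(s2$v - 0.5)), 0, tolerance = 1e-13)
  st$u[] <- 1e4
  expect_error(navier_stokes_step(st, 0, 0, 0.01), "CFL")
})

test_that("momentum is conserved under zero net Lagrangian force", {
  g <- fluid_grid(10, 10, 32)
  sp <- spread_forces(rbind(c(1, 2), c(-1, -2)), rbind(c(3, 3), c(7, 7)),
                      g, ds = 1)
  st <- fluid_init(g)
  set.seed(8)
  st$u <- matrix(rnorm(g$nx * g$ny, 0, 0.1), g$nx)
  st$v <- matrix(rnorm(g$nx * g$ny, 0, 0.1), g$nx)
  m0 <- c(sum(st$u), sum(st$v))
  for (i in 1:20) st <- navier_stokes_step(st, sp$fx, sp$fy, 0.005)
  expect_equal(c(sum(st$u), sum(st$v)), m0, tolerance = 1e-10)
})

test_that("the resistive drag law is local and linear", {
  F <- matrix(c(1, -2, 0.5, 4), 2, 2)
  expect_identical(resistive_step(F * 0, 3), F * 0)
  expect_equal(resistive_step(F, 6), resistive_step(F, 3) / 2)
})

test_that("the overdamped solver recovers rigid motion and equilibria", {
  # light skin so the very soft test body can still calibrate its springs
  mp <- muscle_params(k_skin = 0.1, k_cb = 0)
  g <- build_body(muscle = mp, E_target = 1e-4)
  st <- body_init(g)
  # zero force: zero velocity
  U0 <- overdamped_velocity(matrix(0, g$n_nodes, 2), st$X, g, 0.1, 1e-3)
  expect_equal(max(abs(U0)), 0, tolerance = 1e-12)
  # uniform force is a rigid mode of the network: U = F / c exactly
  Fu <- matrix(rep(c(0.3, -0.1), each = g$n_nodes), g$n_nodes, 2)
  Uu <- overdamped_velocity(Fu, st$X, g, 0.25, 1e-3)
  expect_equal(Uu, Fu / 0.25, tolerance = 1e-6)
})
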