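#' Uniform staggered (MAC) periodic fluid grid
#'
#' Square cells of side `h = Lx / nx`; `ny` is derived from the requested
#' domain height so cells stay square (the height is rounded to a whole number
#' of cells). Velocity components live on cell faces (`u[i, j]` at
#' `(i*h, (j - 1/2)*h)`, `v[i, j]` at `((i - 1/2)*h, j*h)`), pressure at cell
#' centers. Boundary conditions are periodic in both directions; pressure
#' projection and the Crank-Nicolson viscous solve are done spectrally with the
#' exact eigenvalues of the 5-point Laplacian, so the discrete divergence after
#' projection is at machine precision.
#'
#' @param Lx,Ly Domain extent, cm (the default simulation domain is 7.5 L by
#'   3.0 L).
#' @param nx Number of cells across the domain length.
#' @param rho Fluid density, g/cm^3.
#' @param mu Dynamic viscosity, g/(cm s) (water: 1 mPa s = 0.01 in cgs).
#' @return An object of class `fluid_grid`.
#' @export
fluid_grid <- function(Lx, Ly, nx, rho = 1, mu = 0.01) {
  h <- Lx / nx
  ny <- max(4L, as.integer(round(Ly / h)))
  # eigenvalues of the periodic 5-point Laplacian, as an nx x ny matrix
  kx <- -(2 / h)^2 * sin(pi * (seq_len(nx) - 1) / nx)^2
  ky <- -(2 / h)^2 * sin(pi * (seq_len(ny) - 1) / ny)^2
  structure(
    list(nx = as.integer(nx), ny = ny, h = h, Lx = Lx, Ly = ny * h,
         rho = rho, mu = mu,
         lap_eig = outer(kx, rep(1, ny)) + outer(rep(1, nx), ky)),
    class = "fluid_grid"
  )
}

#' Initialize a quiescent fluid state
#'
#' @param grid A [fluid_grid()].
#' @return An object of class `fluid_state`: `u`, `v` (nx x ny face matrices,
#'   cm/s), `p` (cell centers, dyn/cm^2), `time` (s), and the grid.
#' @export
fluid_init <- function(grid) {
  z <- matrix(0, grid$nx, grid$ny)
  structure(list(u = z, v = z, p = z, time = 0, grid = grid),
            class = "fluid_state")
}

# circular shift: element [i, j] of result is M[i + di, j + dj] (periodic)
shift2 <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  M[((seq_len(n) - 1 + di) %% n) + 1, ((seq_len(m) - 1 + dj) %% m) + 1,
    drop = FALSE]
}

fft2 <- function(M) stats::fft(M)
ifft2 <- function(M) Re(stats::fft(M, inverse = TRUE)) / length(M)

# discrete divergence at cell centers
mac_divergence <- function(u, v, h) {
  (u - shift2(u, -1, 0) + v - shift2(v, 0, -1)) / h
}

# 5-point Laplacian on a periodic face grid
lap5 <- function(M, h) {
  (shift2(M, 1, 0) + shift2(M, -1, 0) + shift2(M, 0, 1) + shift2(M, 0, -1) -
     4 * M) / h^2
}

# advection terms in divergence form at the u- and v-points
mac_advection <- function(u, v, h) {
  uc <- (u + shift2(u, -1, 0)) / 2           # u averaged to centers
  uu <- uc^2
  vc <- (v + shift2(v, 0, -1)) / 2
  vv <- vc^2
  # corner (node) products at (i*h, j*h)
  u_n <- (u + shift2(u, 0, 1)) / 2
  v_n <- (v + shift2(v, 1, 0)) / 2
  uv <- u_n * v_n
  Nu <- (shift2(uu, 1, 0) - uu) / h + (uv - shift2(uv, 0, -1)) / h
  Nv <- (uv - shift2(uv, -1, 0)) / h + (shift2(vv, 0, 1) - vv) / h
  list(Nu = Nu, Nv = Nv)
}

poisson_solve <- function(rhs, grid) {
  rh <- fft2(rhs)
  eig <- grid$lap_eig
  eig[1, 1] <- 1
  rh <- rh / eig
  rh[1, 1] <- 0
  ifft2(rh)
}

#' One projection-method step of the incompressible Navier-Stokes equations
#'
#' Explicit central advection (divergence form), Crank-Nicolson diffusion
#' solved spectrally, then an exact discrete pressure projection:
#' `rho (du/dt + u . grad u) = -grad p + mu lap u + f`, `div u = 0`.
#' With periodic boundaries and central advection the total fluid momentum
#' changes only by the integral of the applied force density.
#'
#' @param state A [fluid_init()] state.
#' @param fx,fy Eulerian force densities on the u- and v-face grids, dyn/cm^3
#'   (defaults 0).
#' @param dt Time step, s. Must satisfy the advective CFL condition.
#' @return The advanced `fluid_state` (divergence-free to solver tolerance).
#' @export
navier_stokes_step <- function(state, fx = 0, fy = 0, dt) {
  g <- state$grid
  umax <- max(abs(state$u), abs(state$v), 0)
  if (umax * dt / g$h > 1) {
    stop(sprintf(paste0("advective CFL violated (|u|max dt/h = %.2f > 1); ",
                        "use a smaller dt or fluid substeps"),
                 umax * dt / g$h), call. = FALSE)
  }
  nu2 <- g$mu * dt / (2 * g$rho)
  adv <- mac_advection(state$u, state$v, g$h)
  rhs_u <- state$u + dt * (-adv$Nu + fx / g$rho) + nu2 * lap5(state$u, g$h)
  rhs_v <- state$v + dt * (-adv$Nv + fy / g$rho) + nu2 * lap5(state$v, g$h)
  den <- 1 - nu2 * g$lap_eig
  us <- ifft2(fft2(rhs_u) / den)
  vs <- ifft2(fft2(rhs_v) / den)
  # projection: lap p = rho/dt div u*, u <- u* - dt/rho grad p
  p <- poisson_solve(g$rho / dt * mac_divergence(us, vs, g$h), g)
  u <- us - dt / g$rho * (shift2(p, 1, 0) - p) / g$h
  v <- vs - dt / g$rho * (shift2(p, 0, 1) - p) / g$h
  structure(list(u = u, v = v, p = p, time = state$time + dt, grid = g),
            class = "fluid_state")
}

#' Regularized (Peskin 4-point) delta kernel
#'
#' The one-dimensional 4-point immersed-boundary kernel in grid units:
#' supported on `|r| < 2`, even, with weights over any unit-spaced lattice
#' summing to exactly 1 and satisfying the first-moment condition.
#'
#' @param r Offset in units of the grid spacing. Vectorized.
#' @return Kernel weight(s).
#' @export
discrete_delta <- function(r) {
  a <- abs(r)
  out <- a * 0          # keep dim attributes of matrix input
  i1 <- a <= 1
  out[i1] <- (3 - 2 * a[i1] + sqrt(pmax(0, 1 + 4 * a[i1] - 4 * a[i1]^2))) / 8
  i2 <- a > 1 & a < 2
  out[i2] <- (5 - 2 * a[i2] - sqrt(pmax(0, -7 + 12 * a[i2] - 4 * a[i2]^2))) / 8
  out
}

# 4x4 stencil indices and weights of every node on a face grid with index
# coordinates (rx, ry) (so that grid point [i, j] sits at rx = i, ry = j).
ib_stencil <- function(rx, ry, nx, ny) {
  n <- length(rx)
  base_x <- floor(rx); base_y <- floor(ry)
  offs <- -1:2
  ii <- outer(base_x, offs, "+")              # n x 4
  jj <- outer(base_y, offs, "+")
  wx <- discrete_delta(rx - ii)
  wy <- discrete_delta(ry - jj)
  iiw <- ((ii - 1) %% nx) + 1
  jjw <- ((jj - 1) %% ny) + 1
  # expand to the 16-point tensor stencil
  idx <- matrix(0L, n, 16)
  w <- matrix(0, n, 16)
  for (a in 1:4) {
    for (b in 1:4) {
      col <- (a - 1) * 4 + b
      idx[, col] <- iiw[, a] + (jjw[, b] - 1) * nx
      w[, col] <- wx[, a] * wy[, b]
    }
  }
  list(idx = idx, w = w)
}

# index coordinates of physical points on the u- and v-face grids
u_grid_coords <- function(X, grid) {
  list(rx = X[, 1] / grid$h, ry = X[, 2] / grid$h + 0.5)
}
v_grid_coords <- function(X, grid) {
  list(rx = X[, 1] / grid$h + 0.5, ry = X[, 2] / grid$h)
}

#' Spread Lagrangian forces to the Eulerian grid
#'
#' Conservative spreading through the regularized delta kernel:
#' `f(x) = sum_nodes F * delta_h(x - X) * ds`, so the total Eulerian force
#' (times cell area) equals the total Lagrangian force exactly. The domain is
#' periodic; node coordinates are wrapped.
#'
#' @param forces n x 2 matrix of node forces, dyn.
#' @param X n x 2 node positions, cm.
#' @param grid A [fluid_grid()].
#' @param ds Lagrangian spacing weight per node, cm (scalar or length n).
#' @return List with `fx`, `fy`: force densities on the u-/v-face grids,
#'   dyn/cm^3.
#' @export
spread_forces <- function(forces, X, grid, ds) {
  if (!all(is.finite(X))) stop("non-finite node position in spread_forces",
                               call. = FALSE)
  ds <- rep_len(ds, nrow(X))
  scale <- ds / grid$h^2
  cu <- u_grid_coords(X, grid)
  fx <- ib_spread_cpp(cu$rx, cu$ry, forces[, 1] * scale, grid$nx, grid$ny)
  cv <- v_grid_coords(X, grid)
  fy <- ib_spread_cpp(cv$rx, cv$ry, forces[, 2] * scale, grid$nx, grid$ny)
  list(fx = fx, fy = fy)
}

#' Interpolate the grid velocity to Lagrangian nodes
#'
#' The adjoint of [spread_forces()] (same kernel weights): node velocities
#' `U(X) = sum_cells u * delta_h(x - X) * h^2`. A uniform grid field is
#' reproduced exactly (the kernel weights form a partition of unity).
#'
#' @param state A `fluid_state`.
#' @param X n x 2 node positions, cm.
#' @return n x 2 matrix of node velocities, cm/s.
#' @export
interpolate_velocity <- function(state, X) {
  if (!all(is.finite(X))) stop("non-finite node position in interpolate_velocity",
                               call. = FALSE)
  g <- state$grid
  cu <- u_grid_coords(X, g)
  U <- ib_interp_cpp(cu$rx, cu$ry, state$u, g$nx, g$ny)
  cv <- v_grid_coords(X, g)
  V <- ib_interp_cpp(cv$rx, cv$ry, state$v, g$nx, g$ny)
  cbind(U, V)
}

#' Resistive (local drag) fluid backend
#'
#' A deliberately crude closure that maps each node's force directly to a node
#' velocity through a local drag law, `U = F / c_drag`. It has none of the
#' timing or magnitude fidelity of the Navier-Stokes backend and is used only
#' to exercise the closed loop cheaply (plumbing and trend tests), never for
#' hydrodynamic numbers.
#'
#' @param forces n x 2 node forces, dyn.
#' @param c_drag Drag coefficient, dyn s/cm.
#' @return n x 2 node velocities, cm/s.
#' @export
resistive_step <- function(forces, c_drag) {
  forces / c_drag
}

#' Node velocities of the overdamped (resistive) body backend
#'
#' Solves one backward-Euler step of the overdamped spring-network dynamics
#' `c dX/dt = F(X)`: linearizing the elastic force about the current state,
#' `(c/dt I - J) dX = F(X^n)`, with `J` the spring-network Jacobian. The
#' implicit treatment of the network makes the step unconditionally stable in
#' the spring stiffness, so the quasi-static (drag-dominated) regime can be
#' stepped at the neural time step. Muscle and skin tensions enter explicitly
#' through `forces`.
#'
#' @param forces n x 2 total node forces at the current state, dyn.
#' @param X n x 2 node positions, cm.
#' @param geometry A [build_body()] geometry (supplies the elastic network).
#' @param c_drag Local drag coefficient, dyn s/cm.
#' @param dt Time step, s.
#' @param extra_jac Optional extra Jacobian triplets (list `i`, `j`, `x`),
#'   e.g. from the lateral muscle/skin elements, added to the spring network's.
#' @param c_aniso Normal-to-tangential drag ratio (default 1: isotropic). With
#'   anisotropic drag (slender bodies have roughly twice the normal drag) the
#'   undulating chain generates net thrust, as in resistive-force theory.
#' @param tangents n x 2 unit tangents per node (required when `c_aniso != 1`).
#' @param cache Optional environment caching the sparse LU factorization
#'   across steps; the Jacobian is rebuilt once any node has moved more than
#'   `cache$tol` cm since the last factorization (the body deforms slowly
#'   relative to the step, so a slightly stale Jacobian is safe within that
#'   bound).
#' @return n x 2 matrix of node velocities, cm/s.
#' @export
overdamped_velocity <- function(forces, X, geometry, c_drag, dt,
                                cache = NULL, extra_jac = NULL,
                                c_aniso = 1, tangents = NULL) {
  n <- nrow(X)
  stale <- is.null(cache) || is.null(cache$fac) ||
    max(abs(X - cache$X_fac)) > cache$tol
  if (stale) {
    tr <- spring_jacobian_cpp(X, geometry$links$from, geometry$links$to,
                              geometry$k0 * geometry$k_factor_over_l0,
                              geometry$l0, n)
    i <- tr$i; j <- tr$j; x <- tr$x
    if (!is.null(extra_jac)) {
      i <- c(i, extra_jac$i); j <- c(j, extra_jac$j); x <- c(x, extra_jac$x)
    }
    A <- Matrix::sparseMatrix(i = i, j = j, x = -x, dims = c(2 * n, 2 * n))
    if (c_aniso != 1 && !is.null(tangents)) {
      # anisotropic local drag C = c_t t t^T + c_n n n^T (slender-body style:
      # normal drag exceeds tangential, which is what yields net propulsion
      # from an undulating wave in a resistive medium)
      tx <- tangents[, 1]; ty <- tangents[, 2]
      cn <- c_aniso * c_drag
      Cxx <- c_drag * tx^2 + cn * ty^2
      Cyy <- c_drag * ty^2 + cn * tx^2
      Cxy <- (c_drag - cn) * tx * ty
      idx <- seq_len(n)
      A <- A + Matrix::sparseMatrix(
        i = c(idx, idx + n, idx, idx + n),
        j = c(idx, idx + n, idx + n, idx),
        x = c(Cxx, Cyy, Cxy, Cxy) / dt,
        dims = c(2 * n, 2 * n))
    } else {
      A <- A + Matrix::Diagonal(2 * n, c_drag / dt)
    }
    fac <- Matrix::lu(A)
    if (!is.null(cache)) {
      cache$fac <- fac
      cache$X_fac <- X
    }
  } else {
    fac <- cache$fac
  }
  dX <- Matrix::solve(fac, as.vector(forces))
  matrix(as.vector(dX), n, 2) / dt
}
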