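# Strain/vorticity decomposition, generalized advection, Q stepping.

test_that("strain and vorticity recover linear velocity fields exactly", {
  nx <- 24
  x <- coord_x(nx); y <- coord_y(nx)
  inner <- 3:(nx - 2)   # central stencils are exact on linear fields away
                        # from the (non-periodic) wrap of these fixtures
  def0 <- strain_vorticity(matrix(0.3, nx, nx), matrix(-0.1, nx, nx))
  expect_equal(max(abs(def0$Exx)) + max(abs(def0$Exy)) +
                 max(abs(def0$Omega)), 0)

  w0 <- 0.05
  rig <- strain_vorticity(-w0 * y, w0 * x)
  expect_equal(rig$Exx[inner, inner], matrix(0, 20, 20), tolerance = 1e-13)
  expect_equal(rig$Exy[inner, inner], matrix(0, 20, 20), tolerance = 1e-13)
  expect_equal(rig$Omega[inner, inner], matrix(w0, 20, 20), tolerance = 1e-13)

  gd <- 0.02   # pure shear u = (gd * y, 0)
  sh <- strain_vorticity(gd * y, matrix(0, nx, nx))
  expect_equal(sh$Exy[inner, inner], matrix(gd / 2, 20, 20), tolerance = 1e-13)
  expect_equal(sh$Omega[inner, inner], matrix(-gd / 2, 20, 20),
               tolerance = 1e-13)
})

test_that("generalized advection vanishes at rest and co-rotates at lambda = 0", {
  nx <- 8
  Q <- list(xx = matrix(0.04, nx, nx), xy = matrix(-0.02, nx, nx))
  rest <- list(Exx = matrix(0, nx, nx), Eyy = matrix(0, nx, nx),
               Exy = matrix(0, nx, nx), Omega = matrix(0, nx, nx))
  W <- generalized_advection(Q, rest, lambda = 0.7)
  expect_equal(max(abs(W$xx)) + max(abs(W$xy)), 0)

  # uniform vorticity, lambda = 0: dQ/dt = W must rotate the director with
  # the flow; oracle = closed-form rigidly rotating solution
  w0 <- 0.1; S <- 0.3; th0 <- 0.4
  spin <- rest; spin$Omega <- matrix(w0, nx, nx)
  qof <- function(th) list(xx = matrix(S / 2 * cos(2 * th), nx, nx),
                           xy = matrix(S / 2 * sin(2 * th), nx, nx))
  Qt <- qof(th0)
  rhs <- function(Q) generalized_advection(Q, spin, lambda = 0)
  step <- function(Q, k, h) list(xx = Q$xx + h * k$xx, xy = Q$xy + h * k$xy)
  dt <- 0.05
  for (s in 1:100) {          # RK4
    k1 <- rhs(Qt); k2 <- rhs(step(Qt, k1, dt / 2))
    k3 <- rhs(step(Qt, k2, dt / 2)); k4 <- rhs(step(Qt, k3, dt))
    Qt <- list(xx = Qt$xx + dt / 6 * (k1$xx + 2 * k2$xx + 2 * k3$xx + k4$xx),
               xy = Qt$xy + dt / 6 * (k1$xy + 2 * k2$xy + 2 * k3$xy + k4$xy))
  }
  exact <- qof(th0 + w0 * 5)   # director advanced by w0 * t
  expect_equal(Qt$xx[1, 1], exact$xx[1, 1], tolerance = 1e-6)
  expect_equal(Qt$xy[1, 1], exact$xy[1, 1], tolerance = 1e-6)
  # order magnitude is preserved by pure co-rotation
  expect_equal(2 * sqrt(Qt$xx[1, 1]^2 + Qt$xy[1, 1]^2), S, tolerance = 1e-7)
})

test_that("step_q is a fixed point at rest and decays at the ODE-oracle rate", {
  nx <- 16
  zero <- matrix(0, nx, nx)
  Q <- list(xx = smooth_random_field(nx, seed = 5, amp = 0.04),
            xy = smooth_random_field(nx, seed = 6, amp = 0.04))
  H0 <- list(xx = zero, xy = zero)
  Q1 <- step_q(Q, zero, zero, H0, gamma = 0.3)
  expect_equal(Q1$xx, Q$xx)
  expect_equal(Q1$xy, Q$xy)

  # uniform Q with its molecular field: |Q| obeys da/dt = -gamma C (1+a^2) a;
  # oracle = fine-step RK4 of the scalar ODE
  fe <- free_energy_params(C = 0.05)   # faster relaxation for a short test
  gamma <- 0.3
  a0 <- 0.3; th <- 1.1
  Qu <- list(xx = matrix(a0 * cos(2 * th), nx, nx),
             xy = matrix(a0 * sin(2 * th), nx, nx))
  n_steps <- 400
  for (s in seq_len(n_steps)) {
    H <- molecular_field(Qu, fe)
    Qu <- step_q(Qu, zero, zero, H, gamma = gamma)
  }
  rhs <- function(a) -gamma * fe$C * (1 + a^2) * a
  a <- a0; h <- 0.05
  for (s in seq_len(n_steps / h)) {
    k1 <- rhs(a); k2 <- rhs(a + h / 2 * k1)
    k3 <- rhs(a + h / 2 * k2); k4 <- rhs(a + h * k3)
    a <- a + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(sqrt(Qu$xx[1, 1]^2 + Qu$xy[1, 1]^2), a, tolerance = 2e-3)

  # blow-up guard
  expect_error(step_q(list(xx = matrix(20, nx, nx), xy = zero),
                      zero, zero, H0, gamma = 0.3), "blew up")
})

test_that("a Q pattern advects unchanged under uniform translation", {
  nx <- 64
  u <- 0.4; n_steps <- 80          # total displacement 32 nodes
  Q <- list(xx = fourier_mode(nx, mx = 1, amp = 0.05),
            xy = fourier_mode(nx, mx = 1, phase = 1, amp = 0.05))
  ux <- matrix(u, nx, nx); uy <- matrix(0, nx, nx)
  H0 <- list(xx = matrix(0, nx, nx), xy = matrix(0, nx, nx))
  Qt <- Q
  for (s in seq_len(n_steps)) Qt <- step_q(Qt, ux, uy, H0, gamma = 0)
  # cross-correlation over integer shifts locates the pattern displacement
  cors <- vapply(0:(nx - 1), function(s)
    sum(Qt$xx * shift_field(Q$xx, s, 0)), 0)
  expect_equal(which.max(cors) - 1, round(u * n_steps))
})
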