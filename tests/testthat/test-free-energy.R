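# Free-energy density and its functional derivatives.

fe <- free_energy_params()

test_that("uniform phases give the constant bulk offset and zero drives", {
  nx <- 16
  zeroQ <- list(xx = matrix(0, nx, nx), xy = matrix(0, nx, nx))
  for (phival in c(0, 1)) {
    phi <- matrix(phival, nx, nx)
    f <- free_energy_density(phi, zeroQ, fe)
    expect_equal(f, matrix(fe$C / 2, nx, nx))           # only the C/2 offset
    expect_equal(chemical_potential(phi, fe), matrix(0, nx, nx))
  }
  # phi = 1/2: unstable equilibrium of the (odd about 1/2) well
  expect_equal(chemical_potential(matrix(0.5, nx, nx), fe),
               matrix(0, nx, nx))
  # isotropic state is a fixed point of the nematic dynamics
  H <- molecular_field(zeroQ, fe)
  expect_equal(H$xx, matrix(0, nx, nx))
  expect_equal(H$xy, matrix(0, nx, nx))
})

test_that("uniform nematic relaxes toward the isotropic state", {
  nx <- 12; S <- 0.1; th <- 0.7
  Q <- list(xx = matrix(S / 2 * cos(2 * th), nx, nx),
            xy = matrix(S / 2 * sin(2 * th), nx, nx))
  H <- molecular_field(Q, fe)
  fac <- -fe$C * (1 + S^2 / 4)
  expect_equal(H$xx, fac * Q$xx, tolerance = 1e-12)
  expect_equal(H$xy, fac * Q$xy, tolerance = 1e-12)
  # H drives Q toward 0 (energy decreases along gamma H)
  dF <- sum(-2 * (H$xx^2 + H$xy^2))   # dF/dt under dQ/dt = H
  expect_lt(dF, 0)
  # printed sign convention destabilizes instead
  fe_printed <- free_energy_params(convention = "printed")
  Hp <- molecular_field(Q, fe_printed)
  expect_equal(Hp$xx, -fac * Q$xx, tolerance = 1e-12)
})

test_that("straight-interface energy matches 1D quadrature of the integrand", {
  nx <- 128
  d <- sqrt(8 * fe$K_phi / fe$B)
  x <- (0:(nx - 1))
  # two kinks (periodic stripe): up at x=32, down at x=96
  prof <- 0.5 * (tanh((x - 32) / d) - tanh((x - 96) / d))
  phi <- matrix(rep(prof, nx / 4), nx, nx / 4)
  zeroQ <- list(xx = matrix(0, nx, nx / 4), xy = matrix(0, nx, nx / 4))
  Egrid <- (total_free_energy(phi, zeroQ, fe, scheme = "central") -
              fe$C / 2 * nx * (nx / 4)) / (nx / 4)   # energy per unit length
  integrand <- function(s, x0) {
    ph <- 0.5 * (1 + tanh((s - x0) / d))
    dph <- 0.5 / d / cosh((s - x0) / d)^2
    fe$B / 2 * ph^2 * (1 - ph)^2 + fe$K_phi * dph^2
  }
  Equad <- 2 * stats::integrate(integrand, -40, 40, x0 = 0)$value
  expect_equal(Egrid, Equad, tolerance = 0.02)
})

test_that("H and mu are the exact functional derivatives of the discrete energy", {
  nx <- 12
  phi <- 0.5 + smooth_random_field(nx, seed = 11, amp = 0.12)
  Q <- list(xx = smooth_random_field(nx, seed = 12, amp = 0.05),
            xy = smooth_random_field(nx, seed = 13, amp = 0.05))
  mu <- chemical_potential(phi, fe)
  H <- molecular_field(Q, fe)
  Ftot <- function(phi, Q) total_free_energy(phi, Q, fe, scheme = "forward")
  set.seed(4)
  nodes <- cbind(sample(nx, 6, TRUE), sample(nx, 6, TRUE))
  for (r in seq_len(nrow(nodes))) {
    i <- nodes[r, 1]; j <- nodes[r, 2]
    quot <- function(bump) {
      eps <- 1e-5
      (Ftot(bump(eps)$phi, bump(eps)$Q) - Ftot(bump(-eps)$phi, bump(-eps)$Q)) /
        (2 * eps)
    }
    dphi <- quot(function(e) { p2 <- phi; p2[i, j] <- p2[i, j] + e
                               list(phi = p2, Q = Q) })
    expect_equal(dphi, mu[i, j], tolerance = 1e-6)
    # perturbing the independent component Qxx also moves Qyy = -Qxx, so the
    # numerical derivative is twice the tensor-convention -H component
    dqxx <- quot(function(e) { q2 <- Q; q2$xx[i, j] <- q2$xx[i, j] + e
                               list(phi = phi, Q = q2) })
    expect_equal(dqxx, -2 * H$xx[i, j], tolerance = 1e-6)
    dqxy <- quot(function(e) { q2 <- Q; q2$xy[i, j] <- q2$xy[i, j] + e
                               list(phi = phi, Q = q2) })
    expect_equal(dqxy, -2 * H$xy[i, j], tolerance = 1e-6)
  }
})

test_that("relaxational dynamics at u = 0 monotonically decreases the energy", {
  nx <- 24
  gamma <- 0.3; Gphi <- 0.2
  phi <- 0.5 + smooth_random_field(nx, seed = 21, amp = 0.15)
  Q <- list(xx = smooth_random_field(nx, seed = 22, amp = 0.08),
            xy = smooth_random_field(nx, seed = 23, amp = 0.08))
  en <- numeric(120)
  mass0 <- sum(phi)
  dt <- 0.4    # the compact-stencil Cahn-Hilliard step is unstable at dt = 1
  for (s in seq_along(en)) {
    en[s] <- total_free_energy(phi, Q, fe)
    H <- molecular_field(Q, fe)
    Q$xx <- Q$xx + dt * gamma * H$xx
    Q$xy <- Q$xy + dt * gamma * H$xy
    mu <- chemical_potential(phi, fe)
    phi <- phi + dt * Gphi * laplacian_field(mu)
  }
  expect_true(all(diff(en) <= 1e-12))
  expect_equal(sum(phi), mass0, tolerance = 1e-12)   # conservative
})
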