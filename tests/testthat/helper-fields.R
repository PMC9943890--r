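# Shared fixtures: analytic fields on periodic grids, built in code.

coord_x <- function(nx, ny = nx, dx = 1) {
  matrix(rep((0:(nx - 1)) * dx, ny), nx, ny)
}
coord_y <- function(nx, ny = nx, dx = 1) {
  matrix(rep((0:(ny - 1)) * dx, each = nx), nx, ny)
}

# single periodic Fourier mode with integer wavenumbers (mx, my)
fourier_mode <- function(nx, mx = 1, my = 0, phase = 0, amp = 1, fun = sin) {
  x <- coord_x(nx); y <- coord_y(nx)
  amp * fun(2 * pi * (mx * x + my * y) / nx + phase)
}

# smooth random periodic field from a handful of low modes (deterministic)
smooth_random_field <- function(nx, seed = 1, n_modes = 4, amp = 0.1) {
  set.seed(seed)
  f <- matrix(0, nx, nx)
  for (k in seq_len(n_modes)) {
    f <- f + fourier_mode(nx, sample(1:3, 1), sample(-3:3, 1),
                          phase = runif(1, 0, 2 * pi),
                          amp = amp * runif(1, 0.3, 1))
  }
  f
}

# circular shift of a matrix by (sx, sy) nodes (periodic translation)
shift_field <- function(f, sx = 0, sy = 0) {
  nx <- nrow(f); ny <- ncol(f)
  f[((seq_len(nx) - 1 - sx) %% nx) + 1, ((seq_len(ny) - 1 - sy) %% ny) + 1]
}

# rigid-rotation trajectory table used by several kinematics tests
rigid_rotation_tracks <- function(n = 12, radius = 50, omega0 = 0.05,
                                  times = seq(0, 12, 2), center = c(0, 0),
                                  seed = 1) {
  set.seed(seed)
  th0 <- runif(n, 0, 2 * pi)
  r0 <- radius * sqrt(runif(n))
  do.call(rbind, lapply(times, function(t) {
    data.frame(track_id = seq_len(n), cluster_id = 1L, t_h = t,
               x_um = center[1] + r0 * cos(th0 + omega0 * t),
               y_um = center[2] + r0 * sin(th0 + omega0 * t))
  }))
}
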