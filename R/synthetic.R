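# Seeded synthetic-data generators emulating the study's data products, so
# that every analysis stage can be exercised without microscopy input.
# Every generator returns the dataset together with its ground truth and is
# deterministic given (spec, seed).
#
# Noise model: isotropic Gaussian positional error (manual-tracking error),
# default 1 um per coordinate per frame.  Default coherent rotation rate
# 0.05 rad/h: per 2 h sampling step that is ~5.7 degrees, comfortably inside
# the unwrapping Nyquist bound of pi per interval.

# Uniform sample in an ellipse with semi-axes a, b.  With quotas, exactly
# n_inner points end up within r_split (Euclidean) of the *sample centroid*:
# points are drawn avoiding a small annulus around the split radius (so the
# downstream region partition, which measures radii from the estimated
# centroid, classifies them stably), the cloud is recentred on its mean and
# redrawn until the quota holds relative to that mean.
sample_ellipse <- function(n, a, b, n_inner = NULL, r_split = NULL,
                           margin = 0.12) {
  draw <- function(m) {
    u <- sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
    cbind(a * u * cos(th), b * u * sin(th))
  }
  if (is.null(n_inner)) return(draw(n))
  if (is.null(r_split)) stop("r_split required when n_inner is given")
  if (r_split >= max(a, b) && n - n_inner > 0)
    stop("outer quota infeasible: r_split covers the whole ellipse")
  gap <- margin * r_split
  for (attempt in 1:500) {
    inner <- matrix(0, 0, 2); outer <- matrix(0, 0, 2)
    for (it in 1:200) {
      p <- draw(4 * n)
      r <- sqrt(rowSums(p^2))
      inner <- rbind(inner, p[r < r_split - gap, , drop = FALSE])
      outer <- rbind(outer, p[r >= r_split + gap, , drop = FALSE])
      if (nrow(inner) >= n_inner && nrow(outer) >= n - n_inner) break
    }
    if (nrow(inner) < n_inner || nrow(outer) < n - n_inner)
      stop("could not satisfy the region quotas")
    cloud <- rbind(inner[seq_len(n_inner), , drop = FALSE],
                   outer[seq_len(n - n_inner), , drop = FALSE])
    cloud <- sweep(cloud, 2, colMeans(cloud))   # centroid exactly at origin
    if (sum(sqrt(rowSums(cloud^2)) < r_split) == n_inner) return(cloud)
  }
  stop("could not satisfy the region quotas about the sample centroid")
}

polar_tracks <- function(xy0, times, theta_of, r_of, center_of, noise_sd,
                         cluster_id) {
  n <- nrow(xy0)
  r0 <- sqrt(rowSums(xy0^2)); th0 <- atan2(xy0[, 2], xy0[, 1])
  rows <- lapply(seq_along(times), function(k) {
    t <- times[k]
    th <- theta_of(th0, t, k); r <- r_of(r0, t, k); ctr <- center_of(t)
    data.frame(track_id = seq_len(n), cluster_id = cluster_id, t_h = t,
               x_um = ctr[1] + r * cos(th) + rnorm(n, 0, noise_sd),
               y_um = ctr[2] + r * sin(th) + rnorm(n, 0, noise_sd))
  })
  do.call(rbind, rows)
}

#' Generate a coherently rotating cell cluster
#'
#' Cells are placed uniformly in an ellipse (optionally with exact
#' inner/outer quotas about `r_split`), rotated rigidly at `omega0` about
#' the (possibly drifting) cluster center, given a small outward radial
#' drift, and observed with isotropic Gaussian positional noise.
#'
#' @param n_cells number of cells (>= 3).
#' @param radius mean cluster radius in um (average of the semi-axes).
#' @param aspect aspect ratio (minor/major, in (0, 1]).
#' @param omega0 signed angular velocity, rad/h.
#' @param v_rho radial drift, um/min.
#' @param noise_sd positional noise SD, um.
#' @param sample_step sampling interval, h.
#' @param duration tracking window, h.
#' @param center cluster center at t = 0 (um).
#' @param drift center drift velocity, um/h (length-2).
#' @param n_inner,r_split optional placement quotas: exactly `n_inner`
#'   cells start within `r_split` um of the center.
#' @param cluster_id id attached to the table.
#' @param seed RNG seed.
#' @return list with `tracks` (a trajectory table) and `truth`.
#' @export
gen_rotating_cluster <- function(n_cells = 52, radius = 84, aspect = 0.83,
                                 omega0 = 0.05, v_rho = 0.04, noise_sd = 1,
                                 sample_step = 2, duration = 12,
                                 center = c(0, 0), drift = c(0, 0),
                                 n_inner = NULL, r_split = NULL,
                                 cluster_id = 1L, seed = NULL) {
  if (n_cells < 3) stop("need at least 3 cells")
  if (radius < 0 || noise_sd < 0) stop("radius and noise_sd must be >= 0")
  if (aspect <= 0 || aspect > 1) stop("aspect ratio must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  a <- 2 * radius / (1 + aspect); b <- a * aspect
  xy0 <- sample_ellipse(n_cells, a, b, n_inner, r_split)
  times <- seq(0, duration, by = sample_step)
  v_h <- um_per_min_to_um_per_h(v_rho)
  tracks <- polar_tracks(
    xy0, times,
    theta_of = function(th0, t, k) th0 + omega0 * t,
    r_of = function(r0, t, k) r0 + v_h * t,
    center_of = function(t) center + drift * t,
    noise_sd = noise_sd, cluster_id = cluster_id)
  r0 <- sqrt(rowSums(xy0^2))
  truth <- list(omega0 = omega0, v_rho = v_rho, center = center,
                drift = drift, r0 = r0,
                region = if (!is.null(r_split))
                  ifelse(r0 < r_split, "inner", "outer") else NULL,
                semi_axes = c(a = a, b = b))
  list(tracks = tracks, truth = truth)
}

#' Generate an incoherent (negative-control) cluster
#'
#' Each cell performs an independent zero-mean random walk in its angular
#' and radial coordinates, with per-interval displacement SDs matched to
#' the coherent generator's systematic displacements (`omega_sd` against
#' `omega0`, `v_sd` against `v_rho`).  Population-mean angular velocity is
#' zero by construction; per-cell spread exceeds the coherent case.
#'
#' @inheritParams gen_rotating_cluster
#' @param omega_sd per-interval angular step SD, rad/h.
#' @param v_sd per-interval radial step SD, um/min.
#' @return list with `tracks` and `truth` (`omega0 = 0`).
#' @export
gen_incoherent_cluster <- function(n_cells = 28, radius = 70, aspect = 0.65,
                                   omega_sd = 0.05, v_sd = 0.04,
                                   noise_sd = 1, sample_step = 2,
                                   duration = 12, center = c(0, 0),
                                   n_inner = NULL, r_split = NULL,
                                   cluster_id = 1L, seed = NULL) {
  if (n_cells < 3) stop("need at least 3 cells")
  if (aspect <= 0 || aspect > 1) stop("aspect ratio must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  a <- 2 * radius / (1 + aspect); b <- a * aspect
  xy0 <- sample_ellipse(n_cells, a, b, n_inner, r_split)
  times <- seq(0, duration, by = sample_step)
  nt <- length(times)
  v_h <- um_per_min_to_um_per_h(v_sd)
  dth <- rbind(0, matrix(rnorm(n_cells * (nt - 1), 0,
                               omega_sd * sample_step), nt - 1, n_cells))
  dr <- rbind(0, matrix(rnorm(n_cells * (nt - 1), 0,
                              v_h * sample_step), nt - 1, n_cells))
  cth <- apply(dth, 2, cumsum); cr <- apply(dr, 2, cumsum)
  tracks <- polar_tracks(
    xy0, times,
    theta_of = function(th0, t, k) th0 + cth[k, ],
    r_of = function(r0, t, k) pmax(r0 + cr[k, ], 0),
    center_of = function(t) center,
    noise_sd = noise_sd, cluster_id = cluster_id)
  r0 <- sqrt(rowSums(xy0^2))
  truth <- list(omega0 = 0, omega_sd = omega_sd, v_sd = v_sd, r0 = r0,
                region = if (!is.null(r_split))
                  ifelse(r0 < r_split, "inner", "outer") else NULL)
  list(tracks = tracks, truth = truth)
}

#' Generate exponential cell-count records
#'
#' Per-cluster counts `N(t) = round(N0 2^(t/t_d) eps)` with lognormal
#' multiplicative noise `eps`, and cluster areas tied to the counts through
#' a per-cluster area-per-cell (so density is constant, the free-expansion
#' regime).  With `boundary_spread = TRUE` small clusters get a reduced
#' area per cell that rises towards the plateau below the change-point
#' threshold, mimicking boundary-cell spreading.
#'
#' @param n_clusters number of clusters.
#' @param N0_range integer range of initial counts (uniform draw).
#' @param t_d duplication time, h.
#' @param sigma lognormal noise SD (log scale).
#' @param times sampling times, h.
#' @param a_cell mean area per cell, um^2.
#' @param a_cell_cv between-cluster coefficient of variation of `a_cell`.
#' @param boundary_spread emulate the rising small-cluster regime.
#' @param seed RNG seed.
#' @return list with `records` (`cluster_id`, `t_h`, `n_cells`,
#'   `area_um2`) and `truth`.
#' @export
gen_growth_counts <- function(n_clusters = 50, N0_range = c(5, 50),
                              t_d = 71, sigma = 0.15,
                              times = seq(0, 144, by = 12),
                              a_cell = 500, a_cell_cv = 0,
                              boundary_spread = FALSE, seed = NULL) {
  if (t_d <= 0) stop("t_d must be positive")
  if (!is.null(seed)) set.seed(seed)
  N0 <- sample(N0_range[1]:N0_range[2], n_clusters, replace = TRUE)
  ac <- a_cell * if (a_cell_cv > 0)
    rlnorm(n_clusters, -a_cell_cv^2 / 2, a_cell_cv) else rep(1, n_clusters)
  recs <- lapply(seq_len(n_clusters), function(j) {
    eps <- if (sigma > 0) rlnorm(length(times), 0, sigma) else 1
    n <- pmax(1L, as.integer(round(N0[j] * 2^(times / t_d) * eps)))
    area <- n * ac[j]
    if (boundary_spread) area <- area * pmin(1, (area / 2e4))^0.5
    data.frame(cluster_id = j, t_h = times, n_cells = n, area_um2 = area)
  })
  list(records = do.call(rbind, recs),
       truth = list(t_d = t_d, N0 = N0, a_cell = ac, sigma = sigma))
}

#' Generate confluence-versus-time curves
#'
#' `A_s(t) = min(cap, A_s0 2^(t/tau) eps)` for several initial confluences,
#' with lognormal multiplicative noise.
#'
#' @param a_s0 vector of initial confluence values.
#' @param tau occupancy doubling time, h.
#' @param sigma lognormal noise SD.
#' @param times sampling times, h.
#' @param cap saturation (full confluence).
#' @param seed RNG seed.
#' @return list with `series` (`sample_id`, `t_h`, `a_s`) and `truth`.
#' @export
gen_confluence_curves <- function(a_s0 = c(0.05, 0.1, 0.2, 0.4), tau = 50.8,
                                  sigma = 0.05, times = seq(0, 168, by = 8),
                                  cap = 1, seed = NULL) {
  if (tau <= 0) stop("tau must be positive")
  if (any(a_s0 <= 0 | a_s0 > 1)) stop("a_s0 values must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ser <- lapply(seq_along(a_s0), function(j) {
    eps <- if (sigma > 0) rlnorm(length(times), 0, sigma) else 1
    data.frame(sample_id = sprintf("s%02d", j), t_h = times,
               a_s = pmin(cap, a_s0[j] * 2^(times / tau) * eps))
  })
  list(series = do.call(rbind, ser),
       truth = list(tau = tau, a_s0 = a_s0, sigma = sigma, cap = cap))
}
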