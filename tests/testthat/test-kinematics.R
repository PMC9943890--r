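# Polar decomposition of cell trajectories, region partition, population
# statistics and the angular-velocity-versus-area aggregation.

test_that("cluster centroid is the mean and is translation-equivariant", {
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(cluster_centroid(sq[, 1], sq[, 2]), c(x = 1, y = 1))
  expect_equal(cluster_centroid(sq[, 1] + 5, sq[, 2] - 3), c(x = 6, y = -2))
  expect_error(cluster_centroid(1:2, 3:4), "at least 3")

  # estimated centroid of a generated cluster is close to the true center
  g <- gen_rotating_cluster(n_cells = 52, center = c(120, -40), noise_sd = 1,
                            seed = 5)
  f0 <- g$tracks[g$tracks$t_h == 0, ]
  ctr <- cluster_centroid(f0$x_um, f0$y_um)
  # cells spread over a radius-84 ellipse: SE of the mean ~ 84/2/sqrt(52)
  expect_lt(sqrt(sum((ctr - c(120, -40))^2)), 4 * 84 / 2 / sqrt(52))
})

test_that("rigid rotation is recovered exactly and respects rigid motions", {
  tr <- rigid_rotation_tracks(n = 15, omega0 = 0.05, seed = 2)
  pk <- polar_velocities(tr, interval = 2)
  expect_equal(pk$omega, rep(0.05, nrow(pk)), tolerance = 1e-12)
  expect_equal(pk$v_rho, rep(0, nrow(pk)), tolerance = 1e-12)

  # global translation + rotation of every frame leaves omega, v_rho unchanged
  a <- 0.8; Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  tr2 <- tr
  xy <- as.matrix(tr[c("x_um", "y_um")]) %*% t(Rm)
  tr2$x_um <- xy[, 1] + 300; tr2$y_um <- xy[, 2] - 120
  pk2 <- polar_velocities(tr2, interval = 2)
  expect_equal(pk2$omega, pk$omega, tolerance = 1e-10)
  expect_equal(pk2$v_rho, pk$v_rho, tolerance = 1e-10)
})

test_that("pure radial drift gives v_rho = v and omega = 0", {
  set.seed(3)
  n <- 10; th0 <- runif(n, 0, 2 * pi); r0 <- 30 + 40 * runif(n)
  v_h <- 2.4   # um/h = 0.04 um/min
  tr <- do.call(rbind, lapply(seq(0, 12, 2), function(t)
    data.frame(track_id = seq_len(n), cluster_id = 1L, t_h = t,
               x_um = (r0 + v_h * t) * cos(th0),
               y_um = (r0 + v_h * t) * sin(th0))))
  # measure about the known center: radial motion moves the point centroid
  ctrs <- data.frame(cluster_id = 1L, t_h = seq(0, 12, 2), cx_um = 0, cy_um = 0)
  pk <- polar_velocities(tr, interval = 2, centers = ctrs)
  expect_equal(pk$v_rho, rep(v_h / 60, nrow(pk)), tolerance = 1e-12)
  expect_equal(pk$omega, rep(0, nrow(pk)), tolerance = 1e-12)
})

test_that("angle unwrapping is exact below Nyquist and aliases beyond", {
  mk <- function(om) rigid_rotation_tracks(n = 8, radius = 40, omega0 = om,
                                           times = c(0, 2), seed = 4)
  # |omega| * 2 h just below pi: exact recovery
  om_hi <- (pi - 1e-6) / 2
  expect_equal(polar_velocities(mk(om_hi), 2)$omega[1], om_hi,
               tolerance = 1e-9)
  # just beyond the bound the measured rate aliases to the negative branch
  om_over <- (pi + 0.2) / 2
  expect_lt(polar_velocities(mk(om_over), 2)$omega[1], 0)
})

test_that("near-pole cells lose omega but keep v_rho", {
  tr <- rigid_rotation_tracks(n = 8, radius = 40, seed = 6)
  # plant one cell on the centroid-adjacent pole
  ctrs <- data.frame(cluster_id = 1L, t_h = seq(0, 12, 2), cx_um = 0, cy_um = 0)
  tr[tr$track_id == 1, c("x_um", "y_um")] <-
    cbind(0.5 * cos(0.05 * seq(0, 12, 2)), 0.5 * sin(0.05 * seq(0, 12, 2)))
  pk <- polar_velocities(tr, interval = 2, r_eps = 2, centers = ctrs)
  expect_true(all(is.na(pk$omega[pk$track_id == 1])))
  expect_true(all(is.finite(pk$v_rho[pk$track_id == 1])))
})

test_that("region partition reproduces the reference population counts", {
  g <- gen_rotating_cluster(n_cells = 52, radius = 84, aspect = 0.83,
                            n_inner = 23, r_split = 46, seed = 7,
                            noise_sd = 0)
  reg <- partition_regions(g$tracks, r_split = 46)
  expect_equal(sum(reg$region == "inner"), 23)
  expect_equal(sum(reg$region == "outer"), 29)

  g2 <- gen_incoherent_cluster(n_cells = 28, radius = 70, aspect = 0.65,
                               n_inner = 11, r_split = 38, seed = 8,
                               noise_sd = 0)
  reg2 <- partition_regions(g2$tracks, r_split = 38)
  expect_equal(sum(reg2$region == "inner"), 11)
  expect_equal(sum(reg2$region == "outer"), 17)

  # degenerate split: everything inner, empty region flagged
  expect_warning(reg3 <- partition_regions(g$tracks, r_split = 1e5), "empty")
  expect_true(all(reg3$region == "inner"))
})

test_that("population statistics have the expected structure and symmetry", {
  # identical cells: zero SD
  tr <- rigid_rotation_tracks(n = 6, omega0 = 0.04, seed = 9)
  st <- population_stats(polar_velocities(tr, 2))
  expect_true(all(abs(st$time_series$omega_sd) < 1e-12))
  expect_equal(st$time_averaged$omega_mean, 0.04, tolerance = 1e-12)

  # mirror-symmetric pair of clusters: grand mean zero
  trp <- rigid_rotation_tracks(n = 10, omega0 = 0.05, seed = 10)
  trm <- rigid_rotation_tracks(n = 10, omega0 = -0.05, seed = 10)
  trm$cluster_id <- 2L; trm$track_id <- trm$track_id + 100
  st2 <- population_stats(polar_velocities(rbind(trp, trm), 2))
  expect_equal(mean(st2$time_averaged$omega_mean), 0, tolerance = 1e-12)
})

test_that("noisy generated clusters recover the generator kinematics", {
  g <- gen_rotating_cluster(n_cells = 52, omega0 = 0.05, v_rho = 0.04,
                            noise_sd = 1, seed = 11)
  pk <- polar_velocities(g$tracks, interval = 2)
  om <- pk$omega[is.finite(pk$omega)]
  expect_lt(abs(mean(om) - 0.05), 3 * sd(om) / sqrt(length(om)))
  # the radial component is measured about the known (contour) center: the
  # tracked-cell centroid itself drifts with the radial expansion
  ctrs <- data.frame(cluster_id = 1L, t_h = unique(g$tracks$t_h),
                     cx_um = 0, cy_um = 0)
  vr <- polar_velocities(g$tracks, interval = 2, centers = ctrs)$v_rho
  expect_lt(abs(mean(vr) - 0.04), 3 * sd(vr) / sqrt(length(vr)))

  # coherent cluster beats the incoherent negative control at matched noise
  gi <- gen_incoherent_cluster(n_cells = 52, radius = 84, aspect = 0.83,
                               omega_sd = 0.05, noise_sd = 1, seed = 12)
  sti <- population_stats(polar_velocities(gi$tracks, 2))
  stc <- population_stats(pk)
  expect_gt(abs(stc$time_averaged$omega_mean),
            3 * abs(sti$time_averaged$omega_mean))
})

test_that("omega versus area: zero-mean ensembles and 1/area trends", {
  # all-zero omega input gives the zero line exactly
  flat <- data.frame(cluster_id = 1:5, area_um2 = c(2, 4, 6, 8, 10) * 1e3,
                     omega_mean = 0)
  fit0 <- omega_vs_area(flat)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$intercept, 0)

  # |omega| proportional to 1/area: strong negative Spearman trend
  set.seed(13)
  ar <- seq(2e3, 3e4, length.out = 30)
  om <- 100 / ar * sample(c(-1, 1), 30, TRUE)
  fit1 <- omega_vs_area(data.frame(cluster_id = 1:30, area_um2 = ar,
                                   omega_mean = om))
  expect_lt(fit1$spearman_rho, -0.5)
  expect_lt(fit1$spearman_p, 0.05)

  expect_error(omega_vs_area(flat[1, ]), "at least 2")
  expect_error(omega_vs_area(data.frame(cluster_id = 1:3, area_um2 = 5,
                                        omega_mean = 1:3)), "degenerate")
})

test_that("cluster summaries recover generated geometry", {
  g <- gen_rotating_cluster(n_cells = 200, radius = 84, aspect = 0.83,
                            noise_sd = 0.5, seed = 14)
  cs <- cluster_summary(g$tracks, interval = 2)
  expect_equal(cs$mean_radius_um, 84, tolerance = 0.15)
  expect_equal(cs$aspect_ratio, 0.83, tolerance = 0.15)
  expect_equal(cs$omega_mean, 0.05, tolerance = 0.15)
})
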