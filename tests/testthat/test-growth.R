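# Exponential growth fits, density curves, critical area, master curve.

test_that("doubling time is identified exactly from noiseless counts", {
  g <- gen_growth_counts(n_clusters = 5, t_d = 71, sigma = 0, seed = 1)
  fit <- fit_doubling_time(g$records)
  expect_equal(fit$t_d, 71, tolerance = 0.02)   # rounding of counts only
  expect_gt(fit$r_squared, 0.99)

  # constant counts: flagged non-proliferating with infinite doubling time
  flat <- data.frame(cluster_id = 1, t_h = seq(0, 48, 12), n_cells = 20)
  expect_warning(f2 <- fit_doubling_time(flat), "non-proliferating")
  expect_identical(f2$t_d, Inf)

  expect_error(fit_doubling_time(data.frame(cluster_id = 1, t_h = 0:2,
                                            n_cells = c(1, 0, 2))), "positive")
})

test_that("noisy counts at the reference scale recover t_d inside its band", {
  g <- gen_growth_counts(n_clusters = 50, t_d = 71, sigma = 0.15, seed = 2)
  fit <- fit_doubling_time(g$records)
  expect_lt(abs(fit$t_d - 71), 19)
})

test_that("density curve is flat for exact proportionality and detects the
           boundary-spreading regime", {
  rec <- data.frame(cluster_id = 1:6, t_h = 0,
                    n_cells = c(10, 20, 40, 80, 160, 320))
  rec$area_um2 <- rec$n_cells * 500
  dc <- density_curve(rec)
  expect_equal(dc$table$a_cell_um2, rep(500, 6))
  expect_equal(dc$summary$mean_below, dc$summary$mean_above)

  g <- gen_growth_counts(n_clusters = 40, sigma = 0, boundary_spread = TRUE,
                         seed = 3)
  dc2 <- density_curve(g$records)
  expect_gt(dc2$summary$mean_above, 1.2 * dc2$summary$mean_below)

  one <- density_curve(rec[1, ])
  expect_equal(nrow(one$table), 1)
  expect_true(is.na(one$summary$mean_above))
})

test_that("critical area formula, units and scaling", {
  expect_equal(critical_area(71, 2.4), 4 * pi * 71^2 * 2.4^2)
  # unit identity 0.04 um/min = 2.4 um/h handled exactly
  expect_identical(critical_area(71, 0.04, v_rho_units = "um_per_min"),
                   critical_area(71, 2.4))
  expect_identical(um_per_min_to_um_per_h(0.04), 2.4)
  # homogeneity: A_c(k tau, v) = k^2 A_c(tau, v)
  expect_equal(critical_area(142, 2.4), 4 * critical_area(71, 2.4))
  expect_error(critical_area(-1, 2), "positive")
})

test_that("equivalent diameter and its round trip", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(3000), 61.80, tolerance = 1e-3)
  d <- equivalent_diameter(12345)
  expect_equal(pi * (d / 2)^2, 12345)
  expect_error(equivalent_diameter(-3), "positive")
})

test_that("master curve: noiseless alignment matches the closed form", {
  g <- gen_confluence_curves(a_s0 = c(0.1, 0.2), tau = 50, sigma = 0,
                             times = seq(0, 120, 8), seed = 4)
  mc <- build_master_curve(g$series)
  # reference is the sample whose initial A_s is the median; with two
  # samples that is the first; the other shifts by tau log2(As0_i/As0_ref)
  sh <- mc$shifts
  other <- sh[sh$sample_id != mc$reference_id, ]
  ref0 <- sh$initial_a_s[sh$sample_id == mc$reference_id]
  expect_equal(other$shift_h, 50 * log2(other$initial_a_s / ref0),
               tolerance = 0.05)
  expect_equal(mc$tau, 50, tolerance = 1e-3)

  # translation consistency: shifting one sample's clock moves its offset
  s2 <- g$series
  s2$t_h[s2$sample_id == other$sample_id] <-
    s2$t_h[s2$sample_id == other$sample_id] + 16
  mc2 <- build_master_curve(s2)
  expect_equal(mc2$shifts$shift_h[mc2$shifts$sample_id == other$sample_id],
               other$shift_h - 16, tolerance = 0.05)
})

test_that("master curve recovers tau within 10% under noise and caps", {
  g <- gen_confluence_curves(a_s0 = c(0.05, 0.1, 0.2, 0.4), tau = 50.8,
                             sigma = 0.05, seed = 5)
  mc <- build_master_curve(g$series)
  expect_lt(abs(mc$tau - 50.8) / 50.8, 0.1)

  # saturated tails are excluded rather than biasing the fit
  gcap <- gen_confluence_curves(a_s0 = c(0.2, 0.4), tau = 40, sigma = 0,
                                times = seq(0, 240, 8), seed = 6)
  expect_true(any(gcap$series$a_s == 1))   # the cap binds
  mcc <- build_master_curve(gcap$series)
  expect_equal(mcc$tau, 40, tolerance = 0.01)

  # disjoint confluence ranges cannot be aligned
  bad <- rbind(
    data.frame(sample_id = "a", t_h = seq(0, 16, 8), a_s = c(.01, .011, .012)),
    data.frame(sample_id = "b", t_h = seq(0, 16, 8), a_s = c(.6, .65, .7)))
  expect_error(build_master_curve(bad), "overlap")
})
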