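# Trajectory kinematics: radial and angular cell velocities about the
# cluster centroid, inner/outer region partition, population statistics and
# the angular-velocity-versus-area aggregation.
#
# Conventions: Cartesian coordinates with y increasing upward, angles
# counterclockwise-positive, times in hours, positions in micrometres.
# Radial velocities are reported in um/min, angular velocities in rad/h.

wrap_angle <- function(d) ((d + pi) %% (2 * pi)) - pi

# element-wise time key (format() would pad vectors to a common width)
tkey <- function(t) sprintf("%.12g", t)

# shared validation for trajectory tables
validate_trajectories <- function(tracks) {
  need <- c("track_id", "cluster_id", "t_h", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("trajectory table is missing columns: ", paste(miss, collapse = ", "))
  for (cn in c("t_h", "x_um", "y_um")) {
    v <- tracks[[cn]]
    if (!is.numeric(v)) stop(sprintf("column '%s' must be numeric", cn))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("column '%s' has non-finite values (first at row %d)",
                   cn, bad[1]))
  }
  key <- paste(tracks$track_id, format(tracks$t_h, digits = 12))
  d <- which(duplicated(key))
  if (length(d))
    stop(sprintf("duplicated (track_id, t) pair at row %d: track %s, t = %g",
                 d[1], tracks$track_id[d[1]], tracks$t_h[d[1]]))
  spans <- tapply(tracks$t_h, tracks$track_id, function(t) length(unique(t)))
  if (any(spans < 2))
    stop("each track must span at least 2 sampled times (offending track: ",
         names(spans)[which(spans < 2)[1]], ")")
  invisible(tracks)
}

#' Centroid of tracked cell positions in one frame
#'
#' Arithmetic mean of the cell positions (at least 3 cells).  A
#' contour-derived centre can be used instead throughout the pipeline via
#' the `centers` argument of the downstream functions.
#'
#' @param x,y cell coordinates (um).
#' @return numeric c(x, y).
#' @export
cluster_centroid <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 cells to define a cluster centroid")
  c(x = mean(x), y = mean(y))
}

# centroid lookup for one cluster: tracked-cell mean or supplied centers
frame_centers <- function(sub, centers = NULL) {
  times <- sort(unique(sub$t_h))
  if (!is.null(centers)) {
    cc <- centers[centers$cluster_id == sub$cluster_id[1], ]
    out <- lapply(times, function(t) {
      row <- cc[abs(cc$t_h - t) < 1e-8, ]
      if (nrow(row) != 1) stop(sprintf("no contour center for t = %g", t))
      c(x = row$cx_um[1], y = row$cy_um[1])
    })
  } else {
    out <- lapply(times, function(t) {
      fr <- sub[abs(sub$t_h - t) < 1e-8, ]
      cluster_centroid(fr$x_um, fr$y_um)
    })
  }
  names(out) <- vapply(times, tkey, "")
  out
}

#' Radial and angular cell velocities about the cluster centroid
#'
#' For every cell and interval `[t, t + interval]`, radial velocity
#' `V_rho = (r(t+D) - r(t)) / D` (reported in um/min) and angular velocity
#' `omega = wrap(theta(t+D) - theta(t)) / D` in rad/h, with `r`, `theta`
#' measured from the same-frame centroid and the angle difference unwrapped
#' to (-pi, pi].  Cells closer than `r_eps` to the centroid at either end
#' of an interval get `NA` angular velocity (undefined at the pole); the
#' radial component is kept.  Intervals with a missing frame are skipped.
#'
#' @param tracks trajectory table with columns `track_id`, `cluster_id`,
#'   `t_h`, `x_um`, `y_um`.
#' @param interval analysis interval in hours (a multiple of the sampling
#'   step).
#' @param r_eps pole-exclusion radius (um).
#' @param centers optional contour-centroid table with columns
#'   `cluster_id`, `t_h`, `cx_um`, `cy_um`, used instead of the tracked-cell
#'   mean.
#' @return data frame of class `polar_kinematics`: one row per cell per
#'   interval with `r_start`, `v_rho` (um/min) and `omega` (rad/h).
#' @export
polar_velocities <- function(tracks, interval = 2, r_eps = 2, centers = NULL) {
  validate_trajectories(tracks)
  if (interval <= 0) stop("interval must be positive")
  out <- lapply(split(tracks, tracks$cluster_id), function(sub) {
    times <- sort(unique(sub$t_h))
    step <- min(diff(times))
    if (abs(interval / step - round(interval / step)) > 1e-8)
      stop(sprintf(
        "interval %g h is not a multiple of the sampling step %g h",
        interval, step))
    ctr <- frame_centers(sub, centers)
    key <- function(t) tkey(t)
    rows <- list()
    for (t0 in times) {
      t1 <- t0 + interval
      if (!any(abs(times - t1) < 1e-8)) next
      f0 <- sub[abs(sub$t_h - t0) < 1e-8, ]
      f1 <- sub[abs(sub$t_h - t1) < 1e-8, ]
      common <- intersect(f0$track_id, f1$track_id)
      if (!length(common)) next
      i0 <- match(common, f0$track_id); i1 <- match(common, f1$track_id)
      c0 <- ctr[[key(t0)]]; c1 <- ctr[[key(t1)]]
      dx0 <- f0$x_um[i0] - c0["x"]; dy0 <- f0$y_um[i0] - c0["y"]
      dx1 <- f1$x_um[i1] - c1["x"]; dy1 <- f1$y_um[i1] - c1["y"]
      r0 <- sqrt(dx0^2 + dy0^2); r1 <- sqrt(dx1^2 + dy1^2)
      th0 <- atan2(dy0, dx0); th1 <- atan2(dy1, dx1)
      omega <- wrap_angle(th1 - th0) / interval
      omega[r0 < r_eps | r1 < r_eps] <- NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = sub$cluster_id[1], track_id = common,
        t_start = t0, t_end = t1, r_start = r0,
        v_rho = (r1 - r0) / interval / 60, omega = omega)
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("polar_kinematics", "data.frame")
  out
}

#' Partition cells into inner and outer regions
#'
#' Labels each track by its radius at the first analyzed frame of its
#' cluster: `inner` if within `r_split` of the cluster centre, `outer`
#' otherwise.  Labels are fixed for the whole analysis window.
#'
#' @inheritParams polar_velocities
#' @param r_split split radius (um).
#' @return data frame with `cluster_id`, `track_id`, `r0` and `region`.
#' @export
partition_regions <- function(tracks, r_split, centers = NULL) {
  validate_trajectories(tracks)
  if (!is.finite(r_split) || r_split <= 0) stop("r_split must be positive")
  out <- lapply(split(tracks, tracks$cluster_id), function(sub) {
    t0 <- min(sub$t_h)
    fr <- sub[abs(sub$t_h - t0) < 1e-8, ]
    ctr <- if (is.null(centers)) cluster_centroid(fr$x_um, fr$y_um)
           else frame_centers(sub, centers)[[tkey(t0)]]
    r0 <- sqrt((fr$x_um - ctr["x"])^2 + (fr$y_um - ctr["y"])^2)
    data.frame(cluster_id = sub$cluster_id[1], track_id = fr$track_id,
               r0 = r0, region = ifelse(r0 < r_split, "inner", "outer"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!all(c("inner", "outer") %in% out$region))
    warning("a region is empty at r_split = ", r_split)
  out
}

#' Population statistics of the polar kinematics
#'
#' Unweighted mean and sample SD of the radial and angular velocities per
#' cluster, region and interval, plus the time-averaged values per cluster
#' and region (equal interval weights).  Single-cell groups report `NA` SD.
#'
#' @param pk a `polar_kinematics` data frame from [polar_velocities()].
#' @param regions optional region labels from [partition_regions()]; if
#'   omitted every cell is in region `"all"`.
#' @return list with `time_series` and `time_averaged` data frames.
#' @export
population_stats <- function(pk, regions = NULL) {
  df <- as.data.frame(pk)
  if (!is.null(regions)) {
    df <- merge(df, regions[c("cluster_id", "track_id", "region")],
                by = c("cluster_id", "track_id"), all.x = TRUE)
    df$region[is.na(df$region)] <- "unassigned"
  } else df$region <- "all"
  g <- interaction(df$cluster_id, df$region, df$t_start, drop = TRUE)
  agg <- function(v, f) as.vector(tapply(v, g, f))
  first <- function(v) as.vector(tapply(v, g, `[`, 1))
  msd <- function(v) if (sum(is.finite(v)) >= 2) sd(v[is.finite(v)]) else NA_real_
  mfin <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else NA_real_
  ts <- data.frame(cluster_id = first(df$cluster_id),
                   region = first(df$region),
                   t_start = first(df$t_start),
                   n = agg(df$v_rho, length),
                   v_rho_mean = agg(df$v_rho, mfin),
                   v_rho_sd = agg(df$v_rho, msd),
                   omega_mean = agg(df$omega, mfin),
                   omega_sd = agg(df$omega, msd))
  ts <- ts[order(ts$cluster_id, ts$region, ts$t_start), ]
  rownames(ts) <- NULL
  g2 <- interaction(ts$cluster_id, ts$region, drop = TRUE)
  ta <- data.frame(
    cluster_id = as.vector(tapply(ts$cluster_id, g2, `[`, 1)),
    region = as.vector(tapply(ts$region, g2, `[`, 1)),
    n_intervals = as.vector(tapply(ts$t_start, g2, length)),
    v_rho_mean = as.vector(tapply(ts$v_rho_mean, g2, mfin)),
    omega_mean = as.vector(tapply(ts$omega_mean, g2, mfin)))
  rownames(ta) <- NULL
  list(time_series = ts, time_averaged = ta)
}

#' Geometry and time-averaged kinematics per cluster
#'
#' Cluster geometry is estimated from the cell positions at the first
#' frame by principal axes of the position covariance: for cells spread
#' uniformly over an ellipse with semi-axes a >= b the coordinate variances
#' are a^2/4 and b^2/4, so the axes are twice the principal standard
#' deviations.  Reports mean radius (a+b)/2, aspect ratio b/a, area
#' pi a b, region counts (when `r_split` is given) and the time-averaged
#' angular and radial velocity over all cells (the equally-weighted mean
#' over intervals of the per-interval population mean).
#'
#' @inheritParams polar_velocities
#' @param r_split optional split radius (um) for inner/outer counts.
#' @return data frame with one row per cluster.
#' @export
cluster_summary <- function(tracks, interval = 2, r_eps = 2, r_split = NULL,
                            centers = NULL) {
  validate_trajectories(tracks)
  pk <- polar_velocities(tracks, interval, r_eps, centers)
  st <- population_stats(pk)$time_averaged
  out <- lapply(split(tracks, tracks$cluster_id), function(sub) {
    t0 <- min(sub$t_h)
    fr <- sub[abs(sub$t_h - t0) < 1e-8, ]
    ev <- eigen(stats::cov(cbind(fr$x_um, fr$y_um)), symmetric = TRUE)$values
    a <- 2 * sqrt(max(ev)); b <- 2 * sqrt(max(min(ev), 0))
    n_in <- n_out <- NA_integer_
    if (!is.null(r_split)) {
      reg <- partition_regions(sub, r_split, centers)
      n_in <- sum(reg$region == "inner"); n_out <- sum(reg$region == "outer")
    }
    data.frame(cluster_id = sub$cluster_id[1], n_cells = nrow(fr),
               mean_radius_um = (a + b) / 2, aspect_ratio = b / a,
               area_um2 = pi * a * b, n_inner = n_in, n_outer = n_out)
  })
  out <- do.call(rbind, out)
  out <- merge(out, st[st$region == "all",
                       c("cluster_id", "omega_mean", "v_rho_mean")],
               by = "cluster_id")
  rownames(out) <- NULL
  out
}

#' Angular velocity versus cluster area
#'
#' Ordinary least-squares line of the time-averaged angular velocity on
#' cluster area, the population mean angular velocity with its standard
#' error, and the Spearman trend of |omega| with area.
#'
#' @param summaries data frame with `area_um2` and `omega_mean` columns
#'   (one row per cluster), e.g. from [cluster_summary()].
#' @return list of class `omega_area_fit`.
#' @export
omega_vs_area <- function(summaries) {
  df <- summaries[is.finite(summaries$area_um2) &
                    is.finite(summaries$omega_mean), ]
  if (nrow(df) < 2) stop("need at least 2 clusters")
  if (sd(df$area_um2) == 0) stop("degenerate areas: no spread in cluster area")
  fit <- lm(omega_mean ~ area_um2, data = df)
  sp <- suppressWarnings(
    cor.test(abs(df$omega_mean), df$area_um2, method = "spearman",
             exact = FALSE))
  structure(list(
    table = df[c("cluster_id", "area_um2", "omega_mean")],
    fit = fit,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    mean_omega = mean(df$omega_mean),
    se_mean_omega = sd(df$omega_mean) / sqrt(nrow(df)),
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    n_clusters = nrow(df)), class = "omega_area_fit")
}

#' @export
print.omega_area_fit <- function(x, ...) {
  cat(sprintf(paste0("<omega_area_fit> %d clusters | mean omega %.4g ",
                     "(SE %.3g) rad/h\n  OLS slope %.3g rad/h per um^2; ",
                     "Spearman(|omega|, area) rho = %.3f, p = %.3g\n"),
              x$n_clusters, x$mean_omega, x$se_mean_omega, x$slope,
              x$spearman_rho, x$spearman_p))
  invisible(x)
}
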