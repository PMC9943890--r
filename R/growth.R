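# Colony-growth analysis: exponential doubling-time fit, cell-density
# (area-per-cell) curves, the critical area separating free expansion from
# proliferation inhibition, confluence master curves, and the
# equivalent-diameter conversion.

#' Fit the cell duplication time
#'
#' Cell counts are assumed to grow as `N(t) = N0 2^(t/t_d)`.  For each
#' cluster `N0` is fixed to its first observation, and `t_d` is the single
#' adjustable parameter of a pooled least-squares fit of
#' `log2(N/N0)` on elapsed time through the origin (the log scale is
#' variance-stabilizing for multiplicative noise).
#'
#' @param records data frame with columns `cluster_id`, `t_h`, `n_cells`.
#' @return list of class `doubling_fit` with `t_d` (h), its standard error
#'   `se` (delta method from the slope), `r_squared`, and a
#'   `non_proliferating` flag (slope <= 0, `t_d = Inf`).
#' @export
fit_doubling_time <- function(records) {
  need <- c("cluster_id", "t_h", "n_cells")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$n_cells <= 0)) stop("cell counts must be positive")
  xy <- lapply(split(records, records$cluster_id), function(sub) {
    sub <- sub[order(sub$t_h), ]
    if (nrow(sub) < 2) return(NULL)
    data.frame(x = sub$t_h - sub$t_h[1],
               y = log2(sub$n_cells / sub$n_cells[1]))
  })
  xy <- do.call(rbind, xy)
  xy <- xy[xy$x > 0, ]
  if (nrow(xy) < 3) stop("need at least 3 observations after the first frames")
  slope <- sum(xy$x * xy$y) / sum(xy$x^2)
  res <- xy$y - slope * xy$x
  se_slope <- sqrt(sum(res^2) / (nrow(xy) - 1) / sum(xy$x^2))
  r2 <- 1 - sum(res^2) / sum(xy$y^2)
  non_prolif <- slope <= 0
  if (non_prolif) warning("non-proliferating series: zero or negative slope")
  structure(list(t_d = if (non_prolif) Inf else 1 / slope,
                 se = if (non_prolif) NA_real_ else se_slope / slope^2,
                 r_squared = r2, slope = slope, n_obs = nrow(xy),
                 non_proliferating = non_prolif),
            class = "doubling_fit")
}

#' @export
print.doubling_fit <- function(x, ...) {
  if (x$non_proliferating) cat("<doubling_fit> non-proliferating (t_d = Inf)\n")
  else cat(sprintf("<doubling_fit> t_d = %.3g h (SE %.2g, R^2 = %.2f, n = %d)\n",
                   x$t_d, x$se, x$r_squared, x$n_obs))
  invisible(x)
}

#' Area per cell versus cluster area
#'
#' `A_cell = A_cluster / N_cells` (the reciprocal of cell density) for each
#' observation, with a change-point summary: the mean `A_cell` below and
#' above the free-expansion threshold (default 2e4 um^2, above which cell
#' density is constant in the free-expansion regime).
#'
#' @param records data frame with `cluster_id`, `t_h`, `n_cells`,
#'   `area_um2`.
#' @param threshold_um2 change-point threshold.
#' @return list with the pointwise `table` and the `summary` means.
#' @export
density_curve <- function(records, threshold_um2 = 2e4) {
  if (any(records$n_cells <= 0)) stop("cell counts must be positive")
  if (any(records$area_um2 <= 0)) stop("cluster areas must be positive")
  tab <- data.frame(cluster_id = records$cluster_id, t_h = records$t_h,
                    area_um2 = records$area_um2,
                    a_cell_um2 = records$area_um2 / records$n_cells)
  lo <- tab$a_cell_um2[tab$area_um2 < threshold_um2]
  hi <- tab$a_cell_um2[tab$area_um2 >= threshold_um2]
  list(table = tab,
       summary = data.frame(
         threshold_um2 = threshold_um2,
         n_below = length(lo), n_above = length(hi),
         mean_below = if (length(lo)) mean(lo) else NA_real_,
         mean_above = if (length(hi)) mean(hi) else NA_real_))
}

#' Convert a radial velocity from um/min to um/h
#'
#' @param v_um_min velocity in um per minute.
#' @export
um_per_min_to_um_per_h <- function(v_um_min) v_um_min * 60

#' Critical cluster area of the free-expansion regime
#'
#' The transition between free expansion (constant density, boundary motion
#' keeps pace with proliferation) and proliferation inhibition happens when
#' the radial boundary velocity satisfies `v_rho = sqrt(A_c / (4 pi tau^2))`,
#' i.e. `A_c = 4 pi tau^2 v_rho^2`.  Homogeneous of degree 2 in `tau`.
#'
#' @param tau characteristic (doubling) time of the exponential area
#'   growth, in hours.
#' @param v_rho radial cell velocity at the boundary.
#' @param v_rho_units `"um_per_h"` (default) or `"um_per_min"` (converted
#'   internally: 0.04 um/min = 2.4 um/h).
#' @return critical area in um^2.
#' @export
critical_area <- function(tau, v_rho,
                          v_rho_units = c("um_per_h", "um_per_min")) {
  v_rho_units <- match.arg(v_rho_units)
  if (!is.finite(tau) || tau <= 0 || !is.finite(v_rho) || v_rho <= 0)
    stop("tau and v_rho must be positive")
  if (v_rho_units == "um_per_min") v_rho <- um_per_min_to_um_per_h(v_rho)
  4 * pi * tau^2 * v_rho^2
}

#' Equivalent circular diameter of an area
#'
#' @param area_um2 area in um^2 (> 0).
#' @return diameter `2 sqrt(area/pi)` in um.
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(!is.finite(area_um2) | area_um2 <= 0)) stop("area must be positive")
  2 * sqrt(area_um2 / pi)
}

#' Confluence master curve and occupancy doubling time
#'
#' Confluence curves from samples plated at different initial densities are
#' superposed by horizontal time shifts onto the curve of a reference
#' sample (the one whose initial confluence is the median), then the master
#' curve is fitted by `A_s(t) = A_s0 2^(t/tau)` with `tau` the only free
#' parameter (`A_s0` fixed to the reference's initial value).  The shift of
#' each sample minimizes the summed squared difference of `log2 A_s` from
#' the (linearly interpolated) reference over their overlap, by
#' golden-section search over a bounded window.  Points at the confluence
#' cap (`A_s >= cap`) are excluded from both alignment and fit.
#'
#' @param series data frame with columns `sample_id`, `t_h`, `a_s`
#'   (confluence in (0, 1]).
#' @param cap saturation value; capped points are dropped.
#' @return list of class `master_curve` with per-sample `shifts` (h), the
#'   pooled doubling time `tau` (h), the reference id and the shifted data.
#' @export
build_master_curve <- function(series, cap = 1) {
  need <- c("sample_id", "t_h", "a_s")
  if (!all(need %in% names(series)))
    stop("series need columns: ", paste(need, collapse = ", "))
  if (any(series$a_s <= 0 | series$a_s > cap + 1e-9))
    stop("confluence values must lie in (0, cap]")
  series <- series[series$a_s < cap - 1e-9, ]   # capped tail excluded
  parts <- split(series, series$sample_id)
  if (length(parts) < 2) stop("need at least 2 samples")
  a0 <- vapply(parts, function(s) s$a_s[which.min(s$t_h)], 0)
  ref_id <- names(parts)[which.min(abs(a0 - stats::median(a0)))]
  ref <- parts[[ref_id]]
  ref <- ref[order(ref$t_h), ]
  lref <- stats::approxfun(ref$t_h, log2(ref$a_s))
  t_lo <- min(ref$t_h); t_hi <- max(ref$t_h)
  rng_ref <- range(ref$a_s)
  shift_of <- function(s) {
    rng <- range(s$a_s)
    if (rng[1] > rng_ref[2] || rng[2] < rng_ref[1])
      stop("no overlap in confluence range between sample ", s$sample_id[1],
           " and the reference: cannot align")
    obj <- function(d) {
      tt <- s$t_h + d
      ok <- tt >= t_lo & tt <= t_hi
      if (sum(ok) < 1) return(1e12 + abs(d))   # push back into overlap
      mean((log2(s$a_s[ok]) - lref(tt[ok]))^2)
    }
    win <- c(t_lo - max(s$t_h), t_hi - min(s$t_h))
    opt <- optimize(obj, interval = win, tol = 1e-7)
    if (opt$objective >= 1e12)
      stop("no overlap between sample ", s$sample_id[1], " and the reference")
    opt$minimum
  }
  shifts <- vapply(parts, function(s)
    if (identical(s$sample_id[1], ref[["sample_id"]][1])) 0 else shift_of(s), 0)
  shifted <- do.call(rbind, lapply(names(parts), function(id) {
    s <- parts[[id]]
    data.frame(sample_id = id, t_shifted = s$t_h + shifts[[id]], a_s = s$a_s)
  }))
  # pooled fit with A_s0 fixed to the reference initial value
  t0 <- ref$t_h[1]; la0 <- log2(ref$a_s[1])
  x <- shifted$t_shifted - t0
  y <- log2(shifted$a_s) - la0
  keep <- abs(x) > 1e-12 | abs(y) > 1e-12
  slope <- sum(x[keep] * y[keep]) / sum(x[keep]^2)
  if (slope <= 0) stop("non-increasing confluence: cannot fit a doubling time")
  structure(list(
    shifts = data.frame(sample_id = names(parts), shift_h = unname(shifts),
                        initial_a_s = unname(a0)),
    tau = 1 / slope, reference_id = ref_id, shifted = shifted),
    class = "master_curve")
}

#' @export
print.master_curve <- function(x, ...) {
  cat(sprintf("<master_curve> %d samples, reference '%s', tau = %.3g h\n",
              nrow(x$shifts), x$reference_id, x$tau))
  invisible(x)
}
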