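# Simulation driver: initialize a circular colony (droplet of phi = 1 with a
# random director), evolve the coupled Q / u / phi model, measure colony area
# and angular velocity, and rescale observables onto experimental axes.

#' Model parameters for the colony simulator
#'
#' Physical defaults are the reference parameter set of the model:
#' `rho = 40`, `Gamma_phi = 0.2`, `gamma = 0.3`, `|zeta| = 0.01` (extensile,
#' so `zeta = -0.01`), `lambda = 0.7`, `K = 0.02`, `K_phi = 0.1`, `B = 0.01`,
#' `C = 0.001`, on a periodic box (300 x 300 in the reference configuration;
#' smaller boxes are used for desk-scale work).  Numerical settings: D2Q9
#' BGK with Guo forcing and `tau_lb = 0.55` (eta = 2/3 in lattice units; the
#' reference set prints no viscosity, and this standard choice places the
#' activity-induced ordering instability, growth rate `lambda |zeta|/(2 eta)
#' - gamma C`, well above threshold so colonies order and rotate on desk
#' timescales); the isotropic 9-point laplacian, whose smaller spectral
#' radius keeps the explicit Cahn-Hilliard update stable at dt = 1 (the
#' compact 5-point stencil would not be); and the active stress weighted by
#' the cell phase (`zeta phi Q`), which confines activity to the tissue --
#' with the unweighted `zeta Q` the order leaking past the interface stirs
#' the background and disperses the colony.
#'
#' @param nx,ny grid size (lattice nodes).
#' @param rho suspension density.
#' @param Gamma_phi concentration mobility.
#' @param gamma rotational diffusivity.
#' @param zeta activity; negative = extensile (the cell-monolayer case).
#' @param lambda flow-aligning parameter.
#' @param K Frank elastic constant.
#' @param K_phi concentration gradient stiffness.
#' @param B double-well depth.
#' @param C bulk nematic coefficient.
#' @param dx,dt lattice spacing and time step.
#' @param tau_lb BGK relaxation time.
#' @param S0 initial nematic order magnitude inside the droplet.
#' @param director `"per_node"` (independent random angle at every node,
#'   default) or `"global"` (one random angle for the whole droplet).
#' @param convention bulk-Q sign convention, see [free_energy_params()].
#' @param nine_point use the isotropic 9-point laplacian in the driver.
#' @param phi_substeps concentration substeps per LB step.
#' @param active_phi if TRUE (default) the active stress is `zeta phi Q`,
#'   confining activity to the cell phase; FALSE restores the unweighted
#'   `zeta Q`, under which order leaking into the background disperses the
#'   colony.
#' @param s_max,u_max blow-up and Mach guard thresholds.
#' @return list of class `colony_params`.
#' @export
model_params <- function(nx = 300, ny = nx,
                         rho = 40, Gamma_phi = 0.2, gamma = 0.3,
                         zeta = -0.01, lambda = 0.7,
                         K = 0.02, K_phi = 0.1, B = 0.01, C = 0.001,
                         dx = 1, dt = 1, tau_lb = 0.55,
                         S0 = 0.05, director = c("per_node", "global"),
                         convention = c("stabilizing", "printed"),
                         nine_point = TRUE, phi_substeps = 1L,
                         active_phi = TRUE, s_max = 8, u_max = 0.3) {
  director <- match.arg(director)
  convention <- match.arg(convention)
  vals <- c(rho = rho, Gamma_phi = Gamma_phi, gamma = gamma, zeta = zeta,
            lambda = lambda, K = K, K_phi = K_phi, B = B, C = C,
            dx = dx, dt = dt, tau_lb = tau_lb, S0 = S0)
  if (!all(is.finite(vals))) stop("all model parameters must be finite")
  if (rho <= 0 || Gamma_phi <= 0 || gamma <= 0 || K <= 0 || K_phi <= 0 ||
      B <= 0 || C <= 0 || tau_lb <= 0.5)
    stop("rho, Gamma_phi, gamma, K, K_phi, B, C must be > 0 and tau_lb > 1/2")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 rho = rho, Gamma_phi = Gamma_phi, gamma = gamma,
                 zeta = zeta, lambda = lambda, K = K, K_phi = K_phi,
                 B = B, C = C, dx = dx, dt = dt, tau_lb = tau_lb,
                 S0 = S0, director = director, convention = convention,
                 bulk_sign = if (convention == "stabilizing") 1 else -1,
                 nine_point = isTRUE(nine_point),
                 phi_substeps = as.integer(phi_substeps),
                 active_phi = isTRUE(active_phi),
                 s_max = s_max, u_max = u_max),
            class = "colony_params")
}

#' @export
print.colony_params <- function(x, ...) {
  cat(sprintf(paste0("<colony_params> %d x %d box | rho=%g Gamma_phi=%g ",
                     "gamma=%g zeta=%g lambda=%g\n  K=%g K_phi=%g B=%g C=%g",
                     " | tau_lb=%g, %s director, S0=%g\n"),
              x$nx, x$ny, x$rho, x$Gamma_phi, x$gamma, x$zeta, x$lambda,
              x$K, x$K_phi, x$B, x$C, x$tau_lb, x$director, x$S0))
  invisible(x)
}

# Equilibrium interface width sqrt(K_phi/B); the tanh profile scale is
# sqrt(8 K_phi / B) (kink solution of the double well as written).
interface_width <- function(params) sqrt(params$K_phi / params$B)

#' Initialize a circular colony
#'
#' Concentration phi = 1 inside radius R with a tanh-smoothed edge (the
#' equilibrium kink profile), 0 outside; inside the droplet the nematic
#' tensor is `S0 (nn - I/2)` with director angle drawn uniformly on
#' `[0, 2 pi)` (independently per node, or one global angle); fluid at rest.
#' Deterministic given `seed`.
#'
#' @param params a [model_params()] object.
#' @param radius droplet radius in lattice units (>= 1 lattice cell; the
#'   droplet plus a margin of 5 interface widths must fit in the half-box).
#' @param seed integer seed for the director draw (optional).
#' @return list of class `colony_state` with fields `phi`, `Qxx`, `Qxy`,
#'   LB populations `f`, moments `rho`, `ux`, `uy`, and `step = 0`.
#' @export
init_droplet <- function(params, radius, seed = NULL) {
  stopifnot(inherits(params, "colony_params"))
  if (!is.finite(radius) || radius < 1)
    stop("droplet radius must be at least one lattice cell")
  xi <- interface_width(params)
  if (radius + 5 * xi > min(params$nx, params$ny) / 2)
    stop(sprintf(paste0("droplet too large for box: radius %g + 5 interface",
                        " widths (%g) exceeds the half-box %g"),
                 radius, 5 * xi, min(params$nx, params$ny) / 2))
  if (!is.null(seed)) set.seed(seed)
  nx <- params$nx; ny <- params$ny; dx <- params$dx
  co <- grid_coords(nx, ny, dx)
  cx <- (nx - 1) * dx / 2; cy <- (ny - 1) * dx / 2
  r <- sqrt(outer((co$x - cx)^2, (co$y - cy)^2, "+"))
  d <- sqrt(8 * params$K_phi / params$B)      # tanh profile scale
  phi <- 0.5 * (1 - tanh((r - radius) / d))
  inside <- phi > 0.5
  theta <- if (params$director == "per_node") {
    matrix(runif(nx * ny, 0, 2 * pi), nx, ny)
  } else {
    matrix(runif(1, 0, 2 * pi), nx, ny)
  }
  Qxx <- ifelse(inside, (params$S0 / 2) * cos(2 * theta), 0)
  Qxy <- ifelse(inside, (params$S0 / 2) * sin(2 * theta), 0)
  zero <- matrix(0, nx, ny)
  f <- cpp_lb_equilibrium(nx, ny, params$rho, zero, zero)
  structure(list(params = params, phi = phi, Qxx = Qxx, Qxy = Qxy,
                 f = f, rho = matrix(params$rho, nx, ny),
                 ux = zero, uy = zero, step = 0L, radius = radius),
            class = "colony_state")
}

#' @export
print.colony_state <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<colony_state> %d x %d box, step %d | colony area %g",
                     " (phi > 0.5), max S = %.3g, max |u| = %.3g\n"),
              p$nx, p$ny, x$step, sum(x$phi > 0.5) * p$dx^2,
              2 * sqrt(max(x$Qxx^2 + x$Qxy^2)), sqrt(max(x$ux^2 + x$uy^2))))
  invisible(x)
}

# flat parameter list consumed by the C++ driver
advance_par <- function(p) {
  list(C = p$C, B = p$B, K_phi = p$K_phi, K = p$K, gamma = p$gamma,
       Gamma_phi = p$Gamma_phi, lambda = p$lambda, zeta = p$zeta,
       tau_lb = p$tau_lb, dx = p$dx, dt = p$dt, bulk_sign = p$bulk_sign,
       nine_point = p$nine_point, active_phi = p$active_phi,
       phi_substeps = p$phi_substeps, s_max = p$s_max, u_max = p$u_max)
}

#' Advance a colony state by n steps
#'
#' Runs the fused C++ driver (one LB collide-stream plus finite-difference
#' Q and phi updates per step).  Blow-up and Mach diagnostics abort with the
#' offending step index.
#'
#' @param state a `colony_state`.
#' @param n_steps number of steps.
#' @return the advanced `colony_state`.
#' @export
advance_colony <- function(state, n_steps) {
  stopifnot(inherits(state, "colony_state"), n_steps >= 0)
  if (n_steps == 0) return(state)
  out <- cpp_advance(state$phi, state$Qxx, state$Qxy, state$f,
                     advance_par(state$params), as.integer(n_steps),
                     state$step)
  state$phi <- out$phi; state$Qxx <- out$Qxx; state$Qxy <- out$Qxy
  state$f <- out$f; state$rho <- out$rho; state$ux <- out$ux; state$uy <- out$uy
  state$step <- state$step + as.integer(n_steps)
  state
}

#' Periodic-aware colony centroid
#'
#' phi-weighted center of mass computed by the circular mean in each
#' direction (robust to colonies crossing the periodic boundary).
#'
#' @param phi concentration field.
#' @param dx lattice spacing.
#' @return numeric c(x, y) in lattice-unit coordinates.
#' @export
colony_centroid <- function(phi, dx = 1) {
  nx <- nrow(phi); ny <- ncol(phi)
  w <- pmax(phi, 0)
  if (sum(w) <= 0) stop("empty colony: phi has no positive mass")
  wx <- rowSums(w); wy <- colSums(w)
  ang_x <- 2 * pi * (seq_len(nx) - 1) / nx
  ang_y <- 2 * pi * (seq_len(ny) - 1) / ny
  mx <- atan2(sum(wx * sin(ang_x)), sum(wx * cos(ang_x))) %% (2 * pi)
  my <- atan2(sum(wy * sin(ang_y)), sum(wy * cos(ang_y))) %% (2 * pi)
  c(x = mx * nx / (2 * pi) * dx, y = my * ny / (2 * pi) * dx)
}

#' Mean angular velocity of the colony flow
#'
#' Averages the local angular rate `(r-hat x u).z / r = (x u_y - y u_x)/r^2`
#' (counterclockwise positive) over nodes inside the colony (`phi > 0.5`)
#' farther than `r_min` from the phi-weighted centroid; returns a rigid-body
#' rotation rate exactly for `u = omega0 (-y, x)`.
#'
#' @param state a `colony_state`, or any list with `phi`, `ux`, `uy` and
#'   optionally `params$dx`.
#' @param r_min exclusion radius around the centroid (lattice units).
#' @return scalar angular velocity (radians per time step).
#' @export
measure_angular_velocity <- function(state, r_min = 2) {
  dx <- if (!is.null(state$params)) state$params$dx else 1
  phi <- state$phi; ux <- state$ux; uy <- state$uy
  check_field(phi, "phi"); check_field(ux, "ux"); check_field(uy, "uy")
  ctr <- colony_centroid(phi, dx)
  nx <- nrow(phi); ny <- ncol(phi)
  co <- grid_coords(nx, ny, dx)
  # periodic displacement from the centroid
  wrapd <- function(d, L) (d + L / 2) %% L - L / 2
  X <- matrix(wrapd(co$x - ctr["x"], nx * dx), nx, ny)
  Y <- matrix(wrapd(co$y - ctr["y"], ny * dx), nx, ny, byrow = TRUE)
  r2 <- X^2 + Y^2
  sel <- phi > 0.5 & r2 > r_min^2
  if (!any(sel)) stop("empty colony: no nodes with phi > 0.5 beyond r_min")
  mean((X[sel] * uy[sel] - Y[sel] * ux[sel]) / r2[sel])
}

# One observable row for the current state.
colony_observables <- function(state, r_min = 2) {
  p <- state$params
  inside <- state$phi > 0.5
  fep <- free_energy_params(C = p$C, B = p$B, K_phi = p$K_phi, K = p$K,
                            convention = p$convention)
  data.frame(
    step = state$step,
    area = sum(inside) * p$dx^2,
    omega = if (any(inside)) measure_angular_velocity(state, r_min) else NA_real_,
    speed = if (any(inside)) mean(sqrt(state$ux[inside]^2 + state$uy[inside]^2)) else NA_real_,
    S_mean = if (any(inside))
      mean(2 * sqrt(state$Qxx[inside]^2 + state$Qxy[inside]^2)) else NA_real_,
    phi_total = sum(state$phi) * p$dx^2,
    F_total = total_free_energy(state$phi,
                                list(xx = state$Qxx, xy = state$Qxy),
                                fep, p$dx))
}

#' Run a colony simulation
#'
#' Initializes a droplet (unless a `state` is supplied), advances it in
#' chunks of `sample_every` steps and records the observable time series:
#' colony area, mean angular velocity, mean speed, mean nematic order,
#' total concentration and total free energy.  Deterministic given `seed`.
#'
#' @param params a [model_params()] object.
#' @param radius droplet radius (lattice units).
#' @param n_steps total steps.
#' @param sample_every sampling cadence (steps).
#' @param seed seed for the director initialization.
#' @param state optionally, a prepared `colony_state` to continue from.
#' @param r_min centroid exclusion radius for the angular-velocity measure.
#' @return list of class `colony_run` with `observables` (data frame) and
#'   the final `state`.
#' @export
run_colony <- function(params, radius, n_steps, sample_every = 100,
                       seed = NULL, state = NULL, r_min = 2) {
  if (is.null(state)) state <- init_droplet(params, radius, seed)
  obs <- list(colony_observables(state, r_min))
  done <- 0
  while (done < n_steps) {
    take <- min(sample_every, n_steps - done)
    state <- advance_colony(state, take)
    done <- done + take
    obs[[length(obs) + 1]] <- colony_observables(state, r_min)
  }
  structure(list(observables = do.call(rbind, obs), state = state,
                 params = state$params, radius = state$radius, seed = seed),
            class = "colony_run")
}

#' @export
print.colony_run <- function(x, ...) {
  ob <- x$observables
  cat(sprintf(paste0("<colony_run> %d samples to step %d | final area %g,",
                     " omega %.3g, mean S %.3g\n"),
              nrow(ob), max(ob$step), tail(ob$area, 1), tail(ob$omega, 1),
              tail(ob$S_mean, 1)))
  invisible(x)
}

#' Rescale simulation observables onto experimental axes
#'
#' Matches the initial area and initial angular velocity to experimental
#' values and rescales both series by the resulting affine factors
#' `s_A = A0_exp / A0_sim`, `s_omega = omega0_exp / omega0_sim`.
#'
#' @param obs observable data frame with `area` and `omega` columns (e.g.
#'   from [run_colony()]).
#' @param A0_exp experimental initial area (e.g. um^2).
#' @param omega0_exp experimental initial angular velocity (e.g. rad/h).
#' @return the data frame with rescaled `area` and `omega` columns plus the
#'   scale factors as attributes `s_A` and `s_omega`.
#' @export
rescale_to_experiment <- function(obs, A0_exp, omega0_exp) {
  if (nrow(obs) == 0) stop("empty observable series")
  A0 <- obs$area[1]; w0 <- obs$omega[1]
  if (!is.finite(A0) || A0 <= 0) stop("initial area must be positive")
  if (!is.finite(w0) || w0 == 0)
    stop("initial angular velocity is zero: rescaling undefined")
  s_A <- A0_exp / A0; s_w <- omega0_exp / w0
  obs$area <- obs$area * s_A
  obs$omega <- obs$omega * s_w
  attr(obs, "s_A") <- s_A
  attr(obs, "s_omega") <- s_w
  obs
}

#' Write / read a field snapshot
#'
#' Plain-text snapshot of the continuum fields (one row per node, columns
#' `i, j, phi, Qxx, Qxy, ux, uy`) with `# key=value` header lines recording
#' the step, grid and a hash of the physical parameters.
#'
#' @param state a `colony_state`.
#' @param path output file.
#' @export
write_field_snapshot <- function(state, path) {
  p <- state$params
  phys <- unlist(p[c("rho", "Gamma_phi", "gamma", "zeta", "lambda",
                     "K", "K_phi", "B", "C")])
  hash <- sum(as.integer(charToRaw(paste(format(phys, digits = 12),
                                         collapse = ","))) *
                (seq_along(charToRaw(paste(format(phys, digits = 12),
                                           collapse = ","))) %% 97 + 1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# step=%d", state$step),
               sprintf("# nx=%d ny=%d dx=%g dt=%g", p$nx, p$ny, p$dx, p$dt),
               sprintf("# params_hash=%d", hash)), con)
  idx <- expand.grid(i = seq_len(p$nx), j = seq_len(p$ny))
  df <- data.frame(idx, phi = as.vector(state$phi),
                   Qxx = as.vector(state$Qxx), Qxy = as.vector(state$Qxy),
                   ux = as.vector(state$ux), uy = as.vector(state$uy))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_snapshot
#' @return `read_field_snapshot` returns a list of field matrices plus the
#'   header attributes.
#' @export
read_field_snapshot <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  kv <- unlist(strsplit(sub("^# *", "", hdr), " "))
  kv <- strsplit(kv, "=")
  attrs <- stats::setNames(lapply(kv, function(x) as.numeric(x[2])),
                           vapply(kv, `[`, "", 1))
  df <- read.csv(path, comment.char = "#")
  nx <- as.integer(attrs$nx); ny <- as.integer(attrs$ny)
  out <- lapply(df[c("phi", "Qxx", "Qxy", "ux", "uy")],
                function(v) matrix(v, nx, ny))
  c(out, attrs = list(attrs))
}
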