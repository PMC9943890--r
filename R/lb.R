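# D2Q9 BGK lattice Boltzmann solver for the (near-incompressible)
# Navier-Stokes equation, forced by the divergence of the elastic + active
# stress.  Pressure is supplied by the LB ideal-gas equation of state
# (P = rho c_s^2, c_s^2 = 1/3), so the -P delta_ij term of the passive
# stress is not re-added to the forcing; the viscous stress 2 eta E is
# likewise produced by the BGK collision itself, with
# eta = rho c_s^2 (tau - 1/2) dt.

#' Initialize a lattice-Boltzmann state
#'
#' Populations start at the local equilibrium for density `rho0` and the
#' given velocity field.
#'
#' @param nx,ny grid size.
#' @param rho0 reference density (the suspension density of the model).
#' @param ux,uy initial velocity (matrices or scalars, default rest).
#' @return list of class `lb_state` with the population array `f`
#'   (nx x ny x 9) and the macroscopic moments.
#' @export
lb_init <- function(nx, ny, rho0 = 40, ux = 0, uy = 0) {
  if (length(ux) == 1) ux <- matrix(ux, nx, ny)
  if (length(uy) == 1) uy <- matrix(uy, nx, ny)
  check_field(ux, "ux"); check_field(uy, "uy")
  f <- cpp_lb_equilibrium(nx, ny, rho0, ux, uy)
  structure(list(f = f, nx = nx, ny = ny, rho0 = rho0,
                 rho = matrix(rho0, nx, ny), ux = ux, uy = uy),
            class = "lb_state")
}

#' One BGK collide-stream cycle with Guo forcing
#'
#' Aborts if the velocity magnitude exceeds `u_max` (Mach guard: the scheme
#' is only valid well below the lattice speed of sound, 1/sqrt(3)).
#'
#' @param state an `lb_state`.
#' @param fx,fy body-force components (matrices or scalars).
#' @param tau BGK relaxation time (kinematic viscosity `(tau - 1/2)/3`).
#' @param u_max Mach guard threshold.
#' @return updated `lb_state` with post-step moments `rho`, `ux`, `uy`.
#' @export
lb_step <- function(state, fx = 0, fy = 0, tau = 1, u_max = 0.3) {
  nx <- state$nx; ny <- state$ny
  if (length(fx) == 1) fx <- matrix(fx, nx, ny)
  if (length(fy) == 1) fy <- matrix(fy, nx, ny)
  check_field(fx, "fx"); check_field(fy, "fy")
  out <- cpp_lb_step(state$f, fx, fy, tau, nx, ny)
  umax <- sqrt(max(out$ux^2 + out$uy^2))
  if (!is.finite(umax) || umax > u_max)
    stop(sprintf("Mach guard tripped: |u| = %g > %g", umax, u_max))
  state$f <- out$f; state$rho <- out$rho; state$ux <- out$ux; state$uy <- out$uy
  state
}

#' Dynamic viscosity of the BGK scheme
#'
#' @param tau relaxation time.
#' @param rho density.
#' @param dt time step.
#' @export
lb_viscosity <- function(tau, rho = 1, dt = 1) rho * (tau - 0.5) * dt / 3

#' Assemble the deviatoric stress driving the flow
#'
#' Passive elastic terms plus the active stress `zeta Q` (extensile for
#' `zeta < 0`).  For traceless symmetric 2D `Q` and `H` the passive part
#' collapses to `2 lambda (Q:H) Q - lambda H + (Q H - H Q) - K dQ:dQ`;
#' pressure and the viscous stress are handled inside the LB solver and are
#' deliberately not duplicated here.
#'
#' @param Q,H tensor fields (lists with `xx`, `xy`).
#' @param K Frank elastic constant (Ericksen term).
#' @param lambda flow-aligning parameter.
#' @param zeta activity.
#' @param dx lattice spacing.
#' @return list with full components `xx`, `xy`, `yx`, `yy` (the
#'   antisymmetric part `QH - HQ` makes it non-symmetric).
#' @export
assemble_stress <- function(Q, H, K, lambda, zeta, dx = 1) {
  check_field(Q$xx, "Qxx"); check_field(Q$xy, "Qxy")
  check_field(H$xx, "Hxx"); check_field(H$xy, "Hxy")
  cpp_assemble_stress(Q$xx, Q$xy, H$xx, H$xy, K, lambda, zeta, dx)
}
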