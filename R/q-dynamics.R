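# Beris-Edwards evolution of the nematic tensor:
#   dQ/dt + u.grad Q - W = gamma H
# with the generalized advection (co-rotation plus flow alignment)
#   W = (lambda E + Omega)(Q + I/2) + (Q + I/2)(lambda E - Omega)
#       - 2 lambda (Q + I/2) Tr(Q.E).
# The trace-correction coefficient is the standard 2D one (-2 lambda, acting
# on Q + I/2), which keeps W exactly traceless; the representation by the
# (xx, xy) pair then preserves Tr Q = 0 to machine precision at every step.

#' Strain rate and vorticity of a velocity field
#'
#' `E = (grad u + grad u^T)/2` and the scalar vorticity
#' `Omega_xy = (d_x u_y - d_y u_x)/2`, by central differences (exact for
#' linear velocity fields such as rigid rotation or uniform shear).
#'
#' @param ux,uy velocity component matrices.
#' @param dx lattice spacing.
#' @return list with `Exx`, `Eyy`, `Exy` and `Omega`.
#' @export
strain_vorticity <- function(ux, uy, dx = 1) {
  check_field(ux, "ux"); check_field(uy, "uy")
  check_same_dim(ux, uy)
  cpp_strain_vorticity(ux, uy, dx)
}

#' Generalized advection term W
#'
#' @param Q tensor field (list with `xx`, `xy`).
#' @param def flow deformation from [strain_vorticity()].
#' @param lambda flow-aligning parameter.
#' @return list with components `xx` and `xy` (traceless symmetric by
#'   construction; the strain rate is deviatorized internally).
#' @export
generalized_advection <- function(Q, def, lambda) {
  check_field(Q$xx, "Qxx"); check_field(Q$xy, "Qxy")
  cpp_generalized_advection(Q$xx, Q$xy, def$Exx, def$Eyy, def$Exy, def$Omega,
                            lambda)
}

#' One explicit Euler step of the nematic tensor
#'
#' `Q' = Q + dt (-u.grad Q + W + gamma H)`.  The flow deformation and W are
#' recomputed from `u`; aborts with a diagnostic if the order magnitude
#' `S = 2 sqrt(Qxx^2 + Qxy^2)` exceeds `s_max` (blow-up guard).
#'
#' @param Q tensor field (list with `xx`, `xy`).
#' @param ux,uy velocity components (matrices).
#' @param H molecular field from [molecular_field()].
#' @param gamma rotational diffusivity.
#' @param dt time step.
#' @param lambda flow-aligning parameter.
#' @param dx lattice spacing.
#' @param s_max blow-up threshold on S.
#' @return updated tensor field (list with `xx`, `xy`).
#' @export
step_q <- function(Q, ux, uy, H, gamma, dt = 1, lambda = 0.7, dx = 1,
                   s_max = 10) {
  check_field(ux, "ux"); check_field(uy, "uy")
  def <- strain_vorticity(ux, uy, dx)
  W <- generalized_advection(Q, def, lambda)
  adv_xx <- advect_field(Q$xx, ux, uy, dx)
  adv_xy <- advect_field(Q$xy, ux, uy, dx)
  out <- list(xx = Q$xx + dt * (-adv_xx + W$xx + gamma * H$xx),
              xy = Q$xy + dt * (-adv_xy + W$xy + gamma * H$xy))
  smax <- 2 * sqrt(max(out$xx^2 + out$xy^2))
  if (!is.finite(smax) || smax > s_max)
    stop(sprintf("nematic order blew up (S = %g > %g)", smax, s_max))
  out
}
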