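# Advected Cahn-Hilliard dynamics of the cell concentration:
#   d phi / dt + u . grad phi = Gamma_phi lap mu .
# The advection term is implemented as u . grad phi, exactly as the model
# states it (equivalent to the flux form in the incompressible limit);
# conservation is monitored rather than enforced.  The diffusive part is in
# exact discrete conservation form (a laplacian of mu), so at u = 0 the
# total concentration is conserved to round-off.

#' One explicit Euler step of the concentration field
#'
#' `phi' = phi + dt (-u.grad phi + Gamma_phi lap mu)` with `mu` the
#' chemical potential from [chemical_potential()].
#'
#' @param phi concentration field (matrix).
#' @param ux,uy velocity components (matrices, or 0 for a quiescent fluid).
#' @param mu chemical potential on the same grid.
#' @param Gamma_phi mobility (> 0).
#' @param dt time step.
#' @param dx lattice spacing.
#' @param stencil laplacian stencil (5 or 9); note the explicit scheme at
#'   `dt = 1` is only stable with the 9-point stencil (or with substeps).
#' @return updated concentration matrix.
#' @export
step_phi <- function(phi, ux = 0, uy = 0, mu, Gamma_phi, dt = 1, dx = 1,
                     stencil = 5) {
  check_field(phi, "phi"); check_field(mu, "mu")
  if (Gamma_phi <= 0) stop("Gamma_phi must be positive")
  adv <- 0
  if (!identical(ux, 0) || !identical(uy, 0)) {
    if (length(ux) == 1) ux <- matrix(ux, nrow(phi), ncol(phi))
    if (length(uy) == 1) uy <- matrix(uy, nrow(phi), ncol(phi))
    adv <- advect_field(phi, ux, uy, dx)
  }
  out <- phi + dt * (-adv + Gamma_phi * laplacian_field(mu, dx, stencil))
  if (!all(is.finite(out))) stop("concentration update blew up")
  out
}
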