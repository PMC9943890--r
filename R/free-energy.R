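# Free-energy density of the colony model and its functional derivatives:
# the molecular field H (drives Q) and the chemical potential mu (drives phi).
#
#   f = s (C/2) (1 + Tr(Q.Q)/2)^2  +  (B/2) phi^2 (1-phi)^2
#       +  K_phi |grad phi|^2       +  (K/2) |grad Q|^2
#
# with s = +1 under the default "stabilizing" convention, under which the
# isotropic phase (Q = 0) is the bulk minimum and any nematic order must be
# induced by activity.  s = -1 ("printed") is exposed for sensitivity checks.
# Note the concentration-gradient stiffness enters as K_phi (not K_phi/2),
# so mu carries a factor 2 on its laplacian term.

#' Free-energy parameters
#'
#' @param C bulk nematic coefficient (> 0).
#' @param B double-well depth for the concentration field (> 0); the well has
#'   minima at phi = 0 (cell-free background) and phi = 1 (tissue).
#' @param K_phi concentration gradient stiffness (> 0); together with B it
#'   sets the interface width `sqrt(K_phi/B)`.
#' @param K Frank elastic constant, single-constant approximation (> 0).
#' @param convention `"stabilizing"` (default) makes the isotropic phase the
#'   bulk minimum; `"printed"` flips the sign of the bulk Q term.
#' @return list of class `free_energy_params`.
#' @export
free_energy_params <- function(C = 0.001, B = 0.01, K_phi = 0.1, K = 0.02,
                               convention = c("stabilizing", "printed")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(C), C > 0, is.finite(B), B > 0,
            is.finite(K_phi), K_phi > 0, is.finite(K), K > 0)
  structure(list(C = C, B = B, K_phi = K_phi, K = K,
                 convention = convention,
                 bulk_sign = if (convention == "stabilizing") 1 else -1),
            class = "free_energy_params")
}

#' Pointwise free-energy density
#'
#' @param phi concentration field (matrix).
#' @param Q traceless symmetric tensor field, a list with `xx` and `xy`
#'   (see [q_tensor()]).
#' @param p a [free_energy_params()] object.
#' @param dx lattice spacing.
#' @param scheme gradient scheme for the square-gradient terms.  `"forward"`
#'   (default) makes the summed discrete energy exactly consistent with the
#'   5-point laplacians used in [molecular_field()] and
#'   [chemical_potential()]; `"central"` is the plain second-order stencil.
#' @return matrix of the energy density at each node.
#' @export
free_energy_density <- function(phi, Q, p, dx = 1,
                                scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  check_field(phi, "phi"); check_field(Q$xx, "Qxx"); check_field(Q$xy, "Qxy")
  check_same_dim(phi, Q$xx)
  q2 <- Q$xx^2 + Q$xy^2                       # Tr(Q.Q)/2
  gp  <- gradient_field(phi,  dx, scheme)
  gxx <- gradient_field(Q$xx, dx, scheme)
  gxy <- gradient_field(Q$xy, dx, scheme)
  p$bulk_sign * (p$C / 2) * (1 + q2)^2 +
    (p$B / 2) * phi^2 * (1 - phi)^2 +
    p$K_phi * (gp$x^2 + gp$y^2) +
    p$K * (gxx$x^2 + gxx$y^2 + gxy$x^2 + gxy$y^2)
}

#' Total free energy (grid sum of the density times the cell area)
#'
#' @inheritParams free_energy_density
#' @export
total_free_energy <- function(phi, Q, p, dx = 1,
                              scheme = c("forward", "central")) {
  sum(free_energy_density(phi, Q, p, dx, match.arg(scheme))) * dx^2
}

#' Molecular field H
#'
#' The (traceless symmetric) functional derivative driving the nematic
#' tensor:  `H = -s C (1 + Tr(Q.Q)/2) Q + K lap Q`.
#'
#' @inheritParams free_energy_density
#' @param stencil laplacian stencil, 5 or 9.
#' @return list with components `xx` and `xy`.
#' @export
molecular_field <- function(Q, p, dx = 1, stencil = 5) {
  check_field(Q$xx, "Qxx"); check_field(Q$xy, "Qxy")
  if (!stencil %in% c(5, 9)) stop("stencil must be 5 or 9")
  cpp_molecular_field(Q$xx, Q$xy, p$C, p$K, p$bulk_sign, dx,
                      nine = stencil == 9)
}

#' Chemical potential mu
#'
#' `mu = B phi (1 - phi)(1 - 2 phi) - 2 K_phi lap phi`; it vanishes at both
#' well minima and, by symmetry of the well, at the uniform state phi = 1/2.
#'
#' @inheritParams molecular_field
#' @param phi concentration field.
#' @return matrix.
#' @export
chemical_potential <- function(phi, p, dx = 1, stencil = 5) {
  check_field(phi, "phi")
  if (!stencil %in% c(5, 9)) stop("stencil must be 5 or 9")
  cpp_chemical_potential(phi, p$B, p$K_phi, dx, nine = stencil == 9)
}
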