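# Periodic-grid containers and finite-difference operators.
# Fields are plain numeric matrices, first index = x, second = y; all
# operators wrap periodically and are second-order accurate.

#' Periodic finite-difference grid
#'
#' @param nx,ny number of lattice nodes per direction (>= 8).
#' @param dx lattice spacing (lattice units, default 1).
#' @param dt time step (lattice units, default 1).
#' @return An object of class `fd_grid`.
#' @export
fd_grid <- function(nx, ny = nx, dx = 1, dt = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop("grid must have at least 8 nodes per direction")
  if (!is.finite(dx) || dx <= 0 || !is.finite(dt) || dt <= 0)
    stop("dx and dt must be positive")
  structure(list(nx = nx, ny = ny, dx = dx, dt = dt, boundary = "periodic"),
            class = "fd_grid")
}

#' @export
print.fd_grid <- function(x, ...) {
  cat(sprintf("<fd_grid> %d x %d periodic, dx = %g, dt = %g\n",
              x$nx, x$ny, x$dx, x$dt))
  invisible(x)
}

#' Traceless symmetric tensor field
#'
#' Stores the two independent components (xx, xy) of a symmetric traceless
#' 2x2 tensor field; the yy component is implicitly `-xx`, so tracelessness
#' holds by construction.
#'
#' @param xx,xy numeric matrices of equal dimension.
#' @return A list with components `xx` and `xy`, class `q_field`.
#' @export
q_tensor <- function(xx, xy) {
  check_field(xx, "xx"); check_field(xy, "xy")
  if (!identical(dim(xx), dim(xy))) stop("xx and xy must have equal dimensions")
  structure(list(xx = xx, xy = xy), class = "q_field")
}

check_field <- function(f, name = deparse(substitute(f))) {
  if (!is.matrix(f) || !is.numeric(f))
    stop(sprintf("field '%s' must be a numeric matrix", name))
  if (!all(is.finite(f)))
    stop(sprintf("field '%s' contains non-finite values", name))
  invisible(f)
}

check_same_dim <- function(a, b, what = "fields") {
  if (!identical(dim(a), dim(b))) stop(what, " are on mismatched grids")
  invisible(NULL)
}

#' Gradient of a scalar field
#'
#' Second-order central differences with periodic wrap (or first-order
#' forward differences, used to build a discrete free energy whose exact
#' functional derivative is the compact 5-point laplacian).
#'
#' @param f numeric matrix.
#' @param dx lattice spacing.
#' @param scheme `"central"` (default) or `"forward"`.
#' @return list with matrices `x` and `y`.
#' @export
gradient_field <- function(f, dx = 1, scheme = c("central", "forward")) {
  scheme <- match.arg(scheme)
  check_field(f, "f")
  cpp_gradient(f, dx, forward = scheme == "forward")
}

#' Laplacian of a scalar field
#'
#' @inheritParams gradient_field
#' @param stencil 5 (compact) or 9 (isotropic, lower lattice anisotropy and
#'   smaller spectral radius, hence milder stability limit for
#'   Cahn-Hilliard dynamics).
#' @return numeric matrix.
#' @export
laplacian_field <- function(f, dx = 1, stencil = 5) {
  check_field(f, "f")
  if (!stencil %in% c(5, 9)) stop("stencil must be 5 or 9")
  cpp_laplacian(f, dx, nine = stencil == 9)
}

#' Divergence of a rank-2 tensor field
#'
#' Computes `(div T)_j = d_i T_ij` by central differences.  For a traceless
#' symmetric field pass `xx` and `xy` only; the remaining components are
#' filled in as `yx = xy`, `yy = -xx`.
#'
#' @param Txx,Txy,Tyx,Tyy component matrices.
#' @param dx lattice spacing.
#' @return list with force components `x` and `y`.
#' @export
divergence_tensor <- function(Txx, Txy, Tyx = Txy, Tyy = -Txx, dx = 1) {
  check_field(Txx, "Txx"); check_field(Txy, "Txy")
  check_field(Tyx, "Tyx"); check_field(Tyy, "Tyy")
  check_same_dim(Txx, Txy, "tensor components")
  cpp_div_tensor(Txx, Txy, Tyx, Tyy, dx)
}

#' Advection term u . grad f
#'
#' @param f scalar field (matrix).
#' @param ux,uy velocity components.
#' @param dx lattice spacing.
#' @return numeric matrix.
#' @export
advect_field <- function(f, ux, uy, dx = 1) {
  check_field(f, "f"); check_field(ux, "ux"); check_field(uy, "uy")
  check_same_dim(f, ux)
  cpp_advect(f, ux, uy, dx)
}

# Node coordinates of a grid, in lattice units, first node at 0.
grid_coords <- function(nx, ny, dx = 1) {
  list(x = (seq_len(nx) - 1) * dx, y = (seq_len(ny) - 1) * dx)
}
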