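// Numerical core for the wet active-nematic colony model:
// periodic finite-difference operators, free-energy functional derivatives,
// Beris-Edwards Q-tensor terms, D2Q9 BGK lattice Boltzmann with Guo forcing,
// and a fused time-stepping loop.  All exported entry points share these
// static kernels, so the composed R-level operators and the fused driver
// run the same arithmetic.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Periodic neighbour tables (avoids modulo in inner loops).
struct Nbr {
  std::vector<int> p, m;
  explicit Nbr(int n) : p(n), m(n) {
    for (int i = 0; i < n; ++i) {
      p[i] = (i + 1 == n) ? 0 : i + 1;
      m[i] = (i == 0) ? n - 1 : i - 1;
    }
  }
};

inline int at(int i, int j, int nx) { return j * nx + i; }

// ----- derivative kernels (second-order, periodic) -----

void grad_central(const double* f, int nx, int ny, double dx,
                  const Nbr& X, const Nbr& Y, double* gx, double* gy) {
  const double c = 0.5 / dx;
  for (int j = 0; j < ny; ++j) {
    const int jp = Y.p[j], jm = Y.m[j];
    for (int i = 0; i < nx; ++i) {
      const int ip = X.p[i], im = X.m[i];
      gx[at(i, j, nx)] = c * (f[at(ip, j, nx)] - f[at(im, j, nx)]);
      gy[at(i, j, nx)] = c * (f[at(i, jp, nx)] - f[at(i, jm, nx)]);
    }
  }
}

// Forward (one-sided) differences; used for the discrete free energy so that
// the compact 5-point laplacian is its exact functional derivative.
void grad_forward(const double* f, int nx, int ny, double dx,
                  const Nbr& X, const Nbr& Y, double* gx, double* gy) {
  const double c = 1.0 / dx;
  for (int j = 0; j < ny; ++j) {
    const int jp = Y.p[j];
    for (int i = 0; i < nx; ++i) {
      const int ip = X.p[i];
      const int n = at(i, j, nx);
      gx[n] = c * (f[at(ip, j, nx)] - f[n]);
      gy[n] = c * (f[at(i, jp, nx)] - f[n]);
    }
  }
}

// 5-point, or isotropic 9-point ([1 4 1; 4 -20 4; 1 4 1]/6) laplacian.
void laplacian(const double* f, int nx, int ny, double dx, bool nine,
               const Nbr& X, const Nbr& Y, double* out) {
  const double c = 1.0 / (dx * dx);
  for (int j = 0; j < ny; ++j) {
    const int jp = Y.p[j], jm = Y.m[j];
    for (int i = 0; i < nx; ++i) {
      const int ip = X.p[i], im = X.m[i];
      const double cross = f[at(ip, j, nx)] + f[at(im, j, nx)] +
                           f[at(i, jp, nx)] + f[at(i, jm, nx)];
      if (nine) {
        const double diag = f[at(ip, jp, nx)] + f[at(im, jp, nx)] +
                            f[at(ip, jm, nx)] + f[at(im, jm, nx)];
        out[at(i, j, nx)] = c * (4.0 * cross + diag - 20.0 * f[at(i, j, nx)]) / 6.0;
      } else {
        out[at(i, j, nx)] = c * (cross - 4.0 * f[at(i, j, nx)]);
      }
    }
  }
}

// u . grad f, central differences.
void advect(const double* f, const double* ux, const double* uy,
            int nx, int ny, double dx, const Nbr& X, const Nbr& Y,
            double* out) {
  const double c = 0.5 / dx;
  for (int j = 0; j < ny; ++j) {
    const int jp = Y.p[j], jm = Y.m[j];
    for (int i = 0; i < nx; ++i) {
      const int ip = X.p[i], im = X.m[i];
      const int n = at(i, j, nx);
      out[n] = ux[n] * c * (f[at(ip, j, nx)] - f[at(im, j, nx)]) +
               uy[n] * c * (f[at(i, jp, nx)] - f[at(i, jm, nx)]);
    }
  }
}

// ----- free-energy functional derivatives -----

// Molecular field H = -sgn*C*(1 + Tr(Q^2)/2)*Q + K lap Q, with
// Tr(Q^2)/2 = Qxx^2 + Qxy^2 for the traceless symmetric representation.
// sgn = +1 is the stabilizing convention (isotropic phase at zero activity).
void molecular_field_k(const double* Qxx, const double* Qxy,
                       double C, double K, double sgn,
                       int nx, int ny, double dx, bool nine,
                       const Nbr& X, const Nbr& Y,
                       double* lap_xx, double* lap_xy,
                       double* Hxx, double* Hxy) {
  laplacian(Qxx, nx, ny, dx, nine, X, Y, lap_xx);
  laplacian(Qxy, nx, ny, dx, nine, X, Y, lap_xy);
  const int nn = nx * ny;
  for (int n = 0; n < nn; ++n) {
    const double q2 = Qxx[n] * Qxx[n] + Qxy[n] * Qxy[n];
    const double a = sgn * C * (1.0 + q2);
    Hxx[n] = -a * Qxx[n] + K * lap_xx[n];
    Hxy[n] = -a * Qxy[n] + K * lap_xy[n];
  }
}

// mu = B phi (1-phi)(1-2phi) - 2 K_phi lap phi
void chem_potential_k(const double* phi, double B, double Kphi,
                      int nx, int ny, double dx, bool nine,
                      const Nbr& X, const Nbr& Y,
                      double* lap_phi, double* mu) {
  laplacian(phi, nx, ny, dx, nine, X, Y, lap_phi);
  const int nn = nx * ny;
  for (int n = 0; n < nn; ++n) {
    const double p = phi[n];
    mu[n] = B * p * (1.0 - p) * (1.0 - 2.0 * p) - 2.0 * Kphi * lap_phi[n];
  }
}

// ----- flow deformation and generalized advection -----

void strain_vorticity_k(const double* ux, const double* uy,
                        int nx, int ny, double dx,
                        const Nbr& X, const Nbr& Y,
                        double* Exx, double* Eyy, double* Exy, double* Om) {
  const double c = 0.5 / dx;
  for (int j = 0; j < ny; ++j) {
    const int jp = Y.p[j], jm = Y.m[j];
    for (int i = 0; i < nx; ++i) {
      const int ip = X.p[i], im = X.m[i];
      const int n = at(i, j, nx);
      const double dxux = c * (ux[at(ip, j, nx)] - ux[at(im, j, nx)]);
      const double dyux = c * (ux[at(i, jp, nx)] - ux[at(i, jm, nx)]);
      const double dxuy = c * (uy[at(ip, j, nx)] - uy[at(im, j, nx)]);
      const double dyuy = c * (uy[at(i, jp, nx)] - uy[at(i, jm, nx)]);
      Exx[n] = dxux;
      Eyy[n] = dyuy;
      Exy[n] = 0.5 * (dxuy + dyux);
      Om[n]  = 0.5 * (dxuy - dyux);   // Omega_xy
    }
  }
}

// W = (lam E + Om) (Q + I/2) + (Q + I/2)(lam E - Om) - 2 lam (Q + I/2) Tr(QE),
// with E taken deviatoric so that Tr W = 0 exactly.
void gen_advection_k(const double* Qxx, const double* Qxy,
                     const double* Exx, const double* Eyy,
                     const double* Exy, const double* Om,
                     double lam, int nn, double* Wxx, double* Wxy) {
  for (int n = 0; n < nn; ++n) {
    const double exx = 0.5 * (Exx[n] - Eyy[n]);   // deviatoric strain
    const double exy = Exy[n];
    // Om is the vorticity (d_x u_y - d_y u_x)/2, counterclockwise positive.
    // The antisymmetric tensor entering the generalized advection is the
    // rotation generator with Omega_xy = -vorticity (Jacobian convention
    // d_j u_i), so that at lambda = 0 a uniform director co-rotates with a
    // rigidly rotating flow (Jaumann rate).
    const double om  = -Om[n];
    const double a11 = Qxx[n] + 0.5, a12 = Qxy[n], a22 = 0.5 - Qxx[n];
    // M1 = lam e + Omega, M2 = lam e - Omega (2x2, e traceless symmetric)
    const double m1_11 = lam * exx,        m1_12 = lam * exy + om;
    const double m1_21 = lam * exy - om,   m1_22 = -lam * exx;
    const double m2_11 = m1_11,            m2_12 = m1_21;
    const double m2_21 = m1_12,            m2_22 = m1_22;
    const double t1_11 = m1_11 * a11 + m1_12 * a12;
    const double t1_12 = m1_11 * a12 + m1_12 * a22;
    const double t2_11 = a11 * m2_11 + a12 * m2_21;
    const double t2_12 = a11 * m2_12 + a12 * m2_22;
    (void)m1_21; (void)m1_22;
    const double trQE = 2.0 * (Qxx[n] * exx + Qxy[n] * exy);
    Wxx[n] = t1_11 + t2_11 - 2.0 * lam * trQE * a11;
    Wxy[n] = t1_12 + t2_12 - 2.0 * lam * trQE * a12;
  }
}

// ----- stress assembly -----
// Deviatoric (pressure-free, viscosity-free) stress:
//   Pi = 2 lam (Q:H) (Q + I/2) - lam [H(Q+I/2) + (Q+I/2)H] + (QH - HQ)
//        - K (d_i Q_kl)(d_j Q_kl) + zeta Q
// which for traceless symmetric 2x2 Q, H collapses to
//   Pi = 2 lam (Q:H) Q - lam H + (QH - HQ) - K G + zeta Q,
// with Q:H = 2(Qxx Hxx + Qxy Hxy) and G_ij = 2(d_i Qxx d_j Qxx + d_i Qxy d_j Qxy).
// Pressure and the viscous part live inside the LB solver.
void stress_k(const double* Qxx, const double* Qxy,
              const double* Hxx, const double* Hxy,
              const double* gxQxx, const double* gyQxx,
              const double* gxQxy, const double* gyQxy,
              double K, double lam, double zeta, int nn,
              double* Pxx, double* Pxy, double* Pyx, double* Pyy) {
  for (int n = 0; n < nn; ++n) {
    const double qh = 2.0 * (Qxx[n] * Hxx[n] + Qxy[n] * Hxy[n]);
    const double anti = 2.0 * (Qxx[n] * Hxy[n] - Qxy[n] * Hxx[n]); // (QH-HQ)_xy
    const double Gxx = 2.0 * (gxQxx[n] * gxQxx[n] + gxQxy[n] * gxQxy[n]);
    const double Gyy = 2.0 * (gyQxx[n] * gyQxx[n] + gyQxy[n] * gyQxy[n]);
    const double Gxy = 2.0 * (gxQxx[n] * gyQxx[n] + gxQxy[n] * gyQxy[n]);
    const double sxx = 2.0 * lam * qh * Qxx[n] - lam * Hxx[n] + zeta * Qxx[n];
    const double sxy = 2.0 * lam * qh * Qxy[n] - lam * Hxy[n] + zeta * Qxy[n];
    Pxx[n] = sxx - K * Gxx;
    Pyy[n] = -sxx - K * Gyy;
    Pxy[n] = sxy + anti - K * Gxy;
    Pyx[n] = sxy - anti - K * Gxy;
  }
}

// (div Pi)_j = d_i Pi_ij
void div_tensor_k(const double* Pxx, const double* Pxy,
                  const double* Pyx, const double* Pyy,
                  int nx, int ny, double dx,
                  const Nbr& X, const Nbr& Y,
                  double* fx, double* fy) {
  const double c = 0.5 / dx;
  for (int j = 0; j < ny; ++j) {
    const int jp = Y.p[j], jm = Y.m[j];
    for (int i = 0; i < nx; ++i) {
      const int ip = X.p[i], im = X.m[i];
      const int n = at(i, j, nx);
      fx[n] = c * (Pxx[at(ip, j, nx)] - Pxx[at(im, j, nx)]) +
              c * (Pyx[at(i, jp, nx)] - Pyx[at(i, jm, nx)]);
      fy[n] = c * (Pxy[at(ip, j, nx)] - Pxy[at(im, j, nx)]) +
              c * (Pyy[at(i, jp, nx)] - Pyy[at(i, jm, nx)]);
    }
  }
}

// ----- D2Q9 BGK lattice Boltzmann with Guo forcing -----

const int    CX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
const int    CY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
const double WT[9] = {4.0 / 9.0,
                      1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                      1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};

inline double feq_k(int k, double rho, double ux, double uy) {
  const double cu = CX[k] * ux + CY[k] * uy;
  const double u2 = ux * ux + uy * uy;
  return WT[k] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
}

// One collide + stream cycle.  fpop and ftmp are nx*ny*9 (population-major
// slabs of nx*ny).  On exit fpop holds streamed populations and rho/ux/uy the
// post-step macroscopic moments (with the Guo half-force velocity shift).
void lb_step_k(double* fpop, double* ftmp,
               const double* fx, const double* fy,
               double tau, int nx, int ny,
               const Nbr& X, const Nbr& Y,
               double* rho, double* ux, double* uy) {
  const int nn = nx * ny;
  const double omega = 1.0 / tau;
  const double fpre = 1.0 - 0.5 / tau;
  // moments of the incoming populations
  for (int n = 0; n < nn; ++n) {
    double r = 0.0, mx = 0.0, my = 0.0;
    for (int k = 0; k < 9; ++k) {
      const double f = fpop[k * nn + n];
      r += f; mx += CX[k] * f; my += CY[k] * f;
    }
    rho[n] = r;
    ux[n] = (mx + 0.5 * fx[n]) / r;
    uy[n] = (my + 0.5 * fy[n]) / r;
  }
  // collide
  for (int k = 0; k < 9; ++k) {
    double* fk = fpop + k * nn;
    for (int n = 0; n < nn; ++n) {
      const double cu = CX[k] * ux[n] + CY[k] * uy[n];
      const double src = fpre * WT[k] *
        ((3.0 * (CX[k] - ux[n]) + 9.0 * cu * CX[k]) * fx[n] +
         (3.0 * (CY[k] - uy[n]) + 9.0 * cu * CY[k]) * fy[n]);
      fk[n] += -omega * (fk[n] - feq_k(k, rho[n], ux[n], uy[n])) + src;
    }
  }
  // stream (periodic)
  for (int k = 0; k < 9; ++k) {
    const double* fk = fpop + k * nn;
    double* gk = ftmp + k * nn;
    for (int j = 0; j < ny; ++j) {
      const int jd = (CY[k] == 1) ? Y.p[j] : (CY[k] == -1 ? Y.m[j] : j);
      for (int i = 0; i < nx; ++i) {
        const int id = (CX[k] == 1) ? X.p[i] : (CX[k] == -1 ? X.m[i] : i);
        gk[at(id, jd, nx)] = fk[at(i, j, nx)];
      }
    }
  }
  std::copy(ftmp, ftmp + 9 * nn, fpop);
  // post-stream moments for the caller
  for (int n = 0; n < nn; ++n) {
    double r = 0.0, mx = 0.0, my = 0.0;
    for (int k = 0; k < 9; ++k) {
      const double f = fpop[k * nn + n];
      r += f; mx += CX[k] * f; my += CY[k] * f;
    }
    rho[n] = r;
    ux[n] = (mx + 0.5 * fx[n]) / r;
    uy[n] = (my + 0.5 * fy[n]) / r;
  }
}

} // namespace

// ======================= exported operators =======================

// [[Rcpp::export]]
List cpp_gradient(NumericMatrix f, double dx, bool forward = false) {
  const int nx = f.nrow(), ny = f.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix gx(nx, ny), gy(nx, ny);
  if (forward)
    grad_forward(f.begin(), nx, ny, dx, X, Y, gx.begin(), gy.begin());
  else
    grad_central(f.begin(), nx, ny, dx, X, Y, gx.begin(), gy.begin());
  return List::create(_["x"] = gx, _["y"] = gy);
}

// [[Rcpp::export]]
NumericMatrix cpp_laplacian(NumericMatrix f, double dx, bool nine = false) {
  const int nx = f.nrow(), ny = f.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix out(nx, ny);
  laplacian(f.begin(), nx, ny, dx, nine, X, Y, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_advect(NumericMatrix f, NumericMatrix ux, NumericMatrix uy,
                         double dx) {
  const int nx = f.nrow(), ny = f.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix out(nx, ny);
  advect(f.begin(), ux.begin(), uy.begin(), nx, ny, dx, X, Y, out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_div_tensor(NumericMatrix Pxx, NumericMatrix Pxy,
                    NumericMatrix Pyx, NumericMatrix Pyy, double dx) {
  const int nx = Pxx.nrow(), ny = Pxx.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix fx(nx, ny), fy(nx, ny);
  div_tensor_k(Pxx.begin(), Pxy.begin(), Pyx.begin(), Pyy.begin(),
               nx, ny, dx, X, Y, fx.begin(), fy.begin());
  return List::create(_["x"] = fx, _["y"] = fy);
}

// [[Rcpp::export]]
List cpp_molecular_field(NumericMatrix Qxx, NumericMatrix Qxy,
                         double C, double K, double sgn, double dx,
                         bool nine = false) {
  const int nx = Qxx.nrow(), ny = Qxx.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix Hxx(nx, ny), Hxy(nx, ny);
  std::vector<double> l1(nx * ny), l2(nx * ny);
  molecular_field_k(Qxx.begin(), Qxy.begin(), C, K, sgn, nx, ny, dx, nine,
                    X, Y, l1.data(), l2.data(), Hxx.begin(), Hxy.begin());
  return List::create(_["xx"] = Hxx, _["xy"] = Hxy);
}

// [[Rcpp::export]]
NumericMatrix cpp_chemical_potential(NumericMatrix phi, double B, double Kphi,
                                     double dx, bool nine = false) {
  const int nx = phi.nrow(), ny = phi.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix mu(nx, ny);
  std::vector<double> l(nx * ny);
  chem_potential_k(phi.begin(), B, Kphi, nx, ny, dx, nine, X, Y,
                   l.data(), mu.begin());
  return mu;
}

// [[Rcpp::export]]
List cpp_strain_vorticity(NumericMatrix ux, NumericMatrix uy, double dx) {
  const int nx = ux.nrow(), ny = ux.ncol();
  Nbr X(nx), Y(ny);
  NumericMatrix Exx(nx, ny), Eyy(nx, ny), Exy(nx, ny), Om(nx, ny);
  strain_vorticity_k(ux.begin(), uy.begin(), nx, ny, dx, X, Y,
                     Exx.begin(), Eyy.begin(), Exy.begin(), Om.begin());
  return List::create(_["Exx"] = Exx, _["Eyy"] = Eyy, _["Exy"] = Exy,
                      _["Omega"] = Om);
}

// [[Rcpp::export]]
List cpp_generalized_advection(NumericMatrix Qxx, NumericMatrix Qxy,
                               NumericMatrix Exx, NumericMatrix Eyy,
                               NumericMatrix Exy, NumericMatrix Om,
                               double lambda) {
  const int nn = Qxx.nrow() * Qxx.ncol();
  NumericMatrix Wxx(Qxx.nrow(), Qxx.ncol()), Wxy(Qxx.nrow(), Qxx.ncol());
  gen_advection_k(Qxx.begin(), Qxy.begin(), Exx.begin(), Eyy.begin(),
                  Exy.begin(), Om.begin(), lambda, nn,
                  Wxx.begin(), Wxy.begin());
  return List::create(_["xx"] = Wxx, _["xy"] = Wxy);
}

// [[Rcpp::export]]
List cpp_assemble_stress(NumericMatrix Qxx, NumericMatrix Qxy,
                         NumericMatrix Hxx, NumericMatrix Hxy,
                         double K, double lambda, double zeta, double dx) {
  const int nx = Qxx.nrow(), ny = Qxx.ncol();
  const int nn = nx * ny;
  Nbr X(nx), Y(ny);
  std::vector<double> gxx(nn), gyx(nn), gxy(nn), gyy(nn);
  grad_central(Qxx.begin(), nx, ny, dx, X, Y, gxx.data(), gyx.data());
  grad_central(Qxy.begin(), nx, ny, dx, X, Y, gxy.data(), gyy.data());
  NumericMatrix Pxx(nx, ny), Pxy(nx, ny), Pyx(nx, ny), Pyy(nx, ny);
  stress_k(Qxx.begin(), Qxy.begin(), Hxx.begin(), Hxy.begin(),
           gxx.data(), gyx.data(), gxy.data(), gyy.data(),
           K, lambda, zeta, nn,
           Pxx.begin(), Pxy.begin(), Pyx.begin(), Pyy.begin());
  return List::create(_["xx"] = Pxx, _["xy"] = Pxy,
                      _["yx"] = Pyx, _["yy"] = Pyy);
}

// [[Rcpp::export]]
NumericVector cpp_lb_equilibrium(int nx, int ny, double rho0,
                                 NumericMatrix ux, NumericMatrix uy) {
  const int nn = nx * ny;
  NumericVector f(9 * nn);
  for (int k = 0; k < 9; ++k)
    for (int n = 0; n < nn; ++n)
      f[k * nn + n] = feq_k(k, rho0, ux[n], uy[n]);
  return f;
}

// [[Rcpp::export]]
List cpp_lb_step(NumericVector fpop, NumericMatrix Fx, NumericMatrix Fy,
                 double tau, int nx, int ny) {
  const int nn = nx * ny;
  if (fpop.size() != 9 * nn) stop("population array must have length 9*nx*ny");
  Nbr X(nx), Y(ny);
  NumericVector f = clone(fpop);
  std::vector<double> ftmp(9 * nn);
  NumericMatrix rho(nx, ny), ux(nx, ny), uy(nx, ny);
  lb_step_k(f.begin(), ftmp.data(), Fx.begin(), Fy.begin(), tau, nx, ny,
            X, Y, rho.begin(), ux.begin(), uy.begin());
  return List::create(_["f"] = f, _["rho"] = rho, _["ux"] = ux, _["uy"] = uy);
}

// ======================= fused time stepper =======================

// Advances the coupled model n_steps.  par is the flat parameter list built by
// model_params(); all fields are modified on (cloned) copies and returned.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix phi_in, NumericMatrix Qxx_in,
                 NumericMatrix Qxy_in, NumericVector fpop_in,
                 List par, int n_steps, int step0) {
  NumericMatrix phi = clone(phi_in), Qxx = clone(Qxx_in), Qxy = clone(Qxy_in);
  NumericVector fpop = clone(fpop_in);

  const int nx = phi.nrow(), ny = phi.ncol();
  const int nn = nx * ny;
  if (fpop.size() != 9 * nn) stop("population array must have length 9*nx*ny");
  Nbr X(nx), Y(ny);

  const double C      = as<double>(par["C"]);
  const double B      = as<double>(par["B"]);
  const double Kphi   = as<double>(par["K_phi"]);
  const double K      = as<double>(par["K"]);
  const double gamma  = as<double>(par["gamma"]);
  const double Gphi   = as<double>(par["Gamma_phi"]);
  const double lam    = as<double>(par["lambda"]);
  const double zeta   = as<double>(par["zeta"]);
  const double tau    = as<double>(par["tau_lb"]);
  const double dx     = as<double>(par["dx"]);
  const double dt     = as<double>(par["dt"]);
  const double sgn    = as<double>(par["bulk_sign"]);
  const bool   nine   = as<bool>(par["nine_point"]);
  const bool   actphi = as<bool>(par["active_phi"]);
  const int    nsub   = as<int>(par["phi_substeps"]);
  const double smax   = as<double>(par["s_max"]);
  const double umax   = as<double>(par["u_max"]);

  std::vector<double> lap1(nn), lap2(nn), Hxx(nn), Hxy(nn),
      gxQxx(nn), gyQxx(nn), gxQxy(nn), gyQxy(nn),
      Pxx(nn), Pxy(nn), Pyx(nn), Pyy(nn), fx(nn), fy(nn),
      Exx(nn), Eyy(nn), Exy(nn), Om(nn), Wxx(nn), Wxy(nn),
      adv1(nn), adv2(nn), mu(nn), lapmu(nn), ftmp(9 * nn),
      zQxx(nn), zQxy(nn);
  NumericMatrix rho(nx, ny), ux(nx, ny), uy(nx, ny);

  for (int s = 0; s < n_steps; ++s) {
    // molecular field and stress from the current configuration
    molecular_field_k(Qxx.begin(), Qxy.begin(), C, K, sgn, nx, ny, dx, nine,
                      X, Y, lap1.data(), lap2.data(), Hxx.data(), Hxy.data());
    grad_central(Qxx.begin(), nx, ny, dx, X, Y, gxQxx.data(), gyQxx.data());
    grad_central(Qxy.begin(), nx, ny, dx, X, Y, gxQxy.data(), gyQxy.data());
    const double* sQxx = Qxx.begin();
    const double* sQxy = Qxy.begin();
    if (actphi) {  // optional: activity carried by the cell phase only
      for (int n = 0; n < nn; ++n) {
        zQxx[n] = phi[n] * Qxx[n];
        zQxy[n] = phi[n] * Qxy[n];
      }
      stress_k(Qxx.begin(), Qxy.begin(), Hxx.data(), Hxy.data(),
               gxQxx.data(), gyQxx.data(), gxQxy.data(), gyQxy.data(),
               K, lam, 0.0, nn, Pxx.data(), Pxy.data(), Pyx.data(), Pyy.data());
      for (int n = 0; n < nn; ++n) {
        Pxx[n] += zeta * zQxx[n]; Pyy[n] -= zeta * zQxx[n];
        Pxy[n] += zeta * zQxy[n]; Pyx[n] += zeta * zQxy[n];
      }
    } else {
      stress_k(sQxx, sQxy, Hxx.data(), Hxy.data(),
               gxQxx.data(), gyQxx.data(), gxQxy.data(), gyQxy.data(),
               K, lam, zeta, nn, Pxx.data(), Pxy.data(), Pyx.data(), Pyy.data());
    }
    div_tensor_k(Pxx.data(), Pxy.data(), Pyx.data(), Pyy.data(),
                 nx, ny, dx, X, Y, fx.data(), fy.data());

    // flow update
    lb_step_k(fpop.begin(), ftmp.data(), fx.data(), fy.data(), tau, nx, ny,
              X, Y, rho.begin(), ux.begin(), uy.begin());

    // nematic update (explicit Euler): dQ = -u.grad Q + W + gamma H
    strain_vorticity_k(ux.begin(), uy.begin(), nx, ny, dx, X, Y,
                       Exx.data(), Eyy.data(), Exy.data(), Om.data());
    gen_advection_k(Qxx.begin(), Qxy.begin(), Exx.data(), Eyy.data(),
                    Exy.data(), Om.data(), lam, nn, Wxx.data(), Wxy.data());
    advect(Qxx.begin(), ux.begin(), uy.begin(), nx, ny, dx, X, Y, adv1.data());
    advect(Qxy.begin(), ux.begin(), uy.begin(), nx, ny, dx, X, Y, adv2.data());
    for (int n = 0; n < nn; ++n) {
      Qxx[n] += dt * (-adv1[n] + Wxx[n] + gamma * Hxx[n]);
      Qxy[n] += dt * (-adv2[n] + Wxy[n] + gamma * Hxy[n]);
    }

    // concentration update, sub-stepped (biharmonic stability margin)
    const double dts = dt / nsub;
    for (int ss = 0; ss < nsub; ++ss) {
      chem_potential_k(phi.begin(), B, Kphi, nx, ny, dx, nine, X, Y,
                       lap1.data(), mu.data());
      laplacian(mu.data(), nx, ny, dx, nine, X, Y, lapmu.data());
      advect(phi.begin(), ux.begin(), uy.begin(), nx, ny, dx, X, Y, adv1.data());
      for (int n = 0; n < nn; ++n)
        phi[n] += dts * (-adv1[n] + Gphi * lapmu[n]);
    }

    // guards
    double s2max = 0.0, uu = 0.0;
    for (int n = 0; n < nn; ++n) {
      const double q2 = Qxx[n] * Qxx[n] + Qxy[n] * Qxy[n];
      if (q2 > s2max) s2max = q2;
      const double v2 = ux[n] * ux[n] + uy[n] * uy[n];
      if (v2 > uu) uu = v2;
    }
    if (!(s2max == s2max) || 2.0 * std::sqrt(s2max) > smax)
      stop("nematic order blew up (S = %f) at step %d", 2.0 * std::sqrt(s2max),
           step0 + s + 1);
    if (!(uu == uu) || std::sqrt(uu) > umax)
      stop("Mach guard tripped (|u| = %f) at step %d", std::sqrt(uu),
           step0 + s + 1);
    if ((s & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["phi"] = phi, _["Qxx"] = Qxx, _["Qxy"] = Qxy,
                      _["f"] = fpop, _["rho"] = rho,
                      _["ux"] = ux, _["uy"] = uy);
}
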