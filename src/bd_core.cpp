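// Brownian-dynamics core for the wall-grafted bead-spring chain.
// Reduced units throughout: length in bead radii a, energy in kBT,
// mobility in mu0 = 1/(6 pi eta a), time in tau_a = a^2/(mu0 kBT).
// R wrappers convert physical units at the boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BOND = 2.0;  // rest length = bead diameter, units a

// ---- potentials -----------------------------------------------------------

// wall 10-4 potential (repulsive branch active for 0 < z < sigR)
static inline double wall_u(double z, double sigR, double amp) {
  if (z >= sigR) return 0.0;
  double s4 = std::pow(sigR / z, 4), s10 = std::pow(sigR / z, 10);
  return amp * (0.4 * s10 - s4 + 0.6);
}

// -dU/dz of the wall potential
static inline double wall_fz(double z, double sigR, double amp) {
  if (z >= sigR) return 0.0;
  double s4 = std::pow(sigR, 4) / std::pow(z, 5);
  double s10 = std::pow(sigR, 10) / std::pow(z, 11);
  return amp * 4.0 * (s10 - s4);
}

// [[Rcpp::export]]
double cpp_chain_energy(const arma::mat& pos, double eps, double kappa,
                        bool wall, double sigR, double wall_amp,
                        int wall_skip = -1) {
  const int N = pos.n_rows;
  double U = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double r = arma::norm(pos.row(i) - pos.row(j));
      if (r <= 0.0) stop("coincident beads (r_ij = 0)");
      double s6 = std::pow(BOND / r, 6);
      U += eps * (s6 * s6 - 2.0 * s6);
      if (j == i + 1) U += 0.5 * kappa * (r - BOND) * (r - BOND);
    }
    if (wall && i != wall_skip) {
      if (pos(i, 2) <= 0.0) stop("bead at z <= 0 inside the wall");
      U += wall_u(pos(i, 2), sigR, wall_amp);
    }
  }
  return U;
}

// [[Rcpp::export]]
arma::mat cpp_chain_forces(const arma::mat& pos, double eps, double kappa,
                           bool wall, double sigR, double wall_amp,
                           int wall_skip = -1) {
  const int N = pos.n_rows;
  arma::mat F(N, 3, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      arma::rowvec d = pos.row(i) - pos.row(j);
      double r = arma::norm(d);
      if (r <= 0.0) stop("coincident beads (r_ij = 0)");
      double s6 = std::pow(BOND / r, 6);
      // dU_LJ/dr = (12 eps / r) (s6 - s12)
      double dudr = (12.0 * eps / r) * (s6 - s6 * s6);
      if (j == i + 1) dudr += kappa * (r - BOND);
      arma::rowvec f = -(dudr / r) * d;   // force on i
      F.row(i) += f;
      F.row(j) -= f;
    }
    if (wall && i != wall_skip) {
      if (pos(i, 2) <= 0.0) stop("bead at z <= 0 inside the wall");
      F(i, 2) += wall_fz(pos(i, 2), sigR, wall_amp);
    }
  }
  return F;
}

// ---- mobilities -----------------------------------------------------------

// [0/3] Pade resummation of the wall-corrected self-mobility far-field
// series (positive and monotone for all z > 0; matches
// 1 - (9/16)s + (1/8)s^3 resp. 1 - (9/8)s + (1/2)s^3 to O(s^3), s = a/z)
static inline double mu_self_par(double z) {
  double s = 1.0 / z;
  return 1.0 / (1.0 + s * (9.0 / 16.0 + s * (81.0 / 256.0
                 + s * (217.0 / 4096.0))));
}
static inline double mu_self_perp(double z) {
  double s = 1.0 / z;
  return 1.0 / (1.0 + s * (9.0 / 8.0 + s * (81.0 / 64.0
                 + s * (473.0 / 512.0))));
}

// d mu_perp / dz (analytic; the Ermak-McCammon drift term is kBT times
// this, kBT = 1 in reduced units)
static inline double dmu_perp_dz(double z) {
  double s = 1.0 / z;
  double P = 1.0 + s * (9.0 / 8.0 + s * (81.0 / 64.0
               + s * (473.0 / 512.0)));
  double Pp = 9.0 / 8.0 + s * (2.0 * 81.0 / 64.0 + s * 3.0 * 473.0 / 512.0);
  return Pp * s * s / (P * P);
}

// free-space Rotne-Prager-Yamakawa pair mobility (units mu0), a = 1
static arma::mat33 rpy_pair(const arma::vec3& d) {
  double r = arma::norm(d);
  arma::mat33 I = arma::eye(3, 3);
  if (r < 1e-14) return I;  // coincident guard (never hit in practice)
  arma::vec3 e = d / r;
  arma::mat33 ee = e * e.t();
  if (r >= 2.0) {
    return (3.0 / (4.0 * r)) * (I + ee)
         + (1.0 / (2.0 * r * r * r)) * (I - 3.0 * ee);
  }
  // overlapping form preserves positive-definiteness
  return (1.0 - 9.0 * r / 32.0) * I + (3.0 * r / 32.0) * ee;
}

// Blake image system at point-Stokeslet level: correction to the Green
// function (units of 1/(8 pi eta), i.e. Stokeslet units) for a source at
// height h, evaluated via the image point. Satisfies no-slip at z = 0.
static arma::mat33 blake_image(const arma::vec3& xi, const arma::vec3& xj) {
  double h = xj(2);
  arma::vec3 Rv = xi - arma::vec3({xj(0), xj(1), -h});
  double R = arma::norm(Rv);
  double R3 = R * R * R, R5 = R3 * R * R;
  arma::mat33 C;
  // image Stokeslet
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      C(a, b) = -((a == b ? 1.0 / R : 0.0) + Rv(a) * Rv(b) / R3);
  // doublet terms: 2 h Delta_b { h [d_ab/R^3 - 3 R_a R_b/R^5]
  //   - [ -d_a3 R_b/R^3 + (d_ab R_3 + d_3b R_a)/R^3 - 3 R_a R_3 R_b/R^5 ] }
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      double Delta = (b == 2) ? -1.0 : 1.0;
      double dab = (a == b) ? 1.0 : 0.0;
      double t1 = h * (dab / R3 - 3.0 * Rv(a) * Rv(b) / R5);
      double t2 = -((a == 2) ? 1.0 : 0.0) * Rv(b) / R3
                + (dab * Rv(2) + ((b == 2) ? 1.0 : 0.0) * Rv(a)) / R3
                - 3.0 * Rv(a) * Rv(2) * Rv(b) / R5;
      C(a, b) += 2.0 * h * Delta * (t1 - t2);
    }
  }
  return C;
}

// hydro: 0 = none (mu0 I blocks), 1 = free-space RPY, 2 = wall-corrected
// [[Rcpp::export]]
arma::mat cpp_mobility(const arma::mat& pos, int hydro) {
  const int N = pos.n_rows;
  arma::mat M(3 * N, 3 * N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    arma::mat33 self = arma::eye(3, 3);
    if (hydro == 2) {
      double z = pos(i, 2);
      if (z <= 0.0) stop("bead at z <= 0 in wall-corrected mode");
      self(0, 0) = self(1, 1) = mu_self_par(z);
      self(2, 2) = mu_self_perp(z);
    }
    M.submat(3 * i, 3 * i, 3 * i + 2, 3 * i + 2) = self;
    if (hydro == 0) continue;
    for (int j = i + 1; j < N; ++j) {
      arma::vec3 d = (pos.row(i) - pos.row(j)).t();
      arma::mat33 mij = rpy_pair(d);
      if (hydro == 2) {
        arma::vec3 xi = pos.row(i).t(), xj = pos.row(j).t();
        mij += 0.75 * blake_image(xi, xj);   // mu0 * (3a/4) * Stokeslet units
      }
      M.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2) = mij;
      M.submat(3 * j, 3 * i, 3 * j + 2, 3 * i + 2) = mij.t();
    }
  }
  return 0.5 * (M + M.t());  // enforce exact symmetry
}

// [[Rcpp::export]]
arma::vec cpp_drift(const arma::mat& pos, int hydro) {
  const int N = pos.n_rows;
  arma::vec v(N, arma::fill::zeros);
  if (hydro != 2) return v;
  for (int i = 0; i < N; ++i) v(i) = dmu_perp_dz(pos(i, 2));
  return v;
}

// lower-triangular factor with PSD fallback (eigenvalue clipping)
static arma::mat chol_psd(const arma::mat& M) {
  arma::mat L;
  if (arma::chol(L, M, "lower")) return L;
  arma::vec eval; arma::mat evec;
  if (!arma::eig_sym(eval, evec, M))
    stop("mobility matrix factorisation failed");
  double floor = 1e-12 * eval.max();
  eval.transform([floor](double v) { return v < floor ? floor : v; });
  return evec * arma::diagmat(arma::sqrt(eval));
}

// [[Rcpp::export]]
arma::mat cpp_sqrt_mobility(const arma::mat& M) { return chol_psd(M); }

// One Euler-Maruyama (Ermak-McCammon) step; exported mainly for testing.
// [[Rcpp::export]]
arma::mat cpp_bd_step(const arma::mat& pos, List par) {
  const int N = pos.n_rows;
  double eps = par["eps"], kappa = par["kappa"], sigR = par["sigR"],
         wall_amp = par["wall_amp"], shear = par["shear"], dt = par["dt"];
  bool wall = par["wall"], noise = par["noise"], drift = par["drift"],
       grafted = par["grafted"], literal_shear = par["literal_shear"];
  int hydro = par["hydro"];

  arma::mat M = cpp_mobility(pos, hydro);
  // the anchor constraint, not the wall, holds the grafted bead: no wall
  // force is applied to it (or transmitted hydrodynamically from it)
  arma::mat Fm = cpp_chain_forces(pos, eps, kappa, wall, sigR, wall_amp,
                                  grafted ? 0 : -1);
  arma::vec Fv = arma::vectorise(Fm.t());    // (x1,y1,z1,x2,...)
  arma::vec dx = M * Fv * dt;

  for (int i = 0; i < N; ++i) {
    double muxx = literal_shear ? 1.0 : M(3 * i, 3 * i);
    dx(3 * i) += shear * pos(i, 2) * muxx * dt;
  }
  if (drift && hydro == 2) {
    arma::vec vc = cpp_drift(pos, hydro);
    for (int i = 0; i < N; ++i) dx(3 * i + 2) += vc(i) * dt;
  }
  if (noise && dt > 0) {
    arma::mat L = chol_psd(M);
    NumericVector xi = rnorm(3 * N);
    arma::vec xiv(xi.begin(), 3 * N, false);
    dx += std::sqrt(2.0 * dt) * (L * xiv);
  }
  if (grafted) dx.subvec(0, 2).zeros();

  arma::mat out = pos;
  for (int i = 0; i < N; ++i) {
    out(i, 0) += dx(3 * i);
    out(i, 1) += dx(3 * i + 1);
    out(i, 2) += dx(3 * i + 2);
  }
  if (wall) {
    int i0 = grafted ? 1 : 0;
    for (int i = i0; i < N; ++i) {
      if (out(i, 2) <= 0.0) out(i, 2) = std::max(-out(i, 2), 1e-9);
    }
  }
  return out;
}

// Full run: equilibration (no recording) + production with block means of
// bond lengths; also records per-block x-extension and radius of gyration.
// [[Rcpp::export]]
List cpp_bd_run(const arma::mat& pos0, List par, int n_equil, int n_steps,
                int block_size) {
  const int N = pos0.n_rows;
  double eps = par["eps"], kappa = par["kappa"], sigR = par["sigR"],
         wall_amp = par["wall_amp"], shear = par["shear"], dt = par["dt"];
  bool wall = par["wall"], noise = par["noise"], drift = par["drift"],
       grafted = par["grafted"], literal_shear = par["literal_shear"];
  int hydro = par["hydro"];
  const double contour = BOND * (N - 1);

  arma::mat pos = pos0;
  int n_blocks = n_steps / block_size;
  arma::mat blocks(n_blocks, N - 1, arma::fill::zeros);
  arma::vec ext(n_blocks, arma::fill::zeros);
  arma::vec rg(n_blocks, arma::fill::zeros);

  arma::vec bond_acc(N - 1, arma::fill::zeros);
  double ext_acc = 0.0, rg_acc = 0.0;
  int in_block = 0, ib = 0;

  long total = (long)n_equil + (long)n_steps;
  for (long s = 0; s < total; ++s) {
    // --- one step (inlined for speed) ---
    arma::mat M = cpp_mobility(pos, hydro);
    arma::mat Fm = cpp_chain_forces(pos, eps, kappa, wall, sigR, wall_amp,
                                    grafted ? 0 : -1);
    arma::vec Fv = arma::vectorise(Fm.t());
    arma::vec dx = M * Fv * dt;
    for (int i = 0; i < N; ++i) {
      double muxx = literal_shear ? 1.0 : M(3 * i, 3 * i);
      dx(3 * i) += shear * pos(i, 2) * muxx * dt;
    }
    if (drift && hydro == 2) {
      for (int i = 0; i < N; ++i)
        dx(3 * i + 2) += dmu_perp_dz(pos(i, 2)) * dt;
    }
    if (noise && dt > 0) {
      arma::mat L = chol_psd(M);
      NumericVector xi = rnorm(3 * N);
      arma::vec xiv(xi.begin(), 3 * N, false);
      dx += std::sqrt(2.0 * dt) * (L * xiv);
    }
    if (grafted) dx.subvec(0, 2).zeros();
    for (int i = 0; i < N; ++i) {
      pos(i, 0) += dx(3 * i);
      pos(i, 1) += dx(3 * i + 1);
      pos(i, 2) += dx(3 * i + 2);
    }
    if (wall) {
      int i0 = grafted ? 1 : 0;
      for (int i = i0; i < N; ++i)
        if (pos(i, 2) <= 0.0) pos(i, 2) = std::max(-pos(i, 2), 1e-9);
    }
    // instability guard (also during equilibration)
    for (int i = 0; i < N - 1; ++i) {
      double b = arma::norm(pos.row(i + 1) - pos.row(i));
      if (!std::isfinite(b) || b > 10.0 * contour)
        stop("numerical instability: bond length exceeds 10x contour "
             "length (reduce dt)");
    }
    // --- bookkeeping ---
    if (s >= n_equil && ib < n_blocks) {
      for (int i = 0; i < N - 1; ++i) {
        double b = arma::norm(pos.row(i + 1) - pos.row(i));
        bond_acc(i) += b;
      }
      ext_acc += pos(N - 1, 0) - pos(0, 0);
      arma::rowvec cm = arma::mean(pos, 0);
      double r2 = 0.0;
      for (int i = 0; i < N; ++i)
        r2 += arma::dot(pos.row(i) - cm, pos.row(i) - cm);
      rg_acc += std::sqrt(r2 / N);
      if (++in_block == block_size) {
        blocks.row(ib) = (bond_acc / block_size).t();
        ext(ib) = ext_acc / block_size;
        rg(ib) = rg_acc / block_size;
        bond_acc.zeros(); ext_acc = 0.0; rg_acc = 0.0;
        in_block = 0; ++ib;
      }
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["blocks"] = blocks, _["extension"] = ext,
                      _["rg"] = rg, _["final"] = pos);
}
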