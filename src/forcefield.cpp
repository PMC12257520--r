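// q-TIP4P/F energies and forces for ring-polymer bead configurations.
//
// Position layout throughout: a flat double array indexed as
//   idx = d + 3*(s + nsite*(m + nmol*k))
// with d = dimension (0..2), s = site (0=O, 1=X1, 2=X2), m = molecule,
// k = bead. Units: nm, kJ/mol, amu, ps, elementary charge.
//
// Standard discretized-path-integral factorization: bead slice k of one
// molecule interacts only with bead slice k of the others.

#include "core.h"
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double KE_COUL = 138.935458; // kJ mol^-1 nm e^-2

FFParams parse_ff(const List &ff) {
  FFParams p;
  p.Dr = as<double>(ff["D_r"]);
  p.ar = as<double>(ff["alpha_r"]);
  p.req = as<double>(ff["r_eq"]);
  p.ktheta = as<double>(ff["k_theta"]);
  p.thetaeq = as<double>(ff["theta_eq"]);
  p.eps = as<double>(ff["epsilon"]);
  p.sigma = as<double>(ff["sigma"]);
  p.qH = as<double>(ff["q_H"]);
  p.qM = as<double>(ff["q_M"]);
  p.gammaM = as<double>(ff["m_site_weight"]);
  p.rc = as<double>(ff["r_c"]);
  p.epsrf = as<double>(ff["eps_rf"]);
  p.shift_rf = as<bool>(ff["shift_rf"]);
  p.krf = (p.epsrf - 1.0) / ((2.0 * p.epsrf + 1.0) * p.rc * p.rc * p.rc);
  p.crf = p.shift_rf ? (1.0 / p.rc + p.krf * p.rc * p.rc) : 0.0;
  return p;
}

// round-half-away-from-zero without the libm call; exact for |x| < 2^62
inline double fast_round(double x) {
  return (double)(long long)(x + (x >= 0.0 ? 0.5 : -0.5));
}

inline void min_image(double *dx, double L) {
  if (L > 0.0) {
    for (int d = 0; d < 3; ++d) dx[d] -= L * fast_round(dx[d] / L);
  }
}

inline int pidx(int d, int s, int m, int k, int nsite, int nmol) {
  return d + 3 * (s + nsite * (m + nmol * k));
}

// Intramolecular terms of one bead slice: two quartic-Morse stretches
// per molecule plus one harmonic bend. Accumulates forces and the pair
// virial; returns the slice energy.
static double intra_slice(const double *x, double *f, int nmol, int nsite,
                          int k, double L, const FFParams &p, double *virial) {
  double E = 0.0;
  for (int m = 0; m < nmol; ++m) {
    const int iO = pidx(0, 0, m, k, nsite, nmol);
    double u[3], v[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = x[pidx(d, 1, m, k, nsite, nmol)] - x[iO + d];
      v[d] = x[pidx(d, 2, m, k, nsite, nmol)] - x[iO + d];
    }
    min_image(u, L);
    min_image(v, L);
    const double ru = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    const double rv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (!(ru > 0.0) || !(rv > 0.0)) stop("degenerate covalent bond length");
    // stretches
    const double bl[2] = {ru, rv};
    const double *bv[2] = {u, v};
    const int bs[2] = {1, 2};
    for (int b = 0; b < 2; ++b) {
      const double dlt = bl[b] - p.req;
      const double a = p.ar;
      E += p.Dr * (a * a * dlt * dlt - a * a * a * dlt * dlt * dlt +
                   (7.0 / 12.0) * a * a * a * a * dlt * dlt * dlt * dlt);
      const double dVdr =
          p.Dr * (2.0 * a * a * dlt - 3.0 * a * a * a * dlt * dlt +
                  (7.0 / 3.0) * a * a * a * a * dlt * dlt * dlt);
      for (int d = 0; d < 3; ++d) {
        const double fd = -dVdr * bv[b][d] / bl[b]; // force on X site
        f[pidx(d, bs[b], m, k, nsite, nmol)] += fd;
        f[iO + d] -= fd;
        *virial += fd * bv[b][d];
      }
    }
    // bend
    double cth = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (ru * rv);
    cth = std::max(-1.0, std::min(1.0, cth));
    const double th = std::acos(cth);
    const double sth = std::sqrt(std::max(1e-16, 1.0 - cth * cth));
    const double dVdth = p.ktheta * (th - p.thetaeq);
    double f1[3], f2[3];
    for (int d = 0; d < 3; ++d) {
      const double dthdu = (cth * u[d] / ru - v[d] / rv) / (ru * sth);
      const double dthdv = (cth * v[d] / rv - u[d] / ru) / (rv * sth);
      f1[d] = -dVdth * dthdu;
      f2[d] = -dVdth * dthdv;
    }
    E += 0.5 * p.ktheta * (th - p.thetaeq) * (th - p.thetaeq);
    for (int d = 0; d < 3; ++d) {
      f[pidx(d, 1, m, k, nsite, nmol)] += f1[d];
      f[pidx(d, 2, m, k, nsite, nmol)] += f2[d];
      f[iO + d] -= f1[d] + f2[d];
      *virial += f1[d] * u[d] + f2[d] * v[d];
    }
  }
  return E;
}

// Intermolecular terms of one bead slice: O-O Lennard-Jones plus
// site-site Coulomb with the reaction-field kernel, both cut at rc.
// Charges sit on X1, X2 and the massless M site; forces on M are
// redistributed to the massive sites by the placement weights.
static double inter_slice(const double *x, double *f, int nmol, int nsite,
                          int k, double L, const FFParams &p, double *virial) {
  double E = 0.0;
  const double rc2 = p.rc * p.rc;
  // M-site positions and per-molecule charged-site coordinates
  std::vector<double> site(nmol * 3 * 3); // [mol][cs(0=X1,1=X2,2=M)][d]
  std::vector<double> fM(nmol * 3, 0.0);
  for (int m = 0; m < nmol; ++m) {
    double O[3], u[3], v[3];
    for (int d = 0; d < 3; ++d) {
      O[d] = x[pidx(d, 0, m, k, nsite, nmol)];
      u[d] = x[pidx(d, 1, m, k, nsite, nmol)] - O[d];
      v[d] = x[pidx(d, 2, m, k, nsite, nmol)] - O[d];
    }
    min_image(u, L);
    min_image(v, L);
    const double w = 0.5 * (1.0 - p.gammaM);
    for (int d = 0; d < 3; ++d) {
      site[(m * 3 + 0) * 3 + d] = O[d] + u[d];
      site[(m * 3 + 1) * 3 + d] = O[d] + v[d];
      site[(m * 3 + 2) * 3 + d] = O[d] + w * (u[d] + v[d]);
    }
  }
  const double qs[3] = {p.qH, p.qH, p.qM};
  // molecule pairs whose O-O separation exceeds rc plus twice the largest
  // O->site offset cannot have any site pair inside the cutoff
  const double skip2 = (p.rc + 0.35) * (p.rc + 0.35);
  for (int mi = 0; mi < nmol; ++mi) {
    for (int mj = mi + 1; mj < nmol; ++mj) {
      // LJ O-O
      double dx[3];
      for (int d = 0; d < 3; ++d)
        dx[d] = x[pidx(d, 0, mi, k, nsite, nmol)] -
                x[pidx(d, 0, mj, k, nsite, nmol)];
      min_image(dx, L);
      const double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (r2 > skip2) continue;
      if (r2 < rc2) {
        const double sr2 = p.sigma * p.sigma / r2;
        const double sr6 = sr2 * sr2 * sr2;
        E += 4.0 * p.eps * (sr6 * sr6 - sr6);
        const double fmag = 24.0 * p.eps * (2.0 * sr6 * sr6 - sr6) / r2;
        for (int d = 0; d < 3; ++d) {
          const double fd = fmag * dx[d];
          f[pidx(d, 0, mi, k, nsite, nmol)] += fd;
          f[pidx(d, 0, mj, k, nsite, nmol)] -= fd;
          *virial += fd * dx[d];
        }
      }
      // Coulomb between charged sites
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) {
          double dq[3];
          for (int d = 0; d < 3; ++d)
            dq[d] = site[(mi * 3 + a) * 3 + d] - site[(mj * 3 + b) * 3 + d];
          min_image(dq, L);
          const double rq2 = dq[0] * dq[0] + dq[1] * dq[1] + dq[2] * dq[2];
          if (rq2 >= rc2) continue;
          const double r = std::sqrt(rq2);
          if (r < 1e-4) stop("overlapping charged sites (r < 1e-4 nm)");
          const double qq = KE_COUL * qs[a] * qs[b];
          E += qq * (1.0 / r + p.krf * rq2 - p.crf);
          const double fmag = qq * (1.0 / (rq2 * r) - 2.0 * p.krf);
          for (int d = 0; d < 3; ++d) {
            const double fd = fmag * dq[d];
            *virial += fd * dq[d];
            // accumulate on actual sites; M handled after the loop
            if (a < 2)
              f[pidx(d, a + 1, mi, k, nsite, nmol)] += fd;
            else
              fM[mi * 3 + d] += fd;
            if (b < 2)
              f[pidx(d, b + 1, mj, k, nsite, nmol)] -= fd;
            else
              fM[mj * 3 + d] -= fd;
          }
        }
      }
    }
  }
  // redistribute M-site forces: transpose of the placement weights
  const double w = 0.5 * (1.0 - p.gammaM);
  for (int m = 0; m < nmol; ++m) {
    for (int d = 0; d < 3; ++d) {
      const double fm = fM[m * 3 + d];
      f[pidx(d, 0, m, k, nsite, nmol)] += p.gammaM * fm;
      f[pidx(d, 1, m, k, nsite, nmol)] += w * fm;
      f[pidx(d, 2, m, k, nsite, nmol)] += w * fm;
    }
  }
  return E;
}

// Full potential over all bead slices. Returns per-bead energies, forces
// and per-bead virials. L <= 0 means an isolated (non-periodic) system.
List water_eval(const double *x, int nmol, int nsite, int nb, double L,
                const FFParams &p, bool intra, bool inter) {
  const int n = 3 * nsite * nmol * nb;
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(x[i])) stop("non-finite coordinates");
  NumericVector energy(nb), virial(nb);
  NumericVector forces(n);
  std::fill(forces.begin(), forces.end(), 0.0);
  for (int k = 0; k < nb; ++k) {
    double E = 0.0, W = 0.0;
    if (intra) E += intra_slice(x, REAL(forces), nmol, nsite, k, L, p, &W);
    if (inter && nmol > 1)
      E += inter_slice(x, REAL(forces), nmol, nsite, k, L, p, &W);
    energy[k] = E;
    virial[k] = W;
  }
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["virial"] = virial);
}

// [[Rcpp::export]]
List qtip4pf_eval_cpp(NumericVector pos, int nmol, int nb, double L, List ff,
                      bool intra = true, bool inter = true) {
  if ((int)pos.size() != 3 * 3 * nmol * nb)
    stop("position array has wrong length");
  FFParams p = parse_ff(ff);
  List out = water_eval(REAL(pos), nmol, 3, nb, L, p, intra, inter);
  NumericVector f = out["forces"];
  f.attr("dim") = IntegerVector::create(3, 3, nmol, nb);
  return out;
}

// M-site positions for every molecule and bead slice.
// [[Rcpp::export]]
NumericVector m_site_positions_cpp(NumericVector pos, int nmol, int nb,
                                   double L, double gammaM) {
  NumericVector out(3 * nmol * nb);
  const double *x = REAL(pos);
  const double w = 0.5 * (1.0 - gammaM);
  for (int k = 0; k < nb; ++k) {
    for (int m = 0; m < nmol; ++m) {
      double O[3], u[3], v[3];
      for (int d = 0; d < 3; ++d) {
        O[d] = x[pidx(d, 0, m, k, 3, nmol)];
        u[d] = x[pidx(d, 1, m, k, 3, nmol)] - O[d];
        v[d] = x[pidx(d, 2, m, k, 3, nmol)] - O[d];
      }
      min_image(u, L);
      min_image(v, L);
      for (int d = 0; d < 3; ++d)
        out[d + 3 * (m + nmol * k)] = O[d] + w * (u[d] + v[d]);
    }
  }
  out.attr("dim") = IntegerVector::create(3, nmol, nb);
  return out;
}
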