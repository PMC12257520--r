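// Ring-polymer propagator: PILE-thermostated normal-mode integrator
// (OBABO splitting with exact free-ring-polymer drift), optional Monte
// Carlo barostat, and centroid-virial quantum estimators.
//
// Supported potentials: "qtip4pf" (3 massive sites per molecule),
// "harmonic" (independent isotropic oscillators, one site per molecule)
// and "none" (free particles).

#include "core.h"
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.00831446261815324;  // kJ mol^-1 K^-1
static const double HBAR = 0.0635077985;       // kJ mol^-1 ps
static const double KJ_NM3_TO_MPA = 1.66054; // kJ mol^-1 nm^-3 -> MPa

enum PotKind { POT_WATER, POT_HARM, POT_NONE };

struct Eval {
  double U;       // bead-summed potential
  double W;       // bead-summed pair virial
  std::vector<double> f;
};

static void eval_potential(const std::vector<double> &x, int nmol, int nsite,
                           int nb, double L, PotKind pot, const FFParams &ffp,
                           bool intra, bool inter, double omega_h,
                           const std::vector<double> &mass, Eval &ev) {
  const int n = (int)x.size();
  ev.f.assign(n, 0.0);
  ev.U = 0.0;
  ev.W = 0.0;
  if (pot == POT_NONE) return;
  if (pot == POT_HARM) {
    for (int k = 0; k < nb; ++k)
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s) {
          const double msw = mass[s] * omega_h * omega_h;
          for (int d = 0; d < 3; ++d) {
            const int i = d + 3 * (s + nsite * (m + nmol * k));
            ev.U += 0.5 * msw * x[i] * x[i];
            ev.f[i] = -msw * x[i];
            ev.W += -msw * x[i] * x[i];
          }
        }
    return;
  }
  List r = water_eval(x.data(), nmol, nsite, nb, L, ffp, intra, inter);
  NumericVector e = r["energy"], f = r["forces"], w = r["virial"];
  for (int k = 0; k < nb; ++k) {
    ev.U += e[k];
    ev.W += w[k];
  }
  std::copy(f.begin(), f.end(), ev.f.begin());
}

// Orthonormal real normal-mode matrix C[k][j] of the nb-bead ring.
static std::vector<double> nm_matrix(int nb) {
  std::vector<double> C(nb * nb);
  const double s1 = std::sqrt(1.0 / nb), s2 = std::sqrt(2.0 / nb);
  for (int j = 0; j < nb; ++j) C[0 * nb + j] = s1;
  for (int k = 1; k <= nb / 2; ++k) {
    if (2 * k == nb) {
      for (int j = 0; j < nb; ++j)
        C[k * nb + j] = s1 * (j % 2 == 0 ? 1.0 : -1.0);
    } else {
      for (int j = 0; j < nb; ++j)
        C[k * nb + j] = s2 * std::cos(2.0 * M_PI * j * k / nb);
    }
  }
  for (int k = nb / 2 + 1; k < nb; ++k)
    for (int j = 0; j < nb; ++j)
      C[k * nb + j] = s2 * std::sin(2.0 * M_PI * j * k / nb);
  return C;
}

struct Engine {
  int nmol, nsite, nb, natom;
  double L, T, dt;
  std::vector<double> x, p, mass; // mass per site (amu)
  std::vector<double> C;          // nm transform
  std::vector<double> omegak;     // nm frequencies
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;
  std::uniform_real_distribution<double> unif;

  double beta() const { return 1.0 / (KB * T); }
  double omega_n() const { return nb / (beta() * HBAR); }

  int idx(int d, int s, int m, int k) const {
    return d + 3 * (s + nsite * (m + nmol * k));
  }

  void init_freqs() {
    omegak.assign(nb, 0.0);
    for (int k = 1; k < nb; ++k)
      omegak[k] = 2.0 * omega_n() * std::sin(M_PI * k / nb);
  }

  // Transform bead vector to normal modes and back. The flat layout is an
  // (3*nsite*nmol) x nb column-major matrix (bead index slowest), so both
  // directions are contiguous axpy sweeps.
  void to_nm(const std::vector<double> &v, std::vector<double> &vm) {
    const int A = 3 * nsite * nmol;
    std::fill(vm.begin(), vm.end(), 0.0);
    for (int k = 0; k < nb; ++k) {
      double *out = &vm[(size_t)A * k];
      for (int j = 0; j < nb; ++j) {
        const double c = C[k * nb + j];
        const double *in = &v[(size_t)A * j];
        for (int a = 0; a < A; ++a) out[a] += c * in[a];
      }
    }
  }
  void from_nm(const std::vector<double> &vm, std::vector<double> &v) {
    const int A = 3 * nsite * nmol;
    std::fill(v.begin(), v.end(), 0.0);
    for (int j = 0; j < nb; ++j) {
      double *out = &v[(size_t)A * j];
      for (int k = 0; k < nb; ++k) {
        const double c = C[k * nb + j];
        const double *in = &vm[(size_t)A * k];
        for (int a = 0; a < A; ++a) out[a] += c * in[a];
      }
    }
  }
};

// [[Rcpp::export]]
List pimd_run_cpp(NumericVector pos, NumericVector mom, NumericVector site_mass,
                  int nmol, int nsite, int nb, double L, List ff,
                  std::string potential, double omega_harm, double temperature,
                  double dt, int nsteps, double gamma0, bool pile_internal,
                  bool thermostat_on, std::string ensemble, double P_ext_MPa,
                  int baro_every, double baro_dlnV, int seed, int stride_est,
                  int stride_frame, int stride_vel, bool intra = true,
                  bool inter = true, double max_disp = 0.05) {
  Engine eg;
  eg.nmol = nmol;
  eg.nsite = nsite;
  eg.nb = nb;
  eg.natom = nmol * nsite;
  eg.L = L;
  eg.T = temperature;
  eg.dt = dt;
  eg.x.assign(pos.begin(), pos.end());
  eg.p.assign(mom.begin(), mom.end());
  eg.mass.assign(site_mass.begin(), site_mass.end());
  eg.C = nm_matrix(nb);
  eg.init_freqs();
  eg.rng.seed((uint64_t)seed);

  PotKind pot = POT_WATER;
  if (potential == "harmonic") pot = POT_HARM;
  else if (potential == "none") pot = POT_NONE;
  else if (potential != "qtip4pf") stop("unknown potential kind");

  FFParams ffp{};
  if (pot == POT_WATER) ffp = parse_ff(ff);
  const bool npt = (ensemble == "NPT");
  const double P_ext = P_ext_MPa / KJ_NM3_TO_MPA; // kJ/mol/nm^3

  const int n = (int)eg.x.size();
  if ((int)eg.p.size() != n) stop("momenta length mismatch");
  const double beta = eg.beta();
  const double kT = KB * eg.T;

  // thermostat OU coefficients per mode
  std::vector<double> c1(nb), c2(nb);
  for (int k = 0; k < nb; ++k) {
    double g = (k == 0) ? gamma0 : (pile_internal ? 2.0 * eg.omegak[k] : 0.0);
    c1[k] = std::exp(-0.5 * g * dt);
    c2[k] = std::sqrt(std::max(0.0, 1.0 - c1[k] * c1[k]));
  }

  Eval ev;
  eval_potential(eg.x, nmol, nsite, nb, eg.L, pot, ffp, intra, inter,
                 omega_harm, eg.mass, ev);

  std::vector<double> pm(n), xm(n);
  const int nest = (stride_est > 0) ? nsteps / stride_est : 0;
  const int nfr = (stride_frame > 0) ? nsteps / stride_frame : 0;
  const int nvl = (stride_vel > 0) ? nsteps / stride_vel : 0;
  NumericVector est_U(nest), est_Kcv(nest), est_Kpr(nest), est_P(nest),
      est_V(nest), est_Tc(nest), est_step(nest);
  NumericVector frames(nfr > 0 ? (R_xlen_t)n * nfr : 0);
  NumericVector vels(nvl > 0 ? (R_xlen_t)3 * eg.natom * nvl : 0);
  NumericVector dips(nvl > 0 ? (R_xlen_t)3 * nvl : 0);
  NumericVector boxes(nfr > 0 ? nfr : 0);
  int iest = 0, ifr = 0, ivl = 0;
  long baro_try = 0, baro_acc = 0;

  const double wM = (pot == POT_WATER) ? 0.5 * (1.0 - ffp.gammaM) : 0.0;

  for (int step = 1; step <= nsteps; ++step) {
    // O: half thermostat in normal-mode space
    if (thermostat_on) {
      eg.to_nm(eg.p, pm);
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s) {
          const double sig = std::sqrt(eg.mass[s] * nb * kT);
          for (int d = 0; d < 3; ++d)
            for (int k = 0; k < nb; ++k) {
              if (k == 0 && gamma0 <= 0.0) continue;
              const int i = eg.idx(d, s, m, k);
              pm[i] = c1[k] * pm[i] + sig * c2[k] * eg.gauss(eg.rng);
            }
        }
      eg.from_nm(pm, eg.p);
    }
    // B: half kick
    for (int i = 0; i < n; ++i) eg.p[i] += 0.5 * dt * ev.f[i];
    // A: exact free-ring-polymer drift in normal modes
    if (nb == 1) {
      double md = 0.0;
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s)
          for (int d = 0; d < 3; ++d) {
            const int i = eg.idx(d, s, m, 0);
            const double dx = dt * eg.p[i] / eg.mass[s];
            eg.x[i] += dx;
            md = std::max(md, std::fabs(dx));
          }
      if (md > max_disp) stop("instability: displacement %f nm in one step at step %d", md, step);
    } else {
      eg.to_nm(eg.p, pm);
      eg.to_nm(eg.x, xm);
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s) {
          const double ms = eg.mass[s];
          for (int d = 0; d < 3; ++d) {
            // centroid: free drift
            const int i0 = eg.idx(d, s, m, 0);
            const double dx0 = dt * pm[i0] / ms;
            if (std::fabs(dx0) > max_disp * std::sqrt((double)nb))
              stop("instability: centroid displacement too large at step %d", step);
            xm[i0] += dx0;
            for (int k = 1; k < nb; ++k) {
              const int i = eg.idx(d, s, m, k);
              const double w = eg.omegak[k];
              const double cw = std::cos(w * dt), sw = std::sin(w * dt);
              const double q = xm[i], pq = pm[i];
              xm[i] = q * cw + pq * sw / (ms * w);
              pm[i] = pq * cw - ms * w * q * sw;
            }
          }
        }
      eg.from_nm(pm, eg.p);
      eg.from_nm(xm, eg.x);
    }
    // forces at new positions
    eval_potential(eg.x, nmol, nsite, nb, eg.L, pot, ffp, intra, inter,
                   omega_harm, eg.mass, ev);
    if (!std::isfinite(ev.U))
      stop("instability: non-finite potential at step %d", step);
    // B: half kick
    for (int i = 0; i < n; ++i) eg.p[i] += 0.5 * dt * ev.f[i];
    // O: half thermostat
    if (thermostat_on) {
      eg.to_nm(eg.p, pm);
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s) {
          const double sig = std::sqrt(eg.mass[s] * nb * kT);
          for (int d = 0; d < 3; ++d)
            for (int k = 0; k < nb; ++k) {
              if (k == 0 && gamma0 <= 0.0) continue;
              const int i = eg.idx(d, s, m, k);
              pm[i] = c1[k] * pm[i] + sig * c2[k] * eg.gauss(eg.rng);
            }
        }
      eg.from_nm(pm, eg.p);
    }

    // Monte Carlo barostat: isotropic ln-V proposal with molecular
    // centroid scaling; Metropolis weight uses the bead-averaged
    // potential so detailed balance holds for the quantum system.
    if (npt && baro_every > 0 && step % baro_every == 0) {
      ++baro_try;
      const double V = eg.L * eg.L * eg.L;
      const double lnVp = std::log(V) + baro_dlnV * (2.0 * eg.unif(eg.rng) - 1.0);
      const double Vp = std::exp(lnVp);
      const double sc = std::cbrt(Vp / V);
      std::vector<double> xp(eg.x);
      for (int m = 0; m < nmol; ++m) {
        double cgm[3] = {0, 0, 0};
        double msum = 0.0;
        for (int s = 0; s < nsite; ++s) {
          msum += eg.mass[s] * nb;
          for (int k = 0; k < nb; ++k)
            for (int d = 0; d < 3; ++d)
              cgm[d] += eg.mass[s] * eg.x[eg.idx(d, s, m, k)];
        }
        for (int d = 0; d < 3; ++d) cgm[d] /= msum;
        for (int s = 0; s < nsite; ++s)
          for (int k = 0; k < nb; ++k)
            for (int d = 0; d < 3; ++d)
              xp[eg.idx(d, s, m, k)] += (sc - 1.0) * cgm[d];
      }
      const double Lp = std::cbrt(Vp);
      Eval evp;
      eval_potential(xp, nmol, nsite, nb, Lp, pot, ffp, intra, inter,
                     omega_harm, eg.mass, evp);
      const double dUbar = (evp.U - ev.U) / nb;
      const double darg = dUbar + P_ext * (Vp - V) - (nmol + 1) * kT * (lnVp - std::log(V));
      if (eg.unif(eg.rng) < std::exp(-darg / kT)) {
        eg.x.swap(xp);
        eg.L = Lp;
        ev = evp;
        ++baro_acc;
      }
    }

    // estimators
    if (stride_est > 0 && step % stride_est == 0 && iest < nest) {
      const double V = eg.L * eg.L * eg.L;
      const double Ubar = ev.U / nb;
      // spring energy and centroid-virial correction
      double Espr = 0.0, cvcorr = 0.0, Tc = 0.0;
      const double wn2 = eg.omega_n() * eg.omega_n();
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s) {
          const double ms = eg.mass[s];
          for (int d = 0; d < 3; ++d) {
            double xc = 0.0, pc = 0.0;
            for (int k = 0; k < nb; ++k) {
              xc += eg.x[eg.idx(d, s, m, k)];
              pc += eg.p[eg.idx(d, s, m, k)];
            }
            xc /= nb;
            pc /= nb;
            Tc += pc * pc / ms;
            for (int k = 0; k < nb; ++k) {
              const int i = eg.idx(d, s, m, k);
              const int kn = (k + 1) % nb;
              const double dxk = eg.x[eg.idx(d, s, m, kn)] - eg.x[i];
              Espr += 0.5 * ms * wn2 * dxk * dxk;
              cvcorr += (eg.x[i] - xc) * ev.f[i];
            }
          }
        }
      // primitive estimator: spring term carries a 1/nb with the
      // omega_n convention used here (beta_n sampling)
      double Kcv = 1.5 * eg.natom * kT - cvcorr / (2.0 * nb);
      double Kpr = 1.5 * eg.natom * nb * kT - Espr / nb;
      if (nb == 1) {
        // classical collapse: both estimators are the kinetic energy
        double ke = 0.0;
        for (int m = 0; m < nmol; ++m)
          for (int s = 0; s < nsite; ++s)
            for (int d = 0; d < 3; ++d) {
              const double pv = eg.p[eg.idx(d, s, m, 0)];
              ke += pv * pv / (2.0 * eg.mass[s]);
            }
        Kcv = Kpr = ke;
      }
      const double Wbar = ev.W / nb;
      est_step[iest] = step;
      est_U[iest] = Ubar;
      est_Kcv[iest] = Kcv;
      est_Kpr[iest] = Kpr;
      est_P[iest] = (2.0 * Kcv + Wbar) / (3.0 * V) * KJ_NM3_TO_MPA;
      est_V[iest] = V;
      est_Tc[iest] = Tc / (3.0 * eg.natom * KB);
      ++iest;
    }
    if (stride_frame > 0 && step % stride_frame == 0 && ifr < nfr) {
      std::copy(eg.x.begin(), eg.x.end(), frames.begin() + (R_xlen_t)n * ifr);
      boxes[ifr] = eg.L;
      ++ifr;
    }
    if (stride_vel > 0 && step % stride_vel == 0 && ivl < nvl) {
      // centroid velocities per atom and total dipole
      double mu[3] = {0, 0, 0};
      for (int m = 0; m < nmol; ++m)
        for (int s = 0; s < nsite; ++s) {
          double vc[3];
          for (int d = 0; d < 3; ++d) {
            double pc = 0.0;
            for (int k = 0; k < nb; ++k) pc += eg.p[eg.idx(d, s, m, k)];
            vc[d] = pc / (nb * eg.mass[s]);
          }
          const int ia = s + nsite * m;
          for (int d = 0; d < 3; ++d)
            vels[(R_xlen_t)3 * eg.natom * ivl + 3 * ia + d] = vc[d];
        }
      if (pot == POT_WATER) {
        for (int m = 0; m < nmol; ++m) {
          double O[3], X1[3], X2[3];
          for (int d = 0; d < 3; ++d) {
            O[d] = X1[d] = X2[d] = 0.0;
            for (int k = 0; k < nb; ++k) {
              O[d] += eg.x[eg.idx(d, 0, m, k)];
              X1[d] += eg.x[eg.idx(d, 1, m, k)];
              X2[d] += eg.x[eg.idx(d, 2, m, k)];
            }
            O[d] /= nb;
            X1[d] /= nb;
            X2[d] /= nb;
          }
          for (int d = 0; d < 3; ++d) {
            const double Md = O[d] + wM * ((X1[d] - O[d]) + (X2[d] - O[d]));
            mu[d] += ffp.qH * (X1[d] + X2[d]) + ffp.qM * Md;
          }
        }
      }
      for (int d = 0; d < 3; ++d) dips[(R_xlen_t)3 * ivl + d] = mu[d];
      ++ivl;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector xout(eg.x.begin(), eg.x.end());
  NumericVector pout(eg.p.begin(), eg.p.end());
  xout.attr("dim") = IntegerVector::create(3, nsite, nmol, nb);
  pout.attr("dim") = IntegerVector::create(3, nsite, nmol, nb);
  if (nfr > 0) frames.attr("dim") = IntegerVector::create(3, nsite, nmol, nb, nfr);
  if (nvl > 0) {
    vels.attr("dim") = IntegerVector::create(3, nsite * nmol, nvl);
    dips.attr("dim") = IntegerVector::create(3, nvl);
  }
  return List::create(
      _["positions"] = xout, _["momenta"] = pout, _["L"] = eg.L,
      _["estimators"] = DataFrame::create(
          _["step"] = est_step, _["U"] = est_U, _["K_cv"] = est_Kcv,
          _["K_prim"] = est_Kpr, _["P"] = est_P, _["V"] = est_V,
          _["T_centroid"] = est_Tc),
      _["frames"] = frames, _["frame_L"] = boxes, _["velocities"] = vels,
      _["dipoles"] = dips,
      _["barostat"] = NumericVector::create(_["attempts"] = (double)baro_try,
                                            _["accepted"] = (double)baro_acc));
}

// [[Rcpp::export]]
NumericMatrix nm_matrix_cpp(int nb) {
  std::vector<double> C = nm_matrix(nb);
  NumericMatrix out(nb, nb);
  for (int k = 0; k < nb; ++k)
    for (int j = 0; j < nb; ++j) out(k, j) = C[k * nb + j];
  return out;
}

// [[Rcpp::export]]
NumericVector nm_frequencies_cpp(int nb, double temperature) {
  const double wn = nb * KB * temperature / HBAR;
  NumericVector w(nb);
  for (int k = 0; k < nb; ++k) w[k] = 2.0 * wn * std::sin(M_PI * k / nb);
  return w;
}
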