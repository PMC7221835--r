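// Coarse-grained force field and Langevin (BAOAB) propagator.
//
// Units: length A, time ps, mass amu, energy kcal/mol, charge e.
// Accelerations use 1 kcal/mol = 418.4 amu A^2 ps^-2 (exact, since
// 1 amu A^2 ps^-2 = 10 J/mol).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double KCAL_TO_AKMA = 418.4;
static const double KB_KCAL = 0.001987204259;   // kcal/mol/K
static const double COULOMB_K = 332.0636;       // kcal*A/(mol*e^2)

// Deterministic, compiler-independent normal deviates: mt19937_64 + Box-Muller.
struct GaussRNG {
  std::mt19937_64 gen;
  bool have_spare;
  double spare;
  explicit GaussRNG(uint64_t seed) : gen(seed), have_spare(false), spare(0.0) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

struct FFParams {
  int n;
  const double *q, *eps, *sig, *mass;
  const int *restrained;           // 0/1
  const double *refpos;            // n x 3 column-major
  double k_restraint;              // 0.5*k*|dx|^2
  int nbonds;
  std::vector<int> b1, b2;         // 0-based
  const double *bond_k, *bond_r0;  // 0.5*k*(r-r0)^2
  double rc2, rs2, sw_denom;       // cutoff^2, switch_on^2, (rc2-rs2)^3
  bool use_cutoff;
  bool all_pairs;                  // include scaffold-scaffold nonbonded
  std::unordered_set<int64_t> excl;
  std::vector<int> pi, pj;         // precomputed active nonbonded pairs

  bool excluded(int i, int j) const {
    return excl.count(static_cast<int64_t>(i) * n + j) > 0;
  }
};

static inline double cube(double x) { return x * x * x; }

// Accumulate forces (kcal/mol/A) and energy components into e[4]:
// {bond, lj, coulomb, restraint}. Returns false on non-finite input.
static bool eval_forces(const FFParams &p, const double *pos, double *f,
                        double *e, int *bad_particle) {
  const int n = p.n;
  for (int i = 0; i < 3 * n; ++i) {
    if (!std::isfinite(pos[i])) { *bad_particle = (i % n) + 1; return false; }
  }
  std::fill(f, f + 3 * n, 0.0);
  std::fill(e, e + 4, 0.0);

  // nonbonded over the precomputed active pair list
  const size_t npair = p.pi.size();
  for (size_t k = 0; k < npair; ++k) {
    const int i = p.pi[k], j = p.pj[k];
    {
      const double dx = pos[i] - pos[j], dy = pos[i + n] - pos[j + n],
                   dz = pos[i + 2 * n] - pos[j + 2 * n];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (p.use_cutoff && r2 >= p.rc2) continue;

      double V = 0.0, dVdr2 = 0.0;       // raw potential and dV/dr2
      const double eij = std::sqrt(p.eps[i] * p.eps[j]);
      if (eij > 0.0) {
        const double sij = 0.5 * (p.sig[i] + p.sig[j]);
        const double sr6 = cube(sij * sij / r2);
        V += 4.0 * eij * (sr6 * sr6 - sr6);
        dVdr2 += -12.0 * eij * sr6 * (2.0 * sr6 - 1.0) / r2;
      }
      double Vc = 0.0;
      const double qq = p.q[i] * p.q[j];
      if (qq != 0.0) {
        const double r = std::sqrt(r2);
        Vc = COULOMB_K * qq / r;
        dVdr2 += -0.5 * Vc / r2;
        V += Vc;
      }
      if (V == 0.0 && dVdr2 == 0.0) continue;

      double S = 1.0, dSdr2 = 0.0;
      if (p.use_cutoff && r2 > p.rs2) {
        const double a = p.rc2 - r2;
        const double b = p.rc2 + 2.0 * r2 - 3.0 * p.rs2;
        S = a * a * b / p.sw_denom;
        dSdr2 = (-2.0 * a * b + 2.0 * a * a) / p.sw_denom;
      }
      const double dUdr2 = dVdr2 * S + V * dSdr2;
      const double e_lj_pair = (V - Vc) * S;
      const double e_c_pair = Vc * S;
      e[1] += e_lj_pair;
      e[2] += e_c_pair;
      const double g = -2.0 * dUdr2;
      f[i] += g * dx;          f[j] -= g * dx;
      f[i + n] += g * dy;      f[j + n] -= g * dy;
      f[i + 2 * n] += g * dz;  f[j + 2 * n] -= g * dz;
    }
  }

  // bonds: 0.5*k*(r-r0)^2
  for (int k = 0; k < p.nbonds; ++k) {
    const int i = p.b1[k], j = p.b2[k];
    const double dx = pos[i] - pos[j];
    const double dy = pos[i + n] - pos[j + n];
    const double dz = pos[i + 2 * n] - pos[j + 2 * n];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - p.bond_r0[k];
    e[0] += 0.5 * p.bond_k[k] * dr * dr;
    if (r > 0.0) {
      const double g = -p.bond_k[k] * dr / r;
      f[i] += g * dx;          f[j] -= g * dx;
      f[i + n] += g * dy;      f[j + n] -= g * dy;
      f[i + 2 * n] += g * dz;  f[j + 2 * n] -= g * dz;
    }
  }

  // positional restraints on scaffold: 0.5*k*|x-ref|^2
  if (p.k_restraint > 0.0) {
    for (int i = 0; i < n; ++i) {
      if (!p.restrained[i]) continue;
      for (int d = 0; d < 3; ++d) {
        const double dx = pos[i + d * n] - p.refpos[i + d * n];
        e[3] += 0.5 * p.k_restraint * dx * dx;
        f[i + d * n] += -p.k_restraint * dx;
      }
    }
  }
  return true;
}

static FFParams make_params(const NumericMatrix &pos, const NumericVector &q,
                            const NumericVector &eps, const NumericVector &sig,
                            const NumericVector &mass,
                            const IntegerVector &restrained,
                            const NumericMatrix &refpos, double k_restraint,
                            const IntegerMatrix &bonds,
                            const NumericVector &bond_k,
                            const NumericVector &bond_r0, double cutoff,
                            double switch_on, bool use_cutoff, bool all_pairs) {
  FFParams p;
  p.n = pos.nrow();
  p.q = q.begin(); p.eps = eps.begin(); p.sig = sig.begin();
  p.mass = mass.begin();
  p.restrained = restrained.begin();
  p.refpos = refpos.begin();
  p.k_restraint = k_restraint;
  p.nbonds = bonds.nrow();
  p.bond_k = bond_k.begin(); p.bond_r0 = bond_r0.begin();
  p.rc2 = cutoff * cutoff;
  p.rs2 = switch_on * switch_on;
  p.sw_denom = std::pow(p.rc2 - p.rs2, 3.0);
  p.use_cutoff = use_cutoff;
  p.all_pairs = all_pairs;
  p.b1.resize(p.nbonds); p.b2.resize(p.nbonds);
  for (int k = 0; k < p.nbonds; ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;  // 1-based from R
    p.b1[k] = i; p.b2[k] = j;
    p.excl.insert(static_cast<int64_t>(std::min(i, j)) * p.n + std::max(i, j));
  }
  // active nonbonded pairs: bonded pairs excluded; scaffold-scaffold pairs
  // excluded unless all_pairs
  for (int i = 0; i < p.n; ++i) {
    for (int j = i + 1; j < p.n; ++j) {
      if (!p.all_pairs && p.restrained[i] && p.restrained[j]) continue;
      if (p.excluded(i, j)) continue;
      p.pi.push_back(i);
      p.pj.push_back(j);
    }
  }
  return p;
}

// [[Rcpp::export]]
List ff_eval_cpp(NumericMatrix pos, NumericVector q, NumericVector eps,
                 NumericVector sig, NumericVector mass,
                 IntegerVector restrained, NumericMatrix refpos,
                 double k_restraint, IntegerMatrix bonds, NumericVector bond_k,
                 NumericVector bond_r0, double cutoff, double switch_on,
                 bool use_cutoff, bool all_pairs) {
  FFParams p = make_params(pos, q, eps, sig, mass, restrained, refpos,
                           k_restraint, bonds, bond_k, bond_r0, cutoff,
                           switch_on, use_cutoff, all_pairs);
  const int n = p.n;
  NumericMatrix f(n, 3);
  double e[4];
  int bad = 0;
  if (!eval_forces(p, pos.begin(), f.begin(), e, &bad))
    stop("non-finite coordinate for particle %d", bad);
  return List::create(_["forces"] = f,
                      _["e_bond"] = e[0], _["e_lj"] = e[1],
                      _["e_coulomb"] = e[2], _["e_restraint"] = e[3]);
}

// Cross-group nonbonded interaction energy (no bonded/restraint terms).
// [[Rcpp::export]]
NumericVector pair_interaction_cpp(NumericMatrix pos, NumericVector q,
                                   NumericVector eps, NumericVector sig,
                                   IntegerVector ia, IntegerVector ib,
                                   double cutoff, double switch_on,
                                   bool use_cutoff) {
  const int n = pos.nrow();
  const double rc2 = cutoff * cutoff, rs2 = switch_on * switch_on;
  const double denom = std::pow(rc2 - rs2, 3.0);
  double e_elec = 0.0, e_vdw = 0.0;
  for (int a = 0; a < ia.size(); ++a) {
    const int i = ia[a] - 1;
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    for (int b = 0; b < ib.size(); ++b) {
      const int j = ib[b] - 1;
      const double dx = xi - pos(j, 0), dy = yi - pos(j, 1), dz = zi - pos(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (use_cutoff && r2 >= rc2) continue;
      double S = 1.0;
      if (use_cutoff && r2 > rs2) {
        const double aa = rc2 - r2;
        S = aa * aa * (rc2 + 2.0 * r2 - 3.0 * rs2) / denom;
      }
      const double eij = std::sqrt(eps[i] * eps[j]);
      if (eij > 0.0) {
        const double sij = 0.5 * (sig[i] + sig[j]);
        const double sr6 = cube(sij * sij / r2);
        e_vdw += 4.0 * eij * (sr6 * sr6 - sr6) * S;
      }
      const double qq = q[i] * q[j];
      if (qq != 0.0) e_elec += COULOMB_K * qq / std::sqrt(r2) * S;
    }
  }
  return NumericVector::create(e_elec, e_vdw);
}

// BAOAB Langevin propagator with optional moving-anchor harmonic spring
// (constant-velocity SMD) and optional ligand-site distance monitoring.
// [[Rcpp::export]]
List langevin_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector q,
                  NumericVector eps, NumericVector sig, NumericVector mass,
                  IntegerVector restrained, NumericMatrix refpos,
                  double k_restraint, IntegerMatrix bonds, NumericVector bond_k,
                  NumericVector bond_r0, double cutoff, double switch_on,
                  bool use_cutoff, bool all_pairs, int n_steps, double dt,
                  double temperature, double friction, double seed,
                  int record_every, int traj_every, bool pull,
                  IntegerVector pull_idx, double k_pull, NumericVector anchor0,
                  NumericVector pull_dir, double v_pull, bool monitor,
                  NumericVector site, IntegerVector lig_idx,
                  double arrival_radius, int monitor_every,
                  bool stop_on_arrival, double blowup_threshold) {
  FFParams p = make_params(pos0, q, eps, sig, mass, restrained, refpos,
                           k_restraint, bonds, bond_k, bond_r0, cutoff,
                           switch_on, use_cutoff, all_pairs);
  const int n = p.n;
  std::vector<double> x(pos0.begin(), pos0.end());
  std::vector<double> v(vel0.begin(), vel0.end());
  std::vector<double> f(3 * n);
  double e[4];
  GaussRNG rng(static_cast<uint64_t>(seed));

  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double kT = KB_KCAL * std::max(temperature, 0.0);
  std::vector<double> c2(n, 0.0), half_dt_over_m(n);
  for (int i = 0; i < n; ++i) {
    half_dt_over_m[i] = 0.5 * dt * KCAL_TO_AKMA / mass[i];
    if (kT > 0.0 && friction > 0.0)
      c2[i] = std::sqrt((1.0 - c1 * c1) * kT * KCAL_TO_AKMA / mass[i]);
  }
  const bool do_O = (friction > 0.0);

  // pulled-group mass weights
  std::vector<int> pidx(pull_idx.size());
  double pull_mass = 0.0;
  for (int a = 0; a < pull_idx.size(); ++a) {
    pidx[a] = pull_idx[a] - 1;
    pull_mass += mass[pidx[a]];
  }
  std::vector<int> lidx(lig_idx.size());
  double lig_mass = 0.0;
  for (int a = 0; a < lig_idx.size(); ++a) {
    lidx[a] = lig_idx[a] - 1;
    lig_mass += mass[lidx[a]];
  }

  const int n_rec = (record_every > 0) ? n_steps / record_every + 1 : 0;
  const int n_frm = (traj_every > 0) ? n_steps / traj_every + 1 : 0;
  NumericMatrix rec(n_rec > 0 ? n_rec : 1, 10);
  NumericMatrix traj(n_frm > 0 ? n_frm : 1, 3 * n);
  int rec_count = 0, frm_count = 0;

  auto group_com = [&](const std::vector<int> &idx, double m_tot, double *out) {
    out[0] = out[1] = out[2] = 0.0;
    for (size_t a = 0; a < idx.size(); ++a) {
      const int i = idx[a];
      out[0] += mass[i] * x[i];
      out[1] += mass[i] * x[i + n];
      out[2] += mass[i] * x[i + 2 * n];
    }
    out[0] /= m_tot; out[1] /= m_tot; out[2] /= m_tot;
  };

  // add spring force at time t, return spring force vector (kcal/mol/A)
  auto add_spring = [&](double t, double *fs) {
    double com[3];
    group_com(pidx, pull_mass, com);
    double anchor[3];
    for (int d = 0; d < 3; ++d) anchor[d] = anchor0[d] + v_pull * t * pull_dir[d];
    for (int d = 0; d < 3; ++d) fs[d] = k_pull * (anchor[d] - com[d]);
    for (size_t a = 0; a < pidx.size(); ++a) {
      const int i = pidx[a];
      const double w = mass[i] / pull_mass;
      f[i] += w * fs[0];
      f[i + n] += w * fs[1];
      f[i + 2 * n] += w * fs[2];
    }
  };

  auto record_row = [&](int step) {
    const double t = step * dt;
    double com[3], fs[3], anchor[3];
    if (pull) {
      group_com(pidx, pull_mass, com);
      for (int d = 0; d < 3; ++d) {
        anchor[d] = anchor0[d] + v_pull * t * pull_dir[d];
        fs[d] = k_pull * (anchor[d] - com[d]);
      }
    } else {
      com[0] = com[1] = com[2] = 0.0;
      anchor[0] = anchor[1] = anchor[2] = 0.0;
      fs[0] = fs[1] = fs[2] = 0.0;
      if (!lidx.empty()) group_com(lidx, lig_mass, com);
    }
    rec(rec_count, 0) = t;
    for (int d = 0; d < 3; ++d) {
      rec(rec_count, 1 + d) = anchor[d];
      rec(rec_count, 4 + d) = com[d];
      rec(rec_count, 7 + d) = fs[d];
    }
    ++rec_count;
  };
  auto record_frame = [&]() {
    for (int i = 0; i < 3 * n; ++i) traj(frm_count, i) = x[i];
    ++frm_count;
  };

  int bad = 0;
  bool blowup = false, arrived = false;
  if (!eval_forces(p, x.data(), f.data(), e, &bad))
    stop("non-finite coordinate for particle %d", bad);
  double fs[3];
  if (pull) add_spring(0.0, fs);
  if (record_every > 0) record_row(0);
  if (traj_every > 0) record_frame();
  if (monitor && !lidx.empty()) {
    double com[3];
    group_com(lidx, lig_mass, com);
    const double d0 = std::sqrt(std::pow(com[0] - site[0], 2) +
                                std::pow(com[1] - site[1], 2) +
                                std::pow(com[2] - site[2], 2));
    if (d0 <= arrival_radius) arrived = true;
  }

  int steps_done = 0;
  for (int step = 1; step <= n_steps && !(arrived && stop_on_arrival); ++step) {
    for (int i = 0; i < n; ++i) {
      const double h = half_dt_over_m[i];
      v[i] += h * f[i];
      v[i + n] += h * f[i + n];
      v[i + 2 * n] += h * f[i + 2 * n];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (do_O) {
      for (int i = 0; i < n; ++i) {
        v[i] = c1 * v[i] + c2[i] * rng.norm();
        v[i + n] = c1 * v[i + n] + c2[i] * rng.norm();
        v[i + 2 * n] = c1 * v[i + 2 * n] + c2[i] * rng.norm();
      }
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];

    if (!eval_forces(p, x.data(), f.data(), e, &bad)) { blowup = true; break; }
    if (pull) add_spring(step * dt, fs);
    const double e_tot = e[0] + e[1] + e[2] + e[3];
    if (!std::isfinite(e_tot) || e_tot > blowup_threshold) { blowup = true; break; }

    for (int i = 0; i < n; ++i) {
      const double h = half_dt_over_m[i];
      v[i] += h * f[i];
      v[i + n] += h * f[i + n];
      v[i + 2 * n] += h * f[i + 2 * n];
    }
    steps_done = step;
    if (record_every > 0 && step % record_every == 0) record_row(step);
    if (traj_every > 0 && step % traj_every == 0) record_frame();
    if (monitor && monitor_every > 0 && step % monitor_every == 0) {
      double com[3];
      group_com(lidx, lig_mass, com);
      const double d = std::sqrt(std::pow(com[0] - site[0], 2) +
                                 std::pow(com[1] - site[1], 2) +
                                 std::pow(com[2] - site[2], 2));
      if (d <= arrival_radius) arrived = true;
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  std::copy(x.begin(), x.end(), pos_out.begin());
  std::copy(v.begin(), v.end(), vel_out.begin());
  return List::create(
      _["positions"] = pos_out, _["velocities"] = vel_out,
      _["steps_done"] = steps_done, _["blowup"] = blowup,
      _["arrived"] = arrived, _["record"] = rec, _["n_record"] = rec_count,
      _["trajectory"] = traj, _["n_frames"] = frm_count,
      _["e_bond"] = e[0], _["e_lj"] = e[1], _["e_coulomb"] = e[2],
      _["e_restraint"] = e[3]);
}
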