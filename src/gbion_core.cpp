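// Compute core: pairwise-descreening Born radii, pair-class generalized Born
// energetics with analytic forces, BAOAB Langevin dynamics and Metropolis MC.
//
// Units: length A, charge e, energy kcal/mol, mass amu, time ps.
// Class codes: 0 = solute, 1 = cation, 2 = anion.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const double KE   = 332.0636;   // kcal*A/(mol*e^2)
static const double KBOL = 0.0019872;  // kcal/(mol*K)
static const double AKMA = 418.4;      // (amu*A^2/ps^2) per kcal/mol

// ---------------------------------------------------------------------------
// Hawkins-Cramer-Truhlar pairwise descreening integral
//
// I(d) = (1/4pi) * Integral over { x in sphere(radius sj at distance d),
//                                  |x| >= rho_i } of |x|^-4 dV
// No scaling factors, no neck corrections.  Exact for a single descreening
// sphere; summed pairwise over neighbours (union overlaps are double counted,
// which the quadrature-oracle tests bound).

// shell part between radii L..U where the descreener subtends a partial cap
static inline double hct_partial(double L, double U, double d, double sj) {
  double A = 0.5 * (1.0 / L - 1.0 / U);
  double B = 0.125 * (d - sj * sj / d) * (1.0 / (U * U) - 1.0 / (L * L));
  double C = 0.25 / d * std::log(L / U);
  return A + B + C;
}

static double hct_I(double d, double rho_i, double sj) {
  if (d + sj <= rho_i) return 0.0;          // descreener buried in own radius
  double U = d + sj;
  double L = std::max(rho_i, std::fabs(d - sj));
  double I = hct_partial(L, U, d, sj);
  if (d < sj && sj - d > rho_i)             // atom i inside descreener j
    I += 1.0 / rho_i - 1.0 / (sj - d);
  return I;
}

// dI/dd; continuous across all branch boundaries (verified analytically and
// by finite differences in the test suite)
static double hct_dI(double d, double rho_i, double sj) {
  if (d + sj <= rho_i) return 0.0;
  double U = d + sj, Up = 1.0;
  double L, Lp;
  double adiff = std::fabs(d - sj);
  if (rho_i >= adiff) { L = rho_i; Lp = 0.0; }
  else                { L = adiff; Lp = (d > sj) ? 1.0 : -1.0; }
  double dA = 0.5 * (-Lp / (L * L) + Up / (U * U));
  double dB = 0.125 * (1.0 + sj * sj / (d * d)) * (1.0 / (U * U) - 1.0 / (L * L))
            + 0.125 * (d - sj * sj / d) * (-2.0 * Up / (U * U * U) + 2.0 * Lp / (L * L * L));
  double dC = -0.25 / (d * d) * std::log(L / U) + 0.25 / d * (Lp / L - Up / U);
  double dI = dA + dB + dC;
  if (d < sj && sj - d > rho_i)
    dI += -1.0 / ((sj - d) * (sj - d));
  return dI;
}

// [[Rcpp::export]]
double cpp_hct_I(double d, double rho_i, double sj) { return hct_I(d, rho_i, sj); }

// [[Rcpp::export]]
double cpp_hct_dI(double d, double rho_i, double sj) { return hct_dI(d, rho_i, sj); }

// ---------------------------------------------------------------------------
// Effective Born radii: R_i = 1 / (1/rho_i - sum_j I(d_ij; rho_i, rho_j))

static void born_radii(const std::vector<double>& pos, int n,
                       const double* rho,
                       const std::vector<char>& usecache,
                       const double* cachedR,
                       std::vector<double>& R) {
  for (int i = 0; i < n; ++i) {
    if (usecache[i]) { R[i] = cachedR[i]; continue; }
    double psi = 1.0 / rho[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pos[3 * i] - pos[3 * j];
      double dy = pos[3 * i + 1] - pos[3 * j + 1];
      double dz = pos[3 * i + 2] - pos[3 * j + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 1e-12)
        stop("coincident particles %d and %d (d = 0)", i + 1, j + 1);
      psi -= hct_I(std::sqrt(d2), rho[i], rho[j]);
    }
    if (psi < 1e-8) psi = 1e-8;  // guard against over-descreening blowup
    R[i] = 1.0 / psi;
  }
}

// [[Rcpp::export]]
NumericVector cpp_effective_radii(NumericMatrix pos, NumericVector rho) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  std::vector<char> uc(n, 0);
  std::vector<double> R(n);
  born_radii(p, n, REAL(rho), uc, nullptr, R);
  return wrap(R);
}

// ---------------------------------------------------------------------------
// Energy + forces

struct Restraints {
  std::vector<int> fb_idx;      // flat-bottom restrained particles
  int anchor_mode = 0;          // 0 = point, 1 = COM of group
  double anchor_pt[3] = {0, 0, 0};
  std::vector<int> agrp;
  double r3 = 0.0, kfb = 0.0;
  std::vector<int> pr_idx;      // positionally restrained particles
  std::vector<double> pr_ref;   // 3 * pr_idx.size()
  double kpr = 0.0;
};

struct EFResult {
  double ecoul = 0, egb = 0, eself = 0, elj = 0, erestr = 0, total = 0;
  std::vector<double> radii;
  std::vector<double> forces;      // 3n when requested
  double elec_class[3][3] = {{0}}; // coulomb + gb cross, by unordered class pair
};

static void compute_ef(const std::vector<double>& pos, int n,
                       const double* q, const double* rho,
                       const double* sig, const double* epslj,
                       const int* cls,
                       const double* G, const double* EI, double epsout,
                       const int* fixedf, bool skip_fixed,
                       const std::vector<char>& usecache, const double* cachedR,
                       bool need_radii,
                       const Restraints& rs,
                       const double* mass,
                       bool want_forces,
                       EFResult& out) {
  out.ecoul = out.egb = out.eself = out.elj = out.erestr = 0.0;
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) out.elec_class[a][b] = 0.0;
  out.radii.assign(n, 0.0);
  if (want_forces) out.forces.assign(3 * n, 0.0);

  if (need_radii) {
    born_radii(pos, n, rho, usecache, cachedR, out.radii);
  } else {
    for (int i = 0; i < n; ++i) out.radii[i] = rho[i];
  }
  const std::vector<double>& R = out.radii;

  std::vector<double> B;              // dE/dR_i accumulators
  if (need_radii) B.assign(n, 0.0);

  // pair loop: Coulomb, GB cross term, Lennard-Jones
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (skip_fixed && fixedf[i] && fixedf[j]) continue;
      double dx = pos[3 * i] - pos[3 * j];
      double dy = pos[3 * i + 1] - pos[3 * j + 1];
      double dz = pos[3 * i + 2] - pos[3 * j + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 1e-12)
        stop("coincident particles %d and %d (d = 0)", i + 1, j + 1);
      double d = std::sqrt(d2);
      int a = cls[i], b = cls[j];
      double g  = G[a + 3 * b];
      double ei = EI[a + 3 * b];
      double qq = q[i] * q[j];

      double coul = KE * qq / (ei * d);
      out.ecoul += coul;
      double dEdd = -KE * qq / (ei * d2);
      double egb_ij = 0.0;

      double pref = KE * (1.0 / ei - 1.0 / epsout) * qq;
      if (pref != 0.0) {
        double f, dfdd, dfdRi = 0.0, dfdRj = 0.0;
        if (g > 0.0) {
          double P = R[i] * R[j];
          double e = std::exp(-d2 / (g * P));
          f = std::sqrt(d2 + P * e);
          dfdd = d * (1.0 - e / g) / f;
          dfdRi = e * (R[j] + d2 / (g * R[i])) / (2.0 * f);
          dfdRj = e * (R[i] + d2 / (g * R[j])) / (2.0 * f);
        } else {
          f = d; dfdd = 1.0;
        }
        egb_ij = -pref / f;
        out.egb += egb_ij;
        dEdd += pref * dfdd / (f * f);
        if (need_radii) {
          B[i] += pref * dfdRi / (f * f);
          B[j] += pref * dfdRj / (f * f);
        }
      }
      out.elec_class[std::min(a, b)][std::max(a, b)] += coul + egb_ij;

      double eij = std::sqrt(epslj[i] * epslj[j]);
      if (eij > 0.0) {
        double sij = 0.5 * (sig[i] + sig[j]);
        double sr2 = sij * sij / d2;
        double s6 = sr2 * sr2 * sr2;
        double s12 = s6 * s6;
        out.elj += 4.0 * eij * (s12 - s6);
        dEdd += 4.0 * eij * (-12.0 * s12 + 6.0 * s6) / d;
      }

      if (want_forces) {
        double fx = -dEdd * dx / d, fy = -dEdd * dy / d, fz = -dEdd * dz / d;
        out.forces[3 * i] += fx;  out.forces[3 * i + 1] += fy;  out.forces[3 * i + 2] += fz;
        out.forces[3 * j] -= fx;  out.forces[3 * j + 1] -= fy;  out.forces[3 * j + 2] -= fz;
      }
    }
  }

  // Born self-energies (diagonal class parameters)
  if (need_radii) {
    for (int i = 0; i < n; ++i) {
      if (skip_fixed && fixedf[i]) continue;
      int a = cls[i];
      double eid = EI[a + 3 * a];
      double prefs = 0.5 * KE * (1.0 / eid - 1.0 / epsout) * q[i] * q[i];
      out.eself += -prefs / R[i];
      B[i] += prefs / (R[i] * R[i]);
    }
  }

  // chain-rule pass: dE/dx through R_i(positions)
  if (want_forces && need_radii) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        bool ci = (!usecache[i] && B[i] != 0.0);
        bool cj = (!usecache[j] && B[j] != 0.0);
        if (!ci && !cj) continue;
        double dx = pos[3 * i] - pos[3 * j];
        double dy = pos[3 * i + 1] - pos[3 * j + 1];
        double dz = pos[3 * i + 2] - pos[3 * j + 2];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        double s = 0.0;
        if (ci) s += B[i] * R[i] * R[i] * hct_dI(d, rho[i], rho[j]);
        if (cj) s += B[j] * R[j] * R[j] * hct_dI(d, rho[j], rho[i]);
        if (s == 0.0) continue;
        double fx = -s * dx / d, fy = -s * dy / d, fz = -s * dz / d;
        out.forces[3 * i] += fx;  out.forces[3 * i + 1] += fy;  out.forces[3 * i + 2] += fz;
        out.forces[3 * j] -= fx;  out.forces[3 * j + 1] -= fy;  out.forces[3 * j + 2] -= fz;
      }
    }
  }

  // flat-bottom spherical restraint (defines the simulation volume)
  if (!rs.fb_idx.empty() && rs.kfb > 0.0) {
    double ax = rs.anchor_pt[0], ay = rs.anchor_pt[1], az = rs.anchor_pt[2];
    if (rs.anchor_mode == 1) {
      double M = 0.0; ax = ay = az = 0.0;
      for (int k : rs.agrp) {
        double m = mass ? mass[k] : 1.0;
        M += m;
        ax += m * pos[3 * k]; ay += m * pos[3 * k + 1]; az += m * pos[3 * k + 2];
      }
      ax /= M; ay /= M; az /= M;
    }
    for (int k : rs.fb_idx) {
      double dx = pos[3 * k] - ax, dy = pos[3 * k + 1] - ay, dz = pos[3 * k + 2] - az;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r > rs.r3) {
        double ex = r - rs.r3;
        out.erestr += rs.kfb * ex * ex;
        if (want_forces) {
          double c = -2.0 * rs.kfb * ex / r;
          out.forces[3 * k] += c * dx;
          out.forces[3 * k + 1] += c * dy;
          out.forces[3 * k + 2] += c * dz;
          // no reaction force on a COM anchor group: anchors are fixed or
          // heavily restrained solute in all supported configurations
        }
      }
    }
  }

  // positional (harmonic) restraints, AMBER convention U = k * |dx|^2
  if (!rs.pr_idx.empty() && rs.kpr > 0.0) {
    for (size_t m = 0; m < rs.pr_idx.size(); ++m) {
      int k = rs.pr_idx[m];
      double dx = pos[3 * k] - rs.pr_ref[3 * m];
      double dy = pos[3 * k + 1] - rs.pr_ref[3 * m + 1];
      double dz = pos[3 * k + 2] - rs.pr_ref[3 * m + 2];
      out.erestr += rs.kpr * (dx * dx + dy * dy + dz * dz);
      if (want_forces) {
        out.forces[3 * k] -= 2.0 * rs.kpr * dx;
        out.forces[3 * k + 1] -= 2.0 * rs.kpr * dy;
        out.forces[3 * k + 2] -= 2.0 * rs.kpr * dz;
      }
    }
  }

  out.total = out.ecoul + out.egb + out.eself + out.elj + out.erestr;
}

// Unpack an R-side restraint list (already 0-based indices)
static Restraints unpack_restraints(List rlist) {
  Restraints rs;
  if (rlist.size() == 0) return rs;
  if (rlist.containsElementNamed("fb_idx")) {
    rs.fb_idx = as<std::vector<int> >(rlist["fb_idx"]);
    rs.anchor_mode = as<int>(rlist["anchor_mode"]);
    NumericVector ap = rlist["anchor_pt"];
    for (int k = 0; k < 3; ++k) rs.anchor_pt[k] = ap[k];
    rs.agrp = as<std::vector<int> >(rlist["anchor_grp"]);
    rs.r3 = as<double>(rlist["r3"]);
    rs.kfb = as<double>(rlist["k"]);
  }
  if (rlist.containsElementNamed("pr_idx")) {
    rs.pr_idx = as<std::vector<int> >(rlist["pr_idx"]);
    NumericMatrix ref = rlist["pr_ref"];
    rs.pr_ref.resize(3 * rs.pr_idx.size());
    for (size_t m = 0; m < rs.pr_idx.size(); ++m)
      for (int k = 0; k < 3; ++k) rs.pr_ref[3 * m + k] = ref(m, k);
    rs.kpr = as<double>(rlist["k_pos"]);
  }
  return rs;
}

// Radii (and their gradients) are only needed when some energy term that is
// actually evaluated carries a nonzero generalized Born prefactor
// (1/eps_in - 1/eps_out).  With an all-Coulomb table the whole Born
// machinery is skipped.
static bool system_needs_radii(const double* EI, double epsout,
                               const int* cls, const int* fixedf, int n,
                               bool skip_fixed) {
  int count[3][2] = {{0}};
  for (int i = 0; i < n; ++i) count[cls[i]][fixedf[i] ? 1 : 0]++;
  for (int a = 0; a < 3; ++a) for (int fa = 0; fa < 2; ++fa) {
    if (!count[a][fa]) continue;
    // self terms
    if (!(skip_fixed && fa) &&
        std::fabs(1.0 / EI[a + 3 * a] - 1.0 / epsout) > 0.0)
      return true;
    // pair terms
    for (int b = 0; b < 3; ++b) for (int fb = 0; fb < 2; ++fb) {
      if (!count[b][fb]) continue;
      if (a == b && fa == fb && count[a][fa] < 2) continue;
      if (skip_fixed && fa && fb) continue;
      if (std::fabs(1.0 / EI[a + 3 * b] - 1.0 / epsout) > 0.0) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector q, NumericVector rho,
                       NumericVector sig, NumericVector epslj, IntegerVector cls,
                       NumericMatrix gamma_tab, NumericMatrix epsin_tab, double epsout,
                       IntegerVector fixedf, bool skip_fixed,
                       LogicalVector use_cache, NumericVector cached_R,
                       List restraints, NumericVector mass, bool want_forces) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  std::vector<char> uc(n, 0);
  for (int i = 0; i < n; ++i) uc[i] = use_cache[i] ? 1 : 0;
  Restraints rs = unpack_restraints(restraints);
  bool need_radii = system_needs_radii(REAL(epsin_tab), epsout, INTEGER(cls), INTEGER(fixedf), n, true);
  EFResult out;
  compute_ef(p, n, REAL(q), REAL(rho), REAL(sig), REAL(epslj), INTEGER(cls),
             REAL(gamma_tab), REAL(epsin_tab), epsout, INTEGER(fixedf),
             skip_fixed, uc, cached_R.size() == (R_xlen_t)n ? REAL(cached_R) : nullptr,
             need_radii, rs, REAL(mass), want_forces, out);
  // upper-triangular by unordered class pair, so the entries sum to the
  // total electrostatic pair energy
  NumericMatrix ecls(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = a; b < 3; ++b)
      ecls(a, b) = out.elec_class[a][b];
  List res = List::create(
    _["coulomb"] = out.ecoul, _["gb_cross"] = out.egb, _["gb_self"] = out.eself,
    _["lj"] = out.elj, _["restraint"] = out.erestr, _["total"] = out.total,
    _["radii"] = wrap(out.radii), _["elec_by_class"] = ecls);
  if (want_forces) {
    NumericMatrix F(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) F(i, k) = out.forces[3 * i + k];
    res["forces"] = F;
  }
  return res;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator.  Uses R's RNG: deterministic under set.seed().

// [[Rcpp::export]]
List cpp_langevin(NumericMatrix pos0, NumericVector q, NumericVector rho,
                  NumericVector sig, NumericVector epslj, IntegerVector cls,
                  NumericMatrix gamma_tab, NumericMatrix epsin_tab, double epsout,
                  IntegerVector fixedf, NumericVector mass,
                  List restraints,
                  double temperature, double dt_ps, double friction_ps,
                  int n_steps, int stride,
                  bool cache_fixed_radii, bool skip_fixed_pairs,
                  double blowup_threshold) {
  int n = pos0.nrow();
  std::vector<double> p(3 * n), v(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos0(i, k);
  Restraints rs = unpack_restraints(restraints);
  bool need_radii = system_needs_radii(REAL(epsin_tab), epsout, INTEGER(cls), INTEGER(fixedf), n, true);

  RNGScope rng;

  // cache Born radii of fixed particles (computed once, full system)
  std::vector<char> uc(n, 0);
  std::vector<double> cached(n, 0.0);
  if (need_radii && cache_fixed_radii) {
    std::vector<char> nouc(n, 0);
    std::vector<double> R0(n);
    born_radii(p, n, REAL(rho), nouc, nullptr, R0);
    for (int i = 0; i < n; ++i)
      if (fixedf[i]) { uc[i] = 1; cached[i] = R0[i]; }
  }

  // Maxwell-Boltzmann start for mobile particles
  int n_mobile = 0;
  for (int i = 0; i < n; ++i) {
    if (fixedf[i]) continue;
    ++n_mobile;
    double sd = std::sqrt(KBOL * temperature * AKMA / mass[i]);
    for (int k = 0; k < 3; ++k) v[3 * i + k] = sd * norm_rand();
  }
  if (n_mobile == 0) stop("no mobile particles to integrate");

  double c1 = std::exp(-friction_ps * dt_ps);
  double c2 = std::sqrt(1.0 - c1 * c1);

  EFResult ef;
  compute_ef(p, n, REAL(q), REAL(rho), REAL(sig), REAL(epslj), INTEGER(cls),
             REAL(gamma_tab), REAL(epsin_tab), epsout, INTEGER(fixedf),
             skip_fixed_pairs, uc, cached.data(), need_radii, rs, REAL(mass),
             true, ef);

  int n_frames = 1 + n_steps / stride;
  NumericVector frames(Dimension(n, 3, n_frames));
  NumericMatrix emat(n_frames, 8);  // coul, gb, self, lj, restr, total, ekin, Tkin
  colnames(emat) = CharacterVector::create("coulomb", "gb_cross", "gb_self",
                                           "lj", "restraint", "total",
                                           "kinetic", "temperature");
  int frame = 0;
  int status = 0;  // 0 ok, 1 blow-up halt
  int last_step = 0;

  auto record = [&](int fidx) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        frames[i + n * k + 3 * n * fidx] = p[3 * i + k];
    double ekin = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fixedf[i]) continue;
      double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] + v[3 * i + 2] * v[3 * i + 2];
      ekin += 0.5 * mass[i] * v2 / AKMA;
    }
    emat(fidx, 0) = ef.ecoul;  emat(fidx, 1) = ef.egb;   emat(fidx, 2) = ef.eself;
    emat(fidx, 3) = ef.elj;    emat(fidx, 4) = ef.erestr; emat(fidx, 5) = ef.total;
    emat(fidx, 6) = ekin;
    emat(fidx, 7) = 2.0 * ekin / (3.0 * n_mobile * KBOL);
  };
  record(frame++);

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (fixedf[i]) continue;
      double c = 0.5 * dt_ps * AKMA / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += c * ef.forces[3 * i + k];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (fixedf[i]) continue;
      for (int k = 0; k < 3; ++k) p[3 * i + k] += 0.5 * dt_ps * v[3 * i + k];
    }
    // O: thermostat
    for (int i = 0; i < n; ++i) {
      if (fixedf[i]) continue;
      double sd = std::sqrt(KBOL * temperature * AKMA / mass[i]);
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] = c1 * v[3 * i + k] + c2 * sd * norm_rand();
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (fixedf[i]) continue;
      for (int k = 0; k < 3; ++k) p[3 * i + k] += 0.5 * dt_ps * v[3 * i + k];
    }
    // recompute forces, B: half kick
    compute_ef(p, n, REAL(q), REAL(rho), REAL(sig), REAL(epslj), INTEGER(cls),
               REAL(gamma_tab), REAL(epsin_tab), epsout, INTEGER(fixedf),
               skip_fixed_pairs, uc, cached.data(), need_radii, rs, REAL(mass),
               true, ef);
    if (!std::isfinite(ef.total) || std::fabs(ef.total) > blowup_threshold) {
      status = 1; last_step = step;
      break;
    }
    for (int i = 0; i < n; ++i) {
      if (fixedf[i]) continue;
      double c = 0.5 * dt_ps * AKMA / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += c * ef.forces[3 * i + k];
    }
    last_step = step;
    if (step % stride == 0) record(frame++);
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { pout(i, k) = p[3 * i + k]; vout(i, k) = v[3 * i + k]; }

  return List::create(_["frames"] = frames, _["energies"] = emat,
                      _["n_frames"] = frame, _["status"] = status,
                      _["last_step"] = last_step,
                      _["final_pos"] = pout, _["final_vel"] = vout);
}

// ---------------------------------------------------------------------------
// Metropolis Monte Carlo: single-particle displacements of mobile particles,
// acceptance on the total energy difference (radii recomputed per proposal).

// [[Rcpp::export]]
List cpp_mc(NumericMatrix pos0, NumericVector q, NumericVector rho,
            NumericVector sig, NumericVector epslj, IntegerVector cls,
            NumericMatrix gamma_tab, NumericMatrix epsin_tab, double epsout,
            IntegerVector fixedf, NumericVector mass,
            List restraints,
            double temperature, int n_sweeps, double max_disp, int stride,
            bool cache_fixed_radii) {
  int n = pos0.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos0(i, k);
  Restraints rs = unpack_restraints(restraints);
  bool need_radii = system_needs_radii(REAL(epsin_tab), epsout, INTEGER(cls), INTEGER(fixedf), n, true);

  RNGScope rng;

  std::vector<char> uc(n, 0);
  std::vector<double> cached(n, 0.0);
  if (need_radii && cache_fixed_radii) {
    std::vector<char> nouc(n, 0);
    std::vector<double> R0(n);
    born_radii(p, n, REAL(rho), nouc, nullptr, R0);
    for (int i = 0; i < n; ++i)
      if (fixedf[i]) { uc[i] = 1; cached[i] = R0[i]; }
  }

  std::vector<int> mobile;
  for (int i = 0; i < n; ++i) if (!fixedf[i]) mobile.push_back(i);
  if (mobile.empty()) stop("no mobile particles to sample");

  EFResult ef;
  auto energy = [&]() {
    compute_ef(p, n, REAL(q), REAL(rho), REAL(sig), REAL(epslj), INTEGER(cls),
               REAL(gamma_tab), REAL(epsin_tab), epsout, INTEGER(fixedf),
               true, uc, cached.data(), need_radii, rs, REAL(mass), false, ef);
    return ef.total;
  };
  double E = energy();
  double beta = 1.0 / (KBOL * temperature);

  int n_frames = 1 + n_sweeps / stride;
  NumericVector frames(Dimension(n, 3, n_frames));
  NumericVector etot(n_frames);
  int frame = 0;
  auto record = [&]() {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        frames[i + n * k + 3 * n * frame] = p[3 * i + k];
    etot[frame] = E;
    ++frame;
  };
  record();

  long accepted = 0, attempted = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int idx : mobile) {
      double old_[3];
      for (int k = 0; k < 3; ++k) {
        old_[k] = p[3 * idx + k];
        p[3 * idx + k] += (unif_rand() - 0.5) * 2.0 * max_disp;
      }
      ++attempted;
      double Enew = energy();
      double dE = Enew - E;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        E = Enew;
        ++accepted;
      } else {
        for (int k = 0; k < 3; ++k) p[3 * idx + k] = old_[k];
      }
    }
    if (sweep % stride == 0) record();
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["frames"] = frames, _["energy"] = etot,
                      _["n_frames"] = frame,
                      _["acceptance"] = (double)accepted / (double)attempted);
}
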