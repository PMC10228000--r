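// Compiled core: pair potentials, force/energy evaluation with a cell-list
// neighbor search, and the BAOAB Langevin integrator. All lengths are in um,
// energies in kT, time in units of the LJ time tau, masses in reduced units
// chosen so that tau = sigma_min * sqrt(m_min / eps_LJ) = 1.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double RMIN_FACT = 1.122462048309373; // 2^(1/6)

// Truncated LJ core, 4*eps*[(s/r)^12 - (s/r)^6] + shift, with a linear
// continuation below the radius where the energy reaches cap_u ("soft" beads:
// the core force is capped so initialization overlaps stay integrable).
static inline void lj_core(double r, double sigma, double eps, double cap_u,
                           double shift, double &u, double &dudr) {
  double cap_eff = cap_u - shift;
  // (sigma/rcap)^6 solving 4*eps*(x^2 - x) = cap_eff
  double x = 0.5 * (1.0 + std::sqrt(1.0 + cap_eff / eps));
  double rcap = sigma * std::pow(x, -1.0 / 6.0);
  if (r >= rcap) {
    double sr2 = (sigma / r) * (sigma / r);
    double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    u = 4.0 * eps * (sr12 - sr6) + shift;
    dudr = -24.0 * eps * (2.0 * sr12 - sr6) / r;
  } else {
    double sr6 = x, sr12 = sr6 * sr6;
    double ucap = 4.0 * eps * (sr12 - sr6) + shift;
    double dcap = -24.0 * eps * (2.0 * sr12 - sr6) / rcap;
    u = ucap + dcap * (r - rcap);
    dudr = dcap;
  }
}

// LJ-cos pair interaction: LJ core for r < 2^(1/6)*sigma, then a cos^2 taper
// of depth eps_att reaching exactly 0 at rc = 2^(1/6)*sigma + omega.
// eps_att == 0 degenerates to the purely repulsive (WCA-like) potential with
// amplitude eps_rep. Returns energy u and derivative dudr = dU/dr.
static inline void pair_ue(double r, double sigma, double eps_att,
                           double eps_rep, double omega_factor, double cap_u,
                           double &u, double &dudr) {
  u = 0.0; dudr = 0.0;
  double rmin = RMIN_FACT * sigma;
  if (eps_att > 0.0) {
    double omega = omega_factor * sigma;
    double rc = rmin + omega;
    if (r >= rc) return;
    if (r < rmin) {
      lj_core(r, sigma, eps_att, cap_u, 0.0, u, dudr);
    } else {
      double a = M_PI / (2.0 * omega), t = a * (r - rmin);
      double c = std::cos(t);
      u = -eps_att * c * c;
      dudr = eps_att * a * std::sin(2.0 * t);
    }
  } else {
    if (r >= rmin) return;
    lj_core(r, sigma, eps_rep, cap_u, eps_rep, u, dudr);
  }
}

// [[Rcpp::export]]
NumericVector cpp_pair_potential(NumericVector r, double sigma, double eps_att,
                                 double eps_rep, double omega_factor,
                                 double cap_u, bool derivative) {
  int n = r.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double u, d;
    pair_ue(r[k], sigma, eps_att, eps_rep, omega_factor, cap_u, u, d);
    out[k] = derivative ? d : u;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cell-list candidate pair search (no periodic boundaries).
static void candidate_pairs(const NumericMatrix &pos, double cutoff,
                            std::vector<int> &pi, std::vector<int> &pj) {
  pi.clear(); pj.clear();
  int n = pos.nrow();
  if (n < 2) return;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (pos(i, d) < lo[d]) lo[d] = pos(i, d);
      if (pos(i, d) > hi[d]) hi[d] = pos(i, d);
    }
  // no point in having many more cells than beads: cap per-dimension count
  // by cbrt(n) so sparse/unconfined systems do not churn empty cells
  int nc_max = std::max(2, (int)std::ceil(std::cbrt((double)n)) + 1);
  int nc[3]; double cw[3];
  for (int d = 0; d < 3; ++d) {
    double ext = hi[d] - lo[d];
    nc[d] = std::max(1, std::min(nc_max, (int)std::floor(ext / cutoff)));
    cw[d] = std::max(cutoff, ext / nc[d] + 1e-12);
    nc[d] = std::max(1, (int)std::floor(ext / cw[d]) + 1);
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> cells(ncell);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = std::min(nc[0] - 1, (int)((pos(i, 0) - lo[0]) / cw[0]));
    cj[i] = std::min(nc[1] - 1, (int)((pos(i, 1) - lo[1]) / cw[1]));
    ck[i] = std::min(nc[2] - 1, (int)((pos(i, 2) - lo[2]) / cw[2]));
    cells[(ci[i] * nc[1] + cj[i]) * nc[2] + ck[i]].push_back(i);
  }
  double cut2 = cutoff * cutoff;
  for (int a = 0; a < nc[0]; ++a)
    for (int b = 0; b < nc[1]; ++b)
      for (int c = 0; c < nc[2]; ++c) {
        const std::vector<int> &cell = cells[(a * nc[1] + b) * nc[2] + c];
        if (cell.empty()) continue;
        // pairs within the cell
        for (size_t s = 0; s < cell.size(); ++s)
          for (size_t t = s + 1; t < cell.size(); ++t) {
            int i = cell[s], j = cell[t];
            double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
            if (dx*dx + dy*dy + dz*dz <= cut2) { pi.push_back(std::min(i,j)); pj.push_back(std::max(i,j)); }
          }
        // half of the 26 neighbor cells
        for (int da = -1; da <= 1; ++da)
          for (int db = -1; db <= 1; ++db)
            for (int dc = -1; dc <= 1; ++dc) {
              if (da < 0) continue;
              if (da == 0 && (db < 0 || (db == 0 && dc <= 0))) continue;
              int a2 = a + da, b2 = b + db, c2 = c + dc;
              if (a2 < 0 || a2 >= nc[0] || b2 < 0 || b2 >= nc[1] || c2 < 0 || c2 >= nc[2]) continue;
              const std::vector<int> &other = cells[(a2 * nc[1] + b2) * nc[2] + c2];
              for (size_t s = 0; s < cell.size(); ++s)
                for (size_t t = 0; t < other.size(); ++t) {
                  int i = cell[s], j = other[t];
                  double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
                  if (dx*dx + dy*dy + dz*dz <= cut2) { pi.push_back(std::min(i,j)); pj.push_back(std::max(i,j)); }
                }
            }
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_candidate_pairs(NumericMatrix pos, double cutoff) {
  std::vector<int> pi, pj;
  candidate_pairs(pos, cutoff, pi, pj);
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k] + 1; out(k, 1) = pj[k] + 1; }
  return out;
}

// ---------------------------------------------------------------------------
// Full force-field evaluation.
struct FF {
  int n;
  NumericVector radius, mass;
  IntegerVector type;      // 0-based row index into eps matrix
  LogicalVector is_ltad;
  NumericMatrix eps;       // type-pair attractive well depths (kT)
  IntegerMatrix bonds;     // 0-based, m x 2
  NumericVector bond_r0, bond_k;
  bool exclude_bonded;
  IntegerVector spec_i, spec_j;  // 0-based
  NumericVector spec_eps;
  double omega_factor, cap_u, eps_rep;
  double ne_radius, eps_l, confine_radius;
  int nuc_index;           // 0-based, -1 = none
  double nuc_d0, nuc_k;
  double center_kappa, center_l0;
  bool has_wedge;
  NumericMatrix wedge_n1, wedge_n2; // n x 2 xy inward normals
  LogicalVector wedge_active;
  double k_wedge;
  double cutoff;           // largest nonbonded pair cutoff
  std::unordered_set<long long> bonded_keys;
  std::vector<int> nb1, nb2;  // up to two bonded neighbours per bead
};

static FF unpack_ff(const List &ff) {
  FF f;
  f.radius = ff["radius"]; f.mass = ff["mass"];
  f.type = ff["type"]; f.is_ltad = ff["is_ltad"];
  f.eps = as<NumericMatrix>(ff["eps"]);
  f.bonds = as<IntegerMatrix>(ff["bonds"]);
  f.bond_r0 = ff["bond_r0"]; f.bond_k = ff["bond_k"];
  f.exclude_bonded = as<bool>(ff["exclude_bonded"]);
  f.spec_i = ff["spec_i"]; f.spec_j = ff["spec_j"]; f.spec_eps = ff["spec_eps"];
  f.omega_factor = as<double>(ff["omega_factor"]);
  f.cap_u = as<double>(ff["cap_u"]);
  f.eps_rep = as<double>(ff["eps_rep"]);
  f.ne_radius = as<double>(ff["ne_radius"]);
  f.eps_l = as<double>(ff["eps_l"]);
  f.confine_radius = as<double>(ff["confine_radius"]);
  f.nuc_index = as<int>(ff["nuc_index"]);
  f.nuc_d0 = as<double>(ff["nuc_d0"]); f.nuc_k = as<double>(ff["nuc_k"]);
  f.center_kappa = as<double>(ff["center_kappa"]);
  f.center_l0 = as<double>(ff["center_l0"]);
  f.k_wedge = as<double>(ff["k_wedge"]);
  f.has_wedge = !Rf_isNull(ff["wedge_n1"]);
  if (f.has_wedge) {
    f.wedge_n1 = as<NumericMatrix>(ff["wedge_n1"]);
    f.wedge_n2 = as<NumericMatrix>(ff["wedge_n2"]);
    f.wedge_active = as<LogicalVector>(ff["wedge_active"]);
  }
  f.cutoff = as<double>(ff["cutoff"]);
  f.n = f.radius.size();
  f.nb1.assign(f.n, -1);
  f.nb2.assign(f.n, -1);
  if (f.exclude_bonded)
    for (int b = 0; b < f.bonds.nrow(); ++b) {
      int i = f.bonds(b, 0), j = f.bonds(b, 1);
      f.bonded_keys.insert((long long)i * f.n + j);
      f.bonded_keys.insert((long long)j * f.n + i);
      if (f.nb1[i] < 0) f.nb1[i] = j; else f.nb2[i] = j;
      if (f.nb1[j] < 0) f.nb1[j] = i; else f.nb2[j] = i;
    }
  return f;
}

// Evaluate all terms; fills F (must be n x 3, zeroed by caller) and the 8
// energy components: bond, nonbonded, specific, wall, confine, nucleolus,
// center, wedge.
static void eval_all(const FF &f, const NumericMatrix &pos,
                     const std::vector<int> &pi, const std::vector<int> &pj,
                     NumericMatrix &F, double *comp, bool want_force) {
  for (int k = 0; k < 8; ++k) comp[k] = 0.0;
  // bonds
  for (int b = 0; b < f.bonds.nrow(); ++b) {
    int i = f.bonds(b, 0), j = f.bonds(b, 1);
    double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - f.bond_r0[b];
    comp[0] += 0.5 * f.bond_k[b] * dr * dr;
    if (want_force && r > 1e-12) {
      double fmag = -f.bond_k[b] * dr / r; // along (i - j)
      F(i,0) += fmag*dx; F(i,1) += fmag*dy; F(i,2) += fmag*dz;
      F(j,0) -= fmag*dx; F(j,1) -= fmag*dy; F(j,2) -= fmag*dz;
    }
  }
  // nonbonded class-pair terms over candidate pairs
  {
    const double *px = &pos(0, 0), *py = &pos(0, 1), *pz = &pos(0, 2);
    double *fx = &F(0, 0), *fy = &F(0, 1), *fz = &F(0, 2);
    const double *rad = &f.radius[0];
    const int *type = &f.type[0];
    const double *eps = &f.eps(0, 0);
    int net = f.eps.nrow();
    for (size_t k = 0; k < pi.size(); ++k) {
      int i = pi[k], j = pj[k];
      if (f.exclude_bonded && (f.nb1[i] == j || f.nb2[i] == j)) continue;
      double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
      double r2 = dx*dx + dy*dy + dz*dz;
      double sigma = rad[i] + rad[j];
      double e_att = eps[type[i] + net * type[j]];
      double rc = (e_att > 0.0 ? RMIN_FACT + f.omega_factor : RMIN_FACT) * sigma;
      if (r2 >= rc * rc || r2 < 1e-24) continue;
      double r = std::sqrt(r2);
      double u, dudr;
      pair_ue(r, sigma, e_att, f.eps_rep, f.omega_factor, f.cap_u, u, dudr);
      comp[1] += u;
      if (want_force && dudr != 0.0) {
        double fmag = -dudr / r;
        fx[i] += fmag*dx; fy[i] += fmag*dy; fz[i] += fmag*dz;
        fx[j] -= fmag*dx; fy[j] -= fmag*dy; fz[j] -= fmag*dz;
      }
    }
  }
  // specific pairs: extra well on top of the class term (evaluated directly)
  for (int k = 0; k < f.spec_i.size(); ++k) {
    int i = f.spec_i[k], j = f.spec_j[k];
    double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-12) continue;
    double sigma = f.radius[i] + f.radius[j];
    double e_cls = f.eps(f.type[i], f.type[j]);
    bool excl = f.exclude_bonded && f.bonded_keys.count((long long)i * f.n + j);
    double u0 = 0.0, d0 = 0.0, u1, d1;
    if (!excl) pair_ue(r, sigma, e_cls, f.eps_rep, f.omega_factor, f.cap_u, u0, d0);
    pair_ue(r, sigma, e_cls + f.spec_eps[k], f.eps_rep, f.omega_factor, f.cap_u, u1, d1);
    if (excl) { u0 = 0.0; d0 = 0.0; }
    comp[2] += u1 - u0;
    if (want_force) {
      double dd = d1 - d0;
      if (dd != 0.0) {
        double fmag = -dd / r;
        F(i,0) += fmag*dx; F(i,1) += fmag*dy; F(i,2) += fmag*dz;
        F(j,0) -= fmag*dx; F(j,1) -= fmag*dy; F(j,2) -= fmag*dz;
      }
    }
  }
  // per-bead radial terms
  for (int i = 0; i < f.n; ++i) {
    double x = pos(i,0), y = pos(i,1), z = pos(i,2);
    double rr = std::sqrt(x*x + y*y + z*z);
    double ux = 0.0, uy = 0.0, uz = 0.0;
    if (rr > 1e-12) { ux = x/rr; uy = y/rr; uz = z/rr; }
    // NE wall: distance of the bead center from the inner surface. The
    // contact scale is radius/2^(1/6) so the well minimum (or the onset of
    // repulsion) sits exactly at d = bead radius, i.e. bead touching the wall.
    if (f.ne_radius > 0.0) {
      double d = f.ne_radius - rr;
      double sw = f.radius[i] / RMIN_FACT;
      double e_att = (f.is_ltad[i] && f.eps_l > 0.0) ? f.eps_l : 0.0;
      double cut = e_att > 0.0 ? (RMIN_FACT + f.omega_factor) * sw : RMIN_FACT * sw;
      if (d < cut) {
        double u, dudd;
        pair_ue(d, sw, e_att, f.eps_rep, f.omega_factor, f.cap_u, u, dudd);
        comp[3] += u;
        if (want_force) { // F = dU/dd * rhat (since d = R - |r|)
          F(i,0) += dudd*ux; F(i,1) += dudd*uy; F(i,2) += dudd*uz;
        }
      }
    }
    // plain repulsive confinement sphere (used during assembly/shrink)
    if (f.confine_radius > 0.0) {
      double d = f.confine_radius - rr;
      double sw = f.radius[i] / RMIN_FACT;
      if (d < RMIN_FACT * sw) {
        double u, dudd;
        pair_ue(d, sw, 0.0, f.eps_rep, f.omega_factor, f.cap_u, u, dudd);
        comp[4] += u;
        if (want_force) {
          F(i,0) += dudd*ux; F(i,1) += dudd*uy; F(i,2) += dudd*uz;
        }
      }
    }
    // nucleolus radial restraint
    if (i == f.nuc_index && f.nuc_k > 0.0) {
      double dr = rr - f.nuc_d0;
      comp[5] += 0.5 * f.nuc_k * dr * dr;
      if (want_force) {
        F(i,0) -= f.nuc_k*dr*ux; F(i,1) -= f.nuc_k*dr*uy; F(i,2) -= f.nuc_k*dr*uz;
      }
    }
    // chain-collapse center harmonic
    if (f.center_kappa > 0.0 && i != f.nuc_index) {
      double dr = rr - f.center_l0;
      comp[6] += 0.5 * f.center_kappa * dr * dr;
      if (want_force) {
        F(i,0) -= f.center_kappa*dr*ux; F(i,1) -= f.center_kappa*dr*uy; F(i,2) -= f.center_kappa*dr*uz;
      }
    }
    // wedge half-plane restraints (xy only)
    if (f.has_wedge && f.wedge_active[i]) {
      for (int w = 0; w < 2; ++w) {
        double ax = w == 0 ? f.wedge_n1(i,0) : f.wedge_n2(i,0);
        double ay = w == 0 ? f.wedge_n1(i,1) : f.wedge_n2(i,1);
        double v = ax*x + ay*y;
        if (v < 0.0) {
          comp[7] += 0.5 * f.k_wedge * v * v;
          if (want_force) { F(i,0) -= f.k_wedge*v*ax; F(i,1) -= f.k_wedge*v*ay; }
        }
      }
    }
  }
}

static const char *COMP_NAMES[8] = {"bond", "nonbonded", "specific", "wall",
                                    "confine", "nucleolus", "center", "wedge"};

// [[Rcpp::export]]
NumericVector cpp_energy(List ff, NumericMatrix pos) {
  FF f = unpack_ff(ff);
  std::vector<int> pi, pj;
  candidate_pairs(pos, f.cutoff, pi, pj);
  NumericMatrix F(1, 3); // unused
  double comp[8];
  eval_all(f, pos, pi, pj, F, comp, false);
  NumericVector out(8);
  for (int k = 0; k < 8; ++k) out[k] = comp[k];
  out.attr("names") = CharacterVector::create("bond", "nonbonded", "specific",
      "wall", "confine", "nucleolus", "center", "wedge");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(List ff, NumericMatrix pos) {
  FF f = unpack_ff(ff);
  std::vector<int> pi, pj;
  candidate_pairs(pos, f.cutoff, pi, pj);
  NumericMatrix F(f.n, 3);
  double comp[8];
  eval_all(f, pos, pi, pj, F, comp, true);
  return F;
}

// BAOAB Langevin integrator. Positions in um, dt in tau, gamma in 1/tau,
// friction is mass-proportional (-gamma * m_i * v_i) so the same gamma applies
// to every bead; noise amplitude per bead satisfies fluctuation-dissipation at
// temperature kT. Uses R's RNG so a set.seed() call makes runs bit-identical.
// [[Rcpp::export]]
List cpp_run_langevin(List ff, NumericMatrix pos0, NumericMatrix vel0,
                      int n_steps, double dt, double gamma, double kT,
                      int stride, int nlist_every, double skin) {
  FF f = unpack_ff(ff);
  int n = f.n;
  NumericMatrix pos(clone(pos0)), vel(clone(vel0)), F(n, 3);
  std::vector<int> pi, pj;
  double comp[8];
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  std::vector<double> sd(n), inv_m(n);
  for (int i = 0; i < n; ++i) {
    sd[i] = std::sqrt(kT / f.mass[i]);
    inv_m[i] = 1.0 / f.mass[i];
  }
  int n_snap = n_steps / stride;
  NumericVector traj(Dimension(n, 3, n_snap));
  IntegerVector snap_steps(n_snap);
  NumericVector snap_ktemp(n_snap);
  GetRNGstate();
  candidate_pairs(pos, f.cutoff + skin, pi, pj);
  eval_all(f, pos, pi, pj, F, comp, true);
  bool ok = true;
  int bad_step = -1, rec = 0;
  double *P = &pos(0, 0), *V = &vel(0, 0), *Fp = &F(0, 0);
  int n3 = 3 * n;
  double hdt = 0.5 * dt;
  for (int s = 1; s <= n_steps; ++s) {
    for (int k = 0; k < n3; ++k) {
      V[k] += hdt * Fp[k] * inv_m[k % n];
      P[k] += hdt * V[k];
    }
    if (c2 > 0.0)
      for (int k = 0; k < n3; ++k)
        V[k] = c1 * V[k] + c2 * sd[k % n] * norm_rand();
    for (int k = 0; k < n3; ++k) P[k] += hdt * V[k];
    if (s % nlist_every == 0) candidate_pairs(pos, f.cutoff + skin, pi, pj);
    std::fill(F.begin(), F.end(), 0.0);
    eval_all(f, pos, pi, pj, F, comp, true);
    for (int k = 0; k < n3; ++k) V[k] += hdt * Fp[k] * inv_m[k % n];
    // divergence check (cheap: first bead + periodic full scan)
    if (!std::isfinite(P[0]) || s % 500 == 0) {
      bool fin = true;
      for (int k = 0; k < n3 && fin; ++k)
        if (!std::isfinite(P[k]) || !std::isfinite(V[k])) fin = false;
      if (!fin) { ok = false; bad_step = s; break; }
    }
    if (s % stride == 0 && rec < n_snap) {
      std::copy(P, P + n3, &traj[(size_t)rec * n3]);
      snap_steps[rec] = s;
      double ke2 = 0.0;
      for (int k = 0; k < n3; ++k) ke2 += f.mass[k % n] * V[k] * V[k];
      snap_ktemp[rec] = ke2 / (3.0 * n);
      ++rec;
    }
  }
  PutRNGstate();
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["traj"] = traj, _["snap_steps"] = snap_steps,
                      _["snap_ktemp"] = snap_ktemp,
                      _["n_recorded"] = rec, _["ok"] = ok,
                      _["bad_step"] = bad_step);
}

// Accumulate contact counts for a subset of beads over the snapshots of a
// trajectory block. traj has dim (n, 3, n_snap); idx is 0-based into beads;
// a contact is center distance <= scale * (r_i + r_j).
// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(NumericVector traj, NumericVector radius,
                                 IntegerVector idx, double scale,
                                 int snap_from, int snap_to) {
  IntegerVector dims = traj.attr("dim");
  int n = dims[0];
  int m = idx.size();
  NumericMatrix counts(m, m);
  for (int s = snap_from; s < snap_to; ++s) {
    const double *base = &traj[(size_t)s * 3 * n];
    for (int a = 0; a < m; ++a) {
      int i = idx[a];
      double xi = base[i], yi = base[n + i], zi = base[2 * n + i];
      for (int b = a + 1; b < m; ++b) {
        int j = idx[b];
        double dx = xi - base[j], dy = yi - base[n + j], dz = zi - base[2 * n + j];
        double thr = scale * (radius[i] + radius[j]);
        if (dx*dx + dy*dy + dz*dz <= thr * thr) {
          counts(a, b) += 1.0; counts(b, a) += 1.0;
        }
      }
    }
  }
  return counts;
}
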