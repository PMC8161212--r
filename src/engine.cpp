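// Langevin (BAOAB) dynamics of ions and a rigid two-site dipolar solvent in
// the field of a fixed pore model. Units: Angstrom, ps, amu, kcal/mol, e.
//
// Pair potential: 12-6 Lennard-Jones (per-pair rmin = sum of per-atom rmin/2,
// epsilon by geometric mean), truncated at the cutoff with the energy shifted
// to zero there; Coulomb with the shifted-force truncation so both the
// potential and the force go continuously to zero at the cutoff. Minimum
// image convention in all three (periodic) dimensions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double F_CONV = 418.4;           // kcal/mol -> amu A^2/ps^2
static const double KB = 0.001987204259;      // kcal/mol/K
static const double COULOMB = 332.0636;       // kcal A/(mol e^2)
static const double R_MIN_CLAMP = 0.1;        // A, overlap clamp distance

struct PairParams {
  double cutoff, cutoff2, inv_rc, inv_rc2;
  double ke;   // Coulomb constant / background dielectric
};

// Accumulate the LJ + Coulomb force of j on i; returns pair energy.
// fx,fy,fz: force components on i (Newton's third law applied by caller).
static inline double pair_kernel(double dx, double dy, double dz, double r2,
                                 double qi, double qj, double rhi, double rhj,
                                 double ei, double ej, const PairParams &pp,
                                 double &fx, double &fy, double &fz,
                                 int &n_clamped) {
  if (r2 < R_MIN_CLAMP * R_MIN_CLAMP) {
    r2 = R_MIN_CLAMP * R_MIN_CLAMP;
    ++n_clamped;
  }
  double r = std::sqrt(r2);
  double inv_r2 = 1.0 / r2;
  double u = 0.0, fscale = 0.0;
  double e = (ei > 0.0 && ej > 0.0) ? std::sqrt(ei * ej) : 0.0;
  if (e > 0.0) {
    double rm = rhi + rhj;
    double s2 = rm * rm * inv_r2;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    double rmc = rm * pp.inv_rc;
    double sc6 = rmc * rmc * rmc * rmc * rmc * rmc;
    u += e * (s12 - 2.0 * s6) - e * (sc6 * sc6 - 2.0 * sc6);
    fscale += 12.0 * e * (s12 - s6) * inv_r2;
  }
  double qq = qi * qj;
  if (qq != 0.0) {
    u += pp.ke * qq * (1.0 / r - pp.inv_rc + (r - pp.cutoff) * pp.inv_rc2);
    fscale += pp.ke * qq * (inv_r2 - pp.inv_rc2) / r;
  }
  fx = fscale * dx;
  fy = fscale * dy;
  fz = fscale * dz;
  return u;
}

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// Direct O(N^2) pair forces for testing and small systems.
// excl_i/excl_j: 0-based excluded pairs.
// [[Rcpp::export]]
List cpp_pair_forces(NumericMatrix pos, NumericVector q, NumericVector rh,
                     NumericVector eps, NumericVector box, double cutoff,
                     IntegerVector excl_i, IntegerVector excl_j,
                     double dielectric) {
  int n = pos.nrow();
  PairParams pp{cutoff, cutoff * cutoff, 1.0 / cutoff, 1.0 / (cutoff * cutoff),
                COULOMB / dielectric};
  NumericMatrix F(n, 3);
  double energy = 0.0;
  int n_clamped = 0;
  std::vector<std::pair<int, int>> excl;
  for (int k = 0; k < excl_i.size(); ++k)
    excl.push_back({std::min(excl_i[k], excl_j[k]),
                    std::max(excl_i[k], excl_j[k])});
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool skip = false;
      for (auto &pr : excl)
        if (pr.first == i && pr.second == j) { skip = true; break; }
      if (skip) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), box[0]);
      double dy = min_image(pos(i, 1) - pos(j, 1), box[1]);
      double dz = min_image(pos(i, 2) - pos(j, 2), box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pp.cutoff2) continue;
      double fx, fy, fz;
      energy += pair_kernel(dx, dy, dz, r2, q[i], q[j], rh[i], rh[j],
                            eps[i], eps[j], pp, fx, fy, fz, n_clamped);
      F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
      F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
    }
  }
  return List::create(_["forces"] = F, _["energy"] = energy,
                      _["n_clamped"] = n_clamped);
}

// ---------------------------------------------------------------------------
// Simulation system with cell-list based neighbour lists.

struct System {
  int nf, ni, nw, N;                 // fixed, ions, waters, total sites
  std::vector<double> x, y, z;       // site positions (unwrapped)
  std::vector<double> q, rh, eps;    // per-site parameters
  std::vector<double> fx, fy, fz;    // site forces
  double box[3];
  PairParams pp;
  double rlist, rlist2;              // cutoff + skin
  // neighbour list (for mobile sites only); periodic shifts are frozen at
  // build time (valid while displacements stay within the skin)
  std::vector<int> nl_start, nl;
  std::vector<double> nlsx, nlsy, nlsz;
  std::vector<double> x0, y0, z0;    // positions at last build
  // field and repulsion
  double efz;                        // kcal/mol/A per e, along z
  double rep_fmax, rep_zhalf, rep_rgate;
  int n_clamped;
  double energy;

  int wO(int k) const { return nf + ni + 2 * k; }
  int wH(int k) const { return nf + ni + 2 * k + 1; }
  bool same_molecule(int i, int j) const {
    if (i < nf + ni || j < nf + ni) return false;
    return (i - nf - ni) / 2 == (j - nf - ni) / 2;
  }

  void build_nlist() {
    int nm = N - nf;
    int nc[3];
    double cl[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(box[d] / rlist));
      cl[d] = box[d] / nc[d];
    }
    int ncells = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncells, -1), nxt(N, -1), cellof(N);
    auto cell_index = [&](double px, double py, double pz) {
      int cx = (int)std::floor((px - box[0] * std::floor(px / box[0])) / cl[0]);
      int cy = (int)std::floor((py - box[1] * std::floor(py / box[1])) / cl[1]);
      int cz = (int)std::floor((pz - box[2] * std::floor(pz / box[2])) / cl[2]);
      if (cx >= nc[0]) cx = nc[0] - 1;
      if (cy >= nc[1]) cy = nc[1] - 1;
      if (cz >= nc[2]) cz = nc[2] - 1;
      return (cz * nc[1] + cy) * nc[0] + cx;
    };
    for (int i = 0; i < N; ++i) {
      int c = cell_index(x[i], y[i], z[i]);
      cellof[i] = c;
      nxt[i] = head[c];
      head[c] = i;
    }
    // neighbour cells of each cell (deduplicated for small cell counts)
    std::vector<std::vector<int>> cneigh(ncells);
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int c = (cz * nc[1] + cy) * nc[0] + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ox = (cx + dx + nc[0]) % nc[0];
                int oy = (cy + dy + nc[1]) % nc[1];
                int oz = (cz + dz + nc[2]) % nc[2];
                int o = (oz * nc[1] + oy) * nc[0] + ox;
                bool seen = false;
                for (int s : cneigh[c]) if (s == o) { seen = true; break; }
                if (!seen) cneigh[c].push_back(o);
              }
        }
    nl_start.assign(nm + 1, 0);
    nl.clear();
    nlsx.clear(); nlsy.clear(); nlsz.clear();
    nl.reserve((size_t)nm * 64);
    for (int m = 0; m < nm; ++m) {
      int i = nf + m;
      nl_start[m] = (int)nl.size();
      for (int c : cneigh[cellof[i]]) {
        for (int j = head[c]; j >= 0; j = nxt[j]) {
          if (j == i) continue;
          if (j >= nf && j > i) continue;     // mobile pair counted once (j < i)
          if (same_molecule(i, j)) continue;
          double sx = box[0] * std::round((x[i] - x[j]) / box[0]);
          double sy = box[1] * std::round((y[i] - y[j]) / box[1]);
          double sz = box[2] * std::round((z[i] - z[j]) / box[2]);
          double dx = x[i] - x[j] - sx;
          double dy = y[i] - y[j] - sy;
          double dz = z[i] - z[j] - sz;
          if (dx * dx + dy * dy + dz * dz < rlist2) {
            nl.push_back(j);
            nlsx.push_back(sx); nlsy.push_back(sy); nlsz.push_back(sz);
          }
        }
      }
    }
    nl_start[nm] = (int)nl.size();
    x0 = x; y0 = y; z0 = z;
  }

  bool need_rebuild(double skin) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = nf; i < N; ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void compute_forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    energy = 0.0;
    int nm = N - nf;
    for (int m = 0; m < nm; ++m) {
      int i = nf + m;
      for (int k = nl_start[m]; k < nl_start[m + 1]; ++k) {
        int j = nl[k];
        double dx = x[i] - x[j] - nlsx[k];
        double dy = y[i] - y[j] - nlsy[k];
        double dz = z[i] - z[j] - nlsz[k];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= pp.cutoff2) continue;
        double pfx, pfy, pfz;
        energy += pair_kernel(dx, dy, dz, r2, q[i], q[j], rh[i], rh[j],
                              eps[i], eps[j], pp, pfx, pfy, pfz, n_clamped);
        fx[i] += pfx; fy[i] += pfy; fz[i] += pfz;
        fx[j] -= pfx; fy[j] -= pfy; fz[j] -= pfz;
      }
    }
    // constant external field on mobile charges (fixed atoms are insensitive)
    if (efz != 0.0)
      for (int i = nf; i < N; ++i)
        if (q[i] != 0.0) fz[i] += q[i] * efz;
    // repulsive control potential on ions only
    if (rep_fmax > 0.0) {
      for (int i = nf; i < nf + ni; ++i) {
        double zl = min_image(z[i], box[2]);
        if (std::fabs(zl) >= rep_zhalf) continue;
        double xl = min_image(x[i], box[0]);
        double yl = min_image(y[i], box[1]);
        if (xl * xl + yl * yl >= rep_rgate * rep_rgate) continue;
        double s = (zl >= 0.0) ? 1.0 : -1.0;
        fz[i] += s * rep_fmax * (1.0 - std::fabs(zl) / rep_zhalf);
      }
    }
  }
};

static void setup_system(System &S,
                         const NumericMatrix &fpos, const NumericVector &fq,
                         const NumericVector &frh, const NumericVector &feps,
                         const NumericMatrix &ipos, const NumericVector &iq,
                         const NumericVector &irh, const NumericVector &ieps,
                         const NumericMatrix &wcom, const NumericMatrix &wu,
                         double w_q, double w_d, double w_rh, double w_eps,
                         const NumericVector &box, double cutoff, double skin,
                         double dielectric) {
  S.nf = fpos.nrow();
  S.ni = ipos.nrow();
  S.nw = wcom.nrow();
  S.N = S.nf + S.ni + 2 * S.nw;
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  S.q.resize(S.N); S.rh.resize(S.N); S.eps.resize(S.N);
  S.fx.resize(S.N); S.fy.resize(S.N); S.fz.resize(S.N);
  for (int d = 0; d < 3; ++d) S.box[d] = box[d];
  S.pp = PairParams{cutoff, cutoff * cutoff, 1.0 / cutoff,
                    1.0 / (cutoff * cutoff), COULOMB / dielectric};
  S.rlist = cutoff + skin;
  S.rlist2 = S.rlist * S.rlist;
  S.n_clamped = 0;
  for (int i = 0; i < S.nf; ++i) {
    S.x[i] = fpos(i, 0); S.y[i] = fpos(i, 1); S.z[i] = fpos(i, 2);
    S.q[i] = fq[i]; S.rh[i] = frh[i]; S.eps[i] = feps[i];
  }
  for (int i = 0; i < S.ni; ++i) {
    int s = S.nf + i;
    S.x[s] = ipos(i, 0); S.y[s] = ipos(i, 1); S.z[s] = ipos(i, 2);
    S.q[s] = iq[i]; S.rh[s] = irh[i]; S.eps[s] = ieps[i];
  }
  for (int k = 0; k < S.nw; ++k) {
    int o = S.wO(k), h = S.wH(k);
    double hx = 0.5 * w_d * wu(k, 0), hy = 0.5 * w_d * wu(k, 1),
           hz = 0.5 * w_d * wu(k, 2);
    S.x[o] = wcom(k, 0) - hx; S.y[o] = wcom(k, 1) - hy; S.z[o] = wcom(k, 2) - hz;
    S.x[h] = wcom(k, 0) + hx; S.y[h] = wcom(k, 1) + hy; S.z[h] = wcom(k, 2) + hz;
    S.q[o] = -w_q; S.q[h] = w_q;
    S.rh[o] = w_rh; S.rh[h] = w_rh;
    S.eps[o] = w_eps; S.eps[h] = w_eps;
  }
}

static inline void rodrigues(double &ux, double &uy, double &uz,
                             double wx, double wy, double wz, double dt) {
  double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
  if (wn < 1e-14) return;
  double th = wn * dt;
  double c = std::cos(th), s = std::sin(th);
  double ax = wx / wn, ay = wy / wn, az = wz / wn;
  double dot = ax * ux + ay * uy + az * uz;
  double cx = ay * uz - az * uy, cy = az * ux - ax * uz, cz = ax * uy - ay * ux;
  double nx = ux * c + cx * s + ax * dot * (1 - c);
  double ny = uy * c + cy * s + ay * dot * (1 - c);
  double nz = uz * c + cz * s + az * dot * (1 - c);
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nn; uy = ny / nn; uz = nz / nn;
}

static inline void project_perp(double &wx, double &wy, double &wz,
                                double ux, double uy, double uz) {
  double d = wx * ux + wy * uy + wz * uz;
  wx -= d * ux; wy -= d * uy; wz -= d * uz;
}

// Langevin BAOAB run. Returns saved trajectory arrays and the final state.
// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix fpos, NumericVector fq, NumericVector frh,
                NumericVector feps,
                NumericMatrix ipos, NumericVector iq, NumericVector irh,
                NumericVector ieps, NumericVector imass, NumericMatrix ivel,
                NumericMatrix wcom, NumericMatrix wu, NumericMatrix wvel,
                NumericMatrix womega,
                double w_q, double w_d, double w_rh, double w_eps,
                double w_site_mass,
                NumericVector box, double cutoff, double skin,
                double dielectric,
                double dt, double temperature, double gamma,
                int n_steps, int save_every, double efz,
                double rep_fmax, double rep_zhalf, double rep_rgate,
                int minimize_steps) {
  System S;
  setup_system(S, fpos, fq, frh, feps, ipos, iq, irh, ieps,
               wcom, wu, w_q, w_d, w_rh, w_eps, box, cutoff, skin, dielectric);
  S.efz = efz;
  S.rep_fmax = rep_fmax; S.rep_zhalf = rep_zhalf; S.rep_rgate = rep_rgate;

  int ni = S.ni, nw = S.nw, nf = S.nf;
  std::vector<double> cx(nw), cy(nw), cz(nw), ux(nw), uy(nw), uz(nw);
  std::vector<double> vwx(nw), vwy(nw), vwz(nw), wx(nw), wy(nw), wz(nw);
  for (int k = 0; k < nw; ++k) {
    cx[k] = wcom(k, 0); cy[k] = wcom(k, 1); cz[k] = wcom(k, 2);
    ux[k] = wu(k, 0); uy[k] = wu(k, 1); uz[k] = wu(k, 2);
    vwx[k] = wvel(k, 0); vwy[k] = wvel(k, 1); vwz[k] = wvel(k, 2);
    wx[k] = womega(k, 0); wy[k] = womega(k, 1); wz[k] = womega(k, 2);
    project_perp(wx[k], wy[k], wz[k], ux[k], uy[k], uz[k]);
  }
  std::vector<double> vix(ni), viy(ni), viz(ni);
  for (int i = 0; i < ni; ++i) {
    vix[i] = ivel(i, 0); viy[i] = ivel(i, 1); viz[i] = ivel(i, 2);
  }
  double mW = 2.0 * w_site_mass;
  double I = 0.5 * w_site_mass * w_d * w_d;   // 2 * m_site * (d/2)^2

  auto sync_sites = [&]() {
    for (int k = 0; k < nw; ++k) {
      int o = S.wO(k), h = S.wH(k);
      double hx = 0.5 * w_d * ux[k], hy = 0.5 * w_d * uy[k],
             hz = 0.5 * w_d * uz[k];
      S.x[o] = cx[k] - hx; S.y[o] = cy[k] - hy; S.z[o] = cz[k] - hz;
      S.x[h] = cx[k] + hx; S.y[h] = cy[k] + hy; S.z[h] = cz[k] + hz;
    }
  };

  // --- steepest-descent minimization (translations only) -------------------
  if (minimize_steps > 0 && (ni + nw) > 0) {
    const double dmax = 0.2, alpha = 1e-3;
    S.build_nlist();
    for (int it = 0; it < minimize_steps; ++it) {
      if (S.need_rebuild(S.rlist - S.pp.cutoff)) S.build_nlist();
      S.compute_forces();
      for (int i = 0; i < ni; ++i) {
        int s = nf + i;
        double fn = std::sqrt(S.fx[s] * S.fx[s] + S.fy[s] * S.fy[s] +
                              S.fz[s] * S.fz[s]);
        if (fn < 1e-12) continue;
        double step = std::min(dmax, alpha * fn);
        S.x[s] += step * S.fx[s] / fn;
        S.y[s] += step * S.fy[s] / fn;
        S.z[s] += step * S.fz[s] / fn;
      }
      for (int k = 0; k < nw; ++k) {
        int o = S.wO(k), h = S.wH(k);
        double gx = S.fx[o] + S.fx[h], gy = S.fy[o] + S.fy[h],
               gz = S.fz[o] + S.fz[h];
        double fn = std::sqrt(gx * gx + gy * gy + gz * gz);
        if (fn < 1e-12) continue;
        double step = std::min(dmax, alpha * fn);
        cx[k] += step * gx / fn; cy[k] += step * gy / fn;
        cz[k] += step * gz / fn;
      }
      sync_sites();
    }
  }

  // --- BAOAB Langevin dynamics ---------------------------------------------
  double kT = KB * temperature;
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> sig_i(ni);
  for (int i = 0; i < ni; ++i) sig_i[i] = std::sqrt(kT * F_CONV / imass[i]);
  double sig_w = std::sqrt(kT * F_CONV / mW);
  double sig_r = (nw > 0) ? std::sqrt(kT * F_CONV / I) : 0.0;

  int n_save = (save_every > 0 && n_steps > 0) ? n_steps / save_every : 0;
  NumericVector ion_traj(n_save * ni * 3);
  NumericVector ion_vtraj(n_save * ni * 3);
  NumericVector wO_traj(n_save * nw * 3);
  NumericVector dip_traj(n_save * nw * 3);
  NumericVector wv_traj(n_save * nw * 3);
  NumericVector times(n_save);
  NumericVector energies(n_save);
  int isave = 0;

  S.build_nlist();
  S.compute_forces();

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < ni; ++i) {
      int s = nf + i;
      double f = 0.5 * dt * F_CONV / imass[i];
      vix[i] += f * S.fx[s]; viy[i] += f * S.fy[s]; viz[i] += f * S.fz[s];
    }
    for (int k = 0; k < nw; ++k) {
      int o = S.wO(k), h = S.wH(k);
      double f = 0.5 * dt * F_CONV / mW;
      vwx[k] += f * (S.fx[o] + S.fx[h]);
      vwy[k] += f * (S.fy[o] + S.fy[h]);
      vwz[k] += f * (S.fz[o] + S.fz[h]);
      double dfx = S.fx[h] - S.fx[o], dfy = S.fy[h] - S.fy[o],
             dfz = S.fz[h] - S.fz[o];
      double tx = 0.5 * w_d * (uy[k] * dfz - uz[k] * dfy);
      double ty = 0.5 * w_d * (uz[k] * dfx - ux[k] * dfz);
      double tz = 0.5 * w_d * (ux[k] * dfy - uy[k] * dfx);
      double g = 0.5 * dt * F_CONV / I;
      wx[k] += g * tx; wy[k] += g * ty; wz[k] += g * tz;
      project_perp(wx[k], wy[k], wz[k], ux[k], uy[k], uz[k]);
    }
    // A: half drift
    for (int i = 0; i < ni; ++i) {
      int s = nf + i;
      S.x[s] += 0.5 * dt * vix[i];
      S.y[s] += 0.5 * dt * viy[i];
      S.z[s] += 0.5 * dt * viz[i];
    }
    for (int k = 0; k < nw; ++k) {
      cx[k] += 0.5 * dt * vwx[k];
      cy[k] += 0.5 * dt * vwy[k];
      cz[k] += 0.5 * dt * vwz[k];
      rodrigues(ux[k], uy[k], uz[k], wx[k], wy[k], wz[k], 0.5 * dt);
    }
    // O: thermostat
    for (int i = 0; i < ni; ++i) {
      vix[i] = c1 * vix[i] + c2 * sig_i[i] * R::norm_rand();
      viy[i] = c1 * viy[i] + c2 * sig_i[i] * R::norm_rand();
      viz[i] = c1 * viz[i] + c2 * sig_i[i] * R::norm_rand();
    }
    for (int k = 0; k < nw; ++k) {
      vwx[k] = c1 * vwx[k] + c2 * sig_w * R::norm_rand();
      vwy[k] = c1 * vwy[k] + c2 * sig_w * R::norm_rand();
      vwz[k] = c1 * vwz[k] + c2 * sig_w * R::norm_rand();
      wx[k] = c1 * wx[k] + c2 * sig_r * R::norm_rand();
      wy[k] = c1 * wy[k] + c2 * sig_r * R::norm_rand();
      wz[k] = c1 * wz[k] + c2 * sig_r * R::norm_rand();
      project_perp(wx[k], wy[k], wz[k], ux[k], uy[k], uz[k]);
    }
    // A: half drift
    for (int i = 0; i < ni; ++i) {
      int s = nf + i;
      S.x[s] += 0.5 * dt * vix[i];
      S.y[s] += 0.5 * dt * viy[i];
      S.z[s] += 0.5 * dt * viz[i];
    }
    for (int k = 0; k < nw; ++k) {
      cx[k] += 0.5 * dt * vwx[k];
      cy[k] += 0.5 * dt * vwy[k];
      cz[k] += 0.5 * dt * vwz[k];
      rodrigues(ux[k], uy[k], uz[k], wx[k], wy[k], wz[k], 0.5 * dt);
    }
    sync_sites();
    if (S.need_rebuild(S.rlist - S.pp.cutoff)) S.build_nlist();
    S.compute_forces();
    // B: half kick
    for (int i = 0; i < ni; ++i) {
      int s = nf + i;
      double f = 0.5 * dt * F_CONV / imass[i];
      vix[i] += f * S.fx[s]; viy[i] += f * S.fy[s]; viz[i] += f * S.fz[s];
    }
    for (int k = 0; k < nw; ++k) {
      int o = S.wO(k), h = S.wH(k);
      double f = 0.5 * dt * F_CONV / mW;
      vwx[k] += f * (S.fx[o] + S.fx[h]);
      vwy[k] += f * (S.fy[o] + S.fy[h]);
      vwz[k] += f * (S.fz[o] + S.fz[h]);
      double dfx = S.fx[h] - S.fx[o], dfy = S.fy[h] - S.fy[o],
             dfz = S.fz[h] - S.fz[o];
      double tx = 0.5 * w_d * (uy[k] * dfz - uz[k] * dfy);
      double ty = 0.5 * w_d * (uz[k] * dfx - ux[k] * dfz);
      double tz = 0.5 * w_d * (ux[k] * dfy - uy[k] * dfx);
      double g = 0.5 * dt * F_CONV / I;
      wx[k] += g * tx; wy[k] += g * ty; wz[k] += g * tz;
      project_perp(wx[k], wy[k], wz[k], ux[k], uy[k], uz[k]);
    }

    if (save_every > 0 && step % save_every == 0) {
      for (int i = 0; i < ni; ++i) {
        int s = nf + i;
        if (!std::isfinite(S.x[s]) || !std::isfinite(S.y[s]) ||
            !std::isfinite(S.z[s]))
          stop("non-finite ion coordinate at step %d (particle %d)", step, i + 1);
        ion_traj[isave + n_save * (i + (std::size_t)0 * ni)] = S.x[s];
        ion_traj[isave + n_save * (i + (std::size_t)1 * ni)] = S.y[s];
        ion_traj[isave + n_save * (i + (std::size_t)2 * ni)] = S.z[s];
        ion_vtraj[isave + n_save * (i + (std::size_t)0 * ni)] = vix[i];
        ion_vtraj[isave + n_save * (i + (std::size_t)1 * ni)] = viy[i];
        ion_vtraj[isave + n_save * (i + (std::size_t)2 * ni)] = viz[i];
      }
      for (int k = 0; k < nw; ++k) {
        int o = S.wO(k);
        if (!std::isfinite(S.x[o]) || !std::isfinite(S.z[o]))
          stop("non-finite solvent coordinate at step %d (molecule %d)",
               step, k + 1);
        wO_traj[isave + n_save * (k + (std::size_t)0 * nw)] = S.x[o];
        wO_traj[isave + n_save * (k + (std::size_t)1 * nw)] = S.y[o];
        wO_traj[isave + n_save * (k + (std::size_t)2 * nw)] = S.z[o];
        dip_traj[isave + n_save * (k + (std::size_t)0 * nw)] = ux[k];
        dip_traj[isave + n_save * (k + (std::size_t)1 * nw)] = uy[k];
        dip_traj[isave + n_save * (k + (std::size_t)2 * nw)] = uz[k];
        wv_traj[isave + n_save * (k + (std::size_t)0 * nw)] = vwx[k];
        wv_traj[isave + n_save * (k + (std::size_t)1 * nw)] = vwy[k];
        wv_traj[isave + n_save * (k + (std::size_t)2 * nw)] = vwz[k];
      }
      times[isave] = step * dt;
      energies[isave] = S.energy;
      ++isave;
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // final state
  NumericMatrix fin_ipos(ni, 3), fin_ivel(ni, 3);
  for (int i = 0; i < ni; ++i) {
    int s = nf + i;
    fin_ipos(i, 0) = S.x[s]; fin_ipos(i, 1) = S.y[s]; fin_ipos(i, 2) = S.z[s];
    fin_ivel(i, 0) = vix[i]; fin_ivel(i, 1) = viy[i]; fin_ivel(i, 2) = viz[i];
  }
  NumericMatrix fin_wcom(nw, 3), fin_wu(nw, 3), fin_wvel(nw, 3),
      fin_womega(nw, 3);
  for (int k = 0; k < nw; ++k) {
    fin_wcom(k, 0) = cx[k]; fin_wcom(k, 1) = cy[k]; fin_wcom(k, 2) = cz[k];
    fin_wu(k, 0) = ux[k]; fin_wu(k, 1) = uy[k]; fin_wu(k, 2) = uz[k];
    fin_wvel(k, 0) = vwx[k]; fin_wvel(k, 1) = vwy[k]; fin_wvel(k, 2) = vwz[k];
    fin_womega(k, 0) = wx[k]; fin_womega(k, 1) = wy[k]; fin_womega(k, 2) = wz[k];
  }

  // initial-force snapshot for validation against the direct pair sum
  sync_sites();
  S.build_nlist();
  S.compute_forces();
  NumericMatrix F_now(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    F_now(i, 0) = S.fx[i]; F_now(i, 1) = S.fy[i]; F_now(i, 2) = S.fz[i];
  }

  ion_traj.attr("dim") = IntegerVector::create(n_save, ni, 3);
  ion_vtraj.attr("dim") = IntegerVector::create(n_save, ni, 3);
  wO_traj.attr("dim") = IntegerVector::create(n_save, nw, 3);
  dip_traj.attr("dim") = IntegerVector::create(n_save, nw, 3);
  wv_traj.attr("dim") = IntegerVector::create(n_save, nw, 3);

  return List::create(
      _["n_save"] = n_save,
      _["times"] = times,
      _["ion_traj"] = ion_traj,
      _["ion_vel"] = ion_vtraj,
      _["wO_traj"] = wO_traj,
      _["dip_traj"] = dip_traj,
      _["w_vel"] = wv_traj,
      _["energies"] = energies,
      _["n_clamped"] = S.n_clamped,
      _["final"] = List::create(
          _["ion_pos"] = fin_ipos, _["ion_vel"] = fin_ivel,
          _["w_com"] = fin_wcom, _["w_u"] = fin_wu,
          _["w_vel"] = fin_wvel, _["w_omega"] = fin_womega),
      _["forces_final"] = F_now);
}
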