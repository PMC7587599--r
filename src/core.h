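#ifndef LLPSMD_CORE_H
#define LLPSMD_CORE_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// Minimum-image displacement for an orthorhombic, fully periodic box.
static inline double min_img(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// division-free variant for hot loops (invL = 1/L precomputed); the
// arithmetic round avoids a libm call on targets without sse4.1 (ties are
// immaterial: both images lie at exactly L/2)
static inline double min_img_i(double d, double L, double invL) {
  double t = d * invL;
  double r = (double)(long long)(t >= 0.0 ? t + 0.5 : t - 0.5);
  return d - L * r;
}

static inline double wrap0(double x, double L) {
  // wrap into [0, L)
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L;
  if (w < 0.0) w = 0.0;
  return w;
}

struct PairList {
  std::vector<int> i, j;
  void clear() { i.clear(); j.clear(); }
  size_t size() const { return i.size(); }
  void push(int a, int b) { i.push_back(a); j.push_back(b); }
};

// Per-bead exclusion table (directly bonded partners only; rigid-body
// exclusion is handled separately through the body id).
struct Exclusions {
  std::vector<std::vector<int>> ex;
  void build(int n, const Rcpp::IntegerMatrix &bonds) {
    ex.assign(n, {});
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      ex[i].push_back(j);
      ex[j].push_back(i);
    }
  }
  bool excluded(int i, int j) const {
    const std::vector<int> &e = ex[i];
    return std::find(e.begin(), e.end(), j) != e.end();
  }
};

// Build candidate pair list with a cell grid (falls back to the O(N^2)
// double loop when the box holds fewer than 3 cells per edge or the system
// is small). Pairs are unordered (i < j), within rlist under minimum image,
// with bonded and same-rigid-body pairs removed.
inline void build_pairs(const std::vector<double> &x, int n,
                        const double box[3], double rlist,
                        const Exclusions &excl,
                        const std::vector<int> &body,
                        PairList &out) {
  out.clear();
  const double rl2 = rlist * rlist;
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = (int)std::floor(box[d] / rlist);
  // a cell grid only pays off when beads outnumber cells (dilute single-chain
  // boxes would spend the rebuild walking empty cells)
  bool use_cells = n > 64 && nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3 &&
                   (double)nc[0] * nc[1] * nc[2] <= (double)n;

  const double ib0 = 1.0 / box[0], ib1 = 1.0 / box[1], ib2 = 1.0 / box[2];
  auto try_pair = [&](int i, int j) {
    double dx = min_img_i(x[3 * i] - x[3 * j], box[0], ib0);
    double dy = min_img_i(x[3 * i + 1] - x[3 * j + 1], box[1], ib1);
    double dz = min_img_i(x[3 * i + 2] - x[3 * j + 2], box[2], ib2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rl2) return;
    if (body[i] >= 0 && body[i] == body[j]) return;
    if (excl.excluded(i, j)) return;
    out.push(i, j);
  };

  if (!use_cells) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) try_pair(i, j);
    return;
  }

  // cap the grid so that memory stays modest for very dilute boxes
  for (int d = 0; d < 3; ++d) nc[d] = std::min(nc[d], 48);
  double cw[3];
  for (int d = 0; d < 3; ++d) cw[d] = box[d] / nc[d];
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1), cellof(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(wrap0(x[3 * i], box[0]) / cw[0]);
    int cy = (int)(wrap0(x[3 * i + 1], box[1]) / cw[1]);
    int cz = (int)(wrap0(x[3 * i + 2], box[2]) / cw[2]);
    if (cx >= nc[0]) cx = nc[0] - 1;
    if (cy >= nc[1]) cy = nc[1] - 1;
    if (cz >= nc[2]) cz = nc[2] - 1;
    int c = (cz * nc[1] + cy) * nc[0] + cx;
    cellof[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  // half stencil: self + 13 neighbours
  static const int off[14][3] = {
      {0, 0, 0},  {1, 0, 0},  {-1, 1, 0}, {0, 1, 0},  {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
      {1, 0, 1},  {-1, 1, 1}, {0, 1, 1},  {1, 1, 1}};
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int c = (cz * nc[1] + cy) * nc[0] + cx;
        for (int s = 0; s < 14; ++s) {
          int ox = (cx + off[s][0] + nc[0]) % nc[0];
          int oy = (cy + off[s][1] + nc[1]) % nc[1];
          int oz = (cz + off[s][2] + nc[2]) % nc[2];
          int c2 = (oz * nc[1] + oy) * nc[0] + ox;
          if (s > 0 && c2 == c) continue; // tiny grids: neighbour wraps to self
          for (int i = head[c]; i >= 0; i = nxt[i]) {
            for (int j = (c2 == c ? nxt[i] : head[c2]); j >= 0; j = nxt[j]) {
              if (c2 != c && j == i) continue;
              try_pair(std::min(i, j), std::max(i, j));
            }
          }
        }
      }
}

struct ForceParams {
  double sigma, rcut, kbond, r0, theta0;
  // species-pair epsilon, row-major n_sp x n_sp
  std::vector<double> eps;
  int n_sp;
  bool cap;       // cap the LJ core (construction / annealing only)
  double cap_r;   // cap radius in units of sigma (default 0.3)
  double eps_of(int si, int sj) const { return eps[si * n_sp + sj]; }
};

struct EnergyReport {
  double e_lj = 0, e_bond = 0, e_angle = 0, virial = 0;
  double eps_in_cut = 0; // sum of pair eps over pairs inside the cutoff;
                         // times the per-eps cutoff value this is the tail
                         // that a shifted convention would subtract
  int n_overlap = 0;
  double min_r2 = 1e30;
  double total() const { return e_lj + e_bond + e_angle; }
};

// LJ energy and force magnitude over r (f_over_r) at squared distance r2,
// for eps = 1; caller scales by eps. Truncated, unshifted at rcut.
static inline void lj_eval(double r2, double sigma2, double &e, double &fr) {
  double inv_r2 = 1.0 / r2;
  double s2 = sigma2 * inv_r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  e = 4.0 * (s12 - s6);
  fr = 24.0 * (2.0 * s12 - s6) * inv_r2;
}

// Evaluate all forces and energies. `pairs` must contain every non-excluded
// pair within rcut (it may contain more; distances are re-checked).
inline EnergyReport eval_forces(const std::vector<double> &x, int n,
                                const double box[3], const PairList &pairs,
                                const Rcpp::IntegerMatrix &bonds,
                                const Rcpp::IntegerMatrix &angles,
                                const std::vector<double> &angle_k,
                                const std::vector<int> &species,
                                const ForceParams &fp,
                                std::vector<double> &f) {
  EnergyReport rep;
  std::fill(f.begin(), f.end(), 0.0);
  const double ib0 = 1.0 / box[0], ib1 = 1.0 / box[1], ib2 = 1.0 / box[2];
  const double rc2 = fp.rcut * fp.rcut;
  const double sigma2 = fp.sigma * fp.sigma;
  const double capr = fp.cap_r * fp.sigma;
  const double capr2 = capr * capr;
  double e_cap1 = 0, fr_cap1 = 0;
  if (fp.cap) {
    lj_eval(capr2, sigma2, e_cap1, fr_cap1); // eps = 1 reference values
  }
  const size_t np = pairs.size();
  for (size_t p = 0; p < np; ++p) {
    int i = pairs.i[p], j = pairs.j[p];
    double dx = min_img_i(x[3 * i] - x[3 * j], box[0], ib0);
    double dy = min_img_i(x[3 * i + 1] - x[3 * j + 1], box[1], ib1);
    double dz = min_img_i(x[3 * i + 2] - x[3 * j + 2], box[2], ib2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    if (r2 < rep.min_r2) rep.min_r2 = r2;
    double eps = fp.eps_of(species[i], species[j]);
    rep.eps_in_cut += eps;
    double e, fr;
    if (r2 < capr2 * (1.0 + 1e-12)) {
      ++rep.n_overlap;
      if (fp.cap) {
        // linear continuation below the cap radius: constant repulsive force
        double r = std::sqrt(r2);
        double fmag = eps * fr_cap1 * capr; // |F|(capr)
        e = eps * e_cap1 + fmag * (capr - r);
        fr = fmag / std::max(r, 1e-12);
      } else {
        lj_eval(r2, sigma2, e, fr);
        e *= eps;
        fr *= eps;
      }
    } else {
      lj_eval(r2, sigma2, e, fr);
      e *= eps;
      fr *= eps;
    }
    rep.e_lj += e;
    f[3 * i] += fr * dx;
    f[3 * i + 1] += fr * dy;
    f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx;
    f[3 * j + 1] -= fr * dy;
    f[3 * j + 2] -= fr * dz;
    rep.virial += fr * r2;
  }

  // bonds: u = kbond (r - r0)^2 (no 1/2 prefactor)
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = min_img(x[3 * i] - x[3 * j], box[0]);
    double dy = min_img(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double dz = min_img(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - fp.r0;
    rep.e_bond += fp.kbond * dr * dr;
    double fr = -2.0 * fp.kbond * dr / std::max(r, 1e-12);
    f[3 * i] += fr * dx;
    f[3 * i + 1] += fr * dy;
    f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx;
    f[3 * j + 1] -= fr * dy;
    f[3 * j + 2] -= fr * dz;
    rep.virial += fr * r * r;
  }

  // angles: u = k (theta - theta0)^2, theta0 = pi in this model.
  // Stable near theta = pi: a = -2k(theta-theta0)/sin(theta) -> 2k h/sin(h)
  // with h = pi - theta, evaluated by series for small h.
  for (int a = 0; a < angles.nrow(); ++a) {
    int i1 = angles(a, 0), i2 = angles(a, 1), i3 = angles(a, 2);
    double k = angle_k[a];
    if (k == 0.0) continue;
    double d1x = min_img(x[3 * i1] - x[3 * i2], box[0]);
    double d1y = min_img(x[3 * i1 + 1] - x[3 * i2 + 1], box[1]);
    double d1z = min_img(x[3 * i1 + 2] - x[3 * i2 + 2], box[2]);
    double d2x = min_img(x[3 * i3] - x[3 * i2], box[0]);
    double d2y = min_img(x[3 * i3 + 1] - x[3 * i2 + 1], box[1]);
    double d2z = min_img(x[3 * i3 + 2] - x[3 * i2 + 2], box[2]);
    double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
    double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
    double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    c = std::max(-1.0, std::min(1.0, c));
    double theta = std::acos(c);
    double dth = theta - fp.theta0;
    rep.e_angle += k * dth * dth;
    double aa;
    if (fp.theta0 == M_PI) {
      double h = M_PI - theta; // >= 0
      double ratio = (h < 1e-4) ? (1.0 + h * h / 6.0)
                                : (h / std::sin(h));
      aa = 2.0 * k * ratio;
    } else {
      double s = std::sin(theta);
      if (s < 1e-8) s = 1e-8;
      aa = -2.0 * k * dth / s;
    }
    double a11 = aa * c / rsq1;
    double a12 = -aa / (r1 * r2);
    double a22 = aa * c / rsq2;
    double f1x = a11 * d1x + a12 * d2x;
    double f1y = a11 * d1y + a12 * d2y;
    double f1z = a11 * d1z + a12 * d2z;
    double f3x = a22 * d2x + a12 * d1x;
    double f3y = a22 * d2y + a12 * d1y;
    double f3z = a22 * d2z + a12 * d1z;
    f[3 * i1] += f1x;
    f[3 * i1 + 1] += f1y;
    f[3 * i1 + 2] += f1z;
    f[3 * i3] += f3x;
    f[3 * i3 + 1] += f3y;
    f[3 * i3 + 2] += f3z;
    f[3 * i2] -= f1x + f3x;
    f[3 * i2 + 1] -= f1y + f3y;
    f[3 * i2 + 2] -= f1z + f3z;
    rep.virial += d1x * f1x + d1y * f1y + d1z * f1z +
                  d2x * f3x + d2y * f3y + d2z * f3z;
  }
  return rep;
}

#endif
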