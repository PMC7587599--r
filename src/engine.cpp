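#include "core.h"
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small dense 3x3 symmetric eigen-solver (cyclic Jacobi) for inertia tensors
// ---------------------------------------------------------------------------
static void jacobi3(double A[3][3], double eval[3], double evec[3][3]) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      a[i][j] = A[i][j];
      evec[i][j] = (i == j) ? 1.0 : 0.0;
    }
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-18) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double cph = 1.0 / std::sqrt(t * t + 1.0), sph = t * cph;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = cph * akp - sph * akq;
          a[k][q] = sph * akp + cph * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = cph * apk - sph * aqk;
          a[q][k] = sph * apk + cph * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = evec[k][p], vkq = evec[k][q];
          evec[k][p] = cph * vkp - sph * vkq;
          evec[k][q] = sph * vkp + cph * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) eval[i] = a[i][i];
}

// ---------------------------------------------------------------------------
// quaternion helpers (q = [w, x, y, z]; A maps body frame -> space frame)
// ---------------------------------------------------------------------------
static inline void quat_to_mat(const double q[4], double A[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  A[0][0] = 1 - 2 * (y * y + z * z);
  A[0][1] = 2 * (x * y - w * z);
  A[0][2] = 2 * (x * z + w * y);
  A[1][0] = 2 * (x * y + w * z);
  A[1][1] = 1 - 2 * (x * x + z * z);
  A[1][2] = 2 * (y * z - w * x);
  A[2][0] = 2 * (x * z - w * y);
  A[2][1] = 2 * (y * z + w * x);
  A[2][2] = 1 - 2 * (x * x + y * y);
}

static inline void mat_to_quat(const double A[3][3], double q[4]) {
  double tr = A[0][0] + A[1][1] + A[2][2];
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2;
    q[0] = 0.25 * s;
    q[1] = (A[2][1] - A[1][2]) / s;
    q[2] = (A[0][2] - A[2][0]) / s;
    q[3] = (A[1][0] - A[0][1]) / s;
  } else if (A[0][0] > A[1][1] && A[0][0] > A[2][2]) {
    double s = std::sqrt(1.0 + A[0][0] - A[1][1] - A[2][2]) * 2;
    q[0] = (A[2][1] - A[1][2]) / s;
    q[1] = 0.25 * s;
    q[2] = (A[0][1] + A[1][0]) / s;
    q[3] = (A[0][2] + A[2][0]) / s;
  } else if (A[1][1] > A[2][2]) {
    double s = std::sqrt(1.0 + A[1][1] - A[0][0] - A[2][2]) * 2;
    q[0] = (A[0][2] - A[2][0]) / s;
    q[1] = (A[0][1] + A[1][0]) / s;
    q[2] = 0.25 * s;
    q[3] = (A[1][2] + A[2][1]) / s;
  } else {
    double s = std::sqrt(1.0 + A[2][2] - A[0][0] - A[1][1]) * 2;
    q[0] = (A[1][0] - A[0][1]) / s;
    q[1] = (A[0][2] + A[2][0]) / s;
    q[2] = (A[1][2] + A[2][1]) / s;
    q[3] = 0.25 * s;
  }
  double nrm = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= nrm;
}

// left-multiply q by the rotation of angle |w|*dt about axis w (space frame)
static inline void quat_rotate(double q[4], const double w[3], double dt) {
  double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (wn < 1e-300) return;
  double half = 0.5 * wn * dt;
  double c = std::cos(half), s = std::sin(half) / wn;
  double dq[4] = {c, s * w[0], s * w[1], s * w[2]};
  double r[4];
  r[0] = dq[0] * q[0] - dq[1] * q[1] - dq[2] * q[2] - dq[3] * q[3];
  r[1] = dq[0] * q[1] + dq[1] * q[0] + dq[2] * q[3] - dq[3] * q[2];
  r[2] = dq[0] * q[2] - dq[1] * q[3] + dq[2] * q[0] + dq[3] * q[1];
  r[3] = dq[0] * q[3] + dq[1] * q[2] - dq[2] * q[1] + dq[3] * q[0];
  double nrm = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2] + r[3] * r[3]);
  for (int k = 0; k < 4; ++k) q[k] = r[k] / nrm;
}

struct RigidBody {
  std::vector<int> members;
  double M = 0;
  std::vector<double> ref; // body-frame (principal axes) coordinates
  double Ibody[3] = {0, 0, 0};
  double q[4] = {1, 0, 0, 0};
  double xcm[3] = {0, 0, 0};
  double vcm[3] = {0, 0, 0};
  double L[3] = {0, 0, 0}; // space-frame angular momentum about the COM

  void omega_space(double w[3]) const {
    double A[3][3];
    quat_to_mat(q, A);
    // w = A I^-1 A^T L
    double Lb[3] = {0, 0, 0}, wb[3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Lb[i] += A[j][i] * L[j];
    for (int i = 0; i < 3; ++i)
      wb[i] = (Ibody[i] > 1e-12) ? Lb[i] / Ibody[i] : 0.0;
    for (int i = 0; i < 3; ++i) {
      w[i] = 0;
      for (int j = 0; j < 3; ++j) w[i] += A[i][j] * wb[j];
    }
  }

  double kinetic2() const { // 2 * kinetic energy
    double w[3];
    omega_space(w);
    double A[3][3];
    quat_to_mat(q, A);
    double wb[3] = {0, 0, 0};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) wb[i] += A[j][i] * w[j];
    double ke2 = M * (vcm[0] * vcm[0] + vcm[1] * vcm[1] + vcm[2] * vcm[2]);
    for (int i = 0; i < 3; ++i) ke2 += Ibody[i] * wb[i] * wb[i];
    return ke2;
  }

  void set_bead_positions(std::vector<double> &x) const {
    double A[3][3];
    quat_to_mat(q, A);
    for (size_t m = 0; m < members.size(); ++m) {
      int i = members[m];
      for (int d = 0; d < 3; ++d)
        x[3 * i + d] = xcm[d] + A[d][0] * ref[3 * m] +
                       A[d][1] * ref[3 * m + 1] + A[d][2] * ref[3 * m + 2];
    }
  }

  void set_bead_velocities(const std::vector<double> &x,
                           std::vector<double> &v) const {
    double w[3];
    omega_space(w);
    for (size_t m = 0; m < members.size(); ++m) {
      int i = members[m];
      double rx = x[3 * i] - xcm[0], ry = x[3 * i + 1] - xcm[1],
             rz = x[3 * i + 2] - xcm[2];
      v[3 * i] = vcm[0] + w[1] * rz - w[2] * ry;
      v[3 * i + 1] = vcm[1] + w[2] * rx - w[0] * rz;
      v[3 * i + 2] = vcm[2] + w[0] * rx - w[1] * ry;
    }
  }
};

static std::vector<RigidBody> setup_bodies(const std::vector<double> &x,
                                           const std::vector<double> &v,
                                           const std::vector<double> &mass,
                                           const std::vector<int> &body,
                                           int n_bodies) {
  std::vector<RigidBody> bodies(n_bodies);
  int n = (int)mass.size();
  for (int i = 0; i < n; ++i)
    if (body[i] >= 0) bodies[body[i]].members.push_back(i);
  for (auto &b : bodies) {
    for (int i : b.members) {
      b.M += mass[i];
      for (int d = 0; d < 3; ++d) b.xcm[d] += mass[i] * x[3 * i + d];
    }
    for (int d = 0; d < 3; ++d) b.xcm[d] /= b.M;
    double I[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int i : b.members) {
      double r[3];
      for (int d = 0; d < 3; ++d) r[d] = x[3 * i + d] - b.xcm[d];
      double r2 = r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < 3; ++c)
          I[a][c] += mass[i] * ((a == c ? r2 : 0.0) - r[a] * r[c]);
    }
    double eval[3], evec[3][3];
    jacobi3(I, eval, evec);
    // right-handed principal frame
    double det = evec[0][0] * (evec[1][1] * evec[2][2] - evec[1][2] * evec[2][1]) -
                 evec[0][1] * (evec[1][0] * evec[2][2] - evec[1][2] * evec[2][0]) +
                 evec[0][2] * (evec[1][0] * evec[2][1] - evec[1][1] * evec[2][0]);
    if (det < 0)
      for (int k = 0; k < 3; ++k) evec[k][2] = -evec[k][2];
    for (int d = 0; d < 3; ++d) b.Ibody[d] = std::max(eval[d], 0.0);
    double A[3][3];
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) A[a][c] = evec[a][c];
    mat_to_quat(A, b.q);
    b.ref.resize(3 * b.members.size());
    for (size_t m = 0; m < b.members.size(); ++m) {
      int i = b.members[m];
      double r[3];
      for (int d = 0; d < 3; ++d) r[d] = x[3 * i + d] - b.xcm[d];
      for (int d = 0; d < 3; ++d)
        b.ref[3 * m + d] = A[0][d] * r[0] + A[1][d] * r[1] + A[2][d] * r[2];
    }
    // project velocities onto rigid motion
    for (int i : b.members)
      for (int d = 0; d < 3; ++d) b.vcm[d] += mass[i] * v[3 * i + d];
    for (int d = 0; d < 3; ++d) b.vcm[d] /= b.M;
    for (int i : b.members) {
      double r[3], u[3];
      for (int d = 0; d < 3; ++d) {
        r[d] = x[3 * i + d] - b.xcm[d];
        u[d] = v[3 * i + d];
      }
      b.L[0] += mass[i] * (r[1] * u[2] - r[2] * u[1]);
      b.L[1] += mass[i] * (r[2] * u[0] - r[0] * u[2]);
      b.L[2] += mass[i] * (r[0] * u[1] - r[1] * u[0]);
    }
    double Mx[3] = {0, 0, 0}; // subtract COM part: L about COM of m*vcm terms
    for (int d = 0; d < 3; ++d) Mx[d] = b.vcm[d];
    // sum m r x vcm = (sum m r) x vcm = 0 about the COM, nothing to subtract
    (void)Mx;
  }
  return bodies;
}

// ---------------------------------------------------------------------------
// Nose-Hoover chain thermostat (length M, applied as a half-step wrapper)
// ---------------------------------------------------------------------------
// small deterministic RNG for the Langevin kicks (xoshiro256++ seeded by
// splitmix64 from the run seed; polar Box-Muller normals). Much cheaper than
// calling back into R's generator several times per bead per step.
struct GaussRng {
  uint64_t s[4];
  double spare = 0;
  bool has_spare = false;
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) { // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
    has_spare = false;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

struct NHC {
  int M = 3;
  double kT = 1.0, g = 1.0;
  std::vector<double> Q, xi, vxi;
  void init(int M_, double kT_, double g_, double tau) {
    M = M_;
    kT = kT_;
    g = g_;
    Q.assign(M, kT * tau * tau);
    Q[0] = g * kT * tau * tau;
    xi.assign(M, 0.0);
    vxi.assign(M, 0.0);
  }
  // returns the velocity scale factor for a half step dt2
  double update(double ke2, double dt2) {
    double dt4 = dt2 / 2, dt8 = dt2 / 4;
    std::vector<double> G(M);
    G[0] = (ke2 - g * kT) / Q[0];
    for (int j = 1; j < M; ++j)
      G[j] = (Q[j - 1] * vxi[j - 1] * vxi[j - 1] - kT) / Q[j];
    vxi[M - 1] += G[M - 1] * dt4;
    for (int j = M - 2; j >= 0; --j) {
      vxi[j] *= std::exp(-vxi[j + 1] * dt8);
      vxi[j] += G[j] * dt4;
      vxi[j] *= std::exp(-vxi[j + 1] * dt8);
    }
    double s = std::exp(-vxi[0] * dt2);
    ke2 *= s * s;
    for (int j = 0; j < M; ++j) xi[j] += vxi[j] * dt2;
    G[0] = (ke2 - g * kT) / Q[0];
    for (int j = 0; j < M - 1; ++j) {
      vxi[j] *= std::exp(-vxi[j + 1] * dt8);
      vxi[j] += G[j] * dt4;
      vxi[j] *= std::exp(-vxi[j + 1] * dt8);
      G[j + 1] = (Q[j] * vxi[j] * vxi[j] - kT) / Q[j + 1];
    }
    vxi[M - 1] += G[M - 1] * dt4;
    return s;
  }
};

// ---------------------------------------------------------------------------
// exported: single-point energy/forces
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix x, NumericVector box,
                       IntegerMatrix bonds, IntegerMatrix angles,
                       NumericVector angle_k, IntegerVector species,
                       NumericMatrix epsmat, double sigma, double rcut,
                       double kbond, double r0, double theta0,
                       IntegerVector body, bool cap, double cap_r) {
  int n = x.nrow();
  std::vector<double> xv(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) xv[3 * i + d] = x(i, d);
  double bx[3] = {box[0], box[1], box[2]};
  Exclusions excl;
  excl.build(n, bonds);
  std::vector<int> bodyv(body.begin(), body.end());
  std::vector<int> sp(species.begin(), species.end());
  ForceParams fp;
  fp.sigma = sigma;
  fp.rcut = rcut;
  fp.kbond = kbond;
  fp.r0 = r0;
  fp.theta0 = theta0;
  fp.n_sp = epsmat.nrow();
  fp.eps.assign(epsmat.begin(), epsmat.end()); // symmetric: order irrelevant
  fp.cap = cap;
  fp.cap_r = cap_r;
  PairList pairs;
  build_pairs(xv, n, bx, rcut, excl, bodyv, pairs);
  std::vector<double> ak(angle_k.begin(), angle_k.end());
  EnergyReport rep = eval_forces(xv, n, bx, pairs, bonds, angles, ak, sp, fp, f);
  NumericMatrix fo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fo(i, d) = f[3 * i + d];
  return List::create(
      _["energy"] = rep.total(), _["e_lj"] = rep.e_lj, _["e_bond"] = rep.e_bond,
      _["e_angle"] = rep.e_angle, _["virial"] = rep.virial,
      _["forces"] = fo, _["n_overlap"] = rep.n_overlap,
      _["min_distance"] = std::sqrt(rep.min_r2));
}

// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix x, NumericVector box,
                                 double rlist, IntegerMatrix bonds,
                                 IntegerVector body) {
  int n = x.nrow();
  std::vector<double> xv(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) xv[3 * i + d] = x(i, d);
  double bx[3] = {box[0], box[1], box[2]};
  Exclusions excl;
  excl.build(n, bonds);
  std::vector<int> bodyv(body.begin(), body.end());
  PairList pairs;
  build_pairs(xv, n, bx, rlist, excl, bodyv, pairs);
  IntegerMatrix out(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs.i[p] + 1; // 1-based for R
    out(p, 1) = pairs.j[p] + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix project_rigid_velocities_cpp(NumericMatrix x, NumericMatrix v,
                                           NumericVector mass,
                                           IntegerVector body, int n_bodies) {
  int n = x.nrow();
  std::vector<double> xv(3 * n), vv(3 * n), mv(mass.begin(), mass.end());
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xv[3 * i + d] = x(i, d);
      vv[3 * i + d] = v(i, d);
    }
  std::vector<int> bodyv(body.begin(), body.end());
  std::vector<RigidBody> bodies = setup_bodies(xv, vv, mv, bodyv, n_bodies);
  for (auto &b : bodies) b.set_bead_velocities(xv, vv);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = vv[3 * i + d];
  return out;
}

// ---------------------------------------------------------------------------
// exported: the MD driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_md_cpp(NumericMatrix x0, NumericMatrix v0, NumericVector box0,
                NumericVector mass, IntegerMatrix bonds, IntegerMatrix angles,
                NumericVector angle_k, IntegerVector species,
                NumericMatrix epsmat, double sigma, double rcut, double kbond,
                double r0, double theta0, IntegerVector body, int n_bodies,
                List settings) {
  const int n = x0.nrow();
  const double dt = as<double>(settings["dt"]);
  const int n_steps = as<int>(settings["n_steps"]);
  const std::string ensemble = as<std::string>(settings["ensemble"]);
  const std::string thermostat = as<std::string>(settings["thermostat"]);
  const double T_target = as<double>(settings["T_target"]);
  const double p_target = as<double>(settings["p_target"]);
  const double tau_t = as<double>(settings["thermostat_tau"]);
  const double tau_p = as<double>(settings["barostat_tau"]);
  const double skin = as<double>(settings["neighbor_skin"]);
  const int thermo_every = as<int>(settings["thermo_every"]);
  const int snap_every = as<int>(settings["snapshot_every"]);
  const bool cap = as<bool>(settings["cap_lj"]);
  const double cap_r = as<double>(settings["cap_r"]);
  const std::string npt_axis = as<std::string>(settings["npt_axis"]);
  const double kappa = as<double>(settings["barostat_compressibility"]);
  const double abort_e = as<double>(settings["abort_energy_per_bead"]);
  const double t0 = as<double>(settings["time0"]);

  const bool nvt = (ensemble == "nvt" || ensemble == "npt");
  const bool npt = (ensemble == "npt");
  const bool langevin = nvt && thermostat == "langevin";
  const bool nose = nvt && !langevin;
  const int p_every = 10; // barostat application stride

  std::vector<double> x(3 * n), v(3 * n), f(3 * n, 0.0),
      mv(mass.begin(), mass.end());
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = x0(i, d);
      v[3 * i + d] = v0(i, d);
    }
  double box[3] = {box0[0], box0[1], box0[2]};
  std::vector<int> bodyv(body.begin(), body.end());
  std::vector<int> sp(species.begin(), species.end());
  std::vector<double> ak(angle_k.begin(), angle_k.end());

  Exclusions excl;
  excl.build(n, bonds);
  ForceParams fp;
  fp.sigma = sigma;
  fp.rcut = rcut;
  fp.kbond = kbond;
  fp.r0 = r0;
  fp.theta0 = theta0;
  fp.n_sp = epsmat.nrow();
  fp.eps.assign(epsmat.begin(), epsmat.end());
  fp.cap = cap;
  fp.cap_r = cap_r;

  std::vector<RigidBody> bodies;
  std::vector<bool> is_rigid_bead(n, false);
  int n_free = n;
  if (n_bodies > 0) {
    bodies = setup_bodies(x, v, mv, bodyv, n_bodies);
    for (auto &b : bodies) {
      b.set_bead_positions(x);
      b.set_bead_velocities(x, v);
      n_free -= (int)b.members.size();
      for (int i : b.members) is_rigid_bead[i] = true;
    }
    if (langevin)
      stop("Langevin dynamics is not available for rigid-body systems; use the Nose-Hoover thermostat.");
  }
  const double dof = 3.0 * n_free + 6.0 * n_bodies - (langevin ? 0.0 : 3.0);

  auto kinetic2 = [&]() {
    double ke2 = 0.0;
    for (int i = 0; i < n; ++i)
      if (!is_rigid_bead[i])
        ke2 += mv[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                        v[3 * i + 2] * v[3 * i + 2]);
    for (auto &b : bodies) ke2 += b.kinetic2();
    return ke2;
  };

  NHC nhc;
  if (nose) nhc.init(3, T_target, dof, tau_t);
  const double c1 = langevin ? std::exp(-dt / tau_t) : 0.0;
  const double c2 = langevin ? std::sqrt((1.0 - c1 * c1) * T_target) : 0.0;
  GaussRng rng;
  rng.seed((uint64_t)as<int>(settings["seed"]) * 2654435761ULL + 17ULL);

  // neighbour list management
  PairList pairs;
  std::vector<double> x_ref(3 * n);
  auto rebuild = [&]() {
    build_pairs(x, n, box, rcut + skin, excl, bodyv, pairs);
    x_ref = x;
  };
  auto needs_rebuild = [&]() {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - x_ref[3 * i], dy = x[3 * i + 1] - x_ref[3 * i + 1],
             dz = x[3 * i + 2] - x_ref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  };

  rebuild();
  EnergyReport rep =
      eval_forces(x, n, box, pairs, bonds, angles, ak, sp, fp, f);

  // per-body force/torque aggregation
  std::vector<double> Fb(3 * n_bodies), Tb(3 * n_bodies);
  auto aggregate = [&]() {
    std::fill(Fb.begin(), Fb.end(), 0.0);
    std::fill(Tb.begin(), Tb.end(), 0.0);
    for (int bi = 0; bi < n_bodies; ++bi) {
      RigidBody &b = bodies[bi];
      for (int i : b.members) {
        double rx = x[3 * i] - b.xcm[0], ry = x[3 * i + 1] - b.xcm[1],
               rz = x[3 * i + 2] - b.xcm[2];
        Fb[3 * bi] += f[3 * i];
        Fb[3 * bi + 1] += f[3 * i + 1];
        Fb[3 * bi + 2] += f[3 * i + 2];
        Tb[3 * bi] += ry * f[3 * i + 2] - rz * f[3 * i + 1];
        Tb[3 * bi + 1] += rz * f[3 * i] - rx * f[3 * i + 2];
        Tb[3 * bi + 2] += rx * f[3 * i + 1] - ry * f[3 * i];
      }
    }
  };
  if (n_bodies > 0) aggregate();

  auto half_kick = [&]() {
    double h = 0.5 * dt;
    for (int i = 0; i < n; ++i)
      if (!is_rigid_bead[i]) {
        double im = h / mv[i];
        v[3 * i] += im * f[3 * i];
        v[3 * i + 1] += im * f[3 * i + 1];
        v[3 * i + 2] += im * f[3 * i + 2];
      }
    for (int bi = 0; bi < n_bodies; ++bi) {
      RigidBody &b = bodies[bi];
      for (int d = 0; d < 3; ++d) {
        b.vcm[d] += h * Fb[3 * bi + d] / b.M;
        b.L[d] += h * Tb[3 * bi + d];
      }
    }
  };

  auto drift = [&](double h) {
    for (int i = 0; i < n; ++i)
      if (!is_rigid_bead[i]) {
        x[3 * i] += h * v[3 * i];
        x[3 * i + 1] += h * v[3 * i + 1];
        x[3 * i + 2] += h * v[3 * i + 2];
      }
    for (auto &b : bodies) {
      for (int d = 0; d < 3; ++d) b.xcm[d] += h * b.vcm[d];
      double w[3];
      b.omega_space(w);
      quat_rotate(b.q, w, h);
      b.set_bead_positions(x);
    }
  };

  auto scale_velocities = [&](double s) {
    for (int i = 0; i < n; ++i)
      if (!is_rigid_bead[i]) {
        v[3 * i] *= s;
        v[3 * i + 1] *= s;
        v[3 * i + 2] *= s;
      }
    for (auto &b : bodies)
      for (int d = 0; d < 3; ++d) {
        b.vcm[d] *= s;
        b.L[d] *= s;
      }
  };

  // output buffers
  int n_thermo = n_steps / thermo_every + 1;
  int n_snap = n_steps / snap_every + 1;
  NumericMatrix thermo(n_thermo, 11);
  NumericVector frames(Dimension(n, 3, n_snap));
  NumericVector frame_times(n_snap), frame_boxz(n_snap);
  NumericMatrix frame_box(n_snap, 3);
  int it = 0, isnap = 0;

  double volume = box[0] * box[1] * box[2];
  auto record = [&](int step) {
    double ke2 = kinetic2();
    double Tk = ke2 / dof;
    double press = (ke2 / 3.0 + rep.virial / 3.0) / volume;
    if (step % thermo_every == 0 && it < n_thermo) {
      thermo(it, 0) = step;
      thermo(it, 1) = t0 + step * dt;
      thermo(it, 2) = Tk;
      thermo(it, 3) = press;
      thermo(it, 4) = rep.e_lj;
      thermo(it, 5) = rep.e_bond;
      thermo(it, 6) = rep.e_angle;
      thermo(it, 7) = ke2 / 2.0;
      thermo(it, 8) = rep.total() + ke2 / 2.0;
      thermo(it, 9) = n / volume * sigma * sigma * sigma;
      thermo(it, 10) = rep.eps_in_cut;
      ++it;
    }
    if (step % snap_every == 0 && isnap < n_snap) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[i + n * d + (R_xlen_t)3 * n * isnap] = x[3 * i + d];
      frame_times[isnap] = t0 + step * dt;
      for (int d = 0; d < 3; ++d) frame_box(isnap, d) = box[d];
      ++isnap;
    }
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    if (nose) {
      double s = nhc.update(kinetic2(), 0.5 * dt);
      scale_velocities(s);
    }
    half_kick();
    if (langevin) {
      drift(0.5 * dt);
      for (int i = 0; i < n; ++i) {
        double sd = c2 / std::sqrt(mv[i]);
        v[3 * i] = c1 * v[3 * i] + sd * rng.normal();
        v[3 * i + 1] = c1 * v[3 * i + 1] + sd * rng.normal();
        v[3 * i + 2] = c1 * v[3 * i + 2] + sd * rng.normal();
      }
      drift(0.5 * dt);
    } else {
      drift(dt);
    }
    if (needs_rebuild()) rebuild();
    rep = eval_forces(x, n, box, pairs, bonds, angles, ak, sp, fp, f);
    if (n_bodies > 0) aggregate();
    half_kick();
    if (nose) {
      double s = nhc.update(kinetic2(), 0.5 * dt);
      scale_velocities(s);
    }

    if (npt && step % p_every == 0) {
      double ke2 = kinetic2();
      double press = (ke2 / 3.0 + rep.virial / 3.0) / volume;
      double mu3 = 1.0 - (p_every * dt / tau_p) * kappa * (p_target - press);
      mu3 = std::max(0.97, std::min(1.03, mu3));
      if (npt_axis == "z") {
        box[2] *= mu3;
        for (int i = 0; i < n; ++i) x[3 * i + 2] *= mu3;
        for (auto &b : bodies) b.xcm[2] *= mu3;
      } else {
        double mu = std::cbrt(mu3);
        for (int d = 0; d < 3; ++d) box[d] *= mu;
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) x[3 * i + d] *= mu;
        for (auto &b : bodies)
          for (int d = 0; d < 3; ++d) b.xcm[d] *= mu;
      }
      if (n_bodies > 0)
        for (auto &b : bodies) b.set_bead_positions(x); // COM moved, beads follow
      volume = box[0] * box[1] * box[2];
      rebuild();
      rep = eval_forces(x, n, box, pairs, bonds, angles, ak, sp, fp, f);
      if (n_bodies > 0) aggregate();
    }

    if (step % thermo_every == 0 || step % snap_every == 0) {
      double etot = rep.total() + kinetic2() / 2.0;
      if (!std::isfinite(etot) || etot / n > abort_e)
        stop("numeric blow-up at step %d: total energy %g per bead", step,
             etot / n);
      record(step);
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = x[3 * i + d];
      vout(i, d) = v[3 * i + d];
    }
  colnames(thermo) = CharacterVector::create(
      "step", "time", "T_kin", "p", "e_lj", "e_bond", "e_angle", "e_kin",
      "e_total", "rho", "eps_in_cutoff");
  return List::create(
      _["frames"] = frames, _["frame_times"] = frame_times,
      _["frame_box"] = frame_box, _["thermo"] = thermo, _["x"] = xout,
      _["v"] = vout, _["box"] = NumericVector::create(box[0], box[1], box[2]),
      _["n_overlap"] = rep.n_overlap);
}
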