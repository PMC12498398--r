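// Kern-Frenkel patchy-particle Monte Carlo engine.
//
// Reduced units: sigma = 1, reference bond energy = 1, k_B = 1. Cubic
// periodic boxes, minimum-image convention. Orientations are unit
// quaternions; patch directions are body-frame unit vectors rotated on the
// fly. Uses R's RNG so runs are reproducible with set.seed().
//
// Move set: single-particle translations and rotations, aggregation-volume-
// bias (AVB) in/out moves on bonding shells, log-volume moves (NPT), paired
// log-volume exchange and particle transfer (Gibbs ensemble), and
// insertion/deletion (grand canonical). Transfers and insertions can be
// orientationally biased into the bonding shell of a random target particle;
// the generation densities of both the biased and the uniform channel enter
// the acceptance rule exactly, so detailed balance holds for any bias
// probability.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;
static const double E_INF = 1e30;  // hard-core overlap sentinel

struct Design {
  int nsp = 0, ntypes = 0;
  std::vector<double> eps;        // ntypes x ntypes, column-major
  std::vector<int> p_off, p_cnt;  // per-species patch offset/count
  std::vector<double> pvec;       // 3 x total_patches, body frame
  std::vector<int> ptype;         // global type per patch (0-based)
  double sigma = 1, delta = 0.2, ctm = 0.98;
  double rc2 = 0;                 // (sigma+delta)^2
  int max_gamma = 0;
};

struct Box {
  double L = 0;
  std::vector<double> pos;   // 3N
  std::vector<double> quat;  // 4N (w, x, y, z)
  std::vector<int> sp;       // species, 0-based
  double E = 0;
  int n() const { return (int)sp.size(); }
};

static inline double runi() { return unif_rand(); }

// quaternion (w,x,y,z) to rotation matrix (row-major)
static inline void quat_to_mat(const double* q, double* R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

static inline void quat_mult(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static inline void quat_normalize(double* q) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

static void random_quat(double* q) {
  // Shoemake's uniform quaternion
  double u1 = runi(), u2 = runi(), u3 = runi();
  double s1 = std::sqrt(1 - u1), s2 = std::sqrt(u1);
  q[0] = s1 * std::sin(2 * PI_ * u2);
  q[1] = s1 * std::cos(2 * PI_ * u2);
  q[2] = s2 * std::sin(2 * PI_ * u3);
  q[3] = s2 * std::cos(2 * PI_ * u3);
}

// rotation quaternion: angle about unit axis
static inline void axis_angle_quat(const double* axis, double ang, double* q) {
  double h = 0.5 * ang, s = std::sin(h);
  q[0] = std::cos(h); q[1] = axis[0] * s; q[2] = axis[1] * s; q[3] = axis[2] * s;
}

static inline void minimg(double& d, double L) { d -= L * std::nearbyint(d / L); }

// Kern-Frenkel pair energy between particles i (pos/quat/species given
// explicitly so trial states can be evaluated) and j in the same box.
static double pair_energy_raw(const Design& D, const double* ri, const double* qi,
                              int si, const double* rj, const double* qj, int sj,
                              double L) {
  double d[3] = { rj[0] - ri[0], rj[1] - ri[1], rj[2] - ri[2] };
  minimg(d[0], L); minimg(d[1], L); minimg(d[2], L);
  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (r2 < D.sigma * D.sigma) return E_INF;
  if (r2 >= D.rc2) return 0.0;
  double r = std::sqrt(r2);
  double rhat[3] = { d[0] / r, d[1] / r, d[2] / r };  // from i to j
  double Ri[9], Rj[9];
  quat_to_mat(qi, Ri); quat_to_mat(qj, Rj);
  double e = 0.0;
  for (int a = 0; a < D.p_cnt[si]; ++a) {
    const double* va = &D.pvec[3 * (D.p_off[si] + a)];
    double pa[3] = { Ri[0] * va[0] + Ri[1] * va[1] + Ri[2] * va[2],
                     Ri[3] * va[0] + Ri[4] * va[1] + Ri[5] * va[2],
                     Ri[6] * va[0] + Ri[7] * va[1] + Ri[8] * va[2] };
    double ca = pa[0] * rhat[0] + pa[1] * rhat[1] + pa[2] * rhat[2];
    if (ca <= D.ctm) continue;
    int ta = D.ptype[D.p_off[si] + a];
    for (int b = 0; b < D.p_cnt[sj]; ++b) {
      double epsab = D.eps[ta + D.ntypes * D.ptype[D.p_off[sj] + b]];
      if (epsab <= 0.0) continue;
      const double* vb = &D.pvec[3 * (D.p_off[sj] + b)];
      double pb[3] = { Rj[0] * vb[0] + Rj[1] * vb[1] + Rj[2] * vb[2],
                       Rj[3] * vb[0] + Rj[4] * vb[1] + Rj[5] * vb[2],
                       Rj[6] * vb[0] + Rj[7] * vb[1] + Rj[8] * vb[2] };
      double cb = -(pb[0] * rhat[0] + pb[1] * rhat[1] + pb[2] * rhat[2]);
      if (cb > D.ctm) e -= epsab;
    }
  }
  return e;
}

// energy of particle i (with optionally overridden state) with all others
static double particle_energy(const Design& D, const Box& B, int i,
                              const double* ri, const double* qi, int si) {
  double e = 0.0;
  for (int j = 0; j < B.n(); ++j) {
    if (j == i) continue;
    e += pair_energy_raw(D, ri, qi, si, &B.pos[3 * j], &B.quat[4 * j], B.sp[j], B.L);
    if (e >= E_INF) return E_INF;
  }
  return e;
}

static double total_energy(const Design& D, const Box& B) {
  double e = 0.0;
  for (int i = 0; i < B.n(); ++i)
    for (int j = i + 1; j < B.n(); ++j) {
      e += pair_energy_raw(D, &B.pos[3 * i], &B.quat[4 * i], B.sp[i],
                           &B.pos[3 * j], &B.quat[4 * j], B.sp[j], B.L);
      if (e >= E_INF) return E_INF;
    }
  return e;
}

// geometric bond criterion for the AVB "in" region: centers within the
// bonding shell and one patch cone of each particle containing the other's
// center direction (patch types and energies are not consulted)
static bool in_region(const Design& D, const double* rj, const double* qj, int sj,
                      const double* rk, const double* qk, int sk, double L) {
  double d[3] = { rk[0] - rj[0], rk[1] - rj[1], rk[2] - rj[2] };
  minimg(d[0], L); minimg(d[1], L); minimg(d[2], L);
  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (r2 < D.sigma * D.sigma || r2 >= D.rc2) return false;
  double r = std::sqrt(r2);
  double rhat[3] = { d[0] / r, d[1] / r, d[2] / r };  // j -> k
  double Rj[9], Rk[9];
  quat_to_mat(qj, Rj); quat_to_mat(qk, Rk);
  bool okj = false;
  for (int a = 0; a < D.p_cnt[sj] && !okj; ++a) {
    const double* v = &D.pvec[3 * (D.p_off[sj] + a)];
    double p[3] = { Rj[0] * v[0] + Rj[1] * v[1] + Rj[2] * v[2],
                    Rj[3] * v[0] + Rj[4] * v[1] + Rj[5] * v[2],
                    Rj[6] * v[0] + Rj[7] * v[1] + Rj[8] * v[2] };
    okj = p[0] * rhat[0] + p[1] * rhat[1] + p[2] * rhat[2] > D.ctm;
  }
  if (!okj) return false;
  for (int b = 0; b < D.p_cnt[sk]; ++b) {
    const double* v = &D.pvec[3 * (D.p_off[sk] + b)];
    double p[3] = { Rk[0] * v[0] + Rk[1] * v[1] + Rk[2] * v[2],
                    Rk[3] * v[0] + Rk[4] * v[1] + Rk[5] * v[2],
                    Rk[6] * v[0] + Rk[7] * v[1] + Rk[8] * v[2] };
    if (-(p[0] * rhat[0] + p[1] * rhat[1] + p[2] * rhat[2]) > D.ctm) return true;
  }
  return false;
}

// shell-cone measures
static inline double v_patch_shell(const Design& D) {
  double w = 0.5 * (1 - D.ctm);
  return 4.0 * PI_ / 3.0 * (std::pow(D.sigma + D.delta, 3) - std::pow(D.sigma, 3)) * w;
}
// (position x orientation) measure of the in region of a (j, k) pair
static inline double m_in_pair(const Design& D, int sj, int sk) {
  double w = 0.5 * (1 - D.ctm);
  return D.p_cnt[sj] * v_patch_shell(D) * D.p_cnt[sk] * w;
}

// sample a direction uniformly in the spherical cap of half-angle
// acos(ctm) around unit vector a
static void sample_cap(const double* a, double ctm, double* u) {
  double c = ctm + runi() * (1 - ctm);
  double s = std::sqrt(std::max(0.0, 1 - c * c));
  double ph = 2 * PI_ * runi();
  // orthonormal frame around a
  double e1[3];
  if (std::fabs(a[0]) < 0.9) { e1[0] = 0; e1[1] = -a[2]; e1[2] = a[1]; }
  else { e1[0] = -a[1]; e1[1] = a[0]; e1[2] = 0; }
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  double e2[3] = { a[1] * e1[2] - a[2] * e1[1], a[2] * e1[0] - a[0] * e1[2],
                   a[0] * e1[1] - a[1] * e1[0] };
  for (int i = 0; i < 3; ++i)
    u[i] = c * a[i] + s * (std::cos(ph) * e1[i] + std::sin(ph) * e2[i]);
}

// orientation with body vector v mapped to lab direction u, azimuth uniform
static void sample_oriented_quat(const double* v, const double* u, double* q) {
  // base rotation aligning v to u
  double c = v[0] * u[0] + v[1] * u[1] + v[2] * u[2];
  double qa[4];
  if (c > 1 - 1e-12) { qa[0] = 1; qa[1] = qa[2] = qa[3] = 0; }
  else if (c < -1 + 1e-12) {
    double ax[3];
    if (std::fabs(v[0]) < 0.9) { ax[0] = 0; ax[1] = -v[2]; ax[2] = v[1]; }
    else { ax[0] = -v[1]; ax[1] = v[0]; ax[2] = 0; }
    double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int i = 0; i < 3; ++i) ax[i] /= n;
    axis_angle_quat(ax, PI_, qa);
  } else {
    double ax[3] = { v[1] * u[2] - v[2] * u[1], v[2] * u[0] - v[0] * u[2],
                     v[0] * u[1] - v[1] * u[0] };
    double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int i = 0; i < 3; ++i) ax[i] /= n;
    axis_angle_quat(ax, std::acos(c), qa);
  }
  double qspin[4];
  axis_angle_quat(u, 2 * PI_ * runi(), qspin);
  quat_mult(qspin, qa, q);
  quat_normalize(q);
}

// generation density (w.r.t. dr x normalized Haar) for placing particle of
// species sk at (rk, qk) in box B by the mixed channel: with probability
// qbias an oriented insertion into the shell of a uniformly chosen target,
// otherwise uniform. `skip` excludes one index (the particle being moved).
static double insert_density(const Design& D, const Box& B, double qbias,
                             const double* rk, const double* qk, int sk, int skip) {
  int ntarg = 0;
  double dens_bias = 0.0;
  double w = 0.5 * (1 - D.ctm);
  for (int j = 0; j < B.n(); ++j) {
    if (j == skip) continue;
    ++ntarg;
    if (qbias > 0 &&
        in_region(D, &B.pos[3 * j], &B.quat[4 * j], B.sp[j], rk, qk, sk, B.L)) {
      // cones are disjoint for the narrow patches used here, so the
      // generation density inside the in region is 1 / (measure of region)
      dens_bias += 1.0 / (D.p_cnt[B.sp[j]] * v_patch_shell(D) * D.p_cnt[sk] * w);
    }
  }
  double V = B.L * B.L * B.L;
  if (ntarg == 0) return 1.0 / V;  // no targets: uniform channel only
  return qbias * dens_bias / ntarg + (1 - qbias) / V;
}

// propose an insertion state by the mixed channel; returns false if no
// target exists for the biased channel (falls back to uniform)
static void propose_insertion(const Design& D, const Box& B, double qbias,
                              int sk, int skip, double* rk, double* qk) {
  int ntarg = B.n() - (skip >= 0 ? 1 : 0);
  bool biased = ntarg > 0 && runi() < qbias;
  if (!biased) {
    rk[0] = runi() * B.L; rk[1] = runi() * B.L; rk[2] = runi() * B.L;
    random_quat(qk);
    return;
  }
  int j = -1;
  do {
    j = (int)(runi() * B.n());
    if (j >= B.n()) j = B.n() - 1;
  } while (j == skip);
  int sj = B.sp[j];
  int a = (int)(runi() * D.p_cnt[sj]);
  const double* va = &D.pvec[3 * (D.p_off[sj] + a)];
  double Rj[9];
  quat_to_mat(&B.quat[4 * j], Rj);
  double pa[3] = { Rj[0] * va[0] + Rj[1] * va[1] + Rj[2] * va[2],
                   Rj[3] * va[0] + Rj[4] * va[1] + Rj[5] * va[2],
                   Rj[6] * va[0] + Rj[7] * va[1] + Rj[8] * va[2] };
  double u[3];
  sample_cap(pa, D.ctm, u);
  double s3 = std::pow(D.sigma, 3), rc3 = std::pow(D.sigma + D.delta, 3);
  double r = std::cbrt(s3 + runi() * (rc3 - s3));
  for (int i = 0; i < 3; ++i) {
    rk[i] = B.pos[3 * j + i] + r * u[i];
    rk[i] -= B.L * std::floor(rk[i] / B.L);
  }
  // orient a random patch of the inserted particle back toward the target
  int b = (int)(runi() * D.p_cnt[sk]);
  double back[3] = { -u[0], -u[1], -u[2] };
  double ub[3];
  sample_cap(back, D.ctm, ub);
  sample_oriented_quat(&D.pvec[3 * (D.p_off[sk] + b)], ub, qk);
}

static Design design_from_list(List dc) {
  Design D;
  NumericMatrix eps = dc["eps"];
  D.ntypes = eps.nrow();
  D.eps.assign(eps.begin(), eps.end());
  IntegerVector pc = dc["patch_count"], po = dc["patch_offset"], pt = dc["patch_type"];
  D.nsp = pc.size();
  D.p_cnt.assign(pc.begin(), pc.end());
  D.p_off.assign(po.begin(), po.end());
  D.ptype.assign(pt.begin(), pt.end());
  NumericMatrix pv = dc["patch_vectors"];  // total_patches x 3
  D.pvec.resize(3 * pv.nrow());
  for (int i = 0; i < pv.nrow(); ++i)
    for (int k = 0; k < 3; ++k) D.pvec[3 * i + k] = pv(i, k);
  D.sigma = dc["sigma"]; D.delta = dc["delta"]; D.ctm = dc["cos_theta_max"];
  D.rc2 = (D.sigma + D.delta) * (D.sigma + D.delta);
  for (int s = 0; s < D.nsp; ++s) D.max_gamma = std::max(D.max_gamma, D.p_cnt[s]);
  return D;
}

static Box box_from_list(List st) {
  Box B;
  B.L = st["L"];
  NumericMatrix pos = st["positions"], quat = st["orientations"];
  IntegerVector sp = st["species"];
  int N = sp.size();
  B.pos.resize(3 * N); B.quat.resize(4 * N); B.sp.resize(N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) B.pos[3 * i + k] = pos(i, k);
    for (int k = 0; k < 4; ++k) B.quat[4 * i + k] = quat(i, k);
    B.sp[i] = sp[i] - 1;
  }
  return B;
}

static List box_to_list(const Box& B) {
  int N = B.n();
  NumericMatrix pos(N, 3), quat(N, 4);
  IntegerVector sp(N);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) pos(i, k) = B.pos[3 * i + k];
    for (int k = 0; k < 4; ++k) quat(i, k) = B.quat[4 * i + k];
    sp[i] = B.sp[i] + 1;
  }
  return List::create(_["L"] = B.L, _["positions"] = pos,
                      _["orientations"] = quat, _["species"] = sp,
                      _["energy"] = B.E);
}

// single-particle displacement / rotation / AVB sweep helpers ---------------

struct Counters {
  long att_tr = 0, acc_tr = 0, att_rot = 0, acc_rot = 0;
  long att_avb = 0, acc_avb = 0, att_vol = 0, acc_vol = 0;
  long att_xfer = 0, acc_xfer = 0, att_ins = 0, acc_ins = 0, att_del = 0, acc_del = 0;
};

static void move_translate(const Design& D, Box& B, double T, double dmax, Counters& C) {
  if (B.n() == 0) return;
  ++C.att_tr;
  int i = (int)(runi() * B.n()); if (i >= B.n()) i = B.n() - 1;
  double rn[3];
  for (int k = 0; k < 3; ++k) {
    rn[k] = B.pos[3 * i + k] + (2 * runi() - 1) * dmax;
    rn[k] -= B.L * std::floor(rn[k] / B.L);
  }
  double e0 = particle_energy(D, B, i, &B.pos[3 * i], &B.quat[4 * i], B.sp[i]);
  double e1 = particle_energy(D, B, i, rn, &B.quat[4 * i], B.sp[i]);
  if (e1 < E_INF && (e1 <= e0 || runi() < std::exp(-(e1 - e0) / T))) {
    std::memcpy(&B.pos[3 * i], rn, 3 * sizeof(double));
    B.E += e1 - e0;
    ++C.acc_tr;
  }
}

static void move_rotate(const Design& D, Box& B, double T, double amax, Counters& C) {
  if (B.n() == 0) return;
  ++C.att_rot;
  int i = (int)(runi() * B.n()); if (i >= B.n()) i = B.n() - 1;
  double ax[3];
  double n2;
  do {
    for (int k = 0; k < 3; ++k) ax[k] = 2 * runi() - 1;
    n2 = ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2];
  } while (n2 > 1 || n2 < 1e-12);
  double n = std::sqrt(n2);
  for (int k = 0; k < 3; ++k) ax[k] /= n;
  double dq[4], qn[4];
  axis_angle_quat(ax, (2 * runi() - 1) * amax, dq);
  quat_mult(dq, &B.quat[4 * i], qn);
  quat_normalize(qn);
  double e0 = particle_energy(D, B, i, &B.pos[3 * i], &B.quat[4 * i], B.sp[i]);
  double e1 = particle_energy(D, B, i, &B.pos[3 * i], qn, B.sp[i]);
  if (e1 < E_INF && (e1 <= e0 || runi() < std::exp(-(e1 - e0) / T))) {
    std::memcpy(&B.quat[4 * i], qn, 4 * sizeof(double));
    B.E += e1 - e0;
    ++C.acc_rot;
  }
}

// AVB in/out move (symmetric choice). In: move an out-particle into the
// bonding shell of target j with oriented placement. Out: move an
// in-particle to a uniform position/orientation outside the shell.
static void move_avb(const Design& D, Box& B, double T, Counters& C) {
  int N = B.n();
  if (N < 2) return;
  ++C.att_avb;
  int j = (int)(runi() * N); if (j >= N) j = N - 1;
  std::vector<int> in_l, out_l;
  for (int k = 0; k < N; ++k) {
    if (k == j) continue;
    if (in_region(D, &B.pos[3 * j], &B.quat[4 * j], B.sp[j],
                  &B.pos[3 * k], &B.quat[4 * k], B.sp[k], B.L))
      in_l.push_back(k);
    else out_l.push_back(k);
  }
  double V = B.L * B.L * B.L;
  bool do_in = runi() < 0.5;
  if (do_in) {
    if (out_l.empty()) return;
    int k = out_l[(int)(runi() * out_l.size())];
    double Min = m_in_pair(D, B.sp[j], B.sp[k]);
    // oriented placement into j's shell (same construction as the biased
    // insertion channel but with the fixed target j)
    int sj = B.sp[j];
    int a = (int)(runi() * D.p_cnt[sj]);
    double Rj[9]; quat_to_mat(&B.quat[4 * j], Rj);
    const double* va = &D.pvec[3 * (D.p_off[sj] + a)];
    double pa[3] = { Rj[0] * va[0] + Rj[1] * va[1] + Rj[2] * va[2],
                     Rj[3] * va[0] + Rj[4] * va[1] + Rj[5] * va[2],
                     Rj[6] * va[0] + Rj[7] * va[1] + Rj[8] * va[2] };
    double u[3]; sample_cap(pa, D.ctm, u);
    double s3 = std::pow(D.sigma, 3), rc3 = std::pow(D.sigma + D.delta, 3);
    double rr = std::cbrt(s3 + runi() * (rc3 - s3));
    double rn[3], qn[4];
    for (int i = 0; i < 3; ++i) {
      rn[i] = B.pos[3 * j + i] + rr * u[i];
      rn[i] -= B.L * std::floor(rn[i] / B.L);
    }
    int b = (int)(runi() * D.p_cnt[B.sp[k]]);
    double back[3] = { -u[0], -u[1], -u[2] };
    double ub[3]; sample_cap(back, D.ctm, ub);
    sample_oriented_quat(&D.pvec[3 * (D.p_off[B.sp[k]] + b)], ub, qn);
    double e0 = particle_energy(D, B, k, &B.pos[3 * k], &B.quat[4 * k], B.sp[k]);
    double e1 = particle_energy(D, B, k, rn, qn, B.sp[k]);
    if (e1 >= E_INF) return;
    double ratio = (double)out_l.size() * Min /
                   (((double)in_l.size() + 1.0) * (V - Min)) *
                   std::exp(-(e1 - e0) / T);
    if (runi() < ratio) {
      std::memcpy(&B.pos[3 * k], rn, 3 * sizeof(double));
      std::memcpy(&B.quat[4 * k], qn, 4 * sizeof(double));
      B.E += e1 - e0;
      ++C.acc_avb;
    }
  } else {
    if (in_l.empty()) return;
    int k = in_l[(int)(runi() * in_l.size())];
    double Min = m_in_pair(D, B.sp[j], B.sp[k]);
    double rn[3], qn[4];
    rn[0] = runi() * B.L; rn[1] = runi() * B.L; rn[2] = runi() * B.L;
    random_quat(qn);
    if (in_region(D, &B.pos[3 * j], &B.quat[4 * j], B.sp[j], rn, qn, B.sp[k], B.L))
      return;  // proposal landed in the in region: invalid for the out channel
    double e0 = particle_energy(D, B, k, &B.pos[3 * k], &B.quat[4 * k], B.sp[k]);
    double e1 = particle_energy(D, B, k, rn, qn, B.sp[k]);
    if (e1 >= E_INF) return;
    double ratio = (double)in_l.size() * (V - Min) /
                   (((double)out_l.size() + 1.0) * Min) *
                   std::exp(-(e1 - e0) / T);
    if (runi() < ratio) {
      std::memcpy(&B.pos[3 * k], rn, 3 * sizeof(double));
      std::memcpy(&B.quat[4 * k], qn, 4 * sizeof(double));
      B.E += e1 - e0;
      ++C.acc_avb;
    }
  }
}

static void move_volume_npt(const Design& D, Box& B, double T, double P,
                            double dlnV, Counters& C) {
  ++C.att_vol;
  int N = B.n();
  double V0 = B.L * B.L * B.L;
  double V1 = V0 * std::exp((2 * runi() - 1) * dlnV);
  double s = std::cbrt(V1 / V0);
  Box Bn = B;
  Bn.L = B.L * s;
  for (int i = 0; i < 3 * N; ++i) Bn.pos[i] *= s;
  double E1 = total_energy(D, Bn);
  if (E1 >= E_INF) return;
  double arg = -(E1 - B.E) / T - P * (V1 - V0) / T + (N + 1) * std::log(V1 / V0);
  if (arg >= 0 || runi() < std::exp(arg)) {
    B = Bn;
    B.E = E1;
    ++C.acc_vol;
  }
}

static void move_volume_gibbs(const Design& D, Box& A, Box& B, double T,
                              double dlnV, Counters& C) {
  ++C.att_vol;
  double Va = A.L * A.L * A.L, Vb = B.L * B.L * B.L;
  double Vt = Va + Vb;
  double lr = std::log(Va / Vb) + (2 * runi() - 1) * dlnV;
  double Va1 = Vt * std::exp(lr) / (1 + std::exp(lr));
  double Vb1 = Vt - Va1;
  Box An = A, Bn = B;
  double sa = std::cbrt(Va1 / Va), sb = std::cbrt(Vb1 / Vb);
  An.L = A.L * sa; Bn.L = B.L * sb;
  for (size_t i = 0; i < An.pos.size(); ++i) An.pos[i] *= sa;
  for (size_t i = 0; i < Bn.pos.size(); ++i) Bn.pos[i] *= sb;
  double Ea1 = total_energy(D, An);
  if (Ea1 >= E_INF) return;
  double Eb1 = total_energy(D, Bn);
  if (Eb1 >= E_INF) return;
  double arg = -(Ea1 - A.E + Eb1 - B.E) / T +
               (A.n() + 1) * std::log(Va1 / Va) + (B.n() + 1) * std::log(Vb1 / Vb);
  if (arg >= 0 || runi() < std::exp(arg)) {
    A = An; B = Bn; A.E = Ea1; B.E = Eb1;
    ++C.acc_vol;
  }
}

static void remove_particle(Box& B, int i) {
  int N = B.n();
  for (int k = 0; k < 3; ++k) B.pos[3 * i + k] = B.pos[3 * (N - 1) + k];
  for (int k = 0; k < 4; ++k) B.quat[4 * i + k] = B.quat[4 * (N - 1) + k];
  B.sp[i] = B.sp[N - 1];
  B.pos.resize(3 * (N - 1)); B.quat.resize(4 * (N - 1)); B.sp.resize(N - 1);
}

static void add_particle(Box& B, const double* r, const double* q, int sp) {
  B.pos.insert(B.pos.end(), r, r + 3);
  B.quat.insert(B.quat.end(), q, q + 4);
  B.sp.push_back(sp);
}

// Gibbs particle transfer with mixed (biased/uniform) insertion channel
static void move_transfer(const Design& D, Box& A, Box& B, double T,
                          double qbias, Counters& C) {
  ++C.att_xfer;
  bool a2b = runi() < 0.5;
  Box& S = a2b ? A : B;
  Box& Dst = a2b ? B : A;
  if (S.n() == 0) return;
  int i = (int)(runi() * S.n()); if (i >= S.n()) i = S.n() - 1;
  int sk = S.sp[i];
  double rk[3], qk[4];
  propose_insertion(D, Dst, qbias, sk, -1, rk, qk);
  double e_ins = E_INF;
  {
    Box tmp;  // evaluate against Dst without copying: use particle_energy with skip=-1
    e_ins = 0.0;
    for (int j = 0; j < Dst.n(); ++j) {
      e_ins += pair_energy_raw(D, rk, qk, sk, &Dst.pos[3 * j], &Dst.quat[4 * j],
                               Dst.sp[j], Dst.L);
      if (e_ins >= E_INF) break;
    }
  }
  if (e_ins >= E_INF) return;
  double e_rem = particle_energy(D, S, i, &S.pos[3 * i], &S.quat[4 * i], sk);
  double p_dst = insert_density(D, Dst, qbias, rk, qk, sk, -1);
  double p_src = insert_density(D, S, qbias, &S.pos[3 * i], &S.quat[4 * i], sk, i);
  // N_src / (N_dst + 1) * (p_src / p_dst) * exp(-beta dE); the 1/V factors
  // of the textbook rule are inside the generation densities
  double ratio = (double)S.n() / ((double)Dst.n() + 1.0) * (p_src / p_dst) *
                 std::exp(-(e_ins - e_rem) / T);
  if (runi() < ratio) {
    add_particle(Dst, rk, qk, sk);
    Dst.E += e_ins;
    S.E -= e_rem;
    remove_particle(S, i);
    ++C.acc_xfer;
  }
}

// grand-canonical insertion/deletion with mixed insertion channel
static void move_gcmc(const Design& D, Box& B, double T, const NumericVector& mu,
                      double qbias, Counters& C) {
  int nsp = D.nsp;
  int sk = (int)(runi() * nsp); if (sk >= nsp) sk = nsp - 1;
  double V = B.L * B.L * B.L;
  if (runi() < 0.5) {
    ++C.att_ins;
    double rk[3], qk[4];
    propose_insertion(D, B, qbias, sk, -1, rk, qk);
    double e_ins = 0.0;
    for (int j = 0; j < B.n(); ++j) {
      e_ins += pair_energy_raw(D, rk, qk, sk, &B.pos[3 * j], &B.quat[4 * j],
                               B.sp[j], B.L);
      if (e_ins >= E_INF) return;
    }
    int Ns = 0;
    for (int j = 0; j < B.n(); ++j) if (B.sp[j] == sk) ++Ns;
    double p_gen = insert_density(D, B, qbias, rk, qk, sk, -1);
    double ratio = std::exp(mu[sk] / T - e_ins / T) / ((Ns + 1.0) * p_gen);
    if (runi() < ratio) {
      add_particle(B, rk, qk, sk);
      B.E += e_ins;
      ++C.acc_ins;
    }
  } else {
    ++C.att_del;
    std::vector<int> of_sp;
    for (int j = 0; j < B.n(); ++j) if (B.sp[j] == sk) of_sp.push_back(j);
    if (of_sp.empty()) return;
    int i = of_sp[(int)(runi() * of_sp.size())];
    double e_rem = particle_energy(D, B, i, &B.pos[3 * i], &B.quat[4 * i], sk);
    double p_gen = insert_density(D, B, qbias, &B.pos[3 * i], &B.quat[4 * i], sk, i);
    double ratio = (double)of_sp.size() * p_gen * std::exp(-mu[sk] / T + e_rem / T);
    if (runi() < ratio) {
      B.E -= e_rem;
      remove_particle(B, i);
      ++C.acc_del;
    }
  }
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double kf_pair_energy_cpp(NumericVector ri, NumericVector qi, int si,
                          NumericVector rj, NumericVector qj, int sj,
                          double L, List design_c) {
  Design D = design_from_list(design_c);
  double e = pair_energy_raw(D, ri.begin(), qi.begin(), si - 1,
                             rj.begin(), qj.begin(), sj - 1, L);
  return e >= E_INF ? R_PosInf : e;
}

// [[Rcpp::export]]
double kf_total_energy_cpp(List state, List design_c) {
  Design D = design_from_list(design_c);
  Box B = box_from_list(state);
  double e = total_energy(D, B);
  return e >= E_INF ? R_PosInf : e;
}

// log of the non-energy part of the AVB acceptance ratio, as used by the
// move code: direction "in" moves a particle from out to in of a target
// [[Rcpp::export]]
double avb_log_ratio_cpp(std::string direction, int n_in, int n_out,
                         double V, int gamma_j, int gamma_k,
                         double sigma, double delta, double cos_theta_max) {
  double w = 0.5 * (1 - cos_theta_max);
  double vps = 4.0 * PI_ / 3.0 * (std::pow(sigma + delta, 3) - std::pow(sigma, 3)) * w;
  double Min = gamma_j * vps * gamma_k * w;
  if (direction == "in")
    return std::log((double)n_out * Min / (((double)n_in + 1.0) * (V - Min)));
  return std::log((double)n_in * (V - Min) / (((double)n_out + 1.0) * Min));
}

// [[Rcpp::export]]
List kf_mc_run_cpp(List state, List design_c, std::string ensemble, double T,
                   double P, NumericVector mu, List sched, int sweeps,
                   int obs_stride, int frame_stride, int audit_stride,
                   Nullable<List> state_b = R_NilValue) {
  Design D = design_from_list(design_c);
  Box A = box_from_list(state);
  Box B;
  bool gibbs = (ensemble == "gibbs");
  if (gibbs) {
    if (state_b.isNull()) stop("gibbs ensemble needs a second box");
    B = box_from_list(List(state_b));
  }
  A.E = total_energy(D, A);
  if (A.E >= E_INF) stop("initial configuration contains hard-core overlaps");
  if (gibbs) {
    B.E = total_energy(D, B);
    if (B.E >= E_INF) stop("initial configuration (box b) contains overlaps");
  }

  double p_tr = sched["p_translate"], p_rot = sched["p_rotate"];
  double p_avb = sched["p_avb"], p_vol = sched["p_volume"], p_x = sched["p_transfer"];
  double dmax = sched["dmax"], amax = sched["rot_max"], dlnV = sched["dlnv"];
  double qbias = sched["transfer_bias"];
  double psum = p_tr + p_rot + p_avb + p_vol + p_x;

  Counters C;
  std::vector<double> obs;     // flat rows
  int obs_cols = 8;            // sweep, box, N, N1, V, rho, x1, E
  List frames;
  std::vector<List> frames_v;
  double max_drift = 0.0;

  GetRNGstate();
  for (int sw = 1; sw <= sweeps; ++sw) {
    int nmoves = std::max(1, A.n() + (gibbs ? B.n() : 0));
    for (int m = 0; m < nmoves; ++m) {
      double u = runi() * psum;
      Box& Bx = (!gibbs || runi() < (double)A.n() / std::max(1, A.n() + B.n())) ? A : B;
      if (u < p_tr) move_translate(D, Bx, T, dmax, C);
      else if (u < p_tr + p_rot) move_rotate(D, Bx, T, amax, C);
      else if (u < p_tr + p_rot + p_avb) move_avb(D, Bx, T, C);
      else if (u < p_tr + p_rot + p_avb + p_vol) {
        if (ensemble == "npt") move_volume_npt(D, A, T, P, dlnV, C);
        else if (gibbs) move_volume_gibbs(D, A, B, T, dlnV, C);
      } else {
        if (gibbs) move_transfer(D, A, B, T, qbias, C);
        else if (ensemble == "gcmc") move_gcmc(D, A, T, mu, qbias, C);
      }
    }
    if (sw % obs_stride == 0) {
      for (int bx = 0; bx < (gibbs ? 2 : 1); ++bx) {
        Box& Bx = bx == 0 ? A : B;
        double V = Bx.L * Bx.L * Bx.L;
        int n1 = 0;
        for (int j = 0; j < Bx.n(); ++j) if (Bx.sp[j] == 0) ++n1;
        double xr[8] = { (double)sw, (double)(bx + 1), (double)Bx.n(), (double)n1,
                         V, Bx.n() / V, Bx.n() ? (double)n1 / Bx.n() : NA_REAL, Bx.E };
        obs.insert(obs.end(), xr, xr + 8);
      }
    }
    if (frame_stride > 0 && sw % frame_stride == 0) {
      frames_v.push_back(box_to_list(A));
      if (gibbs) frames_v.push_back(box_to_list(B));
    }
    if (audit_stride > 0 && sw % audit_stride == 0) {
      double Ef = total_energy(D, A);
      max_drift = std::max(max_drift, std::fabs(Ef - A.E));
      A.E = Ef;
      if (gibbs) {
        double Eb = total_energy(D, B);
        max_drift = std::max(max_drift, std::fabs(Eb - B.E));
        B.E = Eb;
      }
    }
  }
  PutRNGstate();

  int nrow = obs.size() / obs_cols;
  NumericMatrix om(nrow, obs_cols);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < obs_cols; ++j) om(i, j) = obs[i * obs_cols + j];
  colnames(om) = CharacterVector::create("sweep", "box", "N", "N1", "V",
                                         "rho", "x1", "E");
  List fr(frames_v.size());
  for (size_t i = 0; i < frames_v.size(); ++i) fr[i] = frames_v[i];

  List acc = List::create(
    _["translate"] = NumericVector::create(C.att_tr, C.acc_tr),
    _["rotate"] = NumericVector::create(C.att_rot, C.acc_rot),
    _["avb"] = NumericVector::create(C.att_avb, C.acc_avb),
    _["volume"] = NumericVector::create(C.att_vol, C.acc_vol),
    _["transfer"] = NumericVector::create(C.att_xfer, C.acc_xfer),
    _["insert"] = NumericVector::create(C.att_ins, C.acc_ins),
    _["delete"] = NumericVector::create(C.att_del, C.acc_del));

  List out = List::create(_["state"] = box_to_list(A),
                          _["observables"] = om, _["frames"] = fr,
                          _["acceptance"] = acc,
                          _["max_energy_drift"] = max_drift);
  if (gibbs) out["state_b"] = box_to_list(B);
  return out;
}
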