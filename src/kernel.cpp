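// Metropolis Monte Carlo kernel for the SBRIS chain.
//
// State: node coordinates (nm), per-bond lengths, per-interior-node angles,
// one discrete rotational state per rotatable bond, per-site charges.
// Moves: protonation flip (SGCMC only), single-bond trans/gauche pivot of
// the shorter chain arm, Gaussian perturbation of one bond length or angle.
// Energies are in kBT; incremental updates are cross-checked against full
// recomputation when ctrl$check_every > 0.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LN10 = 2.302585092994045684;

// ---------------------------------------------------------------- RNG ----
struct Xoshiro {
  uint64_t s[4];
  bool have_gauss = false;
  double gauss_cache = 0.0;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master + 0x9E3779B97F4A7C15ULL * (stream + 1);
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int randint(int n) { return (int)(unif() * n); }
  double gauss() {
    if (have_gauss) { have_gauss = false; return gauss_cache; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    gauss_cache = v * f; have_gauss = true;
    return u * f;
  }
};

// ------------------------------------------------------------- system ----
struct Chain {
  // topology
  int N, n_nodes, M, n_rot;
  std::vector<int> site_node;   // 0-based node index per ionizable site
  std::vector<int> rot_bond;    // 0-based bond index per rotatable slot
  double l0, a0;                // nm, rad
  double kl, ka;                // kBT/nm^2, kBT/rad^2
  std::vector<double> radii;    // per node, nm
  double pK;
  double eps_int[3], eps_rot[3];

  // control
  int mode;                     // 0 = sgcmc, 1 = ccmc
  double pH, theta;
  double lB, kappa, dcut2;      // electrostatics (dcut2 <= 0: no cutoff)
  double f_int;                 // force / kBT, 1/nm
  bool sev, elastic;

  // state
  std::vector<double> x, y, z;  // node positions
  std::vector<double> l, alp;   // bond lengths, interior angles (rad)
  std::vector<int> dstate;      // 0 = t, 1 = g+, 2 = g-
  std::vector<double> q;        // per-site charge
  int nplus;                    // number of protonated sites (sgcmc)
  int mg;                       // number of gauche rotatable bonds
  double E;                     // running total energy (finite part, kBT)

  // scratch
  std::vector<double> sx, sy, sz;
  std::vector<char> moved;      // node moved in current proposal?

  double pair_v(double d2) const {
    if (dcut2 > 0 && d2 > dcut2) return 0.0;
    double d = std::sqrt(d2);
    return lB / d * std::exp(-kappa * d);
  }
  double dist2(int p, int qn) const {
    double dx = x[p] - x[qn], dy = y[p] - y[qn], dz = z[p] - z[qn];
    return dx * dx + dy * dy + dz * dz;
  }
};

static const double DIH_ANG[3] = {0.0, 2.0943951023931953, -2.0943951023931953};

static void cross(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Build Cartesian coordinates from internal coordinates (natural extension
// frame: node 0 at origin, bond 0 along z, bond 1 in the x-z plane).
static void build_coords(Chain &ch) {
  int M = ch.M;
  std::vector<double> phi(M > 2 ? M - 2 : 0, 0.0); // dihedral of bonds 1..M-2 (0-based)
  for (int k = 0; k < ch.n_rot; k++)
    phi[ch.rot_bond[k] - 1] = DIH_ANG[ch.dstate[k]];
  ch.x.assign(ch.n_nodes, 0.0);
  ch.y.assign(ch.n_nodes, 0.0);
  ch.z.assign(ch.n_nodes, 0.0);
  ch.z[1] = ch.l[0];
  if (M >= 2) {
    double th = M_PI - ch.alp[0];
    ch.x[2] = ch.x[1] + ch.l[1] * std::sin(th);
    ch.z[2] = ch.z[1] + ch.l[1] * std::cos(th);
  }
  for (int k = 3; k <= M; k++) {
    double a[3] = {ch.x[k - 1] - ch.x[k - 2], ch.y[k - 1] - ch.y[k - 2], ch.z[k - 1] - ch.z[k - 2]};
    double b[3] = {ch.x[k - 2] - ch.x[k - 3], ch.y[k - 2] - ch.y[k - 3], ch.z[k - 2] - ch.z[k - 3]};
    double na = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
    for (int d = 0; d < 3; d++) { a[d] /= na; b[d] /= nb; }
    double n[3]; cross(b, a, n);
    double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (nn < 1e-12) {
      // collinear previous bonds (straight rod): reference plane is
      // arbitrary, pick any direction perpendicular to the chain axis
      double e[3] = {0.0, 0.0, 0.0};
      e[std::fabs(a[0]) <= std::fabs(a[1])
          ? (std::fabs(a[0]) <= std::fabs(a[2]) ? 0 : 2)
          : (std::fabs(a[1]) <= std::fabs(a[2]) ? 1 : 2)] = 1.0;
      cross(e, a, n);
      nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    }
    for (int d = 0; d < 3; d++) n[d] /= nn;
    double m[3]; cross(n, a, m);
    double th = M_PI - ch.alp[k - 2];
    double ph = phi[k - 3];
    double ct = std::cos(th), st = std::sin(th), cp = std::cos(ph), sp = std::sin(ph);
    double u[3];
    for (int d = 0; d < 3; d++) u[d] = ct * a[d] + st * (-cp * m[d] + sp * n[d]);
    ch.x[k] = ch.x[k - 1] + ch.l[k - 1] * u[0];
    ch.y[k] = ch.y[k - 1] + ch.l[k - 1] * u[1];
    ch.z[k] = ch.z[k - 1] + ch.l[k - 1] * u[2];
  }
}

// Full energy from the current state; geometric lengths/angles are
// recomputed from coordinates so that bookkeeping errors are caught.
static double full_energy(const Chain &ch) {
  double e = 0.0;
  for (int k = 0; k < ch.n_rot; k++) e += ch.eps_rot[ch.dstate[k]];
  if (ch.mode == 0) {
    double sum = 0.0;
    for (int i = 0; i < ch.N; i++) sum += ch.q[i];
    e += LN10 * (ch.pH - ch.pK) * sum;
  }
  for (int i = 0; i + 1 < ch.N; i++)
    e += LN10 * ch.eps_int[ch.dstate[i]] * ch.q[i] * ch.q[i + 1];
  if (ch.lB > 0) {
    for (int i = 0; i + 2 < ch.N; i++) {
      if (ch.q[i] == 0.0) continue;
      for (int j = i + 2; j < ch.N; j++) {
        if (ch.q[j] == 0.0) continue;
        e += ch.q[i] * ch.q[j] * ch.pair_v(ch.dist2(ch.site_node[i], ch.site_node[j]));
      }
    }
  }
  // elastic terms from geometry
  for (int b = 0; b < ch.M; b++) {
    double dx = ch.x[b + 1] - ch.x[b], dy = ch.y[b + 1] - ch.y[b], dz = ch.z[b + 1] - ch.z[b];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += 0.5 * ch.kl * (len - ch.l0) * (len - ch.l0);
  }
  for (int v = 1; v < ch.M; v++) {
    double a[3] = {ch.x[v - 1] - ch.x[v], ch.y[v - 1] - ch.y[v], ch.z[v - 1] - ch.z[v]};
    double b[3] = {ch.x[v + 1] - ch.x[v], ch.y[v + 1] - ch.y[v], ch.z[v + 1] - ch.z[v]};
    double dot = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
    double na = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
    double ca = dot / (na * nb);
    if (ca > 1.0) ca = 1.0; else if (ca < -1.0) ca = -1.0;
    double ang = std::acos(ca);
    e += 0.5 * ch.ka * (ang - ch.a0) * (ang - ch.a0);
  }
  if (ch.f_int != 0.0) e -= ch.f_int * (ch.z[ch.M] - ch.z[0]);
  return e;
}

// hard-sphere clash between a proposed arm (scratch coords) and the rest
static bool sev_clash_arm(const Chain &ch, int lo, int hi) {
  // moved nodes [lo, hi] vs static nodes with bond separation >= 4
  for (int p = lo; p <= hi; p++) {
    double rp = ch.radii[p];
    for (int qn = 0; qn < ch.n_nodes; qn++) {
      if (qn >= lo && qn <= hi) continue;           // both moved: unchanged
      int sep = p - qn; if (sep < 0) sep = -sep;
      if (sep < 4) continue;                        // controlled by bonded terms
      double dx = ch.sx[p] - ch.x[qn], dy = ch.sy[p] - ch.y[qn], dz = ch.sz[p] - ch.z[qn];
      double rs = rp + ch.radii[qn];
      if (dx * dx + dy * dy + dz * dz <= rs * rs) return true;
    }
  }
  return false;
}

// Delta of the long-range energy when nodes [lo, hi] move to scratch coords.
static double dE_long_range(const Chain &ch, int lo, int hi) {
  if (ch.lB == 0.0) return 0.0;
  // site index range covered by the moved nodes
  int ilo = (lo + 2) / 3;          // first site with node >= lo
  int ihi = hi / 3;                // last site with node <= hi
  if (ilo > ihi) return 0.0;
  double dE = 0.0;
  for (int i = ilo; i <= ihi; i++) {
    if (ch.q[i] == 0.0) continue;
    int ni = ch.site_node[i];
    double nxi = ch.sx[ni], nyi = ch.sy[ni], nzi = ch.sz[ni];
    double oxi = ch.x[ni], oyi = ch.y[ni], ozi = ch.z[ni];
    for (int j = 0; j < ch.N; j++) {
      if (j >= ilo && j <= ihi) continue;          // both moved: unchanged
      if (ch.q[j] == 0.0) continue;
      int dj = i - j; if (dj < 0) dj = -dj;
      if (dj < 2) continue;
      int njn = ch.site_node[j];
      double dx = nxi - ch.x[njn], dy = nyi - ch.y[njn], dz = nzi - ch.z[njn];
      double d2n = dx * dx + dy * dy + dz * dz;
      dx = oxi - ch.x[njn]; dy = oyi - ch.y[njn]; dz = ozi - ch.z[njn];
      double d2o = dx * dx + dy * dy + dz * dz;
      dE += ch.q[i] * ch.q[j] * (ch.pair_v(d2n) - ch.pair_v(d2o));
    }
  }
  return dE;
}

// Rigidly transform nodes [lo, hi] into the scratch buffers: rotation R
// about point p0 (Rodrigues, axis u, angle ang) or translation by t.
static void propose_rotation_arm(Chain &ch, int lo, int hi,
                                 const double *p0, const double *u, double ang) {
  double ct = std::cos(ang), st = std::sin(ang), omc = 1.0 - ct;
  double R[3][3] = {
    {ct + u[0] * u[0] * omc,        u[0] * u[1] * omc - u[2] * st, u[0] * u[2] * omc + u[1] * st},
    {u[1] * u[0] * omc + u[2] * st, ct + u[1] * u[1] * omc,        u[1] * u[2] * omc - u[0] * st},
    {u[2] * u[0] * omc - u[1] * st, u[2] * u[1] * omc + u[0] * st, ct + u[2] * u[2] * omc}
  };
  for (int p = lo; p <= hi; p++) {
    double vx = ch.x[p] - p0[0], vy = ch.y[p] - p0[1], vz = ch.z[p] - p0[2];
    ch.sx[p] = p0[0] + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
    ch.sy[p] = p0[1] + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
    ch.sz[p] = p0[2] + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
  }
}

static void propose_translation_arm(Chain &ch, int lo, int hi, const double *t) {
  for (int p = lo; p <= hi; p++) {
    ch.sx[p] = ch.x[p] + t[0];
    ch.sy[p] = ch.y[p] + t[1];
    ch.sz[p] = ch.z[p] + t[2];
  }
}

static void commit_arm(Chain &ch, int lo, int hi) {
  for (int p = lo; p <= hi; p++) {
    ch.x[p] = ch.sx[p]; ch.y[p] = ch.sy[p]; ch.z[p] = ch.sz[p];
  }
}

static Chain make_chain(const List &topo, const List &ctrl) {
  Chain ch;
  ch.N = as<int>(topo["n_ionizable"]);
  ch.n_nodes = as<int>(topo["n_nodes"]);
  ch.M = as<int>(topo["n_bonds"]);
  IntegerVector sn = topo["site_nodes"], rb = topo["rotatable_bonds"];
  ch.n_rot = rb.size();
  ch.site_node.assign(sn.begin(), sn.end());
  for (auto &v : ch.site_node) v -= 1;
  ch.rot_bond.assign(rb.begin(), rb.end());
  for (auto &v : ch.rot_bond) v -= 1;
  ch.l0 = as<double>(topo["l0"]);
  ch.a0 = as<double>(topo["alpha0"]) * M_PI / 180.0;
  ch.kl = as<double>(topo["k_length_int"]);
  ch.ka = as<double>(topo["k_angle_int"]);
  NumericVector rad = topo["node_radii"];
  ch.radii.assign(rad.begin(), rad.end());
  ch.pK = as<double>(topo["pK"]);
  NumericVector ei = topo["eps_int_vec"], er = topo["eps_rot_vec"];
  for (int k = 0; k < 3; k++) { ch.eps_int[k] = ei[k]; ch.eps_rot[k] = er[k]; }

  ch.mode = as<int>(ctrl["mode"]);
  ch.pH = as<double>(ctrl["pH"]);
  ch.theta = as<double>(ctrl["theta"]);
  ch.lB = as<double>(ctrl["bjerrum"]);
  ch.kappa = as<double>(ctrl["kappa"]);
  ch.f_int = as<double>(ctrl["force_pN"]) / 4.1164;
  ch.sev = as<int>(ctrl["sev"]) != 0;
  ch.elastic = as<int>(ctrl["elastic"]) != 0;

  // cutoff: beyond dcut the screened pair energy is below 1e-12 kBT
  ch.dcut2 = -1.0;
  if (ch.lB > 0 && ch.kappa > 0) {
    double d = 1.0;
    for (int it = 0; it < 60; it++)
      d = (std::log(ch.lB) - std::log(d) + 27.631) / ch.kappa; // -ln(1e-12)
    if (d < 1.0) d = 1.0;
    ch.dcut2 = d * d;
  }

  ch.l.assign(ch.M, ch.l0);
  ch.alp.assign(ch.M - 1, ch.a0);
  ch.dstate.assign(ch.n_rot, 0);
  ch.q.assign(ch.N, ch.mode == 1 ? ch.theta : 0.0);
  ch.nplus = 0;
  ch.mg = 0;
  ch.sx.assign(ch.n_nodes, 0.0);
  ch.sy.assign(ch.n_nodes, 0.0);
  ch.sz.assign(ch.n_nodes, 0.0);
  return ch;
}

// ------------------------------------------------------------- kernel ----
// [[Rcpp::export]]
List run_chain_cpp(List topo, List ctrl) {
  Chain ch = make_chain(topo, ctrl);
  Xoshiro rng;
  rng.seed((uint64_t)as<double>(ctrl["seed"]), (uint64_t)as<int>(ctrl["replicate"]));

  const double p_orient = as<double>(ctrl["p_orient"]);
  const double p_flip = p_orient + (1.0 - p_orient) * as<double>(ctrl["p_flip"]);
  const double p_rot = (1.0 - p_orient) * as<double>(ctrl["p_rot"]);
  const long long n_equil = (long long)as<double>(ctrl["n_equil"]);
  const long long n_steps = (long long)as<double>(ctrl["n_steps"]);
  const int sample_every = as<int>(ctrl["sample_every"]);
  const int check_every = as<int>(ctrl["check_every"]);
  const double sigma_l = as<double>(ctrl["sigma_l"]);
  const double sigma_a = as<double>(ctrl["sigma_a"]); // rad

  // initial protonation: independent-site guess at the working pH
  if (ch.mode == 0) {
    double p0 = 1.0 / (1.0 + std::pow(10.0, ch.pH - ch.pK));
    for (int i = 0; i < ch.N; i++) {
      ch.q[i] = (rng.unif() < p0) ? 1.0 : 0.0;
      ch.nplus += (int)ch.q[i];
    }
  }
  build_coords(ch);
  ch.E = full_energy(ch);

  const int n_samples = (int)(n_steps / sample_every);
  IntegerVector out_np(n_samples), out_mg(n_samples), out_gp(n_samples);
  NumericVector out_rz(n_samples), out_r2(n_samples), out_proj(n_samples);
  NumericVector out_lmid(n_samples), out_amid(n_samples);
  long long att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};
  double max_drift = 0.0;
  const int cbond = ch.M / 2;   // reference bond for the projection estimator
  int isample = 0;

  const long long total = n_equil + n_steps;
  long long att_or = 0, acc_or = 0;
  for (long long step = 1; step <= total; step++) {
    double u = rng.unif();
    if (u < p_orient) {
      // ---- rigid-body reorientation of the whole chain ----
      // Distances are invariant, so only the mechanical work changes; the
      // move restores ergodicity over global orientations, which single-arm
      // pivots alone do not provide (the central bond frame is conserved).
      att_or++;
      double ax[3];
      double nn;
      do {
        ax[0] = 2.0 * rng.unif() - 1.0;
        ax[1] = 2.0 * rng.unif() - 1.0;
        ax[2] = 2.0 * rng.unif() - 1.0;
        nn = ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2];
      } while (nn > 1.0 || nn < 1e-12);
      nn = std::sqrt(nn);
      ax[0] /= nn; ax[1] /= nn; ax[2] /= nn;
      double ang = (2.0 * rng.unif() - 1.0) * M_PI;
      double p0[3] = {ch.x[0], ch.y[0], ch.z[0]};
      propose_rotation_arm(ch, 0, ch.M, p0, ax, ang);
      double dE = 0.0;
      if (ch.f_int != 0.0)
        dE = -ch.f_int * ((ch.sz[ch.M] - ch.sz[0]) - (ch.z[ch.M] - ch.z[0]));
      if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
        acc_or++;
        commit_arm(ch, 0, ch.M);
        ch.E += dE;
      }
    } else if (u < p_flip) {
      // ---- protonation flip (sgcmc) ----
      att[0]++;
      int i = rng.randint(ch.N);
      double dq = 1.0 - 2.0 * ch.q[i];
      double dE = LN10 * (ch.pH - ch.pK) * dq;
      if (i > 0 && ch.q[i - 1] != 0.0)
        dE += LN10 * ch.eps_int[ch.dstate[i - 1]] * dq * ch.q[i - 1];
      if (i < ch.N - 1 && ch.q[i + 1] != 0.0)
        dE += LN10 * ch.eps_int[ch.dstate[i]] * dq * ch.q[i + 1];
      if (ch.lB > 0) {
        int ni = ch.site_node[i];
        for (int j = 0; j < ch.N; j++) {
          int dj = i - j; if (dj < 0) dj = -dj;
          if (dj < 2 || ch.q[j] == 0.0) continue;
          dE += dq * ch.q[j] * ch.pair_v(ch.dist2(ni, ch.site_node[j]));
        }
      }
      if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
        acc[0]++;
        ch.q[i] += dq;
        ch.nplus += (int)dq;
        ch.E += dE;
      }
    } else if (u < p_flip + p_rot) {
      // ---- trans/gauche pivot ----
      att[1]++;
      int k = rng.randint(ch.n_rot);
      int b = ch.rot_bond[k];
      int o = ch.dstate[k];
      int nw = (o + 1 + rng.randint(2)) % 3;
      double dphi = DIH_ANG[nw] - DIH_ANG[o];
      bool head = b < ch.M - 1 - b;
      int lo = head ? 0 : b + 2;
      int hi = head ? b - 1 : ch.M;
      double ang = head ? dphi : -dphi;
      double p0[3] = {ch.x[b], ch.y[b], ch.z[b]};
      double ax[3] = {ch.x[b + 1] - p0[0], ch.y[b + 1] - p0[1], ch.z[b + 1] - p0[2]};
      double an = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
      ax[0] /= an; ax[1] /= an; ax[2] /= an;
      propose_rotation_arm(ch, lo, hi, p0, ax, ang);
      bool clash = ch.sev && sev_clash_arm(ch, lo, hi);
      if (!clash) {
        double dE = ch.eps_rot[nw] - ch.eps_rot[o]
          + LN10 * (ch.eps_int[nw] - ch.eps_int[o]) * ch.q[k] * ch.q[k + 1]
          + dE_long_range(ch, lo, hi);
        if (ch.f_int != 0.0) {
          double drz = head ? -(ch.sz[0] - ch.z[0]) : (ch.sz[ch.M] - ch.z[ch.M]);
          dE -= ch.f_int * drz;
        }
        if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
          acc[1]++;
          commit_arm(ch, lo, hi);
          ch.mg += (nw != 0) - (o != 0);
          ch.dstate[k] = nw;
          ch.E += dE;
        }
      }
    } else {
      // ---- elastic perturbation ----
      att[2]++;
      int idx = rng.randint(2 * ch.M - 1);
      if (idx < ch.M) {
        // bond length move on bond idx
        int b = idx;
        double delta = sigma_l * rng.gauss();
        double ux = (ch.x[b + 1] - ch.x[b]) / ch.l[b];
        double uy = (ch.y[b + 1] - ch.y[b]) / ch.l[b];
        double uz = (ch.z[b + 1] - ch.z[b]) / ch.l[b];
        bool head = (b + 1) < (ch.M - b);
        int lo = head ? 0 : b + 1;
        int hi = head ? b : ch.M;
        double sgn = head ? -delta : delta;
        double t[3] = {sgn * ux, sgn * uy, sgn * uz};
        propose_translation_arm(ch, lo, hi, t);
        bool clash = ch.sev && sev_clash_arm(ch, lo, hi);
        if (!clash) {
          double lnew = ch.l[b] + delta;
          if (lnew > 0) {
            double dE = 0.5 * ch.kl * ((lnew - ch.l0) * (lnew - ch.l0)
                                       - (ch.l[b] - ch.l0) * (ch.l[b] - ch.l0))
              + dE_long_range(ch, lo, hi);
            if (ch.f_int != 0.0) {
              double drz = head ? -(ch.sz[0] - ch.z[0]) : (ch.sz[ch.M] - ch.z[ch.M]);
              dE -= ch.f_int * drz;
            }
            if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
              acc[2]++;
              commit_arm(ch, lo, hi);
              ch.l[b] = lnew;
              ch.E += dE;
            }
          }
        }
      } else {
        // bond angle move at interior node v
        int v = idx - ch.M + 1;           // 1 .. M-1
        double delta = sigma_a * rng.gauss();
        double anew = ch.alp[v - 1] + delta;
        if (anew > 0 && anew < M_PI) {
          double a[3] = {ch.x[v] - ch.x[v - 1], ch.y[v] - ch.y[v - 1], ch.z[v] - ch.z[v - 1]};
          double bb[3] = {ch.x[v + 1] - ch.x[v], ch.y[v + 1] - ch.y[v], ch.z[v + 1] - ch.z[v]};
          double n[3]; cross(a, bb, n);
          double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
          if (nn > 1e-12) {
            n[0] /= nn; n[1] /= nn; n[2] /= nn;
            bool head = v < ch.M - v;     // head nodes 0..v-1, tail v+1..M
            int lo = head ? 0 : v + 1;
            int hi = head ? v - 1 : ch.M;
            double ang = head ? delta : -delta;
            double p0[3] = {ch.x[v], ch.y[v], ch.z[v]};
            propose_rotation_arm(ch, lo, hi, p0, n, ang);
            bool clash = ch.sev && sev_clash_arm(ch, lo, hi);
            if (!clash) {
              double dE = 0.5 * ch.ka * ((anew - ch.a0) * (anew - ch.a0)
                                         - (ch.alp[v - 1] - ch.a0) * (ch.alp[v - 1] - ch.a0))
                + dE_long_range(ch, lo, hi);
              if (ch.f_int != 0.0) {
                double drz = head ? -(ch.sz[0] - ch.z[0]) : (ch.sz[ch.M] - ch.z[ch.M]);
                dE -= ch.f_int * drz;
              }
              if (dE <= 0.0 || rng.unif() < std::exp(-dE)) {
                acc[2]++;
                commit_arm(ch, lo, hi);
                ch.alp[v - 1] = anew;
                ch.E += dE;
              }
            }
          }
        }
      }
    }

    if (check_every > 0 && step % check_every == 0) {
      double ef = full_energy(ch);
      double drift = std::fabs(ef - ch.E);
      if (drift > max_drift) max_drift = drift;
      ch.E = ef;
    }

    if (step > n_equil) {
      long long t = step - n_equil;
      if (t % sample_every == 0 && isample < n_samples) {
        out_np[isample] = ch.nplus;
        out_mg[isample] = ch.mg;
        double rx = ch.x[ch.M] - ch.x[0], ry = ch.y[ch.M] - ch.y[0], rz = ch.z[ch.M] - ch.z[0];
        out_rz[isample] = rz;
        out_r2[isample] = rx * rx + ry * ry + rz * rz;
        // projection of bonds j >= cbond on the direction of bond cbond
        double cx = ch.x[cbond + 1] - ch.x[cbond];
        double cy = ch.y[cbond + 1] - ch.y[cbond];
        double cz = ch.z[cbond + 1] - ch.z[cbond];
        double cn = std::sqrt(cx * cx + cy * cy + cz * cz);
        cx /= cn; cy /= cn; cz /= cn;
        double proj = 0.0;
        for (int j = cbond; j < ch.M; j++)
          proj += (ch.x[j + 1] - ch.x[j]) * cx + (ch.y[j + 1] - ch.y[j]) * cy
                + (ch.z[j + 1] - ch.z[j]) * cz;
        out_proj[isample] = proj;
        int gp = 0;
        for (int k = 0; k < ch.n_rot; k++) gp += (ch.dstate[k] == 1);
        out_gp[isample] = gp;
        out_lmid[isample] = ch.l[ch.M / 2];
        out_amid[isample] = ch.alp[(ch.M - 1) / 2];
        isample++;
      }
    }
  }

  return List::create(
    _["nplus"] = out_np, _["mg"] = out_mg, _["mg_plus"] = out_gp,
    _["rz"] = out_rz, _["r2"] = out_r2, _["proj"] = out_proj,
    _["bond_length_mid"] = out_lmid, _["bond_angle_mid"] = out_amid,
    _["attempts"] = NumericVector::create((double)att[0], (double)att[1],
                                          (double)att[2], (double)att_or),
    _["accepts"] = NumericVector::create((double)acc[0], (double)acc[1],
                                         (double)acc[2], (double)acc_or),
    _["max_energy_drift"] = max_drift,
    _["final_energy"] = ch.E,
    _["final_dstate"] = IntegerVector(ch.dstate.begin(), ch.dstate.end()),
    _["final_charges"] = NumericVector(ch.q.begin(), ch.q.end())
  );
}

// Total energy of an explicitly given state through the compiled code path
// (used to cross-check the plain-R energy functions).
// [[Rcpp::export]]
double kernel_total_energy_cpp(List topo, List ctrl, NumericVector charges,
                               IntegerVector dstate, NumericVector lengths,
                               NumericVector angles_rad) {
  Chain ch = make_chain(topo, ctrl);
  ch.dcut2 = -1.0;   // exact potential for comparisons
  for (int i = 0; i < ch.N; i++) ch.q[i] = charges[i];
  for (int k = 0; k < ch.n_rot; k++) ch.dstate[k] = dstate[k];
  for (int b = 0; b < ch.M; b++) ch.l[b] = lengths[b];
  for (int v = 0; v + 1 < ch.M; v++) ch.alp[v] = angles_rad[v];
  build_coords(ch);
  if (ch.sev) {
    // brute-force clash test over all pairs >= 4 bonds apart
    for (int p = 0; p + 4 < ch.n_nodes; p++)
      for (int qn = p + 4; qn < ch.n_nodes; qn++) {
        double dx = ch.x[p] - ch.x[qn], dy = ch.y[p] - ch.y[qn], dz = ch.z[p] - ch.z[qn];
        double rs = ch.radii[p] + ch.radii[qn];
        if (dx * dx + dy * dy + dz * dz <= rs * rs) return R_PosInf;
      }
  }
  return full_energy(ch);
}

// Coordinates built by the compiled geometry path (round-trip testing).
// [[Rcpp::export]]
NumericMatrix kernel_build_coords_cpp(List topo, IntegerVector dstate,
                                      NumericVector lengths, NumericVector angles_rad) {
  List ctrl = List::create(
    _["mode"] = 1, _["pH"] = 0.0, _["theta"] = 0.0, _["bjerrum"] = 0.0,
    _["kappa"] = 0.0, _["force_pN"] = 0.0, _["sev"] = 0, _["elastic"] = 0);
  Chain ch = make_chain(topo, ctrl);
  for (int k = 0; k < ch.n_rot; k++) ch.dstate[k] = dstate[k];
  for (int b = 0; b < ch.M; b++) ch.l[b] = lengths[b];
  for (int v = 0; v + 1 < ch.M; v++) ch.alp[v] = angles_rad[v];
  build_coords(ch);
  NumericMatrix out(ch.n_nodes, 3);
  for (int p = 0; p < ch.n_nodes; p++) {
    out(p, 0) = ch.x[p]; out(p, 1) = ch.y[p]; out(p, 2) = ch.z[p];
  }
  return out;
}
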