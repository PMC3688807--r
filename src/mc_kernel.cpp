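// Monte Carlo kernel for the coarse-grained C-alpha potential.
//
// Implements the five-term CG energy, the local move set (crankshaft,
// bond, angle), incremental energy differences over the terms touched by
// a move, and the Metropolis/simulated-annealing run loop. Randomness
// comes from R's RNG so a single set.seed() reproduces whole trajectories.
//
// Move acceptance includes the configuration-space volume factors of the
// non-volume-preserving moves (bond: (r'/r)^2, angle: sin(th')/sin(th))
// so that fixed-beta sampling targets the Cartesian Boltzmann measure.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double wrap_pi(double x) {
  // (-pi, pi] wrap without fmod (fmod gained a new symbol version in
  // recent glibc, which breaks loading on older loaders)
  double y = x + M_PI;
  y -= 2.0 * M_PI * std::floor(y / (2.0 * M_PI));
  y -= M_PI;
  if (y <= -M_PI) y = M_PI;
  return y;
}

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  Vec3 unit() const { double n = norm(); return Vec3(x / n, y / n, z / n); }
};

struct CGParamsC {
  // per-letter: theta0_1, theta0_2, tau0, k_theta, k_tau, e_ref
  std::vector<double> th01, th02, tau0, kth, kta, eref;
  std::vector<double> eref2;  // k x k, column-major
  int nlet;
  std::vector<double> proto;  // k x 3 column-major prototypes
  std::vector<double> bond_r0;  // per bond
  double bond_k;
  double r_rep, k_rep;
  int min_sep;
  std::vector<double> hb_edges, hb_values;
  double pn_off, po_off, mix;

  CGParamsC(const List& p, int nbond) {
    NumericMatrix L = p["letters"];
    nlet = L.nrow();
    th01.resize(nlet); th02.resize(nlet); tau0.resize(nlet);
    kth.resize(nlet); kta.resize(nlet); eref.resize(nlet);
    for (int i = 0; i < nlet; ++i) {
      th01[i] = L(i, 0); th02[i] = L(i, 1); tau0[i] = L(i, 2);
      kth[i] = L(i, 3); kta[i] = L(i, 4); eref[i] = L(i, 5);
    }
    NumericMatrix E2 = p["e_ref2"];
    eref2.assign(E2.begin(), E2.end());
    NumericMatrix P = p["prototypes"];
    proto.assign(P.begin(), P.end());
    NumericVector br0 = p["bond_r0"];
    bond_r0.assign(br0.begin(), br0.end());
    if ((int)bond_r0.size() == 1 && nbond > 1)
      bond_r0.assign(nbond, bond_r0[0]);
    bond_k = as<double>(p["bond_k"]);
    r_rep = as<double>(p["r_rep"]);
    k_rep = as<double>(p["k_rep"]);
    min_sep = as<int>(p["min_sep"]);
    NumericVector he = p["hb_edges"], hv = p["hb_values"];
    hb_edges.assign(he.begin(), he.end());
    hb_values.assign(hv.begin(), hv.end());
    pn_off = as<double>(p["pn_offset"]);
    po_off = as<double>(p["po_offset"]);
    mix = as<double>(p["mix_angle"]);
  }
};

struct System {
  int n;
  std::vector<Vec3> x;
  std::vector<char> mobile;
  const CGParamsC& par;

  System(const NumericMatrix& coords, const LogicalVector& mob,
         const CGParamsC& p) : par(p) {
    n = coords.nrow();
    x.resize(n);
    mobile.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = Vec3(coords(i, 0), coords(i, 1), coords(i, 2));
      mobile[i] = mob[i] ? 1 : 0;
    }
  }

  double dist(int i, int j) const { return (x[i] - x[j]).norm(); }

  double angle_at(int i) const {  // 0-based interior
    Vec3 u = x[i - 1] - x[i], v = x[i + 1] - x[i];
    double c = u.dot(v) / (u.norm() * v.norm());
    c = std::max(-1.0, std::min(1.0, c));
    return std::acos(c);
  }

  double dihedral_from(int i) const {  // tetrad i..i+3, 0-based
    Vec3 b1 = x[i + 1] - x[i], b2 = x[i + 2] - x[i + 1], b3 = x[i + 3] - x[i + 2];
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    Vec3 m1 = n1.cross(b2.unit());
    return std::atan2(m1.dot(n2), n1.dot(n2));
  }

  // pseudo N/O of interior residue k (0-based); returns false if degenerate
  bool pseudo_atoms(int k, Vec3& pn, Vec3& po) const {
    Vec3 u1 = (x[k - 1] - x[k]).unit();
    Vec3 u2 = (x[k + 1] - x[k]).unit();
    Vec3 b = u1 + u2;
    double nb = b.norm();
    if (nb < 1e-9) return false;
    b = b * (1.0 / nb);
    Vec3 m = u1.cross(u2);
    double nm = m.norm();
    if (nm < 1e-12) return false;
    m = m * (1.0 / nm);
    double cg = std::cos(par.mix), sg = std::sin(par.mix);
    Vec3 dn = b * cg + m * sg;
    Vec3 dv = b * cg - m * sg;
    pn = x[k] + dn * par.pn_off;
    po = x[k] + dv * par.po_off;
    return true;
  }

  int letter_of(int f) const {  // fragment starting at 0-based f
    double t1 = angle_at(f + 1);
    double t2 = angle_at(f + 2);
    double ta = dihedral_from(f);
    int best = 0;
    double bd = 1e300;
    int k = par.nlet;
    for (int j = 0; j < k; ++j) {
      double d1 = t1 - par.proto[j];
      double d2 = t2 - par.proto[j + k];
      double d3 = wrap_pi(ta - par.proto[j + 2 * k]);
      double d = d1 * d1 + d2 * d2 + d3 * d3;
      if (d < bd) { bd = d; best = j; }  // ties keep the lowest index
    }
    return best;
  }

  double e_bond_one(int b) const {  // bond b: atoms b, b+1 (0-based)
    double r = dist(b, b + 1);
    double dr = r - par.bond_r0[b];
    return 0.5 * par.bond_k * dr * dr;
  }

  double e_steric_pair(int i, int j) const {
    double r = dist(i, j);
    if (r >= par.r_rep) return 0.0;
    double d = par.r_rep - r;
    return 0.5 * par.k_rep * d * d;
  }

  double hb_lookup(double r) const {
    int nb = par.hb_values.size();
    if (nb == 0) return 0.0;
    if (r >= par.hb_edges[nb]) return 0.0;
    if (r < par.hb_edges[0]) return par.hb_values[0];
    int lo = 0, hi = nb;  // find bin: edges[b] <= r < edges[b+1]
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (r >= par.hb_edges[mid]) lo = mid; else hi = mid;
    }
    return par.hb_values[lo];
  }

  bool has_hb() const {
    for (size_t i = 0; i < par.hb_values.size(); ++i)
      if (par.hb_values[i] != 0.0) return true;
    return false;
  }

  double e_hb_pair(int i, int j) const {  // pseudo-N(i)...pseudo-O(j)
    Vec3 ni, oi, nj, oj;
    if (!pseudo_atoms(i, ni, oi)) return 0.0;
    if (!pseudo_atoms(j, nj, oj)) return 0.0;
    return hb_lookup((ni - oj).norm());
  }

  double e_frag(int f, int* letter_out = 0) const {
    int L = letter_of(f);
    if (letter_out) *letter_out = L;
    double t1 = angle_at(f + 1), t2 = angle_at(f + 2), ta = dihedral_from(f);
    double d1 = t1 - par.th01[L], d2 = t2 - par.th02[L];
    double d3 = wrap_pi(ta - par.tau0[L]);
    return 0.5 * par.kth[L] * (d1 * d1 + d2 * d2) +
           0.5 * par.kta[L] * d3 * d3 + par.eref[L];
  }

  // energy of all terms touched by flagged residues; flags may be the
  // mobility mask (total mobile-relevant energy) or a move's moved set
  void energy_touched(const std::vector<char>& flag, double out[5]) const {
    double e_sa = 0, e_ref_tot = 0, e_b = 0, e_st = 0, e_hb = 0;
    // bonds
    for (int b = 0; b < n - 1; ++b)
      if (flag[b] || flag[b + 1]) e_b += e_bond_one(b);
    // fragments and bigrams
    if (n >= 4) {
      std::vector<int> lett(n - 3, -1);
      std::vector<char> ftouch(n - 3, 0);
      for (int f = 0; f <= n - 4; ++f) {
        bool t = flag[f] || flag[f + 1] || flag[f + 2] || flag[f + 3];
        ftouch[f] = t;
      }
      std::vector<char> btouch(std::max(0, n - 4), 0);
      for (int f = 0; f + 1 <= n - 4; ++f) {
        bool t = ftouch[f] || ftouch[f + 1] || flag[f + 4];
        btouch[f] = t;
      }
      for (int f = 0; f <= n - 4; ++f) {
        if (ftouch[f] || (f <= n - 5 && btouch[f]) || (f > 0 && btouch[f - 1])) {
          int L;
          double e = e_frag(f, &L);
          lett[f] = L;
          if (ftouch[f]) { e_sa += e - par.eref[L]; e_ref_tot += par.eref[L]; }
        }
      }
      for (int f = 0; f + 1 <= n - 4; ++f)
        if (btouch[f] && lett[f] >= 0 && lett[f + 1] >= 0)
          e_ref_tot += par.eref2[lett[f] + par.nlet * lett[f + 1]];
    }
    // steric
    for (int i = 0; i < n; ++i) {
      if (!flag[i]) continue;
      for (int j = 0; j < n; ++j) {
        if (std::abs(i - j) < par.min_sep) continue;
        if (flag[j] && j <= i) continue;  // count both-flagged pairs once
        e_st += e_steric_pair(std::min(i, j), std::max(i, j));
      }
    }
    // hbond: pseudo atoms of residue k depend on k-1, k, k+1
    if (n >= 3 && has_hb()) {
      std::vector<char> ktouch(n, 0);
      for (int k = 1; k < n - 1; ++k)
        ktouch[k] = flag[k - 1] || flag[k] || flag[k + 1];
      for (int i = 1; i < n - 1; ++i) {
        for (int j = 1; j < n - 1; ++j) {
          if (std::abs(i - j) < 2) continue;
          if (!(ktouch[i] || ktouch[j])) continue;
          e_hb += e_hb_pair(i, j);
        }
      }
    }
    out[0] = e_sa; out[1] = e_b; out[2] = e_st; out[3] = e_hb; out[4] = e_ref_tot;
  }

  double energy_touched_total(const std::vector<char>& flag) const {
    double c[5];
    energy_touched(flag, c);
    return c[0] + c[1] + c[2] + c[3] + c[4];
  }
};

static List pack_components(const double c[5]) {
  double tot = c[0] + c[1] + c[2] + c[3] + c[4];
  return List::create(_["e_sa_local"] = c[0], _["e_bond"] = c[1],
                      _["e_steric"] = c[2], _["e_hbond"] = c[3],
                      _["e_ref_total"] = c[4], _["total"] = tot);
}

// [[Rcpp::export(name = ".pd2_energy_cpp")]]
List pd2_energy_cpp(NumericMatrix coords, LogicalVector mobile, List params) {
  CGParamsC par(params, std::max(1, (int)coords.nrow() - 1));
  System sys(coords, mobile, par);
  double c[5];
  sys.energy_touched(sys.mobile, c);
  return pack_components(c);
}

// [[Rcpp::export(name = ".pd2_delta_energy_cpp")]]
double pd2_delta_energy_cpp(NumericMatrix coords, IntegerVector moved,
                            NumericMatrix new_pos, LogicalVector mobile,
                            List params) {
  CGParamsC par(params, std::max(1, (int)coords.nrow() - 1));
  System sys(coords, mobile, par);
  std::vector<char> flag(sys.n, 0);
  for (int k = 0; k < moved.size(); ++k) flag[moved[k] - 1] = 1;
  double e0 = sys.energy_touched_total(flag);
  for (int k = 0; k < moved.size(); ++k)
    sys.x[moved[k] - 1] = Vec3(new_pos(k, 0), new_pos(k, 1), new_pos(k, 2));
  double e1 = sys.energy_touched_total(flag);
  return e1 - e0;
}

// rotate p about axis through `o` with unit direction `a` by angle t
static inline Vec3 rot_axis(const Vec3& p, const Vec3& o, const Vec3& a, double t) {
  Vec3 v = p - o;
  double c = std::cos(t), s = std::sin(t);
  Vec3 out = v * c + a.cross(v) * s + a * (a.dot(v) * (1 - c));
  return out + o;
}

// [[Rcpp::export(name = ".pd2_run_mc_cpp")]]
List pd2_run_mc_cpp(NumericMatrix coords, LogicalVector mobile,
                    IntegerMatrix cranks, IntegerVector bond_moves,
                    IntegerVector angle_moves, NumericVector weights,
                    double max_rot, double max_trans, NumericVector beta,
                    List params, int record_stride, int trace_stride,
                    int drift_check_every) {
  CGParamsC par(params, std::max(1, (int)coords.nrow() - 1));
  System sys(coords, mobile, par);
  int n_steps = beta.size();
  RNGScope scope;

  // cumulative move-type weights over non-empty move lists
  double w[3] = {weights[0], weights[1], weights[2]};
  if (cranks.nrow() == 0) w[0] = 0;
  if (bond_moves.size() == 0) w[1] = 0;
  if (angle_moves.size() == 0) w[2] = 0;
  double wsum = w[0] + w[1] + w[2];
  if (wsum <= 0) stop("no eligible moves for this system");
  double cw0 = w[0] / wsum, cw1 = (w[0] + w[1]) / wsum;

  double e_cur = sys.energy_touched_total(sys.mobile);
  double drift_max = 0.0;
  int acc[3] = {0, 0, 0}, prop[3] = {0, 0, 0}, invalid = 0;

  int n_mob = 0;
  for (int i = 0; i < sys.n; ++i) if (sys.mobile[i]) ++n_mob;
  std::vector<int> mob_idx;
  for (int i = 0; i < sys.n; ++i) if (sys.mobile[i]) mob_idx.push_back(i);

  int n_rec = record_stride > 0 ? n_steps / record_stride : 0;
  NumericMatrix samples(n_rec, 3 * n_mob);
  int n_tr = trace_stride > 0 ? n_steps / trace_stride : 0;
  NumericMatrix trace(n_tr, 3);  // step, beta, total
  int rec_i = 0, tr_i = 0;

  std::vector<char> flag(sys.n);
  std::vector<int> moved;
  std::vector<Vec3> oldpos;

  for (int step = 0; step < n_steps; ++step) {
    double b = beta[step];
    double u = unif_rand();
    int type = (u < cw0) ? 0 : (u < cw1 ? 1 : 2);
    ++prop[type];
    moved.clear();
    double logJ = 0.0;
    bool valid = true;

    if (type == 0) {  // crankshaft
      int m = cranks.nrow();
      int pick = std::min(m - 1, (int)(unif_rand() * m));
      int i = cranks(pick, 0) - 1, j = cranks(pick, 1) - 1;
      double ang = (2.0 * unif_rand() - 1.0) * max_rot;
      Vec3 axis = sys.x[j] - sys.x[i];
      if (axis.norm() < 1e-6) { valid = false; }
      else {
        Vec3 a = axis.unit();
        for (int k = i + 1; k < j; ++k) moved.push_back(k);
        std::fill(flag.begin(), flag.end(), 0);
        for (size_t k = 0; k < moved.size(); ++k) flag[moved[k]] = 1;
        double e0 = sys.energy_touched_total(flag);
        oldpos.clear();
        for (size_t k = 0; k < moved.size(); ++k) {
          oldpos.push_back(sys.x[moved[k]]);
          sys.x[moved[k]] = rot_axis(sys.x[moved[k]], sys.x[i], a, ang);
        }
        double e1 = sys.energy_touched_total(flag);
        double dE = e1 - e0;
        bool accept = dE <= 0 || unif_rand() < std::exp(-b * dE + logJ);
        if (!std::isfinite(dE)) accept = false;
        if (accept) { e_cur += dE; ++acc[0]; }
        else for (size_t k = 0; k < moved.size(); ++k) sys.x[moved[k]] = oldpos[k];
      }
    } else if (type == 1) {  // bond move
      int m = bond_moves.size();
      int pick = std::min(m - 1, (int)(unif_rand() * m));
      int i = bond_moves[pick] - 1;
      double delta = (2.0 * unif_rand() - 1.0) * max_trans;
      Vec3 bv = sys.x[i + 1] - sys.x[i];
      double r = bv.norm();
      double rnew = r + 2.0 * delta;
      if (r < 1e-9 || rnew <= 1e-3) { valid = false; }
      else {
        Vec3 uhat = bv * (1.0 / r);
        logJ = 2.0 * std::log(rnew / r);  // Cartesian volume factor
        std::fill(flag.begin(), flag.end(), 0);
        flag[i] = 1; flag[i + 1] = 1;
        double e0 = sys.energy_touched_total(flag);
        Vec3 o1 = sys.x[i], o2 = sys.x[i + 1];
        sys.x[i] = o1 - uhat * delta;
        sys.x[i + 1] = o2 + uhat * delta;
        double e1 = sys.energy_touched_total(flag);
        double dE = e1 - e0;
        double logr = -b * dE + logJ;
        bool accept = logr >= 0 || unif_rand() < std::exp(logr);
        if (!std::isfinite(dE)) accept = false;
        if (accept) { e_cur += dE; ++acc[1]; }
        else { sys.x[i] = o1; sys.x[i + 1] = o2; }
      }
    } else {  // angle move
      int m = angle_moves.size();
      int pick = std::min(m - 1, (int)(unif_rand() * m));
      int i = angle_moves[pick] - 1;  // centre
      double ang = (2.0 * unif_rand() - 1.0) * max_rot;
      Vec3 u1 = sys.x[i - 1] - sys.x[i], u2 = sys.x[i + 1] - sys.x[i];
      Vec3 nrm = u1.cross(u2);
      double snorm = nrm.norm();
      if (snorm < 1e-9) { valid = false; }
      else {
        Vec3 a = nrm * (1.0 / snorm);
        double th0 = sys.angle_at(i);
        std::fill(flag.begin(), flag.end(), 0);
        flag[i - 1] = 1; flag[i + 1] = 1;
        double e0 = sys.energy_touched_total(flag);
        Vec3 o1 = sys.x[i - 1], o2 = sys.x[i + 1];
        sys.x[i - 1] = rot_axis(o1, sys.x[i], a, ang);
        sys.x[i + 1] = rot_axis(o2, sys.x[i], a, -ang);
        double th1 = sys.angle_at(i);
        logJ = std::log(std::max(std::sin(th1), 1e-12)) -
               std::log(std::max(std::sin(th0), 1e-12));
        double e1 = sys.energy_touched_total(flag);
        double dE = e1 - e0;
        double logr = -b * dE + logJ;
        bool accept = logr >= 0 || unif_rand() < std::exp(logr);
        if (!std::isfinite(dE)) accept = false;
        if (accept) { e_cur += dE; ++acc[2]; }
        else { sys.x[i - 1] = o1; sys.x[i + 1] = o2; }
      }
    }
    if (!valid) ++invalid;

    if (drift_check_every > 0 && (step + 1) % drift_check_every == 0) {
      double e_full = sys.energy_touched_total(sys.mobile);
      drift_max = std::max(drift_max, std::fabs(e_full - e_cur));
      e_cur = e_full;
    }
    if (record_stride > 0 && (step + 1) % record_stride == 0 && rec_i < n_rec) {
      for (int k = 0; k < n_mob; ++k) {
        samples(rec_i, 3 * k) = sys.x[mob_idx[k]].x;
        samples(rec_i, 3 * k + 1) = sys.x[mob_idx[k]].y;
        samples(rec_i, 3 * k + 2) = sys.x[mob_idx[k]].z;
      }
      ++rec_i;
    }
    if (trace_stride > 0 && (step + 1) % trace_stride == 0 && tr_i < n_tr) {
      trace(tr_i, 0) = step + 1;
      trace(tr_i, 1) = b;
      trace(tr_i, 2) = e_cur;
      ++tr_i;
    }
  }

  NumericMatrix out(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    out(i, 0) = sys.x[i].x; out(i, 1) = sys.x[i].y; out(i, 2) = sys.x[i].z;
  }
  double comp[5];
  sys.energy_touched(sys.mobile, comp);
  return List::create(_["coords"] = out,
                      _["energy"] = pack_components(comp),
                      _["accepted"] = IntegerVector::create(acc[0], acc[1], acc[2]),
                      _["proposed"] = IntegerVector::create(prop[0], prop[1], prop[2]),
                      _["invalid"] = invalid,
                      _["drift_max"] = drift_max,
                      _["samples"] = samples,
                      _["trace"] = trace);
}
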