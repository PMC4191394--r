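// Coarse-grained force field evaluation and Langevin (BAOAB) dynamics.
// Units: length Angstrom, energy kcal/mol, mass amu, time ps.
// KFAC converts kcal/mol to amu*A^2/ps^2.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

static const double KFAC = 418.4;

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
  double norm2() const { return dot(*this); }
  double norm() const { return std::sqrt(norm2()); }
};

struct ForceField {
  int n;
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_kt;
  std::vector<int> im_i, im_j, im_k, im_l; std::vector<double> im_p0, im_ki;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_p0, d_kd;
  std::vector<double> radius, mass;
  std::vector<int> attract;
  double eps, eps_stack, cutoff;
  std::vector<int> r_i, r_j;
  std::vector<double> r_min, r_max, r_k, r_cap;
  std::unordered_set<int64_t> excl;

  bool excluded(int i, int j) const {
    int a = i < j ? i : j, b = i < j ? j : i;
    return excl.count((int64_t)a * (int64_t)n + b) > 0;
  }
};

static void ivec(const List& d, const char* nm, std::vector<int>& out,
                 int off = 1) {
  IntegerVector v = as<IntegerVector>(d[nm]);
  out.resize(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - off;
}
static void dvec(const List& d, const char* nm, std::vector<double>& out) {
  NumericVector v = as<NumericVector>(d[nm]);
  out.assign(v.begin(), v.end());
}

static ForceField parse_ff(const List& ff) {
  ForceField f;
  f.n = as<int>(ff["n"]);
  List b = ff["bonds"];
  ivec(b, "i", f.b_i); ivec(b, "j", f.b_j);
  dvec(b, "r0", f.b_r0); dvec(b, "k", f.b_k);
  List a = ff["angles"];
  ivec(a, "i", f.a_i); ivec(a, "j", f.a_j); ivec(a, "k", f.a_k);
  dvec(a, "th0", f.a_t0); dvec(a, "kth", f.a_kt);
  List im = ff["impropers"];
  ivec(im, "i", f.im_i); ivec(im, "j", f.im_j);
  ivec(im, "k", f.im_k); ivec(im, "l", f.im_l);
  dvec(im, "phi0", f.im_p0); dvec(im, "kimp", f.im_ki);
  List d = ff["dihedrals"];
  ivec(d, "i", f.d_i); ivec(d, "j", f.d_j);
  ivec(d, "k", f.d_k); ivec(d, "l", f.d_l);
  dvec(d, "phi0", f.d_p0); dvec(d, "kdih", f.d_kd);
  dvec(ff, "radius", f.radius);
  dvec(ff, "mass", f.mass);
  ivec(ff, "attract", f.attract, 0);
  f.eps = as<double>(ff["eps"]);
  f.eps_stack = as<double>(ff["eps_stack"]);
  f.cutoff = as<double>(ff["cutoff"]);
  List r = ff["restraints"];
  ivec(r, "bi", f.r_i); ivec(r, "bj", f.r_j);
  dvec(r, "rmin", f.r_min); dvec(r, "rmax", f.r_max);
  dvec(r, "k", f.r_k); dvec(r, "fcap", f.r_cap);

  // nonbonded exclusions: 1-2 and 1-3 over the bond graph
  std::vector<std::vector<int>> adj(f.n);
  for (size_t e = 0; e < f.b_i.size(); ++e) {
    adj[f.b_i[e]].push_back(f.b_j[e]);
    adj[f.b_j[e]].push_back(f.b_i[e]);
  }
  auto addx = [&](int i, int j) {
    if (i == j) return;
    int a = i < j ? i : j, b = i < j ? j : i;
    f.excl.insert((int64_t)a * (int64_t)f.n + b);
  };
  for (int i = 0; i < f.n; ++i) {
    for (int j : adj[i]) {
      addx(i, j);
      for (int k : adj[j]) addx(i, k);
    }
  }
  return f;
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2 * M_PI;
  while (x <= -M_PI) x += 2 * M_PI;
  return x;
}

// flat-bottom restraint: energy and dE/dd at distance d
static inline void restraint_ef(double d, double rmin, double rmax, double k,
                                double cap, double& e, double& dedd) {
  double delta = 0, sgn = 0;
  if (d < rmin) { delta = rmin - d; sgn = -1; }
  else if (d > rmax) { delta = d - rmax; sgn = 1; }
  else { e = 0; dedd = 0; return; }
  double dstar = cap / k;
  if (delta <= dstar) { e = 0.5 * k * delta * delta; dedd = sgn * k * delta; }
  else { e = 0.5 * k * dstar * dstar + cap * (delta - dstar); dedd = sgn * cap; }
}

struct EnergyAcc {
  double bond = 0, angle = 0, improper = 0, dihedral = 0, lj = 0,
         restraint = 0;
  double total() const {
    return bond + angle + improper + dihedral + lj + restraint;
  }
};

class Engine {
public:
  ForceField ff;
  std::vector<Vec3> x, frc;
  // Verlet neighbor list
  std::vector<std::pair<int, int>> nlist;
  std::vector<Vec3> x_at_build;
  double skin = 2.0;
  bool have_list = false;

  explicit Engine(const ForceField& f) : ff(f), x(f.n), frc(f.n) {}

  void set_coords(const NumericMatrix& m) {
    for (int i = 0; i < ff.n; ++i) x[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
    have_list = false;
  }

  void build_list() {
    nlist.clear();
    double rl = ff.cutoff + skin;
    double rl2 = rl * rl;
    for (int i = 0; i < ff.n; ++i) {
      for (int j = i + 1; j < ff.n; ++j) {
        Vec3 d = x[j] - x[i];
        if (d.norm2() < rl2 && !ff.excluded(i, j)) nlist.emplace_back(i, j);
      }
    }
    x_at_build = x;
    have_list = true;
  }

  void maybe_rebuild() {
    if (!have_list) { build_list(); return; }
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < ff.n; ++i) {
      if ((x[i] - x_at_build[i]).norm2() > lim) { build_list(); return; }
    }
  }

  EnergyAcc compute_forces() {
    EnergyAcc e;
    for (auto& f : frc) f = Vec3();
    // bonds: E = k (r - r0)^2
    for (size_t t = 0; t < ff.b_i.size(); ++t) {
      int i = ff.b_i[t], j = ff.b_j[t];
      Vec3 d = x[j] - x[i];
      double r = d.norm();
      double dr = r - ff.b_r0[t];
      e.bond += ff.b_k[t] * dr * dr;
      double g = 2.0 * ff.b_k[t] * dr / (r > 1e-12 ? r : 1e-12);
      Vec3 f = d * g;
      frc[i] = frc[i] + f;
      frc[j] = frc[j] - f;
    }
    // angles: E = k (theta - theta0)^2, theta in radians
    for (size_t t = 0; t < ff.a_i.size(); ++t) {
      int i = ff.a_i[t], j = ff.a_j[t], k = ff.a_k[t];
      Vec3 a = x[i] - x[j], b = x[k] - x[j];
      double la = a.norm(), lb = b.norm();
      double ct = a.dot(b) / (la * lb);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
      double dth = th - ff.a_t0[t];
      e.angle += ff.a_kt[t] * dth * dth;
      double g = -2.0 * ff.a_kt[t] * dth / st;  // -dE/dtheta / sin
      Vec3 ah = a * (1.0 / la), bh = b * (1.0 / lb);
      Vec3 fi = (bh - ah * ct) * (g / la) * (-1.0);
      Vec3 fk = (ah - bh * ct) * (g / lb) * (-1.0);
      frc[i] = frc[i] + fi;
      frc[k] = frc[k] + fk;
      frc[j] = frc[j] - fi - fk;
    }
    dihedral_terms(ff.d_i, ff.d_j, ff.d_k, ff.d_l, ff.d_p0, ff.d_kd, false,
                   e.dihedral);
    dihedral_terms(ff.im_i, ff.im_j, ff.im_k, ff.im_l, ff.im_p0, ff.im_ki,
                   true, e.improper);
    // nonbonded LJ
    maybe_rebuild();
    double rc2 = ff.cutoff * ff.cutoff;
    for (auto& pr : nlist) {
      int i = pr.first, j = pr.second;
      Vec3 d = x[j] - x[i];
      double r2 = d.norm2();
      if (r2 >= rc2) continue;
      double rm = ff.radius[i] + ff.radius[j];
      double epsij = (ff.attract[i] && ff.attract[j]) ? ff.eps_stack : ff.eps;
      double s2 = rm * rm / r2;
      double s6 = s2 * s2 * s2;
      e.lj += epsij * (s6 * s6 - 2.0 * s6);
      double g = epsij * 12.0 * (s6 * s6 - s6) / r2;  // -dE/dr / r
      Vec3 f = d * (-g);
      frc[i] = frc[i] + f;
      frc[j] = frc[j] - f;
    }
    // flat-bottom restraints
    for (size_t t = 0; t < ff.r_i.size(); ++t) {
      int i = ff.r_i[t], j = ff.r_j[t];
      Vec3 d = x[j] - x[i];
      double r = d.norm();
      double er, dedd;
      restraint_ef(r, ff.r_min[t], ff.r_max[t], ff.r_k[t], ff.r_cap[t], er,
                   dedd);
      e.restraint += er;
      double g = dedd / (r > 1e-12 ? r : 1e-12);
      Vec3 f = d * g;
      frc[i] = frc[i] + f;
      frc[j] = frc[j] - f;
    }
    return e;
  }

  // E = kd (1 - cos(phi - phi0)) for dihedrals,
  // E = kd * wrap(phi - phi0)^2 for impropers (harmonic flag)
  void dihedral_terms(const std::vector<int>& vi, const std::vector<int>& vj,
                      const std::vector<int>& vk, const std::vector<int>& vl,
                      const std::vector<double>& p0,
                      const std::vector<double>& kd, bool harmonic,
                      double& esum) {
    for (size_t t = 0; t < vi.size(); ++t) {
      int i = vi[t], j = vj[t], k = vk[t], l = vl[t];
      Vec3 b1 = x[j] - x[i], b2 = x[k] - x[j], b3 = x[l] - x[k];
      Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
      double n1n2 = n1.norm2(), n2n2 = n2.norm2();
      double b2n = b2.norm();
      if (n1n2 < 1e-10 || n2n2 < 1e-10 || b2n < 1e-8) continue;
      Vec3 u2 = b2 * (1.0 / b2n);
      double cphi = n1.dot(n2);
      double sphi = n1.cross(u2).dot(n2);
      double phi = std::atan2(sphi, cphi);
      double dphi = wrap_pi(phi - p0[t]);
      double g;  // dE/dphi
      if (harmonic) {
        esum += kd[t] * dphi * dphi;
        g = 2.0 * kd[t] * dphi;
      } else {
        esum += kd[t] * (1.0 - std::cos(dphi));
        g = kd[t] * std::sin(dphi);
      }
      // dphi/dri = (b2n/|n1|^2) n1, dphi/drl = -(b2n/|n2|^2) n2 for the
      // atan2((n1 x u2).n2, n1.n2) convention; j/k terms follow from
      // translational and rotational invariance
      Vec3 fi = n1 * (-g * b2n / n1n2);
      Vec3 fl = n2 * (g * b2n / n2n2);
      // near-collinear backbone geometries make the dihedral angle
      // ill-conditioned (|n1| -> 0); cap the term's force magnitude with a
      // uniform scale so net force and torque stay zero
      const double FCAP_DIH = 50.0;
      double fmax2 = std::max(fi.norm2(), fl.norm2());
      if (fmax2 > FCAP_DIH * FCAP_DIH) {
        double sc = FCAP_DIH / std::sqrt(fmax2);
        fi = fi * sc;
        fl = fl * sc;
      }
      double p = b1.dot(b2) / (b2n * b2n);
      double q = b3.dot(b2) / (b2n * b2n);
      Vec3 fj = fi * (-(1.0 + p)) + fl * q;
      Vec3 fk = fi * p - fl * (1.0 + q);
      frc[i] = frc[i] + fi;
      frc[j] = frc[j] + fj;
      frc[k] = frc[k] + fk;
      frc[l] = frc[l] + fl;
    }
  }
};

// --- deterministic RNG: splitmix64 seeding + xoshiro256++, Box-Muller ---
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0, u2;
    while (u1 <= 1e-300) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2 * M_PI * u2);
  }
};

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List ff) {
  ForceField f = parse_ff(ff);
  if (coords.nrow() != f.n) stop("coordinate/topology bead count mismatch");
  Engine eng(f);
  eng.set_coords(coords);
  EnergyAcc e = eng.compute_forces();
  NumericMatrix fr(f.n, 3);
  for (int i = 0; i < f.n; ++i) {
    fr(i, 0) = eng.frc[i].x; fr(i, 1) = eng.frc[i].y; fr(i, 2) = eng.frc[i].z;
  }
  return List::create(
    _["energy"] = e.total(), _["forces"] = fr,
    _["breakdown"] = NumericVector::create(
      _["bond"] = e.bond, _["angle"] = e.angle, _["improper"] = e.improper,
      _["dihedral"] = e.dihedral, _["lj"] = e.lj,
      _["restraint"] = e.restraint));
}

// BAOAB Langevin segment; gamma = 0 gives velocity Verlet (NVE).
// [[Rcpp::export]]
List cpp_run_segment(NumericMatrix coords, NumericMatrix vel, List ff,
                     int n_steps, double dt, double gamma, double kT,
                     double seed) {
  ForceField f = parse_ff(ff);
  if (coords.nrow() != f.n || vel.nrow() != f.n)
    stop("coordinate/topology bead count mismatch");
  Engine eng(f);
  eng.set_coords(coords);
  std::vector<Vec3> v(f.n);
  for (int i = 0; i < f.n; ++i) v[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));
  Rng rng((uint64_t)seed);

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  std::vector<double> inv_m(f.n), sig(f.n);
  for (int i = 0; i < f.n; ++i) {
    inv_m[i] = KFAC / f.mass[i];
    sig[i] = std::sqrt(kT * KFAC / f.mass[i]);
  }

  EnergyAcc e = eng.compute_forces();
  double half = 0.5 * dt;
  double ke_mid_sum = 0;
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < f.n; ++i) {
      v[i] = v[i] + eng.frc[i] * (half * inv_m[i]);
      eng.x[i] = eng.x[i] + v[i] * half;
    }
    if (gamma > 0) {
      for (int i = 0; i < f.n; ++i) {
        Vec3 xi(rng.gauss(), rng.gauss(), rng.gauss());
        v[i] = v[i] * c1 + xi * (c2 * sig[i]);
      }
    }
    double kem = 0;
    for (int i = 0; i < f.n; ++i) kem += 0.5 * f.mass[i] * v[i].norm2();
    ke_mid_sum += kem / KFAC;
    for (int i = 0; i < f.n; ++i) eng.x[i] = eng.x[i] + v[i] * half;
    e = eng.compute_forces();
    for (int i = 0; i < f.n; ++i)
      v[i] = v[i] + eng.frc[i] * (half * inv_m[i]);
    if (s % 200 == 0) {
      bool bad = false;
      for (int i = 0; i < f.n && !bad; ++i)
        if (!std::isfinite(eng.x[i].x) || !std::isfinite(eng.x[i].y) ||
            !std::isfinite(eng.x[i].z)) bad = true;
      if (bad) stop("numerical blow-up: non-finite coordinates at step %d",
                    s + 1);
    }
  }
  NumericMatrix xo(f.n, 3), vo(f.n, 3);
  double ke = 0;
  for (int i = 0; i < f.n; ++i) {
    xo(i, 0) = eng.x[i].x; xo(i, 1) = eng.x[i].y; xo(i, 2) = eng.x[i].z;
    vo(i, 0) = v[i].x; vo(i, 1) = v[i].y; vo(i, 2) = v[i].z;
    ke += 0.5 * f.mass[i] * v[i].norm2() / KFAC;
  }
  return List::create(_["coords"] = xo, _["vel"] = vo,
                      _["epot"] = e.total(), _["ekin"] = ke,
                      _["ekin_mid"] = ke_mid_sum / n_steps);
}

// capped steepest-descent minimization (used by the reference builder)
// [[Rcpp::export]]
NumericMatrix cpp_minimize(NumericMatrix coords, List ff, int n_steps,
                           double max_step) {
  ForceField f = parse_ff(ff);
  Engine eng(f);
  eng.set_coords(coords);
  double step = max_step;
  double eprev = eng.compute_forces().total();
  std::vector<Vec3> xprev = eng.x;
  for (int s = 0; s < n_steps; ++s) {
    double fmax = 1e-12;
    for (int i = 0; i < f.n; ++i)
      fmax = std::max(fmax, eng.frc[i].norm());
    double sc = step / fmax;
    xprev = eng.x;
    for (int i = 0; i < f.n; ++i) eng.x[i] = eng.x[i] + eng.frc[i] * sc;
    eng.have_list = false;
    double e = eng.compute_forces().total();
    if (e > eprev) {
      eng.x = xprev;
      eng.have_list = false;
      eng.compute_forces();
      step *= 0.5;
      if (step < 1e-6) break;
    } else {
      eprev = e;
      step = std::min(max_step, step * 1.2);
    }
  }
  NumericMatrix xo(f.n, 3);
  for (int i = 0; i < f.n; ++i) {
    xo(i, 0) = eng.x[i].x; xo(i, 1) = eng.x[i].y; xo(i, 2) = eng.x[i].z;
  }
  return xo;
}
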