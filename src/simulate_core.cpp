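#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

// Monte Carlo core of the injection-diffusion model.
//
// State: rear-edge coordinates x[0] < x[1] < ... of unfolded monomers in the
// channel (each occupies [x, x+ell]), current filament length L, elapsed
// time t.  Per time step dt every monomer, visited in a fresh random
// permutation, takes an overdamped Brownian move sqrt(2*D*dt)*Z clipped so it
// neither overlaps a neighbour nor re-enters the base (x >= 0).  A monomer
// whose front edge reaches the tip crystallizes immediately: it leaves the
// channel and L grows by dL.  Loading attempts fire on a fixed clock every
// 1/S_load seconds; an attempt may push up to LS resident monomers forward
// (minimal displacement, never past the tip) to clear the first ell nm.

namespace {

// Deterministic fast RNG: xoshiro256++ seeded via splitmix64, with a
// Marsaglia–Tsang ziggurat for standard normals.  The simulator draws one
// normal per monomer per step, so this path dominates run time; it is also
// fully specified (no implementation-defined std:: distributions).
struct ZigNormal {
  uint64_t s[4];
  uint32_t kn[128];
  double wn[128], fn[128];

  static uint64_t splitmix64(uint64_t& z) {
    z += 0x9e3779b97f4a7c15ULL;
    uint64_t r = z;
    r = (r ^ (r >> 30)) * 0xbf58476d1ce4e5b9ULL;
    r = (r ^ (r >> 27)) * 0x94d049bb133111ebULL;
    return r ^ (r >> 31);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  explicit ZigNormal(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(z);
    // ziggurat tables (128 layers), Marsaglia & Tsang constants
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  uint64_t next64() {
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
  double unif() { return (next64() >> 11) * 0x1.0p-53; }

  double operator()() {
    const double r = 3.442619855899, inv_r = 1.0 / r;
    int32_t hz = static_cast<int32_t>(next64() >> 32);
    for (;;) {
      int iz = hz & 127;
      uint32_t ahz = hz < 0 ? static_cast<uint32_t>(-(int64_t)hz)
                            : static_cast<uint32_t>(hz);
      if (ahz < kn[iz]) return hz * wn[iz];
      double x = hz * wn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(unif()) * inv_r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
      hz = static_cast<int32_t>(next64() >> 32);
    }
  }

  // uniform integer in [0, n), Lemire multiply-shift
  int below(int n) {
    uint32_t v = static_cast<uint32_t>(next64() >> 32);
    return static_cast<int>((static_cast<uint64_t>(v) * n) >> 32);
  }
};

// Loading rule: with a new monomer occupying [0, ell], resident k (1-based
// from the base) must sit at >= k*ell.  Entry succeeds iff at most LS
// residents need displacing and no pushed front edge passes the tip.
bool try_load(std::vector<double>& x, double ell, int LS, double L) {
  int M = static_cast<int>(x.size());
  int displaced = 0;
  for (int k = 0; k < M; ++k) {
    double target = (k + 1) * ell;
    if (x[k] < target) {
      ++displaced;
      if (displaced > LS) return false;
      if (target + ell > L) return false;  // cannot push past the tip
    }
  }
  for (int k = 0; k < M; ++k) {
    double target = (k + 1) * ell;
    if (x[k] < target) x[k] = target;
  }
  x.insert(x.begin(), 0.0);
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".simulate_core")]]
Rcpp::List simulate_core(double D, int LS, double S_load, double ell,
                         double dL, double dt, double L0, double L_stop,
                         double t_max, double sample_period, double seed,
                         bool poisson_loading = false) {
  if (D <= 0 || S_load <= 0 || ell <= 0 || dL <= 0 || dt <= 0)
    Rcpp::stop("D, S_load, ell, dL and dt must be positive");
  if (LS < 0) Rcpp::stop("LS must be a non-negative integer");
  if (L0 < ell || L_stop <= L0) Rcpp::stop("need L_stop > L0 >= ell");

  ZigNormal gen(static_cast<uint64_t>(seed));
  const double step_sd = std::sqrt(2.0 * D * dt);
  const double load_interval = 1.0 / S_load;

  std::vector<double> x;      // rear edges, ascending
  x.reserve(256);
  double L = L0;
  double t = 0.0;
  long long n_cryst = 0;
  long long n_attempts = 0, n_loaded = 0;

  std::vector<double> out_t, out_L, out_occ;
  std::vector<int> out_M;
  std::vector<int> perm;
  perm.reserve(256);

  double next_load = load_interval;
  double next_sample = 0.0;

  bool truncated = false;
  long long n_steps = 0;
  for (;;) {
    if (t >= next_sample) {
      out_t.push_back(t);
      out_L.push_back(L);
      out_M.push_back(static_cast<int>(x.size()));
      out_occ.push_back(x.size() * ell / L);
      next_sample += sample_period;
    }
    if (L >= L_stop) break;
    if (t >= t_max) { truncated = true; break; }

    // loading attempts: fixed clock by default (failed attempts do not
    // delay the clock); optional Poisson arrivals at the same mean rate
    while (t >= next_load) {
      ++n_attempts;
      if (try_load(x, ell, LS, L)) ++n_loaded;
      next_load += poisson_loading
                       ? -std::log(1.0 - gen.unif()) * load_interval
                       : load_interval;
    }

    int M = static_cast<int>(x.size());
    if (M > 0) {
      perm.resize(M);
      for (int i = 0; i < M; ++i) perm[i] = i;
      for (int i = M - 1; i > 0; --i)
        std::swap(perm[i], perm[gen.below(i + 1)]);

      for (int pi = 0; pi < M; ++pi) {
        int i = perm[pi];
        int cur = static_cast<int>(x.size());
        if (i >= cur) continue;  // crystallized earlier this sweep
        double prop = x[i] + step_sd * gen();
        double lo = (i == 0) ? 0.0 : x[i - 1] + ell;
        if (prop < lo) prop = lo;
        if (i < cur - 1) {
          double hi = x[i + 1] - ell;
          if (prop > hi) prop = hi;
          x[i] = prop;
        } else {
          // tip-most monomer: may crystallize immediately
          if (prop + ell >= L) {
            x.pop_back();
            L += dL;
            ++n_cryst;
          } else {
            x[i] = prop;
          }
        }
      }
    }
    t += dt;
    if ((++n_steps & 0xFFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // ensure the terminal state is recorded
  if (out_t.empty() || out_t.back() < t) {
    out_t.push_back(t);
    out_L.push_back(L);
    out_M.push_back(static_cast<int>(x.size()));
    out_occ.push_back(x.size() * ell / L);
  }

  return Rcpp::List::create(
      Rcpp::Named("time_s") = out_t, Rcpp::Named("length_nm") = out_L,
      Rcpp::Named("n_monomers") = out_M, Rcpp::Named("occupancy") = out_occ,
      Rcpp::Named("truncated") = truncated,
      Rcpp::Named("n_crystallized") = static_cast<double>(n_cryst),
      Rcpp::Named("n_attempts") = static_cast<double>(n_attempts),
      Rcpp::Named("n_loaded") = static_cast<double>(n_loaded),
      Rcpp::Named("positions") = x);
}
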