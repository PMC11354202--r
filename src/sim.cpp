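#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Self-contained RNG (splitmix64-seeded xoroshiro128+, Box-Muller normals).
// Each trial gets its own substream derived from the master seed, so trial i
// is reproducible regardless of how many trials are requested, and results
// are identical across platforms for a given seed.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rotl64(uint64_t v, int k) {
  return (v << k) | (v >> (64 - k));
}

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers)
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m);
    kn[1] = 0;
    wn[0] = q / m;
    wn[127] = dn / m;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m;
    }
  }
};
static const ZigTables zig;

struct Rng {
  uint64_t s0, s1;
  void seed(uint64_t sd) {
    uint64_t x = sd;
    s0 = splitmix64(x);
    s1 = splitmix64(x);
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = rotl64(a, 24) ^ b ^ (b << 16);
    s1 = rotl64(b, 37);
    return r;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  // standard normal via the ziggurat (layer index and the 32-bit
  // candidate come from disjoint bits of one 64-bit draw)
  inline double norm() {
    for (;;) {
      uint64_t u = next();
      int32_t hz = (int32_t)(u >> 32);
      uint32_t iz = (uint32_t)(u >> 8) & 127u;
      uint32_t ahz = (uint32_t)(hz < 0 ? -(int64_t)hz : (int64_t)hz);
      double x = hz * zig.wn[iz];
      if (ahz < zig.kn[iz]) return x;
      if (iz == 0) {
        // tail beyond r = 3.442619855899
        const double r = 3.442619855899;
        double xx, yy;
        do {
          double u1;
          do { u1 = unif(); } while (u1 <= 0.0);
          double u2;
          do { u2 = unif(); } while (u2 <= 0.0);
          xx = -std::log(u1) / r;
          yy = -std::log(u2);
        } while (yy + yy < xx * xx);
        return hz > 0 ? r + xx : -(r + xx);
      }
      if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

static inline uint64_t trial_stream(uint64_t master, int trial) {
  uint64_t x = master ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(trial + 1));
  return splitmix64(x);
}

// Euler simulation of the standard DDM with between-trial variability in
// start point (sz, uniform), drift (sv, normal) and non-decision time
// (ster, uniform).  Lower boundary at 0, upper at A, unbiased start A/2.
// response: 1 = upper, 0 = lower, -1 = timeout (after `attempts` re-runs).
// [[Rcpp::export]]
List cpp_sim_ddm(double A, double ter, double v, double sz, double sv,
                 double ster, int n_trials, double dt, double sigma,
                 double max_t, int attempts, double seed) {
  IntegerVector resp(n_trials);
  NumericVector rt(n_trials);
  const int nmax = (int)std::ceil(max_t / dt);
  const double sd_step = sigma * std::sqrt(dt);
  uint64_t master = (uint64_t)seed;
  Rng rng;
  for (int i = 0; i < n_trials; ++i) {
    rng.seed(trial_stream(master, i));
    int r = -1;
    double t_out = max_t + ter;
    for (int att = 0; att < attempts && r < 0; ++att) {
      double z = A / 2.0 + sz * (rng.unif() - 0.5);
      double vt = v + sv * rng.norm();
      double tert = ter + ster * (rng.unif() - 0.5);
      double drift = vt * dt;
      double x = z;
      for (int step = 1; step <= nmax; ++step) {
        x += drift + sd_step * rng.norm();
        if (x >= A) { r = 1; t_out = step * dt + tert; break; }
        if (x <= 0.0) { r = 0; t_out = step * dt + tert; break; }
      }
    }
    resp[i] = r;
    rt[i] = t_out;
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}

// Euler simulation of the TV-DDM: drift v*theta(t) and infinitesimal SD
// sqrt(sigma^2*theta(t) + sigma2^2), with theta the regularized lower
// incomplete gamma function of (n, beta*t).  Fixed start A/2 and fixed
// non-decision time (no sz/ster); drift variability sv as in the DDM.
// [[Rcpp::export]]
List cpp_sim_tvddm(double A, double ter, double v, double beta, double nshape,
                   double sigma2, double sv, int n_trials, double dt,
                   double sigma, double max_t, int attempts, double seed) {
  IntegerVector resp(n_trials);
  NumericVector rt(n_trials);
  const int nmax = (int)std::ceil(max_t / dt);
  const double sqdt = std::sqrt(dt);
  // theta and per-step diffusion SD on the within-trial clock (stimulus onset
  // at t = 0; theta evaluated at the left endpoint of each Euler step),
  // tabulated lazily in blocks: most trials are absorbed long before max_t
  std::vector<double> drift_fac, sd_step;
  drift_fac.reserve(2048);
  sd_step.reserve(2048);
  int tab = 0;
  const int block = 2048;
  uint64_t master = (uint64_t)seed;
  Rng rng;
  for (int i = 0; i < n_trials; ++i) {
    rng.seed(trial_stream(master, i));
    int r = -1;
    double t_out = max_t + ter;
    for (int att = 0; att < attempts && r < 0; ++att) {
      double vt = v + sv * rng.norm();
      double x = A / 2.0;
      for (int step = 1; step <= nmax; ++step) {
        if (step > tab) {
          int upto = std::min(tab + block, nmax);
          for (int j = tab; j < upto; ++j) {
            double th = R::pgamma(beta * (j * dt), nshape, 1.0, 1, 0);
            drift_fac.push_back(th * dt);
            sd_step.push_back(
                std::sqrt(sigma * sigma * th + sigma2 * sigma2) * sqdt);
          }
          tab = upto;
        }
        x += vt * drift_fac[step - 1] + sd_step[step - 1] * rng.norm();
        if (x >= A) { r = 1; t_out = step * dt + ter; break; }
        if (x <= 0.0) { r = 0; t_out = step * dt + ter; break; }
      }
    }
    resp[i] = r;
    rt[i] = t_out;
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}

// type-7 quantile of a sorted vector
static double quantile7(const std::vector<double> &x, double p) {
  const int n = (int)x.size();
  if (n == 1) return x[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// Silverman rule-of-thumb bandwidth, replicating stats::bw.nrd0
static double bw_nrd0(const std::vector<double> &x) {
  const int n = (int)x.size();
  double mean = 0.0;
  for (double xi : x) mean += xi;
  mean /= n;
  double ss = 0.0;
  for (double xi : x) ss += (xi - mean) * (xi - mean);
  double sd = std::sqrt(ss / (n - 1));
  double iqr = quantile7(x, 0.75) - quantile7(x, 0.25);
  double lo = std::min(sd, iqr / 1.34);
  if (lo == 0.0) lo = (sd != 0.0) ? sd : ((x[0] != 0.0) ? std::fabs(x[0]) : 1.0);
  return 0.9 * lo * std::pow((double)n, -0.2);
}

// Log defective-KDE density of each datum under a Gaussian-kernel mixture
// built from simulated trials.  Category weight = category count / total
// simulated (timeouts absorb mass); categories with < 2 simulated trials
// evaluate to the floor.  With adaptive = true (the default likelihood),
// per-point bandwidths follow Abramson's square-root law from a Silverman
// pilot, clamped at 10x the pilot bandwidth: sparse tails get wide
// kernels, which removes the floor-flicker noise of fixed bandwidths.
// Kernel sums are truncated at 8 bandwidths (relative error < 1e-13).
// [[Rcpp::export]]
NumericVector cpp_kde_logdens(NumericVector data_rt, IntegerVector data_resp,
                              NumericVector sim_rt, IntegerVector sim_resp,
                              double floor_val, bool adaptive = true) {
  const int nd = data_rt.size();
  const int ns = sim_rt.size();
  const double inv_sqrt2pi = 0.3989422804014327;
  NumericVector out(nd);
  for (int cat = 0; cat <= 1; ++cat) {
    std::vector<double> xs;
    xs.reserve(ns);
    for (int j = 0; j < ns; ++j)
      if (sim_resp[j] == cat) xs.push_back(sim_rt[j]);
    const int nc = (int)xs.size();
    if (nc < 2) {
      for (int i = 0; i < nd; ++i)
        if (data_resp[i] == cat) out[i] = std::log(floor_val);
      continue;
    }
    std::sort(xs.begin(), xs.end());
    const double h0 = bw_nrd0(xs);
    const double w = (double)nc / (double)ns;
    std::vector<double> hi(nc, h0);
    if (adaptive) {
      // pilot density (fixed bandwidth h0) on a 128-point grid, linearly
      // interpolated at the simulation points — the pilot only sets
      // bandwidth ratios, so grid resolution is ample
      const int ng = 128;
      const double lo = xs.front(), span = xs.back() - xs.front();
      const double step = span > 0 ? span / (ng - 1) : 1.0;
      const double win0 = 8.0 * h0;
      const double inv2h2 = 1.0 / (2.0 * h0 * h0);
      std::vector<double> pg(ng);
      for (int gdx = 0; gdx < ng; ++gdx) {
        const double x0 = lo + gdx * step;
        std::vector<double>::iterator a =
            std::lower_bound(xs.begin(), xs.end(), x0 - win0);
        std::vector<double>::iterator b =
            std::upper_bound(xs.begin(), xs.end(), x0 + win0);
        double s = 0.0;
        for (std::vector<double>::iterator it = a; it != b; ++it) {
          double d = x0 - *it;
          s += std::exp(-d * d * inv2h2);
        }
        pg[gdx] = std::max(s * inv_sqrt2pi / (nc * h0), 1e-300);
      }
      std::vector<double> fp(nc);
      double logsum = 0.0;
      for (int j = 0; j < nc; ++j) {
        double pos = (xs[j] - lo) / step;
        int k0 = (int)pos;
        if (k0 >= ng - 1) k0 = ng - 2;
        double fr = pos - k0;
        fp[j] = std::max(pg[k0] * (1 - fr) + pg[k0 + 1] * fr, 1e-300);
        logsum += std::log(fp[j]);
      }
      const double g = std::exp(logsum / nc);
      for (int j = 0; j < nc; ++j) {
        double lam = std::sqrt(g / fp[j]);
        if (lam > 10.0) lam = 10.0;
        hi[j] = h0 * lam;
      }
    }
    // split kernel centres into narrow-bandwidth bulk (windowed search)
    // and the few wide-bandwidth tail centres (scanned per datum)
    const double hbulk = 2.5 * h0;
    std::vector<double> xb, hb, xw, hw;
    xb.reserve(nc); hb.reserve(nc);
    for (int j = 0; j < nc; ++j) {
      if (hi[j] <= hbulk) { xb.push_back(xs[j]); hb.push_back(hi[j]); }
      else { xw.push_back(xs[j]); hw.push_back(hi[j]); }
    }
    const double win = 8.0 * hbulk;
    const int nw = (int)xw.size();
    for (int i = 0; i < nd; ++i) {
      if (data_resp[i] != cat) continue;
      const double x = data_rt[i];
      double s = 0.0;
      std::vector<double>::iterator a =
          std::lower_bound(xb.begin(), xb.end(), x - win);
      std::vector<double>::iterator b =
          std::upper_bound(xb.begin(), xb.end(), x + win);
      for (std::vector<double>::iterator it = a; it != b; ++it) {
        int j = (int)(it - xb.begin());
        double d = x - *it;
        if (std::fabs(d) > 8.0 * hb[j]) continue;
        s += std::exp(-d * d / (2.0 * hb[j] * hb[j])) / hb[j];
      }
      for (int j = 0; j < nw; ++j) {
        double d = x - xw[j];
        if (std::fabs(d) > 8.0 * hw[j]) continue;
        s += std::exp(-d * d / (2.0 * hw[j] * hw[j])) / hw[j];
      }
      double dens = w * s * inv_sqrt2pi / nc;
      out[i] = std::log(std::max(dens, floor_val));
    }
  }
  return out;
}
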