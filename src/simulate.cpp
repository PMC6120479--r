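#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// ---- fast samplers -------------------------------------------------------
// The camera model draws two random numbers per voxel over ~10^9 voxels in a
// study-scale simulation, so the standard library distributions (which
// re-initialise per call for Poisson) are replaced by the usual fast
// algorithms: a 128-layer ziggurat for the normal and Hormann's PTRS
// transformed rejection for Poisson(lambda >= 10), with simple inversion
// below. All draws come from one mt19937_64 stream per call, in fixed voxel
// order, so results are reproducible for a given seed.

static double zig_x[129];
static double zig_r[128];
static bool zig_ready = false;

static void zig_init() {
  const double r = 3.442619855899;
  const double v = 9.91256303526217e-3;
  zig_x[0] = v / std::exp(-0.5 * r * r);
  zig_x[1] = r;
  zig_x[128] = 0.0;
  for (int i = 2; i < 128; ++i) {
    double xx = std::sqrt(-2.0 * std::log(v / zig_x[i - 1] +
                                          std::exp(-0.5 * zig_x[i - 1] *
                                                   zig_x[i - 1])));
    zig_x[i] = xx;
  }
  for (int i = 0; i < 128; ++i) zig_r[i] = zig_x[i + 1] / zig_x[i];
  zig_ready = true;
}

static inline double unif01(std::mt19937_64 &rng) {
  // 53-bit uniform in (0, 1)
  return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double znorm(std::mt19937_64 &rng) {
  for (;;) {
    uint64_t u = rng();
    int i = static_cast<int>(u & 127);
    double sign = (u & 128) ? 1.0 : -1.0;
    double uval = ((u >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    double x = uval * zig_x[i];
    if (uval < zig_r[i]) return sign * x;
    if (i == 0) {
      // tail beyond r
      const double r = 3.442619855899;
      double xx, yy;
      do {
        xx = -std::log(unif01(rng)) / r;
        yy = -std::log(unif01(rng));
      } while (yy + yy < xx * xx);
      return sign * (r + xx);
    }
    double f0 = std::exp(-0.5 * (zig_x[i] * zig_x[i] - x * x));
    double f1 = std::exp(-0.5 * (zig_x[i + 1] * zig_x[i + 1] - x * x));
    if (f1 + unif01(rng) * (f0 - f1) < 1.0) return sign * x;
  }
}

static inline long pois_small(double lambda, std::mt19937_64 &rng) {
  // inversion by sequential search, fine for lambda < 10
  double p = std::exp(-lambda), F = p, u = unif01(rng);
  long k = 0;
  while (u > F && k < 1000) {
    ++k;
    p *= lambda / k;
    F += p;
  }
  return k;
}

static inline long pois_ptrs(double lambda, std::mt19937_64 &rng) {
  // Hormann's PTRS transformed rejection, lambda >= 10
  const double slam = std::sqrt(lambda);
  const double llam = std::log(lambda);
  const double b = 0.931 + 2.53 * slam;
  const double a = -0.059 + 0.02483 * b;
  const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
  const double v_r = 0.9277 - 3.6224 / (b - 2.0);
  for (;;) {
    double U = unif01(rng) - 0.5;
    double V = unif01(rng);
    double us = 0.5 - std::fabs(U);
    long k = static_cast<long>(std::floor((2.0 * a / us + b) * U + lambda +
                                          0.43));
    if (us >= 0.07 && V <= v_r) return k;
    if (k < 0 || (us < 0.013 && V > us)) continue;
    if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
        k * llam - lambda - std::lgamma(k + 1.0)) {
      return k;
    }
  }
}

static inline long rpois_fast(double lambda, std::mt19937_64 &rng) {
  return (lambda < 10.0) ? pois_small(lambda, rng) : pois_ptrs(lambda, rng);
}

// ---- forward model -------------------------------------------------------
// Distribute a blurred 2-D photon image across z with weights `zw`, then per
// voxel: Poisson shot noise (photon counts scaled by `poisson_scale`),
// additive Gaussian read noise, constant camera offset. poisson_scale <= 0
// disables shot noise, read_sigma <= 0 disables read noise; both off gives
// the noise-free forward model plus offset. The maximum projection is
// computed alongside; draw order is identical whether or not the full stack
// is kept.
// [[Rcpp::export]]
List simulate_stack_cpp(NumericMatrix base2d, NumericVector zw,
                        double poisson_scale, double read_sigma,
                        double offset, double seed, bool return_stack) {
  if (!zig_ready) zig_init();
  const int ny = base2d.nrow(), nx = base2d.ncol();
  const int npx = ny * nx, nz = zw.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  NumericMatrix proj(ny, nx);
  std::fill(proj.begin(), proj.end(), R_NegInf);
  NumericVector stack;
  if (return_stack) {
    stack = NumericVector(static_cast<R_xlen_t>(npx) * nz);
    stack.attr("dim") = IntegerVector::create(ny, nx, nz);
  }

  const bool shot = poisson_scale > 0.0;
  const bool read = read_sigma > 0.0;
  const double *b = base2d.begin();
  double *p = proj.begin();
  for (int k = 0; k < nz; ++k) {
    const double w = zw[k];
    double *s = return_stack ? stack.begin() + static_cast<R_xlen_t>(k) * npx
                             : nullptr;
    for (int i = 0; i < npx; ++i) {
      double lam = w * b[i];
      double val;
      if (shot) {
        val = (lam > 1e-12)
          ? static_cast<double>(rpois_fast(lam * poisson_scale, rng)) /
              poisson_scale
          : 0.0;
      } else {
        val = lam;
      }
      if (read) val += read_sigma * znorm(rng);
      val += offset;
      if (s) s[i] = val;
      if (val > p[i]) p[i] = val;
    }
  }
  return List::create(_["proj"] = proj,
                      _["stack"] = return_stack ? (RObject)stack
                                                : (RObject)R_NilValue);
}
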