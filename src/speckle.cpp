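// Photon-driven speckle stream synthesis.
//
// The target field autocorrelation g1 is supplied as a non-negative mixture
// of exponentials sum_k c2[k] * exp(-lambda[k] * tau). Each mixture
// component is realized as an independent complex Ornstein-Uhlenbeck
// process, which can be advanced *exactly* across an arbitrary time gap dt:
//   z <- exp(-lambda dt) z + sqrt(c2 (1 - exp(-2 lambda dt)) / 2) (N1 + i N2)
// The summed field E = sum_k z_k is then a stationary complex Gaussian
// process with autocorrelation exactly the mixture. M independent speckle
// intensities are summed (coherence factor beta = 1/M) and photons are
// drawn by thinning a homogeneous Poisson candidate process whose rate is
// cand_factor times the largest requested count rate; the field is only
// evaluated at candidate times. Candidates shared across the requested
// rates give each rate a valid inhomogeneous Poisson stream.
//
// Randomness comes from an internal xoshiro256++ generator seeded from R's
// RNG (so set.seed() governs reproducibility); R's norm_rand is too slow
// for the ~1e9 draws a noise scan needs.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct GaussGen {
  Xoshiro256pp rng;
  bool have_spare = false;
  double spare = 0.0;
  explicit GaussGen(uint64_t seed) : rng(seed) {}
  double unif() { return rng.unif(); }
  // Box-Muller with cached second draw
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = rng.unif(), u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
  double expdraw() { return -std::log(rng.unif()); }
};

} // namespace

// [[Rcpp::export(name = ".speckle_tags_cpp")]]
List speckle_tags_cpp(double duration_s, NumericVector rates_hz,
                      NumericVector lambda, NumericVector c2, int M,
                      double cand_factor, double seed) {
  const int K = lambda.size();
  if (c2.size() != K) stop("lambda and c2 length mismatch");
  if (M < 1) stop("M must be >= 1");
  const int R = rates_hz.size();
  double rmax = 0.0;
  for (int r = 0; r < R; ++r) rmax = std::max(rmax, rates_hz[r]);
  if (rmax <= 0.0) stop("need a positive rate");
  const double lam_c = cand_factor * rmax;

  GaussGen g((uint64_t)seed);

  // stationary initialization: each component complex N(0, c2[k])
  std::vector<double> zre((size_t)M * K), zim((size_t)M * K);
  for (int mi = 0; mi < M; ++mi)
    for (int k = 0; k < K; ++k) {
      double sd = std::sqrt(c2[k] / 2.0);
      zre[(size_t)mi * K + k] = sd * g.norm();
      zim[(size_t)mi * K + k] = sd * g.norm();
    }

  std::vector<std::vector<double>> out(R);
  for (int r = 0; r < R; ++r)
    out[r].reserve((size_t)(rates_hz[r] * duration_s * 1.05) + 64);

  std::vector<double> dk(K), sk(K);
  double t = 0.0;
  const double invM = 1.0 / (double)M;
  for (;;) {
    double dt = g.expdraw() / lam_c;
    t += dt;
    if (t >= duration_s) break;
    for (int k = 0; k < K; ++k) {
      double d = std::exp(-lambda[k] * dt);
      dk[k] = d;
      sk[k] = std::sqrt(c2[k] * (1.0 - d * d) / 2.0);
    }
    double I = 0.0;
    for (int mi = 0; mi < M; ++mi) {
      double Ere = 0.0, Eim = 0.0;
      size_t off = (size_t)mi * K;
      for (int k = 0; k < K; ++k) {
        double zr = dk[k] * zre[off + k] + sk[k] * g.norm();
        double zi = dk[k] * zim[off + k] + sk[k] * g.norm();
        zre[off + k] = zr; zim[off + k] = zi;
        Ere += zr; Eim += zi;
      }
      I += Ere * Ere + Eim * Eim;
    }
    I *= invM;                       // mean intensity 1
    double u = g.unif() * lam_c;     // accept rate r if u < r * I
    if (u < rmax * I) {
      double t_ps = std::floor(t * 1e12);
      for (int r = 0; r < R; ++r)
        if (u < rates_hz[r] * I) out[r].push_back(t_ps);
    }
  }

  List res(R);
  for (int r = 0; r < R; ++r) res[r] = wrap(out[r]);
  return res;
}
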