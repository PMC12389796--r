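#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Self-contained counter-seeded generator (splitmix64 -> xoshiro256++)
// with Box-Muller normals. Used for the synthetic noise streams so that
// session simulation is fast and bit-reproducible from an explicit seed,
// independent of the caller's R RNG state.

static inline uint64_t splitmix64(uint64_t& x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {  // Marsaglia polar method
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

// Additive physiological noise matrix (n samples x m series): white
// Gaussian noise + random-walk drift + sinusoids with per-series random
// phases. amps/freqs give the sinusoidal components (Hz). Deterministic
// given seed.
// [[Rcpp::export]]
NumericMatrix noise_matrix(int n, int m, double white_sd, double drift_sd,
                           NumericVector amps, NumericVector freqs,
                           double fs, double seed) {
  NumericMatrix out(n, m);
  const int k = amps.size();
  const double w = 6.283185307179586476925286766559 / fs;
  Rng rng(static_cast<uint64_t>(seed));
  for (int j = 0; j < m; ++j) {
    double* col = &out(0, j);
    std::vector<double> phase(k);
    for (int c = 0; c < k; ++c)
      phase[c] = 6.283185307179586476925286766559 * rng.unif();
    if (white_sd > 0.0)
      for (int i = 0; i < n; ++i) col[i] = white_sd * rng.norm();
    if (drift_sd > 0.0) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        acc += drift_sd * rng.norm();
        col[i] += acc;
      }
    }
    for (int c = 0; c < k; ++c) {
      if (amps[c] <= 0.0) continue;
      const double dphi = w * freqs[c];
      // rotation recurrence (unitary, error growth negligible over a
      // session) instead of per-sample sin()
      const double cr = std::cos(dphi), ci = std::sin(dphi);
      double re = std::cos(phase[c]), im = std::sin(phase[c]);
      for (int i = 0; i < n; ++i) {
        col[i] += amps[c] * im;
        const double nr = re * cr - im * ci;
        im = re * ci + im * cr;
        re = nr;
      }
    }
  }
  return out;
}
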