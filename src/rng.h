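#ifndef DIFFJUDGE_RNG_H
#define DIFFJUDGE_RNG_H

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Adapter over R's RNG (respects set.seed in R).
struct RRng {
  double unif() { return unif_rand(); }
  double norm() { return norm_rand(); }
};

// xoshiro256++ with splitmix64 seeding: a fast, self-contained generator
// for the likelihood objective, where the whole stream is pinned by an
// explicit integer seed (common random numbers across optimizer steps).
struct Xoshiro {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Xoshiro(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double norm() {  // polar Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

#endif
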