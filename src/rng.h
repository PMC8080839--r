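#ifndef EWSBENCH_RNG_H
#define EWSBENCH_RNG_H

#include <cstdint>
#include <cmath>

// Counter-seeded xoshiro256++ generator. Each (master seed, stream) pair is
// expanded through splitmix64, so per-step sub-streams are independent and
// reproducible without touching R's global RNG state.
struct XoshiroRNG {
  uint64_t s[4];

  static inline uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  XoshiroRNG(uint64_t master, uint64_t stream) {
    uint64_t x = master * 0x9E3779B97F4A7C15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the all-zero state
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  bool has_spare = false;
  double spare = 0.0;

  // standard normal via Marsaglia's polar method (exact, no table)
  inline double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

#endif
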