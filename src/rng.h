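#ifndef STOOPSIM_RNG_H
#define STOOPSIM_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained PCG32 generator so that simulation streams are
// reproducible bit-for-bit across platforms and independent of R's RNG
// state.  Per-engagement streams are derived from (master seed, counter)
// via splitmix64, so Monte Carlo batches can be sharded deterministically.
struct Pcg32 {
  uint64_t state;
  uint64_t inc;

  Pcg32(uint64_t seed = 42u, uint64_t seq = 54u) { init(seed, seq); }

  void init(uint64_t seed, uint64_t seq) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }

  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }

  // uniform in (0, 1) (never exactly 0 or 1)
  double runif() {
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }

  double runif(double lo, double hi) { return lo + (hi - lo) * runif(); }

  // Box-Muller; cached spare kept out for simplicity (costs one extra log)
  double rnorm() {
    double u1 = runif(), u2 = runif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }

  double rexp(double mean) { return -mean * std::log(runif()); }
};

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// stream i of a master seed
inline Pcg32 stream_rng(uint64_t master, uint64_t index) {
  uint64_t s = splitmix64(master ^ splitmix64(index));
  uint64_t q = splitmix64(s + 0x632BE59BD9B4E019ULL);
  return Pcg32(s, q);
}

#endif
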