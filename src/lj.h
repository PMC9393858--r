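#ifndef AVBMCLJ_LJ_H
#define AVBMCLJ_LJ_H

#include <Rcpp.h>
#include <cstdint>
#include <random>

// Portable uniform deviates: mt19937_64 raw output mapped to [0,1).
// std::uniform_real_distribution is implementation-defined, so we do the
// mapping ourselves to keep seeded runs bit-identical across toolchains.
struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double u() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int ui(int n) { return static_cast<int>(u() * n) % n; }
};

// LJ pair energy from squared distance (no cutoff handling here).
inline double lj_pair_r2(double r2, double eps, double sigma) {
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  return 4.0 * eps * (s6 * s6 - s6);
}

// r * du/dr contribution used in the virial: -48 eps [ (s/r)^12 - 0.5 (s/r)^6 ]
inline double lj_rdudr_r2(double r2, double eps, double sigma) {
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  return -48.0 * eps * (s6 * s6 - 0.5 * s6);
}

inline double min_image(double d, double box) {
  if (d > 0.5 * box) d -= box;
  else if (d < -0.5 * box) d += box;
  return d;
}

// uniform point in a sphere of given radius about (cx,cy,cz)
inline void sphere_point(Rng& rng, double radius, double cx, double cy,
                         double cz, double& px, double& py, double& pz) {
  // isotropic direction via Marsaglia polar sampling on the sphere
  double v1, v2, s;
  do {
    v1 = 2.0 * rng.u() - 1.0;
    v2 = 2.0 * rng.u() - 1.0;
    s = v1 * v1 + v2 * v2;
  } while (s >= 1.0 || s == 0.0);
  double root = 2.0 * std::sqrt(1.0 - s);
  double dx = v1 * root, dy = v2 * root, dz = 1.0 - 2.0 * s;
  double r = radius * std::cbrt(rng.u());
  px = cx + r * dx;
  py = cy + r * dy;
  pz = cz + r * dz;
}

#endif
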