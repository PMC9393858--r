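#include "lj.h"
using namespace Rcpp;

// Pair-sum energy of a configuration. box <= 0 means open (cluster) mode;
// cutoff <= 0 means no cutoff. Tail correction (bulk only) is added in R.
// [[Rcpp::export]]
double cpp_pair_sum_energy(const NumericMatrix& xyz, double eps, double sigma,
                           double cutoff, double box) {
  const int n = xyz.nrow();
  const bool periodic = box > 0.0;
  const double rc2 = cutoff > 0.0 ? cutoff * cutoff : -1.0;
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      if (periodic) {
        dx = min_image(dx, box);
        dy = min_image(dy, box);
        dz = min_image(dz, box);
      }
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-20)
        stop("overlapping identical coordinates (particles %d and %d)", i + 1,
             j + 1);
      if (rc2 > 0.0 && r2 > rc2) continue;
      e += lj_pair_r2(r2, eps, sigma);
    }
  }
  return e;
}

// Energy of one particle (at `pos`) with all others, skipping row `skip`
// (0-based; pass -1 to include everyone).
// [[Rcpp::export]]
double cpp_one_particle_energy(const NumericMatrix& xyz, const NumericVector& pos,
                               int skip, double eps, double sigma, double cutoff,
                               double box) {
  const int n = xyz.nrow();
  const bool periodic = box > 0.0;
  const double rc2 = cutoff > 0.0 ? cutoff * cutoff : -1.0;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == skip) continue;
    double dx = pos[0] - xyz(i, 0);
    double dy = pos[1] - xyz(i, 1);
    double dz = pos[2] - xyz(i, 2);
    if (periodic) {
      dx = min_image(dx, box);
      dy = min_image(dy, box);
      dz = min_image(dz, box);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-20) stop("overlapping identical coordinates");
    if (rc2 > 0.0 && r2 > rc2) continue;
    e += lj_pair_r2(r2, eps, sigma);
  }
  return e;
}
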