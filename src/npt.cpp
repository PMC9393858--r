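#include "lj.h"
using namespace Rcpp;

namespace {

struct BulkSystem {
  std::vector<double> x, y, z;
  double box;
  double eps, sigma, rc, rc2;
  bool tail;
  int n;

  double pair_energy_all() const {
    double e = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], box);
        double dy = min_image(y[i] - y[j], box);
        double dz = min_image(z[i] - z[j], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= rc2) e += lj_pair_r2(r2, eps, sigma);
      }
    return e;
  }

  double virial_all() const {  // sum of -r du/dr over pairs in range
    double w = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], box);
        double dy = min_image(y[i] - y[j], box);
        double dz = min_image(z[i] - z[j], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= rc2) w -= lj_rdudr_r2(r2, eps, sigma);
      }
    return w;
  }

  double one_energy(int k, double px, double py, double pz) const {
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i == k) continue;
      double dx = min_image(px - x[i], box);
      double dy = min_image(py - y[i], box);
      double dz = min_image(pz - z[i], box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= rc2) e += lj_pair_r2(r2, eps, sigma);
    }
    return e;
  }

  double u_tail_total() const {
    if (!tail) return 0.0;
    double rho = n / (box * box * box);
    double sr3 = std::pow(sigma / rc, 3.0), sr9 = sr3 * sr3 * sr3;
    return n * (8.0 / 3.0) * M_PI * rho * eps * sigma * sigma * sigma *
           (sr9 / 3.0 - sr3);
  }

  double p_tail() const {
    if (!tail) return 0.0;
    double rho = n / (box * box * box);
    double sr3 = std::pow(sigma / rc, 3.0), sr9 = sr3 * sr3 * sr3;
    return (16.0 / 3.0) * M_PI * rho * rho * eps * sigma * sigma * sigma *
           (2.0 * sr9 / 3.0 - sr3);
  }

  void wrap(int i) {
    x[i] -= box * std::floor(x[i] / box);
    y[i] -= box * std::floor(y[i] / box);
    z[i] -= box * std::floor(z[i] / box);
  }
};

}  // namespace

// Isobaric-isothermal Metropolis MC for bulk LJ. Translations plus one
// volume move (uniform in ln V, Jacobian (N+1) ln V) per sweep. Returns
// block-averaged density, energy and enthalpy per particle and virial
// pressure. epsilon == 0 gives an exact ideal-gas NPT sampler for tests.
// [[Rcpp::export]]
List cpp_run_npt(const NumericMatrix& xyz0, double box0, double temperature,
                 double pressure, double eps, double sigma, double cutoff,
                 bool tail, int scramble_sweeps, double scramble_temperature,
                 int n_equil, int n_prod, double max_disp, double max_dlnv,
                 int seed, int n_blocks, int virial_every) {
  BulkSystem s;
  s.n = xyz0.nrow();
  s.box = box0;
  s.eps = eps;
  s.sigma = sigma;
  s.rc = cutoff;
  s.rc2 = cutoff * cutoff;
  s.tail = tail;
  s.x.resize(s.n);
  s.y.resize(s.n);
  s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = xyz0(i, 0);
    s.y[i] = xyz0(i, 1);
    s.z[i] = xyz0(i, 2);
  }
  if (s.box < 2.0 * s.rc)
    stop("box length %.4f is below twice the cutoff %.4f", s.box, s.rc);

  Rng rng(static_cast<uint64_t>(seed));
  const double beta = 1.0 / temperature;

  double e_pair = s.pair_energy_all();
  long moves_since_sync = 0, drift_warnings = 0;
  long acc_tr = 0, att_tr = 0, acc_v = 0, att_v = 0, rej_v_box = 0;

  std::vector<double> blk_rho(n_blocks, 0.0), blk_u(n_blocks, 0.0),
      blk_h(n_blocks, 0.0), blk_n(n_blocks, 0.0);
  std::vector<double> blk_pv(n_blocks, 0.0), blk_pn(n_blocks, 0.0);

  auto translate_sweep = [&](double tloc) {
    double b = 1.0 / tloc;
    for (int m = 0; m < s.n; ++m) {
      int k = rng.ui(s.n);
      double px = s.x[k] + (2.0 * rng.u() - 1.0) * max_disp;
      double py = s.y[k] + (2.0 * rng.u() - 1.0) * max_disp;
      double pz = s.z[k] + (2.0 * rng.u() - 1.0) * max_disp;
      ++att_tr;
      // old and new interactions in one pass over the neighbors
      double de = 0.0;
      const double xk = s.x[k], yk = s.y[k], zk = s.z[k];
      for (int i = 0; i < s.n; ++i) {
        if (i == k) continue;
        double dx = min_image(px - s.x[i], s.box);
        double dy = min_image(py - s.y[i], s.box);
        double dz = min_image(pz - s.z[i], s.box);
        double r2n = dx * dx + dy * dy + dz * dz;
        dx = min_image(xk - s.x[i], s.box);
        dy = min_image(yk - s.y[i], s.box);
        dz = min_image(zk - s.z[i], s.box);
        double r2o = dx * dx + dy * dy + dz * dz;
        if (r2n <= s.rc2) de += lj_pair_r2(r2n, s.eps, s.sigma);
        if (r2o <= s.rc2) de -= lj_pair_r2(r2o, s.eps, s.sigma);
      }
      if (de <= 0.0 || rng.u() < std::exp(-b * de)) {
        s.x[k] = px;
        s.y[k] = py;
        s.z[k] = pz;
        s.wrap(k);
        e_pair += de;
        ++acc_tr;
      }
      if (++moves_since_sync >= 100000) {
        double ref = s.pair_energy_all();
        if (std::fabs(ref - e_pair) > 1e-7) ++drift_warnings;
        e_pair = ref;
        moves_since_sync = 0;
      }
    }
  };

  auto volume_move = [&]() {
    ++att_v;
    double v_old = s.box * s.box * s.box;
    double lnv_new = std::log(v_old) + (2.0 * rng.u() - 1.0) * max_dlnv;
    double v_new = std::exp(lnv_new);
    double box_new = std::cbrt(v_new);
    if (box_new < 2.0 * s.rc) {  // keep minimum image valid: hard wall
      ++rej_v_box;
      return;
    }
    double scale = box_new / s.box;
    double e_old = e_pair + s.u_tail_total();
    BulkSystem t = s;
    t.box = box_new;
    for (int i = 0; i < s.n; ++i) {
      t.x[i] *= scale;
      t.y[i] *= scale;
      t.z[i] *= scale;
    }
    double e_pair_new = t.pair_energy_all();
    double e_new = e_pair_new + t.u_tail_total();
    double arg = -beta * (e_new - e_old + pressure * (v_new - v_old)) +
                 (s.n + 1) * std::log(v_new / v_old);
    if (arg >= 0.0 || rng.u() < std::exp(arg)) {
      s = t;
      e_pair = e_pair_new;
      ++acc_v;
    }
  };

  // optional constant-volume scramble stage (melts a lattice start)
  for (int sw = 0; sw < scramble_sweeps; ++sw) translate_sweep(scramble_temperature);
  e_pair = s.pair_energy_all();

  for (int sw = 0; sw < n_equil; ++sw) {
    translate_sweep(temperature);
    volume_move();
  }

  for (int sw = 0; sw < n_prod; ++sw) {
    translate_sweep(temperature);
    volume_move();
    int b = static_cast<int>(static_cast<long>(sw) * n_blocks / n_prod);
    double v = s.box * s.box * s.box;
    double rho = s.n / v;
    double u_tot = e_pair + s.u_tail_total();
    blk_rho[b] += rho;
    blk_u[b] += u_tot / s.n;
    blk_h[b] += (u_tot + pressure * v) / s.n;
    blk_n[b] += 1.0;
    if (virial_every > 0 && sw % virial_every == 0) {
      double w = eps == 0.0 ? 0.0 : s.virial_all();
      blk_pv[b] += rho * temperature + w / (3.0 * v) + s.p_tail();
      blk_pn[b] += 1.0;
    }
  }

  NumericVector rho_b(n_blocks), u_b(n_blocks), h_b(n_blocks), pv_b(n_blocks);
  for (int b = 0; b < n_blocks; ++b) {
    rho_b[b] = blk_rho[b] / blk_n[b];
    u_b[b] = blk_u[b] / blk_n[b];
    h_b[b] = blk_h[b] / blk_n[b];
    pv_b[b] = blk_pn[b] > 0 ? blk_pv[b] / blk_pn[b] : NA_REAL;
  }

  NumericMatrix xyz_out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    xyz_out(i, 0) = s.x[i];
    xyz_out(i, 1) = s.y[i];
    xyz_out(i, 2) = s.z[i];
  }

  return List::create(
      _["rho_blocks"] = rho_b, _["u_blocks"] = u_b, _["h_blocks"] = h_b,
      _["p_virial_blocks"] = pv_b, _["box"] = s.box, _["xyz"] = xyz_out,
      _["acc_translate"] = double(acc_tr) / std::max(att_tr, 1L),
      _["acc_volume"] = double(acc_v) / std::max(att_v, 1L),
      _["volume_rejects_boxmin"] = double(rej_v_box),
      _["drift_warnings"] = double(drift_warnings));
}
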