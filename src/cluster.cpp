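#include "lj.h"
#include <unordered_map>
using namespace Rcpp;

namespace {

// Grand-canonical cluster state. Solid mode keeps a bidirectional
// particle <-> lattice-site assignment; liquid mode ignores the site arrays.
struct ClusterState {
  std::vector<double> x, y, z;
  std::vector<int> occ;        // particle -> site (0-based), -1 in liquid mode
  std::vector<int> site_part;  // site -> particle, -1 vacant
  bool solid;
  int n() const { return static_cast<int>(x.size()); }
};

struct Model {
  const NumericMatrix* site_xyz;
  const IntegerMatrix* site_nbr;  // S x 12, -1 for sites absent from the model
  int energy_mode;                // 0 lj, 1 ideal, 2 frozen (site centers)
  double eps, sigma;
};

double frozen_pair(const Model& m, int s1, int s2) {
  const NumericMatrix& sx = *m.site_xyz;
  double dx = sx(s1, 0) - sx(s2, 0);
  double dy = sx(s1, 1) - sx(s2, 1);
  double dz = sx(s1, 2) - sx(s2, 2);
  return lj_pair_r2(dx * dx + dy * dy + dz * dz, m.eps, m.sigma);
}

// interaction of a point with every particle except `skip`
double point_energy(const ClusterState& st, const Model& m, double px,
                    double py, double pz, int skip) {
  if (m.energy_mode != 0) return 0.0;  // handled by callers for frozen mode
  double e = 0.0;
  for (int i = 0; i < st.n(); ++i) {
    if (i == skip) continue;
    double dx = px - st.x[i], dy = py - st.y[i], dz = pz - st.z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-20) return R_PosInf;
    e += lj_pair_r2(r2, m.eps, m.sigma);
  }
  return e;
}

double insert_energy(const ClusterState& st, const Model& m, double px,
                     double py, double pz, int site) {
  if (m.energy_mode == 1) return 0.0;
  if (m.energy_mode == 2) {
    double e = 0.0;
    for (int i = 0; i < st.n(); ++i) e += frozen_pair(m, site, st.occ[i]);
    return e;
  }
  return point_energy(st, m, px, py, pz, -1);
}

double delete_energy(const ClusterState& st, const Model& m, int k) {
  if (m.energy_mode == 1) return 0.0;
  if (m.energy_mode == 2) {
    double e = 0.0;
    for (int i = 0; i < st.n(); ++i)
      if (i != k) e += frozen_pair(m, st.occ[k], st.occ[i]);
    return -e;
  }
  return -point_energy(st, m, st.x[k], st.y[k], st.z[k], k);
}

double total_energy(const ClusterState& st, const Model& m) {
  double e = 0.0;
  if (m.energy_mode == 1) return 0.0;
  for (int i = 0; i < st.n() - 1; ++i)
    for (int j = i + 1; j < st.n(); ++j) {
      if (m.energy_mode == 2) {
        e += frozen_pair(m, st.occ[i], st.occ[j]);
      } else {
        double dx = st.x[i] - st.x[j], dy = st.y[i] - st.y[j],
               dz = st.z[i] - st.z[j];
        e += lj_pair_r2(dx * dx + dy * dy + dz * dz, m.eps, m.sigma);
      }
    }
  return e;
}

// connected component check on occupied sites, optionally skipping one
bool solid_connected_without(const ClusterState& st, const Model& m,
                             int skip_particle) {
  int n = st.n();
  int target = n - (skip_particle >= 0 ? 1 : 0);
  if (target <= 1) return true;
  const IntegerMatrix& nbr = *m.site_nbr;
  std::vector<int> stack;
  std::unordered_map<int, int> site_to_particle;  // restricted view
  site_to_particle.reserve(n * 2);
  for (int i = 0; i < n; ++i)
    if (i != skip_particle) site_to_particle[st.occ[i]] = i;
  std::vector<char> seen(n, 0);
  int start = skip_particle == 0 ? 1 : 0;
  stack.push_back(start);
  seen[start] = 1;
  int count = 1;
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int s = st.occ[p];
    for (int q = 0; q < 12; ++q) {
      int s2 = nbr(s, q);
      if (s2 < 0) continue;
      auto it = site_to_particle.find(s2);
      if (it == site_to_particle.end()) continue;
      int p2 = it->second;
      if (!seen[p2]) {
        seen[p2] = 1;
        ++count;
        stack.push_back(p2);
      }
    }
  }
  return count == target;
}

// Stillinger connectivity (< radius) with particle `moved` at (px,py,pz);
// moved = -1: as-is; skip = particle removed from the graph.
bool liquid_connected(const ClusterState& st, double radius, int skip,
                      int moved, double px, double py, double pz) {
  int n = st.n();
  int target = n - (skip >= 0 ? 1 : 0);
  if (target <= 1) return true;
  double r2max = radius * radius;
  auto pos = [&](int i, double& ax, double& ay, double& az) {
    if (i == moved) {
      ax = px; ay = py; az = pz;
    } else {
      ax = st.x[i]; ay = st.y[i]; az = st.z[i];
    }
  };
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  int start = -1;
  for (int i = 0; i < n; ++i)
    if (i != skip) { start = i; break; }
  stack.push_back(start);
  seen[start] = 1;
  int count = 1;
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    double ax, ay, az;
    pos(p, ax, ay, az);
    for (int q = 0; q < n; ++q) {
      if (q == skip || seen[q]) continue;
      double bx, by, bz;
      pos(q, bx, by, bz);
      double dx = ax - bx, dy = ay - by, dz = az - bz;
      if (dx * dx + dy * dy + dz * dz < r2max) {
        seen[q] = 1;
        ++count;
        stack.push_back(q);
      }
    }
  }
  return count == target;
}

}  // namespace

// Grand-canonical cluster Monte Carlo driver for both AVB swap variants.
// mode: 0 = solid (lattice-based swaps + intrasite jumps),
//       1 = liquid (original swaps + translations).
// energy_mode: 0 full LJ (open space, all pairs), 1 ideal gas,
//              2 frozen (pair energies at site centers; solid only).
// drop_count_factor corrupts the acceptance rule (drops the N_vac / N_in
// proposal-counting factor) and exists only as a negative control for the
// enumeration oracle.
// [[Rcpp::export]]
List cpp_run_cluster(const NumericMatrix& xyz0, int mode,
                     const NumericMatrix& site_xyz, const IntegerMatrix& site_nbr,
                     const IntegerVector& occ0, double beta, double n_v,
                     double radius, double max_disp, int n_min, int n_max,
                     const NumericVector& eta, int energy_mode, double eps,
                     double sigma, double n_moves_d, int seed, int n_blocks,
                     double p_swap, int sample_every, bool track_patterns,
                     bool drop_count_factor, bool log_moves, int force_kind) {
  const bool solid = mode == 0;
  const long n_moves = static_cast<long>(n_moves_d);
  ClusterState st;
  st.solid = solid;
  const int n0 = xyz0.nrow();
  if (n0 < 1) stop("empty cluster");
  st.x.resize(n0); st.y.resize(n0); st.z.resize(n0);
  for (int i = 0; i < n0; ++i) {
    st.x[i] = xyz0(i, 0); st.y[i] = xyz0(i, 1); st.z[i] = xyz0(i, 2);
  }
  const int n_sites = site_xyz.nrow();
  st.site_part.assign(std::max(n_sites, 1), -1);
  if (solid) {
    if (occ0.size() != n0) stop("occupancy vector does not match particle count");
    st.occ.resize(n0);
    for (int i = 0; i < n0; ++i) {
      int s = occ0[i];
      if (s < 0 || s >= n_sites) stop("occupancy refers to missing site");
      if (st.site_part[s] != -1) stop("two particles share one lattice site");
      st.occ[i] = s;
      st.site_part[s] = i;
    }
  } else {
    st.occ.assign(n0, -1);
  }
  if (n0 < n_min || n0 > n_max) stop("initial size outside window");
  if (eta.size() != n_max - n_min + 1) stop("bias vector does not span window");
  if (track_patterns && n_sites > 32) stop("pattern tracking limited to 32 sites");

  Model m{&site_xyz, &site_nbr, energy_mode, eps, sigma};
  Rng rng(static_cast<uint64_t>(seed));
  const double v_in = (4.0 / 3.0) * M_PI * radius * radius * radius;

  double e_run = total_energy(st, m);

  const int n_size = n_max - n_min + 1;
  NumericMatrix counts(n_size, n_blocks);
  std::unordered_map<uint32_t, double> patterns;
  long att_ins = 0, acc_ins = 0, att_del = 0, acc_del = 0, att_mv = 0,
       acc_mv = 0;

  std::vector<int> scratch;  // vacant-site / neighbor-particle candidates
  std::vector<double> log_kind, log_n, log_de, log_arg, log_acc;
  const long log_cap = log_moves ? std::min(n_moves, 200000L) : 0;

  auto vac_nbrs = [&](int j, std::vector<int>& out) {
    out.clear();
    int s = st.occ[j];
    for (int q = 0; q < 12; ++q) {
      int s2 = site_nbr(s, q);
      if (s2 >= 0 && st.site_part[s2] == -1) out.push_back(s2);
    }
  };
  auto occ_nbrs = [&](int j, std::vector<int>& out) {
    out.clear();
    int s = st.occ[j];
    for (int q = 0; q < 12; ++q) {
      int s2 = site_nbr(s, q);
      if (s2 >= 0 && st.site_part[s2] != -1) out.push_back(st.site_part[s2]);
    }
  };
  auto liquid_nbrs = [&](int j, std::vector<int>& out) {
    out.clear();
    double r2max = radius * radius;
    for (int i = 0; i < st.n(); ++i) {
      if (i == j) continue;
      double dx = st.x[i] - st.x[j], dy = st.y[i] - st.y[j],
             dz = st.z[i] - st.z[j];
      if (dx * dx + dy * dy + dz * dz < r2max) out.push_back(i);
    }
  };

  auto remove_particle = [&](int k) {
    int last = st.n() - 1;
    if (solid) st.site_part[st.occ[k]] = -1;
    if (k != last) {
      st.x[k] = st.x[last]; st.y[k] = st.y[last]; st.z[k] = st.z[last];
      if (solid) {
        st.occ[k] = st.occ[last];
        st.site_part[st.occ[k]] = k;
      }
    }
    st.x.pop_back(); st.y.pop_back(); st.z.pop_back();
    if (solid) st.occ.pop_back(); else st.occ.pop_back();
  };

  for (long mv = 0; mv < n_moves; ++mv) {
    const int n = st.n();
    const int block = static_cast<int>(mv * n_blocks / std::max(n_moves, 1L));
    int kind = 0;          // 1 insert, 2 delete, 3 jump/translate
    double de = 0.0, arg = 0.0;
    bool accepted = false;

    bool do_swap = rng.u() < p_swap;
    if (do_swap) {
      bool do_insert;
      if (force_kind == 1) do_insert = true;
      else if (force_kind == 2) do_insert = false;
      else do_insert = rng.u() < 0.5;
      int j = rng.ui(n);
      if (do_insert) {
        kind = 1;
        ++att_ins;
        if (n + 1 <= n_max) {
          double px, py, pz;
          int site = -1, n_vac = 0, n_in = 0;
          bool proposable = true;
          if (solid) {
            vac_nbrs(j, scratch);
            n_vac = static_cast<int>(scratch.size());
            n_in = 12 - 0;  // recomputed below from occupied neighbors
            std::vector<int> occn;
            occ_nbrs(j, occn);
            n_in = static_cast<int>(occn.size());
            if (n_vac == 0) proposable = false;
            else {
              site = scratch[rng.ui(n_vac)];
              sphere_point(rng, radius, site_xyz(site, 0), site_xyz(site, 1),
                           site_xyz(site, 2), px, py, pz);
            }
          } else {
            liquid_nbrs(j, scratch);
            n_in = static_cast<int>(scratch.size());
            sphere_point(rng, radius, st.x[j], st.y[j], st.z[j], px, py, pz);
          }
          if (proposable) {
            de = insert_energy(st, m, px, py, pz, site);
            double deta = eta[n + 1 - n_min] - eta[n - n_min];
            double count_fac =
                solid ? (drop_count_factor
                             ? double(n) / ((n + 1.0) * (n_in + 1.0))
                             : double(n) * n_vac / ((n + 1.0) * (n_in + 1.0)))
                      : double(n) / ((n + 1.0) * (n_in + 1.0));
            arg = n_v * v_in * std::exp(-beta * (de + deta)) * count_fac;
            if (arg >= 1.0 || rng.u() < arg) {
              st.x.push_back(px); st.y.push_back(py); st.z.push_back(pz);
              if (solid) {
                st.occ.push_back(site);
                st.site_part[site] = n;
              } else {
                st.occ.push_back(-1);
              }
              e_run += de;
              accepted = true;
              ++acc_ins;
            }
          }
        }
      } else {
        kind = 2;
        ++att_del;
        if (n - 1 >= n_min) {
          int n_in = 0, n_vac = 0, k = -1;
          if (solid) {
            occ_nbrs(j, scratch);
            n_in = static_cast<int>(scratch.size());
            if (n_in > 0) {
              k = scratch[rng.ui(n_in)];
              vac_nbrs(j, scratch);
              n_vac = static_cast<int>(scratch.size());
            }
          } else {
            liquid_nbrs(j, scratch);
            n_in = static_cast<int>(scratch.size());
            if (n_in > 0) k = scratch[rng.ui(n_in)];
          }
          bool ok = k >= 0;
          if (ok) {
            ok = solid ? solid_connected_without(st, m, k)
                       : liquid_connected(st, radius, k, -1, 0, 0, 0);
          }
          if (ok) {
            de = delete_energy(st, m, k);
            double deta = eta[n - 1 - n_min] - eta[n - n_min];
            double count_fac =
                solid ? (drop_count_factor
                             ? double(n) * n_in / (n - 1.0)
                             : double(n) * n_in / ((n - 1.0) * (n_vac + 1.0)))
                      : double(n) * n_in / (n - 1.0);
            arg = std::exp(-beta * (de + deta)) / (n_v * v_in) * count_fac;
            if (arg >= 1.0 || rng.u() < arg) {
              remove_particle(k);
              e_run += de;
              accepted = true;
              ++acc_del;
            }
          }
        }
      }
    } else {
      kind = 3;
      ++att_mv;
      int k = rng.ui(n);
      double px, py, pz;
      if (solid) {
        int s = st.occ[k];
        sphere_point(rng, radius, site_xyz(s, 0), site_xyz(s, 1),
                     site_xyz(s, 2), px, py, pz);
      } else {
        px = st.x[k] + (2.0 * rng.u() - 1.0) * max_disp;
        py = st.y[k] + (2.0 * rng.u() - 1.0) * max_disp;
        pz = st.z[k] + (2.0 * rng.u() - 1.0) * max_disp;
      }
      if (m.energy_mode == 0)
        de = point_energy(st, m, px, py, pz, k) -
             point_energy(st, m, st.x[k], st.y[k], st.z[k], k);
      else
        de = 0.0;  // ideal; frozen: site unchanged
      arg = std::exp(-beta * de);
      bool ok = arg >= 1.0 || rng.u() < arg;
      if (ok && !solid && n > 1)
        ok = liquid_connected(st, radius, -1, k, px, py, pz);
      if (ok) {
        st.x[k] = px; st.y[k] = py; st.z[k] = pz;
        e_run += de;
        accepted = true;
        ++acc_mv;
      }
    }

    if ((mv + 1) % sample_every == 0) {
      counts(st.n() - n_min, block) += 1.0;
      if (track_patterns) {
        uint32_t mask = 0;
        for (int i = 0; i < st.n(); ++i) mask |= (uint32_t(1) << st.occ[i]);
        patterns[mask] += 1.0;
      }
    }
    if (log_moves && mv < log_cap) {
      log_kind.push_back(kind);
      log_n.push_back(n);
      log_de.push_back(de);
      log_arg.push_back(arg);
      log_acc.push_back(accepted ? 1.0 : 0.0);
    }
  }

  // audits: energy drift and occupancy consistency
  double e_ref = total_energy(st, m);
  bool occ_ok = true;
  if (solid) {
    for (int i = 0; i < st.n() && occ_ok; ++i)
      occ_ok = st.site_part[st.occ[i]] == i;
    int n_occ = 0;
    for (int s = 0; s < n_sites; ++s)
      if (st.site_part[s] != -1) {
        ++n_occ;
        if (st.occ[st.site_part[s]] != s) occ_ok = false;
      }
    if (n_occ != st.n()) occ_ok = false;
  }

  NumericMatrix xyz_out(st.n(), 3);
  IntegerVector occ_out(st.n());
  for (int i = 0; i < st.n(); ++i) {
    xyz_out(i, 0) = st.x[i]; xyz_out(i, 1) = st.y[i]; xyz_out(i, 2) = st.z[i];
    occ_out[i] = st.occ[i];
  }

  List pat = R_NilValue;
  if (track_patterns) {
    int np = static_cast<int>(patterns.size());
    NumericVector keys(np), vals(np);
    int i = 0;
    for (auto& kv : patterns) {
      keys[i] = kv.first;
      vals[i] = kv.second;
      ++i;
    }
    pat = List::create(_["mask"] = keys, _["count"] = vals);
  }

  List lg = R_NilValue;
  if (log_moves)
    lg = DataFrame::create(_["kind"] = log_kind, _["n_before"] = log_n,
                           _["delta_E"] = log_de, _["arg"] = log_arg,
                           _["accepted"] = log_acc);

  return List::create(
      _["counts"] = counts, _["n_values"] = seq(n_min, n_max),
      _["att_insert"] = double(att_ins), _["acc_insert"] = double(acc_ins),
      _["att_delete"] = double(att_del), _["acc_delete"] = double(acc_del),
      _["att_move"] = double(att_mv), _["acc_move"] = double(acc_mv),
      _["xyz"] = xyz_out, _["occ"] = occ_out, _["energy"] = e_ref,
      _["energy_drift"] = e_ref - e_run, _["occupancy_ok"] = occ_ok,
      _["patterns"] = pat, _["move_log"] = lg);
}
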