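// Event-driven (Gillespie direct) kinetic Monte Carlo core for competitive
// adsorption of hard spherical-cap footprints on a sphere. All random draws
// come from R's RNG (unif_rand / exp_rand), so a set.seed() on the R side
// makes runs bit-reproducible. Semantics mirror the documented contract of
// run_corona()/kmc_step(); the R wrapper owns validation and summaries.
//
// Overlap candidates are found with a uniform 3D cell grid over the unit
// sphere, with cell edge h at least the largest overlap chord between any
// species pair: any two overlapping anchors then differ by at most one
// cell index per axis, so a 27-cell neighbourhood scan is exact. Species
// with whole-surface footprints make h span the sphere and the scan
// degrades gracefully to all-pairs. Per-species member lists give O(1)
// desorption picks. Neither structure changes any random draw or result.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Corona {
  double h;
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<double> ax, ay, az;
  std::vector<int> spi;
  std::vector<long long> cellk;  // cell key per particle
  std::vector<int> posc;         // index within the cell list
  std::vector<std::vector<int> > members;  // particle ids per species
  std::vector<int> posm;         // index within the member list

  explicit Corona(int nsp, double h_) : h(h_), members(nsp) {}

  long long key(double x, double y, double z) const {
    long long kx = (long long)std::floor((x + 1.0) / h);
    long long ky = (long long)std::floor((y + 1.0) / h);
    long long kz = (long long)std::floor((z + 1.0) / h);
    return (kx * 4096 + ky) * 4096 + kz;
  }

  int size() const { return (int)ax.size(); }

  void add(int s, double x, double y, double z) {
    int id = size();
    ax.push_back(x); ay.push_back(y); az.push_back(z);
    spi.push_back(s);
    long long k = key(x, y, z);
    std::vector<int> &v = cells[k];
    cellk.push_back(k);
    posc.push_back((int)v.size());
    v.push_back(id);
    posm.push_back((int)members[s].size());
    members[s].push_back(id);
  }

  void remove(int id) {
    {  // unhook from its cell (swap-with-back inside the cell list)
      std::vector<int> &v = cells[cellk[id]];
      int p = posc[id], moved = v.back();
      v[p] = moved; posc[moved] = p; v.pop_back();
    }
    {  // unhook from its species member list
      std::vector<int> &m = members[spi[id]];
      int p = posm[id], moved = m.back();
      m[p] = moved; posm[moved] = p; m.pop_back();
    }
    int last = size() - 1;
    if (id != last) {  // move the last particle into the freed slot
      ax[id] = ax[last]; ay[id] = ay[last]; az[id] = az[last];
      spi[id] = spi[last]; cellk[id] = cellk[last];
      posc[id] = posc[last]; posm[id] = posm[last];
      cells[cellk[id]][posc[id]] = id;
      members[spi[id]][posm[id]] = id;
    }
    ax.pop_back(); ay.pop_back(); az.pop_back(); spi.pop_back();
    cellk.pop_back(); posc.pop_back(); posm.pop_back();
  }

  // ids of adsorbates whose footprint overlaps an arrival of species s
  void overlaps(int s, double x, double y, double z,
                const NumericMatrix &cos_thresh, std::vector<int> &ov) const {
    ov.clear();
    long long kx = (long long)std::floor((x + 1.0) / h);
    long long ky = (long long)std::floor((y + 1.0) / h);
    long long kz = (long long)std::floor((z + 1.0) / h);
    const double *thr_col = &cos_thresh(0, s);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(((kx + dx) * 4096 + (ky + dy)) * 4096 +
                              (kz + dz));
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            int i = v[q];
            double c = ax[i] * x + ay[i] * y + az[i] * z;
            if (c > thr_col[spi[i]]) ov.push_back(i);
          }
        }
    std::sort(ov.begin(), ov.end());
  }
};

}  // namespace

// [[Rcpp::export(name = ".kmc_engine_cpp")]]
List kmc_engine_cpp(NumericMatrix anchors0, IntegerVector spi0, int n0,
                    double t0, NumericVector scale0,
                    NumericVector ads_base, NumericVector kd_eff,
                    NumericVector e_ads, NumericMatrix cos_thresh,
                    bool displacement, double sim_time, double max_events,
                    double burn_in_fraction, int n_blocks,
                    bool accel, double ao_window, double ao_neq,
                    double ao_flux_tol, double ao_headroom,
                    bool record_events, bool audit,
                    IntegerVector cnt_ads0, IntegerVector cnt_des0,
                    IntegerVector cnt_disp0, IntegerVector cnt_rej0) {
  const int nsp = ads_base.size();
  const bool by_time = R_finite(sim_time);
  const double th = sim_time;
  const double tb = by_time ? burn_in_fraction * sim_time : 0.0;
  const double eb = by_time ? 0.0 : std::floor(burn_in_fraction * max_events);
  const double block_w_time = by_time ? (th - tb) / n_blocks : 0.0;
  const double block_w_ev = by_time ? 0.0 : (max_events - eb) / n_blocks;

  // cell edge: the largest overlap chord between any species pair,
  // clamped below (tiny adsorbates would fragment the grid) and above
  // (whole-surface footprints need only one cell).
  double max_chord = 0.0;
  for (int i = 0; i < nsp; ++i)
    for (int j = 0; j < nsp; ++j) {
      double c = std::sqrt(std::max(0.0, 2.0 - 2.0 * cos_thresh(i, j)));
      max_chord = std::max(max_chord, c);
    }
  double h = std::min(std::max(max_chord * 1.0001, 0.02), 2.01);

  Corona co(nsp, h);
  for (int i = 0; i < n0; ++i)
    co.add(spi0[i] - 1, anchors0(i, 0), anchors0(i, 1), anchors0(i, 2));

  std::vector<double> scale(scale0.begin(), scale0.end());
  std::vector<double> c_ads(cnt_ads0.begin(), cnt_ads0.end());
  std::vector<double> c_des(cnt_des0.begin(), cnt_des0.end());
  std::vector<double> c_disp(cnt_disp0.begin(), cnt_disp0.end());
  std::vector<double> c_rej(cnt_rej0.begin(), cnt_rej0.end());
  std::vector<double> w_ads(nsp, 0.0), w_des(nsp, 0.0);
  double w_count = 0;

  NumericMatrix occ_time(nsp, n_blocks);
  double t_post = 0.0, t = t0, ev = 0.0;
  int overlap_violations = 0;

  std::vector<double> ev_time;
  std::vector<int> ev_kind, ev_sp, ev_ndis;
  if (record_events && R_finite(max_events)) {
    size_t cap = (size_t)max_events;
    ev_time.reserve(cap); ev_kind.reserve(cap);
    ev_sp.reserve(cap); ev_ndis.reserve(cap);
  }

  std::vector<double> ads_r(nsp), des_r(nsp);
  std::vector<int> ov;

  while (ev < max_events) {
    double tot_ads = 0.0, tot_des = 0.0;
    for (int s = 0; s < nsp; ++s) {
      double ns = (double)co.members[s].size();
      ads_r[s] = ads_base[s] * scale[s];
      des_r[s] = kd_eff[s] * scale[s] * ns;
      tot_ads += ads_r[s];
      tot_des += des_r[s];
    }
    double tot = tot_ads + tot_des;
    if (tot <= 0.0) { if (by_time) t = th; break; }

    double dt = exp_rand() / tot;
    double t1 = std::min(t + dt, th);
    double seg = by_time ? std::max(0.0, t1 - std::max(t, tb))
                         : ((ev + 1.0 > eb) ? dt : 0.0);
    if (seg > 0.0) {
      t_post += seg;
      if (co.size() > 0) {
        int blk;
        if (by_time) {
          blk = (int)std::floor(((std::max(t, tb) + t1) / 2.0 - tb) /
                                block_w_time);
        } else {
          blk = (int)std::ceil((ev + 1.0 - eb) / block_w_ev) - 1;
        }
        if (blk < 0) blk = 0;
        if (blk >= n_blocks) blk = n_blocks - 1;
        for (int s = 0; s < nsp; ++s)
          occ_time(s, blk) += (double)co.members[s].size() * seg;
      }
    }
    if (by_time && t + dt >= th) { t = th; break; }
    t += dt;
    ev += 1.0;

    // draw the event (kind codes: 1 adsorb, 2 desorb, 3 displace, 4 reject)
    double r = unif_rand() * tot;
    int kind = 0, s = -1, ndis = 0;
    if (r <= tot_ads) {
      double cum = 0.0;
      s = nsp - 1;
      for (int k = 0; k < nsp; ++k) {
        cum += ads_r[k];
        if (r <= cum) { s = k; break; }
      }
      // arrival: uniform point on the sphere
      double z = -1.0 + 2.0 * unif_rand();
      double azm = 2.0 * M_PI * unif_rand();
      double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
      double X = rho * std::cos(azm), Y = rho * std::sin(azm), Z = z;

      co.overlaps(s, X, Y, Z, cos_thresh, ov);
      bool accept;
      if (!displacement) {
        accept = ov.empty();
        kind = accept ? 1 : 4;
      } else {
        double de = e_ads[s];
        for (size_t k = 0; k < ov.size(); ++k) de -= e_ads[co.spi[ov[k]]];
        double p = (de >= 0.0) ? std::exp(-de) / (1.0 + std::exp(-de))
                               : 1.0 / (1.0 + std::exp(de));
        accept = unif_rand() < p;
        kind = accept ? (ov.empty() ? 1 : 3) : 4;
      }
      if (accept) {
        if (!ov.empty()) {
          ndis = (int)ov.size();
          for (int k = (int)ov.size() - 1; k >= 0; --k) co.remove(ov[k]);
          c_disp[s] += 1;
        }
        co.add(s, X, Y, Z);
        c_ads[s] += 1; w_ads[s] += 1;
      } else {
        c_rej[s] += 1;
      }
    } else {
      // desorption: pick the species, then one of its members uniformly
      double rr = r - tot_ads, cum = 0.0;
      s = nsp - 1;
      for (int k = 0; k < nsp; ++k) {
        cum += des_r[k];
        if (rr <= cum) { s = k; break; }
      }
      int m = (int)co.members[s].size();
      if (m == 0) continue;  // float boundary tie; no-op
      int pick = (int)(unif_rand() * m);
      if (pick >= m) pick = m - 1;
      co.remove(co.members[s][pick]);
      kind = 2;
      c_des[s] += 1; w_des[s] += 1;
    }

    if (audit) {  // independent all-pairs check, no grid involved
      int n = co.size();
      bool bad = false;
      for (int i = 0; i < n - 1 && !bad; ++i)
        for (int j = i + 1; j < n; ++j) {
          double c = co.ax[i] * co.ax[j] + co.ay[i] * co.ay[j] +
                     co.az[i] * co.az[j];
          if (c > cos_thresh(co.spi[i], co.spi[j]) + 1e-12) {
            bad = true;
            break;
          }
        }
      if (bad) ++overlap_violations;
    }

    if (record_events) {
      ev_time.push_back(t); ev_kind.push_back(kind);
      ev_sp.push_back(s + 1); ev_ndis.push_back(ndis);
    }

    // quasi-equilibrium acceleration bookkeeping
    if (accel) {
      w_count += 1;
      bool any_scaled = false;
      for (int k = 0; k < nsp; ++k) if (scale[k] < 1.0) any_scaled = true;
      if (kind != 4 && scale[s] == 1.0 && any_scaled) {
        // a non-equilibrated event class fired: revert scaling
        std::fill(scale.begin(), scale.end(), 1.0);
        std::fill(w_ads.begin(), w_ads.end(), 0.0);
        std::fill(w_des.begin(), w_des.end(), 0.0);
        w_count = 0;
      } else if (w_count >= ao_window) {
        int n_eq_sp = 0;
        std::vector<bool> eq(nsp, false);
        for (int k = 0; k < nsp; ++k) {
          double totk = w_ads[k] + w_des[k];
          eq[k] = w_ads[k] > ao_neq && w_des[k] > ao_neq &&
                  std::fabs(w_ads[k] - w_des[k]) <=
                      ao_flux_tol * std::max(totk, 1.0);
          if (eq[k]) ++n_eq_sp;
        }
        std::fill(scale.begin(), scale.end(), 1.0);
        if (n_eq_sp > 0 && n_eq_sp < nsp) {
          double r_fast = 0.0;
          for (int k = 0; k < nsp; ++k)
            if (!eq[k])
              r_fast = std::max(r_fast, ads_base[k] +
                                kd_eff[k] * (double)co.members[k].size());
          if (r_fast > 0.0)
            for (int k = 0; k < nsp; ++k)
              if (eq[k]) {
                double rk = ads_base[k] +
                            kd_eff[k] * (double)co.members[k].size();
                scale[k] = std::min(1.0, ao_headroom * r_fast / rk);
              }
        }
        std::fill(w_ads.begin(), w_ads.end(), 0.0);
        std::fill(w_des.begin(), w_des.end(), 0.0);
        w_count = 0;
      }
    }
  }

  int n = co.size();
  NumericMatrix anchors_out(n, 3);
  IntegerVector spi_out(n);
  for (int i = 0; i < n; ++i) {
    anchors_out(i, 0) = co.ax[i];
    anchors_out(i, 1) = co.ay[i];
    anchors_out(i, 2) = co.az[i];
    spi_out[i] = co.spi[i] + 1;
  }
  List events = R_NilValue;
  if (record_events && !ev_time.empty())
    events = List::create(_["time"] = wrap(ev_time),
                          _["kind"] = wrap(ev_kind),
                          _["sp"] = wrap(ev_sp),
                          _["n_displaced"] = wrap(ev_ndis));
  return List::create(
      _["anchors"] = anchors_out, _["spi"] = spi_out, _["n"] = n,
      _["time"] = t, _["scale"] = wrap(scale),
      _["adsorb"] = wrap(c_ads), _["desorb"] = wrap(c_des),
      _["displace"] = wrap(c_disp), _["reject"] = wrap(c_rej),
      _["occ_time"] = occ_time, _["t_post"] = t_post,
      _["n_events"] = ev, _["events"] = events,
      _["overlap_violations"] = overlap_violations);
}
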