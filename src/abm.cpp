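#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Off-lattice caricature of tumour-macrophage-vessel dynamics on an hourly
// tick. Rules, in order: (i) macrophage extravasation at vessels while any
// tumour cell exists; (ii) M1 chemotaxis toward the nearest tumour cell with
// isotropic noise; (iii) phenotype switching after accrued tumour proximity;
// (iv) M2 return to the nearest vessel, dragging tumour cells within the
// paracrine radius; (v) density-limited tumour proliferation; (vi) contact
// killing of tumour cells by M1 macrophages; (vii) pairwise overlap
// resolution. Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate(List params, NumericVector vx, NumericVector vy,
                  NumericVector tx0, NumericVector ty0) {
  const double extrav = as<double>(params["extravasation_rate"]);
  const double chi = as<double>(params["chemotaxis_sensitivity"]);
  const double switch_thr = as<double>(params["phenotype_switch_threshold"]);
  const double kill_hours = as<double>(params["kill_contact_hours"]);
  const double prolif = as<double>(params["proliferation_rate"]);
  const double L = as<double>(params["domain_size"]);
  const double cr = as<double>(params["cell_radius"]);
  const int horizon = as<int>(params["horizon"]);
  const int snap = as<int>(params["snapshot_interval"]);
  const double speed = as<double>(params["step_speed"]);

  const double contact_r = 2.0 * cr;      // kill / proximity radius
  const double follow_r = 2.0;            // M2 paracrine drag radius
  const double sep = 1.8 * cr;            // minimum separation after pushes
  const double crowd_r = 4.0 * cr;        // crowding radius for division
  const int crowd_max = 8;                // max neighbours allowing division
  const int nv = vx.size();

  RNGScope scope;

  // cell state (tumour and macrophages; vessels are fixed and kept in R)
  std::vector<int> id, type;              // type: 0 tumour, 1 macrophage
  std::vector<double> x, y, phen, cnt;    // cnt: tumour = consecutive M1
                                          // contact h; macrophage = accrued
                                          // tumour proximity h
  std::vector<bool> alive;
  int next_id = nv + 1;                   // vessels occupy ids 1..nv
  for (int i = 0; i < tx0.size(); ++i) {
    id.push_back(next_id++); type.push_back(0);
    x.push_back(tx0[i]); y.push_back(ty0[i]);
    phen.push_back(NA_REAL); cnt.push_back(0.0); alive.push_back(true);
  }

  // snapshot accumulators
  std::vector<int> s_time, s_id, s_type;
  std::vector<double> s_x, s_y, s_phen;
  auto record = [&](int t) {
    for (size_t i = 0; i < id.size(); ++i) {
      if (!alive[i]) continue;
      s_time.push_back(t); s_id.push_back(id[i]); s_type.push_back(type[i]);
      s_x.push_back(x[i]); s_y.push_back(y[i]); s_phen.push_back(phen[i]);
    }
  };
  record(0);

  for (int t = 1; t <= horizon; ++t) {
    // indices of live cells by type
    std::vector<int> tum, mac;
    for (size_t i = 0; i < id.size(); ++i) {
      if (!alive[i]) continue;
      if (type[i] == 0) tum.push_back(i); else mac.push_back(i);
    }

    // (i) extravasation
    if (!tum.empty()) {
      for (int v = 0; v < nv; ++v) {
        if (unif_rand() < extrav) {
          double th = 2.0 * M_PI * unif_rand();
          id.push_back(next_id++); type.push_back(1);
          x.push_back(vx[v] + 1.2 * cr * std::cos(th));
          y.push_back(vy[v] + 1.2 * cr * std::sin(th));
          phen.push_back(0.0); cnt.push_back(0.0); alive.push_back(true);
        }
      }
    }
    // refresh macrophage index after spawning
    mac.clear();
    for (size_t i = 0; i < id.size(); ++i)
      if (alive[i] && type[i] == 1) mac.push_back(i);

    // (ii)/(iv) macrophage steps; remember displacements for tumour drag
    std::vector<double> mdx(mac.size(), 0.0), mdy(mac.size(), 0.0);
    for (size_t k = 0; k < mac.size(); ++k) {
      int i = mac[k];
      double ux = 0.0, uy = 0.0;
      if (phen[i] < 0.5) {
        // toward nearest tumour cell (pure noise when none left)
        double best = R_PosInf;
        for (int j : tum) {
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d2 = dx * dx + dy * dy;
          if (d2 < best) { best = d2; ux = dx; uy = dy; }
        }
      } else {
        double best = R_PosInf;
        for (int v = 0; v < nv; ++v) {
          double dx = vx[v] - x[i], dy = vy[v] - y[i];
          double d2 = dx * dx + dy * dy;
          if (d2 < best) { best = d2; ux = dx; uy = dy; }
        }
      }
      double un = std::sqrt(ux * ux + uy * uy);
      if (un > 0) { ux /= un; uy /= un; }
      double gx = chi * ux + norm_rand(), gy = chi * uy + norm_rand();
      double gn = std::sqrt(gx * gx + gy * gy);
      if (gn > 0) { gx /= gn; gy /= gn; }
      mdx[k] = speed * gx; mdy[k] = speed * gy;
      x[i] += mdx[k]; y[i] += mdy[k];
    }

    // (iv) tumour cells follow the displacement of the nearest M2 within
    // the paracrine radius
    for (int j : tum) {
      double best = follow_r * follow_r;
      int bk = -1;
      for (size_t k = 0; k < mac.size(); ++k) {
        int i = mac[k];
        if (phen[i] < 0.5) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j];
        double d2 = dx * dx + dy * dy;
        if (d2 <= best) { best = d2; bk = (int)k; }
      }
      if (bk >= 0) { x[j] += mdx[bk]; y[j] += mdy[bk]; }
    }

    // (iii) phenotype dynamics: accrue proximity hours, then ramp p
    for (size_t k = 0; k < mac.size(); ++k) {
      int i = mac[k];
      bool near = false;
      for (int j : tum) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        if (dx * dx + dy * dy <= contact_r * contact_r) { near = true; break; }
      }
      if (near) cnt[i] += 1.0;
      if (cnt[i] >= switch_thr)
        phen[i] = std::min(1.0, phen[i] + 0.05);
    }

    // (vi) contact killing: consecutive M1 contact hours
    for (int j : tum) {
      bool near = false;
      for (size_t k = 0; k < mac.size(); ++k) {
        int i = mac[k];
        if (phen[i] >= 0.5) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy <= contact_r * contact_r) { near = true; break; }
      }
      cnt[j] = near ? cnt[j] + 1.0 : 0.0;
      if (cnt[j] >= kill_hours) alive[j] = false;
    }

    // (v) density-limited proliferation into an adjacent position
    std::vector<int> tum2;
    for (size_t i = 0; i < id.size(); ++i)
      if (alive[i] && type[i] == 0) tum2.push_back(i);
    for (int j : tum2) {
      if (unif_rand() >= prolif) continue;
      int nb = 0, nb_close = 0;
      for (int j2 : tum2) {
        if (j2 == j) continue;
        double dx = x[j2] - x[j], dy = y[j2] - y[j];
        double d2 = dx * dx + dy * dy;
        if (d2 <= crowd_r * crowd_r) ++nb;
        if (d2 <= 4.0) ++nb_close;
      }
      // crowding cap, and detached single cells do not divide
      if (nb >= crowd_max) continue;
      if (nb_close == 0 && tum2.size() > 1) continue;
      double th = 2.0 * M_PI * unif_rand();
      id.push_back(next_id++); type.push_back(0);
      x.push_back(x[j] + 2.0 * cr * std::cos(th));
      y.push_back(y[j] + 2.0 * cr * std::sin(th));
      phen.push_back(NA_REAL); cnt.push_back(0.0); alive.push_back(true);
    }

    // M2 re-entry: a pro-tumour macrophage reaching a vessel despawns
    for (size_t i = 0; i < id.size(); ++i) {
      if (!alive[i] || type[i] != 1 || phen[i] < 0.5) continue;
      for (int v = 0; v < nv; ++v) {
        double dx = vx[v] - x[i], dy = vy[v] - y[i];
        if (dx * dx + dy * dy <= contact_r * contact_r) {
          alive[i] = false; break;
        }
      }
    }

    // tumour cell-cell adhesion: drift toward the centroid of tumour
    // neighbours, keeping the mass compact against contact pushes
    {
      std::vector<int> tl;
      for (size_t i = 0; i < id.size(); ++i)
        if (alive[i] && type[i] == 0) tl.push_back(i);
      std::vector<double> ax(tl.size(), 0.0), ay(tl.size(), 0.0);
      for (size_t a = 0; a < tl.size(); ++a) {
        double cx = 0, cy = 0; int nn = 0;
        for (size_t b = 0; b < tl.size(); ++b) {
          if (a == b) continue;
          double dx = x[tl[b]] - x[tl[a]], dy = y[tl[b]] - y[tl[a]];
          if (dx * dx + dy * dy <= 6.25) { cx += dx; cy += dy; ++nn; }
        }
        if (nn == 0) {
          // detached cell: drift back toward the nearest tumour cell
          double best = R_PosInf, bx = 0, by = 0;
          for (size_t b = 0; b < tl.size(); ++b) {
            if (a == b) continue;
            double dx = x[tl[b]] - x[tl[a]], dy = y[tl[b]] - y[tl[a]];
            double d2 = dx * dx + dy * dy;
            if (d2 < best) { best = d2; bx = dx; by = dy; }
          }
          if (std::isfinite(best) && best > 1e-18) {
            double nrm = std::sqrt(best);
            ax[a] = 0.1 * bx / nrm; ay[a] = 0.1 * by / nrm;
          }
          continue;
        }
        cx /= nn; cy /= nn;
        double nrm = std::sqrt(cx * cx + cy * cy);
        if (nrm > 1e-9) { ax[a] = 0.08 * cx / nrm; ay[a] = 0.08 * cy / nrm; }
      }
      for (size_t a = 0; a < tl.size(); ++a) {
        x[tl[a]] += ax[a]; y[tl[a]] += ay[a];
      }
    }

    // (vii) overlap resolution among live cells
    std::vector<int> live;
    for (size_t i = 0; i < id.size(); ++i) if (alive[i]) live.push_back(i);
    for (int it = 0; it < 3; ++it) {
      for (size_t a = 0; a < live.size(); ++a) {
        for (size_t b = a + 1; b < live.size(); ++b) {
          int i = live[a], j = live[b];
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d2 = dx * dx + dy * dy;
          if (d2 >= sep * sep) continue;
          double d = std::sqrt(d2);
          if (d < 1e-9) {
            double th = 2.0 * M_PI * unif_rand();
            dx = std::cos(th); dy = std::sin(th); d = 1.0;
          } else { dx /= d; dy /= d; }
          double push = 0.5 * (sep - std::min(d, sep));
          x[i] -= push * dx; y[i] -= push * dy;
          x[j] += push * dx; y[j] += push * dy;
        }
      }
    }

    // clamp to the domain
    for (int i : live) {
      x[i] = std::min(L, std::max(0.0, x[i]));
      y[i] = std::min(L, std::max(0.0, y[i]));
    }

    if (t % snap == 0) record(t);
  }

  return List::create(
      _["time"] = wrap(s_time), _["cell_id"] = wrap(s_id),
      _["type"] = wrap(s_type), _["x"] = wrap(s_x), _["y"] = wrap(s_y),
      _["phenotype"] = wrap(s_phen));
}
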