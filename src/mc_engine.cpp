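// Condensed-history Monte Carlo transport of the plaque source term in
// water, scoring dose per decay on a Cartesian voxel grid with
// history-by-history statistics.
//
// Physics model (shared tables with the deterministic kernel solver):
//  - betas: continuous slowing down on the water collision stopping-power
//    table, fixed water-equivalent step, Rayleigh-sampled Highland multiple
//    scattering per step, energy deposited at the step midpoint, terminated
//    when the residual CSDA range in water falls below the cutoff (residual
//    energy deposited locally);
//  - silver layers: water-equivalent path-length scaling by the ratio of
//    linear collision stopping powers (energy loss and scattering both use
//    water-equivalent lengths); electrons crossing the outer backing
//    surface are terminated and tallied as absorbed;
//  - gammas: deterministic kerma-with-attenuation ray trace (no buildup),
//    scored separately from the beta dose.
//
// Single-threaded with a PCG32 generator: identical seed + configuration
// gives bit-identical tallies.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double ME = 0.51099895;
static const double X0_WATER_MM = 360.8;

// ---- PCG32 ----------------------------------------------------------------
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() {  // in (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
};

static double lin_interp(const std::vector<double>& x,
                         const std::vector<double>& y, double xi) {
  if (xi <= x.front()) return y.front();
  if (xi >= x.back()) return y.back();
  size_t hi = std::upper_bound(x.begin(), x.end(), xi) - x.begin();
  size_t lo = hi - 1;
  double t = (xi - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + t * (y[hi] - y[lo]);
}

// ---- per-component scoring with history-by-history variance ---------------
struct Scorer {
  std::vector<double> sum, ssq, hist;
  std::vector<int> tag;
  std::vector<int> touched;
  int cur;
  double dep_total;  // energy deposited in-grid this history (MeV)

  void init(size_t n) {
    sum.assign(n, 0.0); ssq.assign(n, 0.0);
    hist.assign(n, 0.0); tag.assign(n, -1);
    touched.reserve(4096); cur = -1; dep_total = 0.0;
  }
  void begin(int h) { cur = h; touched.clear(); dep_total = 0.0; }
  void add(size_t idx, double v) {
    if (tag[idx] != cur) { tag[idx] = cur; hist[idx] = 0.0; touched.push_back((int)idx); }
    hist[idx] += v;
    dep_total += v;
  }
  void flush() {
    for (int idx : touched) {
      double v = hist[idx];
      sum[idx] += v;
      ssq[idx] += v * v;
    }
  }
};

struct Grid {
  double ox, oy, oz, h;
  int nx, ny, nz;
  bool index(double x, double y, double z, size_t& idx) const {
    int i = (int)std::floor((x - ox) / h);
    int j = (int)std::floor((y - oy) / h);
    int k = (int)std::floor((z - oz) / h);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    idx = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
    return true;
  }
};

// rotate direction (u,v,w) by polar angle theta, azimuth phi
static void rotate_dir(double& u, double& v, double& w,
                       double theta, double phi) {
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  double uu, vv, ww;
  if (std::fabs(w) > 0.99999) {
    double sgn = (w >= 0) ? 1.0 : -1.0;
    uu = st * cp; vv = sgn * st * sp; ww = sgn * ct;
  } else {
    double s = std::sqrt(1.0 - w * w);
    uu = u * ct + st * (u * w * cp - v * sp) / s;
    vv = v * ct + st * (v * w * cp + u * sp) / s;
    ww = w * ct - s * st * cp;
  }
  double n = std::sqrt(uu * uu + vv * vv + ww * ww);
  u = uu / n; v = vv / n; w = ww / n;
}

// [[Rcpp::export]]
List mc_run_cpp(int n_histories, double seed,
                NumericVector quantile_table,
                NumericVector gamma_energy, NumericVector gamma_intensity,
                List geom, List grid_spec, List phys, List config) {
  // geometry
  int mode = as<int>(geom["mode"]);  // 0 = bare point source, 1 = plaque
  bool backing_absorb = true;
  if (geom.containsElementNamed("backing_absorb")) {
    backing_absorb = as<bool>(geom["backing_absorb"]);
  }
  double cx = 0, cy = 0, cz = 0, ax = 0, ay = 0, az = 1;
  double Rin = 0, Rout = 0, Rem = 0, cos_cap = 1, cos_act = 1;
  double e1x = 1, e1y = 0, e1z = 0, e2x = 0, e2y = 1, e2z = 0;
  if (mode == 1) {
    NumericVector cp = geom["center"], axv = geom["axis"],
                  b1 = geom["e1"], b2 = geom["e2"];
    cx = cp[0]; cy = cp[1]; cz = cp[2];
    ax = axv[0]; ay = axv[1]; az = axv[2];
    e1x = b1[0]; e1y = b1[1]; e1z = b1[2];
    e2x = b2[0]; e2y = b2[1]; e2z = b2[2];
    Rin = as<double>(geom["r_inner"]);
    Rout = as<double>(geom["r_outer"]);
    Rem = as<double>(geom["r_emission"]);
    cos_cap = std::cos(as<double>(geom["cap_half_angle"]));
    cos_act = std::cos(as<double>(geom["active_half_angle"]));
  }

  Grid gr;
  NumericVector origin = grid_spec["origin"];
  IntegerVector ng = grid_spec["n"];
  gr.ox = origin[0]; gr.oy = origin[1]; gr.oz = origin[2];
  gr.h = as<double>(grid_spec["h"]);
  gr.nx = ng[0]; gr.ny = ng[1]; gr.nz = ng[2];
  size_t nvox = (size_t)gr.nx * gr.ny * gr.nz;

  // physics tables
  NumericVector eTab = phys["energy"], swTab = phys["sw_per_mm"],
                rTab = phys["range_mm"], fAgTab = phys["f_silver"];
  std::vector<double> etab(eTab.begin(), eTab.end());
  std::vector<double> stab(swTab.begin(), swTab.end());
  std::vector<double> rtab(rTab.begin(), rTab.end());
  std::vector<double> ftab(fAgTab.begin(), fAgTab.end());
  NumericVector gE = phys["photon_energy"], gMu = phys["photon_mu_per_mm"],
                gMuen = phys["photon_muen_per_mm"];
  std::vector<double> pe(gE.begin(), gE.end());
  std::vector<double> pmu(gMu.begin(), gMu.end());
  std::vector<double> pmuen(gMuen.begin(), gMuen.end());
  double f_photon_silver = as<double>(phys["f_photon_silver"]);

  double cutoff_range = as<double>(config["cutoff_range_water"]);
  double step_weq = as<double>(config["step_weq"]);
  bool include_gammas = as<bool>(config["include_gammas"]);
  int n_batches = as<int>(config["n_batches"]);

  std::vector<double> qt(quantile_table.begin(), quantile_table.end());
  int nq = (int)qt.size() - 1;
  int n_lines = gamma_energy.size();

  Scorer beta_sc, gamma_sc;
  beta_sc.init(nvox);
  if (include_gammas) gamma_sc.init(nvox);

  // per-batch energy bookkeeping (MeV)
  NumericVector b_emitted(n_batches), b_dep_grid(n_batches),
      b_dep_outside(n_batches), b_absorbed_backing(n_batches),
      b_gamma_residual(n_batches);

  Pcg32 rng((uint64_t)seed);

  for (int h = 0; h < n_histories; ++h) {
    int ib = (int)(((int64_t)h * n_batches) / n_histories);
    beta_sc.begin(h);
    if (include_gammas) gamma_sc.begin(h);
    double dep_outside = 0.0, absorbed = 0.0, gamma_resid = 0.0;

    // emission position
    double px, py, pz;
    if (mode == 1) {
      double cmu = cos_act + rng.unif() * (1.0 - cos_act);
      double smu = std::sqrt(std::max(0.0, 1.0 - cmu * cmu));
      double aa = 2.0 * M_PI * rng.unif();
      double sx = cmu * ax + smu * (std::cos(aa) * e1x + std::sin(aa) * e2x);
      double sy = cmu * ay + smu * (std::cos(aa) * e1y + std::sin(aa) * e2y);
      double sz = cmu * az + smu * (std::cos(aa) * e1z + std::sin(aa) * e2z);
      px = cx + Rem * sx; py = cy + Rem * sy; pz = cz + Rem * sz;
    } else {
      px = py = pz = 0.0;
    }

    // ---- beta ----
    double u = rng.unif();
    double fi = u * nq;
    int iq = (int)fi;
    if (iq >= nq) iq = nq - 1;
    double E = qt[iq] + (fi - iq) * (qt[iq + 1] - qt[iq]);
    b_emitted[ib] += E;

    // isotropic direction
    double w = 2.0 * rng.unif() - 1.0;
    double aphi = 2.0 * M_PI * rng.unif();
    double sw = std::sqrt(std::max(0.0, 1.0 - w * w));
    double du = sw * std::cos(aphi), dv = sw * std::sin(aphi), dw = w;

    double x = px, y = py, z = pz;
    bool alive = (lin_interp(etab, rtab, E) > cutoff_range);
    if (!alive) {
      size_t idx;
      if (gr.index(x, y, z, idx)) beta_sc.add(idx, E); else dep_outside += E;
      E = 0.0;
    }
    while (alive) {
      // region and water-equivalence factor
      double f = 1.0;
      if (mode == 1) {
        double rx = x - cx, ry = y - cy, rz = z - cz;
        double rr = std::sqrt(rx * rx + ry * ry + rz * rz);
        double ca = (rx * ax + ry * ay + rz * az) / (rr > 1e-12 ? rr : 1.0);
        if (ca >= cos_cap) {
          if (rr > Rout) {
            if (backing_absorb) { absorbed += E; E = 0.0; break; }
          } else if (rr >= Rin) {
            f = lin_interp(etab, ftab, E);
          }
        }
      }
      double step_geo = step_weq / f;
      double dE = lin_interp(etab, stab, E) * step_weq;
      if (dE > E) dE = E;
      // deposit at the step midpoint
      size_t idx;
      double mx = x + du * step_geo * 0.5, my = y + dv * step_geo * 0.5,
             mz = z + dw * step_geo * 0.5;
      if (gr.index(mx, my, mz, idx)) beta_sc.add(idx, dE);
      else dep_outside += dE;
      x += du * step_geo; y += dv * step_geo; z += dw * step_geo;
      E -= dE;
      if (E <= 1e-9 || lin_interp(etab, rtab, E) <= cutoff_range) {
        if (E > 0.0) {
          if (gr.index(x, y, z, idx)) beta_sc.add(idx, E);
          else dep_outside += E;
          E = 0.0;
        }
        break;
      }
      // multiple scattering (Highland, Rayleigh-sampled)
      double pc = std::sqrt(E * (E + 2.0 * ME));
      double beta_v = pc / (E + ME);
      double theta0 = 13.6 / (beta_v * pc) * std::sqrt(step_weq / X0_WATER_MM);
      double theta = theta0 * std::sqrt(-2.0 * std::log(rng.unif()));
      rotate_dir(du, dv, dw, theta, 2.0 * M_PI * rng.unif());
    }

    // ---- gammas: kerma-with-attenuation ray trace ----
    if (include_gammas && n_lines > 0) {
      for (int il = 0; il < n_lines; ++il) {
        if (rng.unif() >= gamma_intensity[il]) continue;
        double Eg = gamma_energy[il];
        b_emitted[ib] += Eg;
        double gw = 2.0 * rng.unif() - 1.0;
        double gphi = 2.0 * M_PI * rng.unif();
        double gs = std::sqrt(std::max(0.0, 1.0 - gw * gw));
        double ku = gs * std::cos(gphi), kv = gs * std::sin(gphi), kw = gw;
        double mu = lin_interp(pe, pmu, Eg);
        double muen = lin_interp(pe, pmuen, Eg);
        double weq = 0.0, depg = 0.0;
        const double dt = 0.1, tmax = 60.0;
        for (double t = 0.5 * dt; t < tmax; t += dt) {
          double gx = px + ku * t, gy = py + kv * t, gz = pz + kw * t;
          double fph = 1.0;
          if (mode == 1) {
            double rx = gx - cx, ry = gy - cy, rz = gz - cz;
            double rr = std::sqrt(rx * rx + ry * ry + rz * rz);
            double ca = (rx * ax + ry * ay + rz * az) / (rr > 1e-12 ? rr : 1.0);
            if (ca >= cos_cap && rr >= Rin && rr <= Rout) fph = f_photon_silver;
          }
          weq += fph * dt;
          double att = std::exp(-mu * weq);
          if (att < 1e-7) break;
          double d = Eg * muen * att * dt;
          size_t idx;
          if (gr.index(gx, gy, gz, idx)) { gamma_sc.add(idx, d); depg += d; }
          else { dep_outside += d; depg += d; }
        }
        gamma_resid += Eg - depg;
      }
    }

    beta_sc.flush();
    double dep_in = beta_sc.dep_total;
    if (include_gammas) { gamma_sc.flush(); dep_in += gamma_sc.dep_total; }
    b_dep_grid[ib] += dep_in;
    b_dep_outside[ib] += dep_outside;
    b_absorbed_backing[ib] += absorbed;
    b_gamma_residual[ib] += gamma_resid;

    if ((h & 0xffff) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["beta_sum"] = NumericVector(beta_sc.sum.begin(), beta_sc.sum.end()),
    _["beta_ssq"] = NumericVector(beta_sc.ssq.begin(), beta_sc.ssq.end()),
    _["batch_emitted"] = b_emitted,
    _["batch_dep_grid"] = b_dep_grid,
    _["batch_dep_outside"] = b_dep_outside,
    _["batch_absorbed_backing"] = b_absorbed_backing,
    _["batch_gamma_residual"] = b_gamma_residual);
  if (include_gammas) {
    out["gamma_sum"] = NumericVector(gamma_sc.sum.begin(), gamma_sc.sum.end());
    out["gamma_ssq"] = NumericVector(gamma_sc.ssq.begin(), gamma_sc.ssq.end());
  }
  return out;
}
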