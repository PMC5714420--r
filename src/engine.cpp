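// Voxel Monte Carlo transport core.
//
// Photons step through the density grid in fixed increments h, accumulating
// optical depth from the local voxel (looked up at the step midpoint) until
// the accumulated transmission falls below a per-flight survival threshold
// drawn once per flight. Compton recoil electrons and sub-cutoff remnants
// deposit energy locally or along straight CSDA tracks. The flattening
// filter is handled with the zero/single-scatter model. All randomness
// comes from one 64-bit Mersenne twister seeded from R.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double MEC2 = 0.511;

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t s) : g(s) {}
  double u() { return ((g() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct Grid {
  int nx, ny, nz;
  double vx, vy, vz, ox, oy, oz;
  const double *rho;
  const int *mat; // 1-based material ids
  bool inside(double x, double y, double z) const {
    return x >= ox && y >= oy && z >= oz && x < ox + nx * vx &&
           y < oy + ny * vy && z < oz + nz * vz;
  }
  long voxel(double x, double y, double z) const {
    int i = (int)std::floor((x - ox) / vx);
    int j = (int)std::floor((y - oy) / vy);
    int k = (int)std::floor((z - oz) / vz);
    return i + (long)nx * (j + (long)ny * k);
  }
  double ztop() const { return oz + nz * vz; }
};

struct Physics {
  int ne;           // energy rows, 10 keV grid starting at 10 keV
  const double *att;    // [ne x nmat] (pe+compton)/rho, cm^2/g
  const double *pefrac; // [ne x nmat]
  const double *spow;   // [ne x nmat] MeV cm^2/g
  const double *cang;   // [1001 x ne] compton angles, radians
  int erow(double e) const {
    int r = (int)std::lround(e / 0.01) - 1;
    return r < 0 ? 0 : (r >= ne ? ne - 1 : r);
  }
  double stop_power(double e, int m) const {
    double x = e / 0.01 - 1.0;
    int i0 = (int)std::floor(x);
    if (i0 < 0) i0 = 0;
    if (i0 > ne - 2) i0 = ne - 2;
    double f = x - i0;
    const double *col = spow + (long)m * ne;
    return col[i0] * (1 - f) + col[i0 + 1] * f;
  }
};

static inline void rotate_dir(double &ux, double &uy, double &uz, double th,
                              double psi) {
  double ct = std::cos(th), st = std::sin(th);
  double cp = std::cos(psi), sp = std::sin(psi);
  double s2 = std::sqrt(std::max(1.0 - uz * uz, 0.0));
  double nx, ny, nz;
  if (s2 > 1e-10) {
    nx = ux * ct + st * (ux * uz * cp - uy * sp) / s2;
    ny = uy * ct + st * (uy * uz * cp + ux * sp) / s2;
    nz = uz * ct - s2 * st * cp;
  } else {
    double sgn = uz >= 0 ? 1.0 : -1.0;
    nx = st * cp * sgn;
    ny = st * sp * sgn;
    nz = ct * sgn;
  }
  double n = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / n; uy = ny / n; uz = nz / n;
}

struct Tally {
  std::vector<double> edep;
  double e_entered = 0, e_exited = 0;
  double n_entered = 0, n_pe = 0, n_compton = 0;
};

struct Config {
  double h, he, cutoff;
};

static void transport_electron(const Grid &g, const Physics &ph,
                               const Config &cf, Tally &t, double x, double y,
                               double z, double ux, double uy, double uz,
                               double e) {
  while (e >= cf.cutoff) {
    double mx = x + 0.5 * cf.he * ux, my = y + 0.5 * cf.he * uy,
           mz = z + 0.5 * cf.he * uz;
    if (!g.inside(mx, my, mz)) { t.e_exited += e; return; }
    long v = g.voxel(mx, my, mz);
    int m = g.mat[v] - 1;
    double srho = ph.stop_power(e, m) * g.rho[v];
    double de = srho * cf.he;
    if (de >= e) {
      double len = e / srho;
      double px = x + 0.5 * len * ux, py = y + 0.5 * len * uy,
             pz = z + 0.5 * len * uz;
      t.edep[g.inside(px, py, pz) ? g.voxel(px, py, pz) : v] += e;
      return;
    }
    t.edep[v] += de;
    e -= de;
    x += cf.he * ux; y += cf.he * uy; z += cf.he * uz;
  }
  // residual below cutoff deposits locally
  if (g.inside(x, y, z)) t.edep[g.voxel(x, y, z)] += e;
  else t.e_exited += e;
}

static void transport_photon(const Grid &g, const Physics &ph,
                             const Config &cf, Tally &t, Rng &rng, double x,
                             double y, double z, double ux, double uy,
                             double uz, double e) {
  while (true) {
    int row = ph.erow(e);
    double tau_th = -std::log(rng.u());
    double tau = 0.0;
    long v = -1;
    bool hit = false;
    while (true) {
      double mx = x + 0.5 * cf.h * ux, my = y + 0.5 * cf.h * uy,
             mz = z + 0.5 * cf.h * uz;
      if (!g.inside(mx, my, mz)) { t.e_exited += e; return; }
      v = g.voxel(mx, my, mz);
      int m = g.mat[v] - 1;
      tau += cf.h * g.rho[v] * ph.att[row + (long)m * ph.ne];
      x += cf.h * ux; y += cf.h * uy; z += cf.h * uz;
      if (tau >= tau_th) { hit = true; break; }
    }
    if (!hit) return;
    int m = g.mat[v] - 1;
    if (rng.u() < ph.pefrac[row + (long)m * ph.ne]) {
      t.edep[v] += e;
      t.n_pe += 1;
      return;
    }
    // Compton
    t.n_compton += 1;
    int slot = (int)std::lround(rng.u() * 1000.0);
    double th = ph.cang[slot + 1001L * row];
    double psi = 2.0 * M_PI * rng.u();
    double hvp = e / (1.0 + e / MEC2 * (1.0 - std::cos(th)));
    double te = e - hvp;
    if (te > 0) {
      if (te < cf.cutoff) {
        t.edep[v] += te;
      } else {
        double phi = std::atan2(1.0, (1.0 + e / MEC2) * std::tan(0.5 * th));
        double ex = ux, ey = uy, ez = uz;
        rotate_dir(ex, ey, ez, phi, psi + M_PI);
        transport_electron(g, ph, cf, t, x, y, z, ex, ey, ez, te);
      }
    }
    rotate_dir(ux, uy, uz, th, psi);
    e = hvp;
    if (e < cf.cutoff) { t.edep[v] += e; return; }
  }
}

static Grid make_grid(IntegerVector dims, NumericVector vox,
                      NumericVector origin, NumericVector density,
                      IntegerVector material) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.vx = vox[0]; g.vy = vox[1]; g.vz = vox[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.rho = density.begin();
  g.mat = material.begin();
  return g;
}

static Physics make_physics(NumericMatrix att, NumericMatrix pefrac,
                            NumericMatrix spow, NumericMatrix cang) {
  Physics ph;
  ph.ne = att.nrow();
  ph.att = att.begin();
  ph.pefrac = pefrac.begin();
  ph.spow = spow.begin();
  ph.cang = cang.begin();
  return ph;
}

static List tally_result(const Grid &g, Tally &t, double n_emitted,
                         double n_filter_absorbed, double n_window_dismissed,
                         double n_unscattered, double n_scattered) {
  double edep_sum = 0;
  NumericVector edep(t.edep.size());
  for (size_t i = 0; i < t.edep.size(); ++i) {
    edep[i] = t.edep[i];
    edep_sum += t.edep[i];
  }
  edep.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  return List::create(
      _["edep"] = edep, _["n_emitted"] = n_emitted,
      _["n_filter_absorbed"] = n_filter_absorbed,
      _["n_window_dismissed"] = n_window_dismissed,
      _["n_unscattered"] = n_unscattered, _["n_scattered"] = n_scattered,
      _["n_entered"] = t.n_entered, _["n_pe"] = t.n_pe,
      _["n_compton"] = t.n_compton, _["energy_entered"] = t.e_entered,
      _["energy_exited"] = t.e_exited, _["energy_deposited"] = edep_sum);
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector dims, NumericVector vox, NumericVector origin,
                  NumericVector density, IntegerVector material,
                  NumericMatrix att, NumericMatrix pefrac, NumericMatrix spow,
                  NumericMatrix cang, NumericVector ray_ang125, List src,
                  List flt, List lead, List cfg) {
  Grid g = make_grid(dims, vox, origin, density, material);
  Physics ph = make_physics(att, pefrac, spow, cang);
  Config cf{as<double>(cfg["step"]), as<double>(cfg["electron_step"]),
            as<double>(cfg["cutoff"])};
  double n_hist = as<double>(cfg["n_histories"]);
  Rng rng((uint64_t)as<double>(cfg["seed"]));

  double src_r = as<double>(src["radius"]), src_h = as<double>(src["height"]);
  double e0 = as<double>(src["energy"]);
  NumericVector field = src["field"];
  NumericVector radii = flt["radii"];
  double pthick = as<double>(flt["plate_thickness"]);
  double clip = as<double>(flt["clip_halfwidth"]);
  double zmid = as<double>(flt["zmid"]);
  double mu125 = as<double>(lead["mu125"]);
  double wpe = as<double>(lead["wpe"]), wc = as<double>(lead["wc"]),
         wr = as<double>(lead["wr"]);
  NumericVector mu_tot = lead["mu_total"]; // linear, on the 10 keV grid
  const double *ray = ray_ang125.begin();
  int nplates = radii.size();
  std::vector<double> exp_t(nplates + 1);
  for (int c = 0; c <= nplates; ++c) exp_t[c] = std::exp(-mu125 * c * pthick);
  int row125 = ph.erow(e0);
  double wsum = wpe + wc + wr;
  double ztop = g.ztop();
  double xmax = g.ox + g.nx * g.vx, ymax = g.oy + g.ny * g.vy;

  Tally t;
  t.edep.assign((size_t)g.nx * g.ny * g.nz, 0.0);
  double n_filter_absorbed = 0, n_window_dismissed = 0, n_unscattered = 0,
         n_scattered = 0;

  for (double hno = 0; hno < n_hist; ++hno) {
    // emission: uniform on the source disk, aimed uniformly at the field
    double rr = src_r * std::sqrt(rng.u());
    double aa = 2.0 * M_PI * rng.u();
    double x = rr * std::cos(aa), y = rr * std::sin(aa), z = src_h;
    double tx = (rng.u() - 0.5) * field[0], ty = (rng.u() - 0.5) * field[1];
    double dx = tx - x, dy = ty - y, dz = -src_h;
    double nn = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ux = dx / nn, uy = dy / nn, uz = dz / nn;
    double e = e0;
    // filter plane
    double s = (zmid - z) / uz;
    double px = x + s * ux, py = y + s * uy;
    double rad = std::sqrt(px * px + py * py);
    int count = 0;
    if (std::fabs(px) <= clip)
      for (int c = 0; c < nplates; ++c)
        if (rad <= radii[c]) ++count;
    double tpb = count * pthick;
    bool scattered = false;
    if (rng.u() >= exp_t[count]) {
      // one interaction in the lead
      double w = rng.u() * wsum;
      if (w < wpe) { n_filter_absorbed += 1; continue; }
      int slot = (int)std::lround(rng.u() * 1000.0);
      double th, psi = 2.0 * M_PI * rng.u();
      if (w < wpe + wc) {
        th = ph.cang[slot + 1001L * row125];
        e = e0 / (1.0 + e0 / MEC2 * (1.0 - std::cos(th)));
      } else {
        th = ray[slot];
      }
      double nux = ux, nuy = uy, nuz = uz;
      rotate_dir(nux, nuy, nuz, th, psi);
      if (nuz >= 0) { n_filter_absorbed += 1; continue; }
      double depth = -std::log(1.0 - rng.u() * (1.0 - exp_t[count])) / mu125;
      double mue = mu_tot[ph.erow(e)];
      if (rng.u() >= std::exp(-mue * (tpb - depth) / std::fabs(nuz))) {
        n_filter_absorbed += 1;
        continue;
      }
      ux = nux; uy = nuy; uz = nuz;
      scattered = true;
    }
    x = px; y = py; z = zmid;
    // project to the entry window (vacuum)
    double s2 = (ztop - z) / uz;
    double exx = x + s2 * ux, eyy = y + s2 * uy;
    if (s2 < 0 || exx < g.ox || exx >= xmax || eyy < g.oy || eyy >= ymax) {
      n_window_dismissed += 1;
      continue;
    }
    if (scattered) n_scattered += 1; else n_unscattered += 1;
    t.n_entered += 1;
    t.e_entered += e;
    transport_photon(g, ph, cf, t, rng, exx, eyy, ztop, ux, uy, uz, e);
  }
  return tally_result(g, t, n_hist, n_filter_absorbed, n_window_dismissed,
                      n_unscattered, n_scattered);
}

// Transport externally prepared photons already on (or inside) the grid.
// photons: n x 7 matrix [x y z ux uy uz energy].
// [[Rcpp::export]]
List cpp_transport_photons(NumericMatrix photons, IntegerVector dims,
                           NumericVector vox, NumericVector origin,
                           NumericVector density, IntegerVector material,
                           NumericMatrix att, NumericMatrix pefrac,
                           NumericMatrix spow, NumericMatrix cang, List cfg) {
  Grid g = make_grid(dims, vox, origin, density, material);
  Physics ph = make_physics(att, pefrac, spow, cang);
  Config cf{as<double>(cfg["step"]), as<double>(cfg["electron_step"]),
            as<double>(cfg["cutoff"])};
  Rng rng((uint64_t)as<double>(cfg["seed"]));
  Tally t;
  t.edep.assign((size_t)g.nx * g.ny * g.nz, 0.0);
  for (int i = 0; i < photons.nrow(); ++i) {
    t.n_entered += 1;
    t.e_entered += photons(i, 6);
    transport_photon(g, ph, cf, t, rng, photons(i, 0), photons(i, 1),
                     photons(i, 2), photons(i, 3), photons(i, 4),
                     photons(i, 5), photons(i, 6));
  }
  return tally_result(g, t, photons.nrow(), 0, 0, 0, 0);
}

// First-interaction depths of a vertical pencil beam entering at the top
// centre of the grid; NA when the photon crosses the grid without
// interacting. Used to validate the survival-probability stepping against
// the analytic free-path distribution.
// [[Rcpp::export]]
NumericVector cpp_pencil_first_depths(int n, IntegerVector dims,
                                      NumericVector vox, NumericVector origin,
                                      NumericVector density,
                                      IntegerVector material,
                                      NumericMatrix att, double energy,
                                      double h, double seed) {
  Grid g = make_grid(dims, vox, origin, density, material);
  int ne = att.nrow();
  const double *a = att.begin();
  Rng rng((uint64_t)seed);
  int row = (int)std::lround(energy / 0.01) - 1;
  if (row < 0) row = 0;
  if (row >= ne) row = ne - 1;
  double x = g.ox + 0.5 * g.nx * g.vx, y = g.oy + 0.5 * g.ny * g.vy;
  double ztop = g.ztop();
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    double tau_th = -std::log(rng.u());
    double tau = 0.0, z = ztop;
    while (true) {
      double mz = z - 0.5 * h;
      if (mz <= g.oz) break;
      long v = g.voxel(x, y, mz);
      int m = g.mat[v] - 1;
      tau += h * g.rho[v] * a[row + (long)m * ne];
      z -= h;
      if (tau >= tau_th) { out[i] = ztop - z; break; }
    }
  }
  return out;
}
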