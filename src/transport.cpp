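// Photon Monte Carlo engine: heel-weighted collimated point source,
// Woodcock (delta) tracking through z-zoned world (air / compression
// paddle / voxel phantom with TLD-chip and map-layer overrides / support
// table), photoelectric + coherent (Thomson) + incoherent (Klein-Nishina,
// Kahn sampling) interactions in the kerma approximation (transferred
// energy deposited locally, 1 keV cutoff), history-by-history tally
// accumulation for sensitive volumes, a pixelized map layer and the
// per-voxel deposition array.
//
// Geometry units are mm; linear attenuation coefficients are 1/mm on a
// uniform energy grid; energies keV.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double KEV_PER_G_TO_MGY = 1.602176634e-10;

// ---- RNG: xoshiro256+, seeded via splitmix64 (stable across platforms) ----
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// linear interpolation on the uniform energy grid
struct EGrid {
  double e0, de;
  int n;
  inline double frac_idx(double e) const {
    double t = (e - e0) / de;
    if (t < 0) t = 0;
    if (t > n - 1.000001) t = n - 1.000001;
    return t;
  }
};

static inline double interp_row(const NumericMatrix& m, int row, double t) {
  int i = (int)t;
  double f = t - i;
  return m(row, i) * (1.0 - f) + m(row, i + 1) * f;
}

struct World {
  // phantom
  bool has_phantom = false;
  IntegerVector labels;      // flattened [nx*ny*nz], index = i + nx*(j + ny*k)
  int nx = 0, ny = 0, nz = 0;
  double ox = 0, oy = 0, oz = 0, voxel = 1;
  std::vector<int> label2mat;      // label value -> material row
  double ph_zlo = 0, ph_zhi = 0;
  // slabs: paddle / support table
  std::vector<double> slab_zlo, slab_zhi;
  std::vector<int> slab_mat;
  // chips
  int n_chips = 0;
  std::vector<double> cx, cy, cz, hx, hy, hz;
  int chip_mat = -1;
  double chips_zlo = 1e30, chips_zhi = -1e30;
  // map layer (material override + pixel tally)
  bool has_map = false;
  double map_zlo = 0, map_zhi = 0, map_xlo = 0, map_ylo = 0, map_pitch = 1;
  int map_nx = 0, map_ny = 0, map_mat = -1;
  // world bounds
  double xw = 0, ylo_w = 0, yhi_w = 0, zlo_w = 0, zhi_w = 0;
  int air_mat = 0;

  // returns material row; sets chip index, voxel index, map pixel (-1 if none)
  inline int material_at(double x, double y, double z,
                         int& chip, long& vox, long& pix) const {
    chip = -1; vox = -1; pix = -1;
    if (z >= chips_zlo && z <= chips_zhi) {
      for (int i = 0; i < n_chips; ++i) {
        if (std::fabs(z - cz[i]) <= hz[i] && std::fabs(x - cx[i]) <= hx[i] &&
            std::fabs(y - cy[i]) <= hy[i]) {
          chip = i;
          return chip_mat;
        }
      }
    }
    if (has_map && z >= map_zlo && z <= map_zhi) {
      int ix = (int)std::floor((x - map_xlo) / map_pitch);
      int iy = (int)std::floor((y - map_ylo) / map_pitch);
      if (ix >= 0 && ix < map_nx && iy >= 0 && iy < map_ny) {
        pix = (long)ix + (long)map_nx * iy;
        return map_mat;
      }
    }
    if (has_phantom && z >= ph_zlo && z < ph_zhi) {
      int i = (int)std::floor((x - ox) / voxel);
      int j = (int)std::floor((y - oy) / voxel);
      int k = (int)std::floor((z - oz) / voxel);
      if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz) {
        long idx = (long)i + (long)nx * ((long)j + (long)ny * k);
        vox = idx;
        return label2mat[labels[idx]];
      }
    }
    for (size_t s = 0; s < slab_mat.size(); ++s) {
      if (z >= slab_zlo[s] && z < slab_zhi[s]) return slab_mat[s];
    }
    return air_mat;
  }
};

struct Source {
  double sx, sy, sz;            // source position
  double zdet;                  // detector plane
  double fx_lo, fx_hi, fy_lo, fy_hi;  // field at detector plane
  double ay, by, cy_, ax, bx, cx_;    // heel polynomials (d in cm)
  double wmax;
  NumericVector e_centers;
  NumericVector e_cdf;
  double bin_half;

  inline double heel(double x, double y) const {
    double dy = y / 10.0, dx = std::fabs(x) / 10.0;
    double hy = ay + by * dy * dy + cy_ * dy * dy * dy * dy;
    double hx = ax + bx * dx * dx + cx_ * dx * dx * dx * dx;
    return hy * hx;
  }
  // heel * cos^3(theta) for a detector-plane point (solid-angle factor)
  inline double weight(double x, double y) const {
    double dx = x - sx, dy = y - sy, dz = zdet - sz;
    double r2 = dx * dx + dy * dy + dz * dz;
    double c = std::fabs(dz) / std::sqrt(r2);
    return heel(x, y) * c * c * c;
  }
  void find_wmax() {
    wmax = 0;
    for (int i = 0; i <= 60; ++i) {
      for (int j = 0; j <= 60; ++j) {
        double x = fx_lo + (fx_hi - fx_lo) * i / 60.0;
        double y = fy_lo + (fy_hi - fy_lo) * j / 60.0;
        double w = weight(x, y);
        if (w > wmax) wmax = w;
      }
    }
    wmax *= 1.0001;
  }
  // sample detector intercept + direction + energy
  inline void sample(Rng& rng, double& x, double& y, double& ux, double& uy,
                     double& uz, double& e) const {
    if (fx_hi - fx_lo < 1e-12 && fy_hi - fy_lo < 1e-12) {
      x = fx_lo; y = fy_lo;
    } else {
      for (;;) {
        x = fx_lo + (fx_hi - fx_lo) * rng.u01();
        y = fy_lo + (fy_hi - fy_lo) * rng.u01();
        if (rng.u01() * wmax <= weight(x, y)) break;
      }
    }
    double dx = x - sx, dy = y - sy, dz = zdet - sz;
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    ux = dx / r; uy = dy / r; uz = dz / r;
    // energy: inverse CDF over bins + uniform jitter inside the bin
    double u = rng.u01();
    int lo = 0, hi = e_cdf.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (e_cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    e = e_centers[lo];
    if (bin_half > 0) e += (2.0 * rng.u01() - 1.0) * bin_half;
  }
};

// rotate direction by polar angle with cos = c and uniform azimuth
static inline void rotate_dir(Rng& rng, double c, double& ux, double& uy,
                              double& uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = 6.283185307179586 * rng.u01();
  double cp = std::cos(phi), sp = std::sin(phi);
  double uz2 = uz * uz;
  if (uz2 < 0.999999) {
    double den = std::sqrt(1.0 - uz2);
    double nx = ux * c + st * (ux * uz * cp - uy * sp) / den;
    double ny = uy * c + st * (uy * uz * cp + ux * sp) / den;
    double nz = uz * c - st * den * cp;
    ux = nx; uy = ny; uz = nz;
  } else {
    double sgn = uz > 0 ? 1.0 : -1.0;
    ux = st * cp; uy = sgn * st * sp; uz = sgn * c;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// Kahn's rejection sampling of the Klein-Nishina distribution.
// k = E/mec2; returns x = E/E'; cosine via 1 - (x-1)/k.
static inline double kahn_sample(Rng& rng, double k) {
  for (;;) {
    double r1 = rng.u01(), r2 = rng.u01(), r3 = rng.u01();
    if (r1 * (9.0 + 2.0 * k) <= (1.0 + 2.0 * k)) {
      double x = 1.0 + 2.0 * k * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = (1.0 + 2.0 * k) / (1.0 + 2.0 * k * r2);
      double c = 1.0 - (x - 1.0) / k;
      if (r3 <= 0.5 * (c * c + 1.0 / x)) return x;
    }
  }
}

static World build_world(List w) {
  World world;
  world.air_mat = as<int>(w["air_mat"]);
  if (w.containsElementNamed("phantom") && !Rf_isNull(w["phantom"])) {
    List ph = w["phantom"];
    world.has_phantom = true;
    world.labels = ph["labels"];
    IntegerVector dims = ph["dims"];
    world.nx = dims[0]; world.ny = dims[1]; world.nz = dims[2];
    NumericVector org = ph["origin"];
    world.ox = org[0]; world.oy = org[1]; world.oz = org[2];
    world.voxel = as<double>(ph["voxel_mm"]);
    IntegerVector l2m = ph["label2mat"];
    world.label2mat.assign(l2m.begin(), l2m.end());
    world.ph_zlo = world.oz;
    world.ph_zhi = world.oz + world.nz * world.voxel;
  }
  if (w.containsElementNamed("slabs") && !Rf_isNull(w["slabs"])) {
    NumericMatrix sl = w["slabs"];
    for (int i = 0; i < sl.nrow(); ++i) {
      world.slab_zlo.push_back(sl(i, 0));
      world.slab_zhi.push_back(sl(i, 1));
      world.slab_mat.push_back((int)sl(i, 2));
    }
  }
  if (w.containsElementNamed("chips") && !Rf_isNull(w["chips"])) {
    List ch = w["chips"];
    NumericMatrix cm = ch["centers"];   // n x 3
    NumericMatrix hm = ch["half_dims"]; // n x 3
    world.n_chips = cm.nrow();
    world.chip_mat = as<int>(ch["mat"]);
    for (int i = 0; i < world.n_chips; ++i) {
      world.cx.push_back(cm(i, 0)); world.cy.push_back(cm(i, 1));
      world.cz.push_back(cm(i, 2));
      world.hx.push_back(hm(i, 0)); world.hy.push_back(hm(i, 1));
      world.hz.push_back(hm(i, 2));
      world.chips_zlo = std::min(world.chips_zlo, cm(i, 2) - hm(i, 2));
      world.chips_zhi = std::max(world.chips_zhi, cm(i, 2) + hm(i, 2));
    }
  }
  if (w.containsElementNamed("map") && !Rf_isNull(w["map"])) {
    List mp = w["map"];
    world.has_map = true;
    world.map_zlo = as<double>(mp["z_lo"]);
    world.map_zhi = as<double>(mp["z_hi"]);
    world.map_xlo = as<double>(mp["x_lo"]);
    world.map_ylo = as<double>(mp["y_lo"]);
    world.map_pitch = as<double>(mp["pitch_mm"]);
    world.map_nx = as<int>(mp["nx"]);
    world.map_ny = as<int>(mp["ny"]);
    world.map_mat = as<int>(mp["mat"]);
  }
  NumericVector b = w["bounds"];  // xw, ylo, yhi, zlo, zhi
  world.xw = b[0]; world.ylo_w = b[1]; world.yhi_w = b[2];
  world.zlo_w = b[3]; world.zhi_w = b[4];
  return world;
}

static Source build_source(List s) {
  Source src;
  NumericVector sp = s["source_pos"];
  src.sx = sp[0]; src.sy = sp[1]; src.sz = sp[2];
  src.zdet = as<double>(s["z_det"]);
  NumericVector f = s["field"];  // fx_lo, fx_hi, fy_lo, fy_hi
  src.fx_lo = f[0]; src.fx_hi = f[1]; src.fy_lo = f[2]; src.fy_hi = f[3];
  NumericVector h = s["heel"];   // ay by cy ax bx cx
  src.ay = h[0]; src.by = h[1]; src.cy_ = h[2];
  src.ax = h[3]; src.bx = h[4]; src.cx_ = h[5];
  src.e_centers = s["e_centers"];
  src.e_cdf = s["e_cdf"];
  src.bin_half = as<double>(s["bin_half"]);
  src.find_wmax();
  return src;
}

// [[Rcpp::export]]
List cpp_sample_primary(List source, int n, double seed) {
  Source src = build_source(source);
  Rng rng((uint64_t)seed);
  NumericVector x(n), y(n), e(n);
  for (int i = 0; i < n; ++i) {
    double ux, uy, uz;
    src.sample(rng, x[i], y[i], ux, uy, uz, e[i]);
  }
  return List::create(_["x_mm"] = x, _["y_mm"] = y, _["energy_keV"] = e);
}

// [[Rcpp::export]]
List cpp_run_mc(List world_spec, List source_spec, List xsec, List physics,
                double n_hist, double seed, bool voxel_tally) {
  World world = build_world(world_spec);
  Source src = build_source(source_spec);

  EGrid eg;
  eg.e0 = as<double>(xsec["e0"]);
  eg.de = as<double>(xsec["de"]);
  eg.n = as<int>(xsec["n"]);
  NumericMatrix mu = xsec["mu"];          // n_mat x nE, 1/mm
  NumericMatrix p_pe = xsec["p_pe"];      // P(photoelectric)
  NumericMatrix p_pecoh = xsec["p_pecoh"];// P(pe) + P(coherent)
  NumericVector zone_lo = xsec["zone_lo"];
  NumericVector zone_hi = xsec["zone_hi"];
  NumericMatrix zone_maj = xsec["zone_maj"];  // n_zone x nE, 1/mm
  int n_zone = zone_lo.size();

  // channel enabling/disabling is handled upstream in the cross-section
  // preparation (disabled channels have zero cross section)
  double cutoff = as<double>(physics["cutoff_keV"]);

  Rng rng((uint64_t)seed);

  int nc = world.n_chips;
  std::vector<double> chip_sum(nc, 0.0), chip_sum2(nc, 0.0);
  std::vector<double> chip_hist(nc, 0.0);
  std::vector<int> chip_touched; chip_touched.reserve(16);

  long n_pix = world.has_map ? (long)world.map_nx * world.map_ny : 0;
  std::vector<double> map_sum(n_pix, 0.0), map_sum2(n_pix, 0.0);
  std::vector<double> map_hist(n_pix, 0.0);
  std::vector<long> map_touched; map_touched.reserve(32);

  long n_vox = (world.has_phantom && voxel_tally)
                   ? (long)world.nx * world.ny * world.nz : 0;
  std::vector<double> vox_e(n_vox, 0.0);

  double emitted = 0.0, deposited = 0.0, escaped = 0.0;
  double etot_sum = 0.0, etot_sum2 = 0.0;   // per-history deposited energy

  const long N = (long)n_hist;
  for (long h = 0; h < N; ++h) {
    double x, y, ux, uy, uz, e;
    src.sample(rng, x, y, ux, uy, uz, e);
    double px = src.sx, py = src.sy, pz = src.sz;
    emitted += e;
    double hist_dep = 0.0;

    bool alive = true;
    while (alive) {
      // zone of current position
      int zi = -1;
      for (int zz = 0; zz < n_zone; ++zz) {
        if (pz >= zone_lo[zz] && pz < zone_hi[zz]) { zi = zz; break; }
      }
      if (zi < 0) { escaped += e; break; }
      double t = eg.frac_idx(e);
      double maj = interp_row(zone_maj, zi, t);
      double s = -std::log(rng.u01()) / maj;
      // distance to zone boundary along z
      double tb = 1e30;
      if (uz > 1e-12) tb = (zone_hi[zi] - pz) / uz;
      else if (uz < -1e-12) tb = (zone_lo[zi] - pz) / uz;
      if (s >= tb) {
        px += ux * (tb + 1e-6); py += uy * (tb + 1e-6); pz += uz * (tb + 1e-6);
        if (pz <= world.zlo_w || pz >= world.zhi_w || std::fabs(px) > world.xw ||
            py < world.ylo_w || py > world.yhi_w) {
          escaped += e;
          break;
        }
        continue;
      }
      px += ux * s; py += uy * s; pz += uz * s;
      if (std::fabs(px) > world.xw || py < world.ylo_w || py > world.yhi_w) {
        escaped += e;
        break;
      }
      int chip; long vox, pix;
      int mat = world.material_at(px, py, pz, chip, vox, pix);
      double mu_tot = interp_row(mu, mat, t);
      if (rng.u01() * maj > mu_tot) continue;  // fictitious interaction

      double ppe = interp_row(p_pe, mat, t);
      double ppc = interp_row(p_pecoh, mat, t);
      double xi = rng.u01();
      double dep = 0.0;
      if (xi < ppe) {
        // photoelectric: full local absorption
        dep = e;
        alive = false;
      } else if (xi < ppc) {
        // coherent: Thomson angular law, no energy loss
        double c;
        do { c = 2.0 * rng.u01() - 1.0; } while (rng.u01() > 0.5 * (1.0 + c * c));
        rotate_dir(rng, c, ux, uy, uz);
      } else {
        // incoherent: Klein-Nishina free electron
        double k = e / 510.99895;
        double xr = kahn_sample(rng, k);
        double c = 1.0 - (xr - 1.0) / k;
        double e_new = e / xr;
        dep = e - e_new;
        e = e_new;
        rotate_dir(rng, c, ux, uy, uz);
        if (e < cutoff) { dep += e; alive = false; }
      }
      if (dep > 0.0) {
        deposited += dep;
        hist_dep += dep;
        if (chip >= 0) {
          if (chip_hist[chip] == 0.0) chip_touched.push_back(chip);
          chip_hist[chip] += dep;
        }
        if (pix >= 0) {
          if (map_hist[pix] == 0.0) map_touched.push_back(pix);
          map_hist[pix] += dep;
        }
        if (vox >= 0 && n_vox > 0) vox_e[vox] += dep;
      }
    }
    // flush history-by-history accumulators
    for (size_t i = 0; i < chip_touched.size(); ++i) {
      int c = chip_touched[i];
      chip_sum[c] += chip_hist[c];
      chip_sum2[c] += chip_hist[c] * chip_hist[c];
      chip_hist[c] = 0.0;
    }
    chip_touched.clear();
    for (size_t i = 0; i < map_touched.size(); ++i) {
      long p = map_touched[i];
      map_sum[p] += map_hist[p];
      map_sum2[p] += map_hist[p] * map_hist[p];
      map_hist[p] = 0.0;
    }
    map_touched.clear();
    etot_sum += hist_dep;
    etot_sum2 += hist_dep * hist_dep;
    if ((h & 0xfffff) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["emitted_keV"] = emitted, _["deposited_keV"] = deposited,
      _["escaped_keV"] = escaped, _["etot_sum"] = etot_sum,
      _["etot_sum2"] = etot_sum2, _["n"] = (double)N);
  if (nc > 0) {
    out["chip_sum_keV"] = NumericVector(chip_sum.begin(), chip_sum.end());
    out["chip_sum2_keV2"] = NumericVector(chip_sum2.begin(), chip_sum2.end());
  }
  if (n_pix > 0) {
    out["map_sum_keV"] = NumericVector(map_sum.begin(), map_sum.end());
    out["map_sum2_keV2"] = NumericVector(map_sum2.begin(), map_sum2.end());
  }
  if (n_vox > 0) {
    out["voxel_keV"] = NumericVector(vox_e.begin(), vox_e.end());
  }
  return out;
}
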