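// Packet-based Monte Carlo photon transport in a layered slab head model.
//
// Geometry: z = 0 is the outer scalp surface, +z points into the head.
// Layers are planar slabs with continuous (non-voxelised) z boundaries;
// the voxel grid is used only for the fluence tally (path length x weight,
// the standard CW estimator). Lateral and bottom domain exits are treated
// as escape; only the top tissue->void surface applies Fresnel reflection.
//
// Reproducibility: each photon gets its own counter-seeded xoshiro256++
// substream derived from the root seed, so results are independent of
// batching or evaluation order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  // per-photon substream: mix root seed and photon index through splitmix64
  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t st = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(st);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
  // uniform on (0, 1]: safe under log()
  inline double u01_open() { return 1.0 - u01(); }
};

struct Tally {
  std::vector<double> flu;
  int nx, ny, nz;
  double vox;
  Tally(int nx_, int ny_, int nz_, double vox_)
    : flu((size_t)nx_ * ny_ * nz_, 0.0), nx(nx_), ny(ny_), nz(nz_), vox(vox_) {}
  inline size_t idx(int ix, int iy, int iz) const {
    return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  // accumulate weight x path length per voxel along a straight segment
  void deposit(double x, double y, double z,
               double ux, double uy, double uz,
               double length, double w) {
    if (length <= 0.0 || w <= 0.0) return;
    // coordinates are non-negative inside the domain: integer truncation
    // is floor, avoiding libm floor() on baseline x86-64
    const double inv_vox = 1.0 / vox;
    int ix = clampi((int)(x * inv_vox), nx);
    int iy = clampi((int)(y * inv_vox), ny);
    int iz = clampi((int)(z * inv_vox), nz);
    // fast path: most steps in strongly scattering layers stay inside one voxel
    {
      double xe = x + ux * length, ye = y + uy * length, ze = z + uz * length;
      if ((int)(xe * inv_vox) == ix &&
          (int)(ye * inv_vox) == iy &&
          (int)(ze * inv_vox) == iz) {
        flu[idx(ix, iy, iz)] += w * length;
        return;
      }
    }
    const double INF = std::numeric_limits<double>::infinity();
    int stepx = ux > 0 ? 1 : -1, stepy = uy > 0 ? 1 : -1, stepz = uz > 0 ? 1 : -1;
    double tdx = ux != 0 ? vox / std::fabs(ux) : INF;
    double tdy = uy != 0 ? vox / std::fabs(uy) : INF;
    double tdz = uz != 0 ? vox / std::fabs(uz) : INF;
    double tmx = ux > 0 ? ((ix + 1) * vox - x) / ux
               : (ux < 0 ? (ix * vox - x) / ux : INF);
    double tmy = uy > 0 ? ((iy + 1) * vox - y) / uy
               : (uy < 0 ? (iy * vox - y) / uy : INF);
    double tmz = uz > 0 ? ((iz + 1) * vox - z) / uz
               : (uz < 0 ? (iz * vox - z) / uz : INF);
    double t = 0.0;
    while (true) {
      double tnext = std::min(std::min(tmx, tmy), tmz);
      if (tnext > length) tnext = length;
      flu[idx(ix, iy, iz)] += w * (tnext - t);
      t = tnext;
      if (t >= length) break;
      if (tmx <= tmy && tmx <= tmz) {
        ix += stepx; tmx += tdx;
        if (ix < 0 || ix >= nx) break;
      } else if (tmy <= tmz) {
        iy += stepy; tmy += tdy;
        if (iy < 0 || iy >= ny) break;
      } else {
        iz += stepz; tmz += tdz;
        if (iz < 0 || iz >= nz) break;
      }
    }
  }
};

// unpolarized Fresnel power reflectance; returns 1.0 under TIR
inline double fresnelR(double n1, double n2, double ci, double &ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  double si2 = 1.0 - ci * ci;
  double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) { ct = 0.0; return 1.0; }
  ct = std::sqrt(1.0 - st2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  return ct > 1.0 ? 1.0 : (ct < -1.0 ? -1.0 : ct);
}

// uniform azimuth (cos, sin) without trig: rejection from the unit disk
inline void rand_azimuth(Xoshiro &rng, double &cp, double &sp) {
  double ax, ay, r2;
  do {
    ax = 2.0 * rng.u01() - 1.0;
    ay = 2.0 * rng.u01() - 1.0;
    r2 = ax * ax + ay * ay;
  } while (r2 > 1.0 || r2 < 1e-12);
  double inv = 1.0 / std::sqrt(r2);
  cp = ax * inv; sp = ay * inv;
}

// MCML-style direction update after scattering by (ct, azimuth (cp, sp)).
// The update maps a unit vector to a unit vector exactly, so no
// renormalisation is needed; rounding drift over O(10^3) steps is ~1e-13.
inline void spin(double &ux, double &uy, double &uz, double ct,
                 double cp, double sp) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(uz) > 0.999999) {
    ux = st * cp; uy = st * sp; uz = uz > 0 ? ct : -ct;
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double st_den = st / den;
    double uxx = (ux * uz * cp - uy * sp) * st_den + ux * ct;
    double uyy = (uy * uz * cp + ux * sp) * st_den + uy * ct;
    double uzz = -den * st * cp + uz * ct;
    ux = uxx; uy = uyy; uz = uzz;
  }
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericVector z_upper,   // upper z boundary of each layer, mm
                NumericVector mu_a, NumericVector mu_s,
                NumericVector g, NumericVector n_idx,
                double n_void,
                IntegerVector domain_shape, double voxel_size,
                double src_x, double src_y, double half_angle_deg,
                double det_x, double det_y, double det_radius,
                double n_photons, double seed,
                double roulette_threshold, double roulette_survival,
                int entry_refraction) {
  const int K = z_upper.size();
  if (K < 1 || mu_a.size() != K || mu_s.size() != K ||
      g.size() != K || n_idx.size() != K)
    stop("layer property vectors must have one entry per layer");
  const int nx = domain_shape[0], ny = domain_shape[1], nz = domain_shape[2];
  const double X = nx * voxel_size, Y = ny * voxel_size;
  const double cos_max = std::cos(half_angle_deg * M_PI / 180.0);
  const double r2det = det_radius * det_radius;
  const long long N = (long long)n_photons;
  const uint64_t root = (uint64_t)seed;
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> z_lo(K), z_hi(K), ma(K), ms(K), gg(K), nn(K),
      mt(K), inv_mt(K), albedo(K), frac_a(K);
  for (int l = 0; l < K; ++l) {
    z_lo[l] = l == 0 ? 0.0 : z_upper[l - 1];
    z_hi[l] = z_upper[l];
    ma[l] = mu_a[l]; ms[l] = mu_s[l]; gg[l] = g[l]; nn[l] = n_idx[l];
    mt[l] = ma[l] + ms[l];
    inv_mt[l] = mt[l] > 0.0 ? 1.0 / mt[l] : 0.0;
    albedo[l] = mt[l] > 0.0 ? ms[l] / mt[l] : 1.0;
    frac_a[l] = mt[l] > 0.0 ? ma[l] / mt[l] : 0.0;
  }

  Tally tally(nx, ny, nz, voxel_size);
  double absorbed = 0.0, escaped = 0.0, detected = 0.0, residual = 0.0;
  long long n_events = 0, n_bounds = 0;
  std::vector<double> dw, dpath, dx_rec, dy_rec;

  for (long long i = 0; i < N; ++i) {
    Xoshiro rng(root, (uint64_t)i);
    // launch: cone about +z, at z = 0 on the surface
    double cz = 1.0 - rng.u01() * (1.0 - cos_max);
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double phi0 = 2.0 * M_PI * rng.u01();
    double ux = sz * std::cos(phi0), uy = sz * std::sin(phi0), uz = cz;
    double x = src_x, y = src_y, z = 0.0;
    double w = 1.0, path = 0.0;
    int layer = 0;
    bool alive = true;
    if (entry_refraction) {
      // the cone is emitted in the void above the scalp: refract through the
      // void->scalp interface; specular reflections never enter the tissue
      double ct;
      double R = fresnelR(n_void, nn[0], uz, ct);
      if (rng.u01() < R) {
        escaped += w;
        alive = false;
      } else {
        double ratio = n_void / nn[0];
        ux *= ratio; uy *= ratio; uz = ct;
      }
    }

    while (alive) {
      // interaction distance; straight-line transport in zero-mu_t media
      double s = mt[layer] > 0.0 ? -std::log(rng.u01_open()) * inv_mt[layer]
                                 : INF;
      // distance to the slab interface along z
      double db = INF;
      int zdir = 0; // +1 deeper, -1 shallower
      if (uz > 0.0)      { db = (z_hi[layer] - z) / uz; zdir = 1; }
      else if (uz < 0.0) { db = (z - z_lo[layer]) / (-uz); zdir = -1; }
      // distance to lateral walls (domain truncation)
      double dwall = INF;
      if (ux > 0.0) dwall = std::min(dwall, (X - x) / ux);
      else if (ux < 0.0) dwall = std::min(dwall, x / (-ux));
      if (uy > 0.0) dwall = std::min(dwall, (Y - y) / uy);
      else if (uy < 0.0) dwall = std::min(dwall, y / (-uy));

      double hit = std::min(s, std::min(db, dwall));
      if (!std::isfinite(hit))
        stop("internal error: non-finite step (photon %lld)", i);
      tally.deposit(x, y, z, ux, uy, uz, hit, w);
      path += hit;
      x += ux * hit; y += uy * hit; z += uz * hit;

      if (hit == dwall && dwall < s && dwall < db) {
        escaped += w;
        alive = false;
      } else if (hit == s && s <= db) {
        // interaction: deposit the absorbed fraction, scatter the rest
        ++n_events;
        absorbed += w * frac_a[layer];
        w *= albedo[layer];
        if (w <= 0.0) { alive = false; continue; }
        double ct = hg_cos(gg[layer], rng.u01());
        double cp, sp;
        rand_azimuth(rng, cp, sp);
        spin(ux, uy, uz, ct, cp, sp);
        if (w < roulette_threshold) {
          if (rng.u01() < roulette_survival) {
            residual += w * (1.0 / roulette_survival - 1.0);
            w /= roulette_survival;
          } else {
            residual -= w;
            alive = false;
          }
        }
      } else {
        // slab interface (or top/bottom domain face)
        ++n_bounds;
        if (zdir > 0) {
          z = z_hi[layer]; // snap to the boundary to avoid fp drift
          if (layer == K - 1) { escaped += w; alive = false; continue; }
          double ct;
          double R = fresnelR(nn[layer], nn[layer + 1], uz, ct);
          if (rng.u01() < R) {
            uz = -uz;
          } else {
            double ratio = nn[layer] / nn[layer + 1];
            ux *= ratio; uy *= ratio; uz = ct;
            ++layer;
          }
        } else {
          z = z_lo[layer];
          double n2 = layer == 0 ? n_void : nn[layer - 1];
          double ct;
          double R = fresnelR(nn[layer], n2, -uz, ct);
          if (rng.u01() < R) {
            uz = -uz;
          } else if (layer == 0) {
            // transmitted through the top surface into the void
            escaped += w;
            double ddx = x - det_x, ddy = y - det_y;
            if (ddx * ddx + ddy * ddy <= r2det) {
              detected += w;
              dw.push_back(w); dpath.push_back(path);
              dx_rec.push_back(x); dy_rec.push_back(y);
            }
            alive = false;
          } else {
            double ratio = nn[layer] / n2;
            ux *= ratio; uy *= ratio; uz = -ct;
            --layer;
          }
        }
      }
      if (alive && !(std::isfinite(x) && std::isfinite(y) && std::isfinite(z) &&
                     std::isfinite(ux) && std::isfinite(uy) && std::isfinite(uz)))
        stop("internal error: non-finite photon state (photon %lld)", i);
    }
  }

  NumericVector flu(tally.flu.begin(), tally.flu.end());
  flu.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(
    _["fluence"] = flu,
    _["det_weight"] = NumericVector(dw.begin(), dw.end()),
    _["det_path"] = NumericVector(dpath.begin(), dpath.end()),
    _["det_x"] = NumericVector(dx_rec.begin(), dx_rec.end()),
    _["det_y"] = NumericVector(dy_rec.begin(), dy_rec.end()),
    _["launched"] = (double)N,
    _["absorbed"] = absorbed,
    _["escaped"] = escaped,
    _["detected"] = detected,
    _["roulette_residual"] = residual,
    _["n_events"] = (double)n_events,
    _["n_boundary_hits"] = (double)n_bounds);
}
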