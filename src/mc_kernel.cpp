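// Photon transport in a slab phantom with one embedded cylindrical vessel.
//
// Hop-drop-spin with photon weight, Henyey-Greenstein scattering, partial
// (deterministic) weight splitting at the top/bottom Fresnel boundaries and
// Russian roulette termination. Geometry: slab occupies 0 <= z <= L,
// |x|, |y| <= half_extent; the vessel is an infinite cylinder along y with
// axis at (x = 0, z = d). Units are mm throughout.
//
// The kernel uses its own xoshiro256++ generator so that a given seed yields
// bit-identical tallies on every platform, independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ------------------------------------------------------------- physics ----

// Unpolarized Fresnel reflectance for incidence cosine ci in [0,1].
static double fresnel(double ni, double nt, double ci) {
  if (ci > 1.0) ci = 1.0;
  if (ni == nt) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = (ni / nt) * (ni / nt) * si2;
  if (st2 >= 1.0) return 1.0;              // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein cosine sample.
static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double ni, double nt, double ci) {
  return fresnel(ni, nt, ci);
}

// [[Rcpp::export(name = ".hg_sample_cpp")]]
NumericVector hg_sample_cpp(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// ------------------------------------------------------------ geometry ----

struct Photon {
  double x, y, z;
  double ux, uy, uz;
  double w;
  int region;                              // 0 = background, 1 = vessel
};

// Distance along the ray to the vessel wall; R_HUGE if no hit.
static const double R_HUGE = 1e30;

static double dist_to_cylinder(const Photon &p, double zd, double rv,
                               bool inside) {
  double qx = p.x, qz = p.z - zd;
  double vx = p.ux, vz = p.uz;
  double a = vx * vx + vz * vz;
  if (a < 1e-20) return R_HUGE;            // travelling parallel to axis
  double b = qx * vx + qz * vz;
  double c = qx * qx + qz * qz - rv * rv;
  double disc = b * b - a * c;
  if (disc <= 0.0) return R_HUGE;
  double sq = std::sqrt(disc);
  if (inside) {
    double t = (-b + sq) / a;
    return (t > 0.0) ? t : R_HUGE;
  }
  double t1 = (-b - sq) / a;
  if (t1 > 1e-12) return t1;
  double t2 = (-b + sq) / a;
  // grazing: if we are (numerically) on the wall heading in, take far root
  if (t2 > 1e-12 && c < 0.0) return t2;
  return R_HUGE;
}

static inline bool in_vessel(double x, double z, double zd, double rv) {
  double qx = x, qz = z - zd;
  return qx * qx + qz * qz < rv * rv;
}

// ------------------------------------------------------------- kernel -----

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(double thickness, double half_extent,
                      double n_above, double n_slab, double n_below,
                      bool has_vessel, double vessel_radius,
                      double vessel_depth, double n_vessel,
                      bool vessel_fresnel,
                      double mua_bg, double mus_bg, double g_bg,
                      double mua_v, double mus_v, double g_v,
                      double spot_radius,
                      int n_photons, double seed,
                      double roulette_threshold, double roulette_survival,
                      bool tally_fluence, double voxel_mm) {
  Xoshiro256pp rng(static_cast<uint64_t>(seed));

  double r_spec = 0.0, r_diff = 0.0, t_tot = 0.0;
  double abs_bg = 0.0, abs_v = 0.0, e_side = 0.0, lost = 0.0, boost = 0.0;
  double sumR = 0.0, sumR2 = 0.0, sumT = 0.0, sumT2 = 0.0;

  int nx = 0, nz = 0;
  std::vector<double> grid;
  if (tally_fluence) {
    nx = std::max(1, (int)std::ceil(2.0 * half_extent / voxel_mm));
    nz = std::max(1, (int)std::ceil(thickness / voxel_mm));
    grid.assign((size_t)nx * nz, 0.0);
  }

  const double mut_bg = mua_bg + mus_bg;
  const double mut_v = mua_v + mus_v;
  const double rs0 = fresnel(n_above, n_slab, 1.0);
  const double EPS = 1e-9;

  for (int ip = 0; ip < n_photons; ++ip) {
    // flat-top circular beam, normal incidence
    double rr = spot_radius * std::sqrt(rng.unif());
    double th = 2.0 * M_PI * rng.unif();
    Photon p;
    p.x = rr * std::cos(th); p.y = rr * std::sin(th); p.z = 0.0;
    p.ux = 0.0; p.uy = 0.0; p.uz = 1.0;
    r_spec += rs0;
    p.w = 1.0 - rs0;
    p.region = 0;
    double cR = 0.0, cT = 0.0;           // this photon's escape contributions

    bool alive = p.w > 0.0;
    while (alive) {
      double sleft = -std::log(1.0 - rng.unif());
      // hop (possibly across region boundaries)
      for (;;) {
        double mut = (p.region == 1) ? mut_v : mut_bg;
        double s = (mut > 0.0) ? sleft / mut : R_HUGE;

        // candidate boundary distances
        double db = R_HUGE; int btype = 0; // 1 top, 2 bottom, 3 side, 4 wall
        if (p.uz < 0.0) { double t = -p.z / p.uz; if (t < db) { db = t; btype = 1; } }
        else if (p.uz > 0.0) { double t = (thickness - p.z) / p.uz; if (t < db) { db = t; btype = 2; } }
        if (p.ux > 0.0) { double t = (half_extent - p.x) / p.ux; if (t < db) { db = t; btype = 3; } }
        else if (p.ux < 0.0) { double t = (-half_extent - p.x) / p.ux; if (t < db) { db = t; btype = 3; } }
        if (p.uy > 0.0) { double t = (half_extent - p.y) / p.uy; if (t < db) { db = t; btype = 3; } }
        else if (p.uy < 0.0) { double t = (-half_extent - p.y) / p.uy; if (t < db) { db = t; btype = 3; } }
        if (has_vessel) {
          bool inside = (p.region == 1);
          // cheap prefilter: can this segment reach the cylinder at all?
          double reach = std::min(s, db) + vessel_radius;
          double qx = p.x, qz = p.z - vessel_depth;
          if (inside || qx * qx + qz * qz <= reach * reach) {
            double t = dist_to_cylinder(p, vessel_depth, vessel_radius, inside);
            if (t < db) { db = t; btype = 4; }
          }
        }

        if (s < db) {                      // interaction inside current region
          p.x += s * p.ux; p.y += s * p.uy; p.z += s * p.uz;
          break;
        }
        // move to boundary
        p.x += db * p.ux; p.y += db * p.uy; p.z += db * p.uz;
        sleft -= db * mut;
        if (sleft < 0.0) sleft = 0.0;

        if (btype == 1 || btype == 2) {    // top or bottom surface
          double nout = (btype == 1) ? n_above : n_below;
          double ci = std::fabs(p.uz);
          double rf = fresnel(n_slab, nout, ci);
          double esc = p.w * (1.0 - rf);
          if (btype == 1) { r_diff += esc; cR += esc; }
          else            { t_tot  += esc; cT += esc; }
          p.w *= rf;
          p.uz = -p.uz;
          p.z = (btype == 1) ? 0.0 : thickness;
          if (p.w <= 0.0) { alive = false; break; }
        } else if (btype == 3) {           // lateral escape
          e_side += p.w;
          p.w = 0.0; alive = false; break;
        } else {                           // vessel wall
          if (vessel_fresnel) {
            // probabilistic specular event at the wall
            double nxw = p.x / vessel_radius;
            double nzw = (p.z - vessel_depth) / vessel_radius;
            double ci = std::fabs(p.ux * nxw + p.uz * nzw);
            double ni = (p.region == 1) ? n_vessel : n_slab;
            double nt = (p.region == 1) ? n_slab : n_vessel;
            double rf = fresnel(ni, nt, ci);
            if (rng.unif() < rf) {
              double dot = p.ux * nxw + p.uz * nzw;
              p.ux -= 2.0 * dot * nxw;
              p.uz -= 2.0 * dot * nzw;
              p.x += EPS * p.ux; p.z += EPS * p.uz;
              continue;
            }
          }
          // cross the wall: nudge through and relabel
          p.x += EPS * p.ux; p.y += EPS * p.uy; p.z += EPS * p.uz;
          p.region = in_vessel(p.x, p.z, vessel_depth, vessel_radius) ? 1 : 0;
        }
      }
      if (!alive) break;

      // drop
      double mua = (p.region == 1) ? mua_v : mua_bg;
      double mus = (p.region == 1) ? mus_v : mus_bg;
      double mut = mua + mus;
      if (mut <= 0.0) { // vacuum region cannot interact; should not happen
        alive = false; lost += p.w; p.w = 0.0; break;
      }
      double dw = p.w * mua / mut;
      if (p.region == 1) abs_v += dw; else abs_bg += dw;
      if (tally_fluence && dw > 0.0) {
        int ix = (int)((p.x + half_extent) / voxel_mm);
        int iz = (int)(p.z / voxel_mm);
        if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
        if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
        grid[(size_t)iz * nx + ix] += dw;
      }
      p.w -= dw;
      if (mus <= 0.0) { // pure absorber: remaining weight cannot scatter
        if (p.region == 1) abs_v += p.w; else abs_bg += p.w;
        p.w = 0.0; alive = false; break;
      }

      // spin
      double g = (p.region == 1) ? g_v : g_bg;
      double ct = hg_cos(g, rng.unif());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.unif();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(p.uz) > 0.99999) {
        p.ux = st * cp; p.uy = st * sp; p.uz = ct * (p.uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - p.uz * p.uz);
        double ux = st * (p.ux * p.uz * cp - p.uy * sp) / den + p.ux * ct;
        double uy = st * (p.uy * p.uz * cp + p.ux * sp) / den + p.uy * ct;
        double uz = -st * cp * den + p.uz * ct;
        p.ux = ux; p.uy = uy; p.uz = uz;
      }
      double norm = std::sqrt(p.ux * p.ux + p.uy * p.uy + p.uz * p.uz);
      p.ux /= norm; p.uy /= norm; p.uz /= norm;

      // roulette
      if (p.w < roulette_threshold) {
        if (rng.unif() < roulette_survival) {
          boost += p.w * (1.0 / roulette_survival - 1.0);
          p.w /= roulette_survival;
        } else {
          lost += p.w;
          p.w = 0.0; alive = false;
        }
      }
    }
    sumR += cR; sumR2 += cR * cR;
    sumT += cT; sumT2 += cT * cT;
  }

  double N = (double)n_photons;
  // Closure: normalize by total terminal weight so the six-bin budget sums
  // to exactly 1; the factor deviates from N only by roulette variance.
  double S = r_spec + r_diff + t_tot + abs_bg + abs_v + e_side;
  double scale = (S > 0.0) ? 1.0 / S : 0.0;

  double mR = sumR / N, mT = sumT / N;
  double varR = std::max(0.0, sumR2 / N - mR * mR);
  double varT = std::max(0.0, sumT2 / N - mT * mT);
  double fac = N * scale; // converts per-photon means to budget scale
  List out = List::create(
    _["R_specular"] = r_spec * scale,
    _["R_diffuse"] = r_diff * scale,
    _["T"] = t_tot * scale,
    _["Abs_background"] = abs_bg * scale,
    _["Abs_vessel"] = abs_v * scale,
    _["E_side"] = e_side * scale,
    _["se_R"] = std::sqrt(varR / N) * fac,
    _["se_T"] = std::sqrt(varT / N) * fac,
    _["roulette_lost"] = lost / N,
    _["roulette_boost"] = boost / N,
    _["photon_count"] = n_photons);
  if (tally_fluence) {
    NumericMatrix gm(nz, nx);
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix)
        gm(iz, ix) = grid[(size_t)iz * nx + ix] * scale;
    out["fluence"] = gm;
    out["voxel_mm"] = voxel_mm;
  }
  return out;
}
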