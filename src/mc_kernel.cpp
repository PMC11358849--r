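// Voxel Monte Carlo photon transport kernel.
//
// Implicit-capture weighting (weight * mu_a/mu_t deposited per interaction),
// dimensionless-step carry-over across voxel boundaries, Henyey-Greenstein
// scattering, Russian roulette termination, aperture detection on the top or
// bottom face. The refractive index is uniform, so there are no Fresnel
// events: photons crossing the outer boundary are terminated (and possibly
// detected). Lengths in cm.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// --- xoshiro256++ RNG, seeded via splitmix64 -------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
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
  // uniform in [0, 1)
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1): safe argument for log()
  inline double u01p() { return ((next() >> 11) + 0.5) * 0x1.0p-53; }
};

// Henyey-Greenstein deflection cosine (inverse CDF); g = 0 is isotropic.
inline double hg_cos(Xoshiro &rng, double g) {
  if (std::fabs(g) < 1e-12) return 2.0 * rng.u01() - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.u01());
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

// Radius from a Gaussian intensity profile with 1/e^2 radius `waist`:
// I(r) ~ exp(-2 r^2 / waist^2), so r^2 ~ Exp(2 / waist^2).
inline double beam_radius(Xoshiro &rng, double waist) {
  if (waist <= 0.0) return 0.0;
  return waist * std::sqrt(-std::log(rng.u01p()) / 2.0);
}

constexpr double BIG = 1e30;

} // namespace

// [[Rcpp::export]]
NumericVector sample_hg_cpp(int n, double g, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(rng, g);
  return out;
}

// [[Rcpp::export]]
NumericVector sample_beam_cpp(int n, double waist, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = beam_radius(rng, waist);
  return out;
}

// [[Rcpp::export]]
List mc_simulate_cpp(IntegerVector labels,
                     IntegerVector bins,       // nx, ny, nz
                     NumericVector extent,     // cm
                     NumericVector mua, NumericVector mus, NumericVector g,
                     double src_x, double src_y, double waist,
                     int det_face,             // 0 = top (z=0), 1 = bottom
                     double det_x, double det_y, double det_radius,
                     double det_cos_min,
                     double n_photons, double seed,
                     bool do_fluence, bool lateral_infinite,
                     double roulette_threshold, double survival_prob) {
  const int nx = bins[0], ny = bins[1], nz = bins[2];
  const double ex = extent[0], ey = extent[1], ez = extent[2];
  const double hx = ex / 2.0, hy = ey / 2.0;
  const double dx = ex / nx, dy = ey / ny, dz = ez / nz;
  const double inv_dx = 1.0 / dx, inv_dy = 1.0 / dy, inv_dz = 1.0 / dz;
  const int nmed = mua.size();
  const int *lab = INTEGER(labels);

  std::vector<double> MUT(nmed), ALB(nmed), GG(nmed);
  for (int m = 0; m < nmed; ++m) {
    MUT[m] = mua[m] + mus[m];
    ALB[m] = MUT[m] > 0.0 ? mua[m] / MUT[m] : 0.0;
    GG[m] = g[m];
  }

  NumericVector fluence(do_fluence ? (R_xlen_t)nx * ny * nz : 0);
  double *flu = do_fluence ? REAL(fluence) : nullptr;

  std::vector<double> rec_w, rec_opl, rec_pd;
  double detected_sum = 0.0, absorbed = 0.0;
  double exit_top = 0.0, exit_bottom = 0.0, exit_lateral = 0.0;
  double roulette_lost = 0.0, roulette_gain = 0.0;
  long long n_detected = 0;

  const double det_r2 = det_radius * det_radius;
  const long long N = static_cast<long long>(n_photons);

  for (long long ph = 0; ph < N; ++ph) {
    // Per-photon RNG substream keyed by (seed, photon index): photon k's
    // draws are independent of how many draws earlier photons consumed,
    // which lets paired runs (e.g. diastole/systole at one seed) act as
    // common random numbers photon by photon.
    Xoshiro rng((static_cast<uint64_t>(seed) << 32) ^
                static_cast<uint64_t>(ph));

    // ---- launch: Gaussian beam on the top face, collimated along +z ----
    double x, y;
    do {
      double r = beam_radius(rng, waist);
      double phi = 2.0 * M_PI * rng.u01();
      x = src_x + r * std::cos(phi);
      y = src_y + r * std::sin(phi);
    } while (x <= -hx || x >= hx || y <= -hy || y >= hy);
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double iux = BIG, iuy = BIG, iuz = 1.0;
    int ix = (int)((x + hx) * inv_dx); if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    int iy = (int)((y + hy) * inv_dy); if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    int iz = 0;
    double w = 1.0, opl = 0.0, maxz = 0.0;
    double s = -std::log(rng.u01p());
    int exit_code = -1;  // 0 top, 1 bottom, 2 lateral; -1 = absorbed/roulette

    for (;;) {
      // With laterally infinite tissue the label lookup clamps x/y to the
      // edge columns (the layer structure continues unchanged beyond the
      // grid); fluence is only recorded inside the grid.
      int cx = ix, cy = iy;
      if (lateral_infinite) {
        if (cx < 0) cx = 0; else if (cx >= nx) cx = nx - 1;
        if (cy < 0) cy = 0; else if (cy >= ny) cy = ny - 1;
      }
      const bool inside = (cx == ix && cy == iy);
      const R_xlen_t vidx = cx + (R_xlen_t)nx * (cy + (R_xlen_t)ny * iz);
      const int m = lab[vidx] - 1;
      const double mut = MUT[m];

      // distances to the voxel walls along the current direction
      double tx = BIG, ty = BIG, tz = BIG;
      if (ux > 0.0)      tx = ((ix + 1) * dx - hx - x) * iux;
      else if (ux < 0.0) tx = (ix * dx - hx - x) * iux;
      if (uy > 0.0)      ty = ((iy + 1) * dy - hy - y) * iuy;
      else if (uy < 0.0) ty = (iy * dy - hy - y) * iuy;
      if (uz > 0.0)      tz = ((iz + 1) * dz - z) * iuz;
      else if (uz < 0.0) tz = (iz * dz - z) * iuz;
      int axis = 0; double tw = tx;
      if (ty < tw) { tw = ty; axis = 1; }
      if (tz < tw) { tw = tz; axis = 2; }
      if (tw < 0.0) tw = 0.0;

      const double tint = (mut > 0.0) ? s / mut : BIG;

      if (tint < tw) {
        // ---- interaction inside this voxel ----
        x += ux * tint; y += uy * tint; z += uz * tint;
        opl += tint;
        if (z > maxz) maxz = z;
        if (flu && inside) flu[vidx] += w * tint;

        const double dep = w * ALB[m];
        absorbed += dep;
        w -= dep;
        if (w <= 0.0) break;
        if (w < roulette_threshold) {
          if (rng.u01() < survival_prob) {
            roulette_gain += w * (1.0 / survival_prob - 1.0);
            w /= survival_prob;
          } else {
            roulette_lost += w;
            break;
          }
        }

        // Henyey-Greenstein scatter
        const double ct = hg_cos(rng, GG[m]);
        const double st = std::sqrt(1.0 - ct * ct);
        const double phi = 2.0 * M_PI * rng.u01();
        const double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp; uy = st * sp; uz = (uz >= 0.0 ? ct : -ct);
        } else {
          const double den = std::sqrt(1.0 - uz * uz);
          const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          const double nuz = -st * cp * den + uz * ct;
          ux = nux; uy = nuy; uz = nuz;
        }
        const double nrm = 1.0 / std::sqrt(ux * ux + uy * uy + uz * uz);
        ux *= nrm; uy *= nrm; uz *= nrm;
        if (!(ux == ux && uy == uy && uz == uz)) {
          stop("internal error: NaN photon direction");
        }
        iux = (ux != 0.0) ? 1.0 / ux : BIG;
        iuy = (uy != 0.0) ? 1.0 / uy : BIG;
        iuz = (uz != 0.0) ? 1.0 / uz : BIG;
        s = -std::log(rng.u01p());
      } else {
        // ---- advance to the voxel wall, carry the remaining step over ----
        x += ux * tw; y += uy * tw; z += uz * tw;
        opl += tw;
        if (z > maxz) maxz = z;
        if (flu && inside) flu[vidx] += w * tw;
        if (mut > 0.0) { s -= tw * mut; if (s < 0.0) s = 0.0; }

        if (axis == 0) {
          ix += (ux > 0.0) ? 1 : -1;
          x = (ux > 0.0) ? (ix * dx - hx) : ((ix + 1) * dx - hx);
          if (!lateral_infinite && (ix < 0 || ix >= nx)) {
            exit_code = 2; break;
          }
        } else if (axis == 1) {
          iy += (uy > 0.0) ? 1 : -1;
          y = (uy > 0.0) ? (iy * dy - hy) : ((iy + 1) * dy - hy);
          if (!lateral_infinite && (iy < 0 || iy >= ny)) {
            exit_code = 2; break;
          }
        } else {
          iz += (uz > 0.0) ? 1 : -1;
          z = (uz > 0.0) ? (iz * dz) : ((iz + 1) * dz);
          if (iz < 0) { exit_code = 0; break; }
          if (iz >= nz) { exit_code = 1; break; }
          if (z > maxz) maxz = z;
        }
      }
    }

    if (exit_code == 0) exit_top += w;
    else if (exit_code == 1) exit_bottom += w;
    else if (exit_code == 2) exit_lateral += w;

    if (exit_code == det_face) {
      const double rx = x - det_x, ry = y - det_y;
      // numerical-aperture cut: |cos| of the exit angle from the face
      // normal must reach det_cos_min (0 accepts all angles)
      if (rx * rx + ry * ry <= det_r2 && std::fabs(uz) >= det_cos_min) {
        detected_sum += w;
        ++n_detected;
        rec_w.push_back(w);
        rec_opl.push_back(opl);
        rec_pd.push_back(maxz);
      }
    }
  }

  if (do_fluence) {
    const double norm = 1.0 / (dx * dy * dz * (double)N);
    for (R_xlen_t i = 0; i < fluence.size(); ++i) fluence[i] *= norm;
    fluence.attr("dim") = IntegerVector::create(nx, ny, nz);
  }

  return List::create(
    _["detected_dc"] = detected_sum / (double)N,
    _["n_detected"] = (double)n_detected,
    _["weight"] = NumericVector(rec_w.begin(), rec_w.end()),
    _["opl"] = NumericVector(rec_opl.begin(), rec_opl.end()),
    _["max_depth"] = NumericVector(rec_pd.begin(), rec_pd.end()),
    _["absorbed"] = absorbed,
    _["exit_top"] = exit_top,
    _["exit_bottom"] = exit_bottom,
    _["exit_lateral"] = exit_lateral,
    _["roulette_lost"] = roulette_lost,
    _["roulette_gain"] = roulette_gain,
    _["fluence"] = do_fluence ? (SEXP)fluence : R_NilValue
  );
}
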