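// Two-layer Monte Carlo photon transport for skin diffuse reflectance.
//
// Geometry: semi-finite slab of two index-matched layers (epidermis over
// dermis, both n = 1.4) under air (n = 1.0); depth positive down, origin at
// the illuminated surface. Photons are launched as a collimated pencil beam
// at normal incidence. Scattering is isotropic (similarity relation
// mus = mus', g = 0), so only the depth coordinate and the polar direction
// cosine need to be tracked; full 3D path length still accumulates per layer.
//
// Two estimators share the walk:
//  * white MC (mua = 0): records (exit weight, epidermal path, dermal path)
//    for every photon leaving the top surface; any absorption combination is
//    later evaluated by Beer-Lambert reweighting of the records,
//  * direct MC: attenuates the photon weight continuously by
//    exp(-mua * substep) during transport and tallies the exit weight.
//
// RNG: xoshiro256+ seeded via splitmix64 so runs are reproducible from a
// single integer seed, independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into xoshiro state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never returns 0 so log() is safe
  inline double runif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  // uniform in [0, 1)
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Fresnel reflectance for unpolarized light, incidence cosine ci in medium
// with index n1 against n2.
inline double fresnel(double n1, double n2, double ci) {
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(1.0 - ci * ci);
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

const double ROULETTE_THRESHOLD = 1e-4;
const double ROULETTE_SURVIVE = 0.1;

// One full photon history. Returns exit channel: 0 = top (diffuse
// reflectance), 1 = bottom (transmitted), 2 = terminated by roulette.
// On return, w, le, ld hold the exit weight and per-layer path lengths.
inline int trace_photon(Rng& rng,
                        double mus1, double mus2,
                        double mua1, double mua2,
                        double d1, double d2,
                        double n_tissue, double n_air,
                        bool direct,
                        double& w, double& le, double& ld) {
  double z = 0.0, uz = 1.0;
  le = 0.0; ld = 0.0;
  // specular entry loss at the air/tissue boundary (normal incidence)
  double rsp = fresnel(n_air, n_tissue, 1.0);
  w = 1.0 - rsp;
  double zbot = d1 + d2;
  for (;;) {
    int layer = (z < d1) ? 0 : 1;
    double mus = layer == 0 ? mus1 : mus2;
    double mua = layer == 0 ? mua1 : mua2;
    double s = -std::log(rng.runif_pos()) / mus;
    for (;;) {
      // distance to the nearest layer boundary along the flight direction
      double db = 1e30;
      int hit = -1;  // 0 = top surface, 1 = interface, 2 = bottom
      if (uz < 0.0) {
        double zb = layer == 0 ? 0.0 : d1;
        db = (zb - z) / uz;
        hit = layer == 0 ? 0 : 1;
      } else if (uz > 0.0) {
        double zb = layer == 0 ? d1 : zbot;
        db = (zb - z) / uz;
        hit = layer == 0 ? 1 : 2;
      }
      if (s < db) {  // interaction inside the current layer
        z += s * uz;
        if (layer == 0) le += s; else ld += s;
        if (direct && mua > 0.0) w *= std::exp(-mua * s);
        break;
      }
      // advance to the boundary
      s -= db;
      z += db * uz;
      if (layer == 0) le += db; else ld += db;
      if (direct && mua > 0.0) w *= std::exp(-mua * db);
      if (hit == 1) {
        // index-matched epidermis/dermis interface: continue in other layer,
        // rescale remaining optical step to the new scattering coefficient
        double mus_new = layer == 0 ? mus2 : mus1;
        s *= mus / mus_new;
        mus = mus_new;
        mua = layer == 0 ? mua2 : mua1;
        layer = 1 - layer;
        z = d1;  // exactly on the boundary; layer index decides the side
        continue;
      }
      if (hit == 0) {
        // air interface: Fresnel reflect or escape
        double r = fresnel(n_tissue, n_air, -uz);
        if (rng.runif() < r) {
          uz = -uz;
          z = 0.0;
          continue;
        }
        return 0;  // diffuse reflectance
      }
      // bottom boundary: transmitted and discarded
      return 1;
    }
    // isotropic scattering: new polar cosine uniform on [-1, 1]
    uz = 2.0 * rng.runif() - 1.0;
    if (direct && w < ROULETTE_THRESHOLD) {
      if (rng.runif() < ROULETTE_SURVIVE) w /= ROULETTE_SURVIVE;
      else return 2;
    }
  }
}

}  // namespace

// White-MC scattering run at one wavelength: zero absorption, records the
// per-layer path lengths of every photon exiting the top surface.
// [[Rcpp::export(name = ".mc_scatter")]]
List mc_scatter(double mus_epi, double mus_derm,
                double d_epi, double d_derm,
                double n_tissue, double n_air,
                int n_photons, double seed) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (mus_epi <= 0.0 || mus_derm <= 0.0) stop("mus must be > 0");
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<double> wv, lev, ldv;
  wv.reserve(n_photons); lev.reserve(n_photons); ldv.reserve(n_photons);
  double w, le, ld;
  double w_reflected = 0.0, w_transmitted = 0.0;
  double rsp = fresnel(n_air, n_tissue, 1.0);
  for (int i = 0; i < n_photons; ++i) {
    int ch = trace_photon(rng, mus_epi, mus_derm, 0.0, 0.0,
                          d_epi, d_derm, n_tissue, n_air, false, w, le, ld);
    if (ch == 0) {
      wv.push_back(w); lev.push_back(le); ldv.push_back(ld);
      w_reflected += w;
    } else if (ch == 1) {
      w_transmitted += w;
    }
  }
  return List::create(
      _["weight"] = wv, _["le"] = lev, _["ld"] = ldv,
      _["n_launched"] = n_photons,
      _["specular_weight"] = rsp * n_photons,
      _["reflected_weight"] = w_reflected,
      _["transmitted_weight"] = w_transmitted);
}

// Direct-absorption MC at one wavelength: returns the reflectance estimate
// and its Monte Carlo standard error.
// [[Rcpp::export(name = ".mc_direct")]]
List mc_direct(double mus_epi, double mus_derm,
               double mua_epi, double mua_derm,
               double d_epi, double d_derm,
               double n_tissue, double n_air,
               int n_photons, double seed) {
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (mua_epi < 0.0 || mua_derm < 0.0) stop("mua must be >= 0");
  if (mus_epi <= 0.0 || mus_derm <= 0.0) stop("mus must be > 0");
  Rng rng(static_cast<uint64_t>(seed));
  double sum = 0.0, sumsq = 0.0;
  double w, le, ld;
  for (int i = 0; i < n_photons; ++i) {
    int ch = trace_photon(rng, mus_epi, mus_derm, mua_epi, mua_derm,
                          d_epi, d_derm, n_tissue, n_air, true, w, le, ld);
    if (ch == 0) { sum += w; sumsq += w * w; }
  }
  double n = static_cast<double>(n_photons);
  double mean = sum / n;
  double var = (sumsq / n - mean * mean) / n;
  return List::create(_["theta"] = mean,
                      _["se"] = var > 0.0 ? std::sqrt(var) : 0.0);
}

// Beer-Lambert reweighting of one wavelength's path-length records for a
// batch of absorption combinations. Returns a matrix with columns theta and
// se (standard error of the per-photon estimator including zero records).
// [[Rcpp::export(name = ".mc_reweight")]]
NumericMatrix mc_reweight(NumericVector weight, NumericVector le,
                          NumericVector ld, double n_launched,
                          NumericVector mua_epi, NumericVector mua_derm) {
  int nrec = weight.size();
  int ncomb = mua_epi.size();
  if (mua_derm.size() != ncomb) stop("mua vectors must have equal length");
  NumericMatrix out(ncomb, 2);
  for (int j = 0; j < ncomb; ++j) {
    double ae = mua_epi[j], ad = mua_derm[j];
    if (ae < 0.0 || ad < 0.0) stop("mua must be >= 0");
    double sum = 0.0, sumsq = 0.0;
    for (int i = 0; i < nrec; ++i) {
      double x = weight[i] * std::exp(-ae * le[i] - ad * ld[i]);
      sum += x; sumsq += x * x;
    }
    double mean = sum / n_launched;
    double var = (sumsq / n_launched - mean * mean) / n_launched;
    out(j, 0) = mean;
    out(j, 1) = var > 0.0 ? std::sqrt(var) : 0.0;
  }
  colnames(out) = CharacterVector::create("theta", "se");
  return out;
}
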