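// Voxel Monte Carlo dose-rate engine.
//
// Histories sample a decay voxel proportional to voxel activity and a
// uniform position inside it. Beta branch: local deposition (sub-voxel
// range) or straight-line continuous-slowing-down transport through the
// density map with energies sampled from an inverse-CDF spectrum table.
// Photon lines: isotropic emission, Woodcock (delta) tracking against a
// grid-wide majorant, photoelectric full local absorption, Compton electron
// energy deposited on the spot (kerma approximation, sub-voxel electron
// ranges at these energies), scattered photon followed until it drops below
// the cutoff or leaves the grid. Energy ledger (emitted = deposited +
// escaped) is closed in double arithmetic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Rng {
  // xoshiro256+ style splitmix-seeded generator: reproducible across
  // platforms, independent of R's RNG stream.
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97f4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      s[i] = x ^ (x >> 31);
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
  inline double u() {  // uniform in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// linear interpolation on a small monotone table
inline double interp(const double* x, const double* y, int n, double xq) {
  if (xq <= x[0]) return y[0];
  if (xq >= x[n - 1]) return y[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= xq) lo = mid; else hi = mid;
  }
  double f = (xq - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + f * (y[hi] - y[lo]);
}

struct AttTable {
  std::vector<double> log_e, log_mu, pf;
  double muRho(double E) const {
    return std::exp(interp(log_e.data(), log_mu.data(),
                           (int)log_e.size(), std::log(E)));
  }
  double photoFrac(double E) const {
    return interp(log_e.data(), pf.data(), (int)log_e.size(), std::log(E));
  }
};

inline void isotropic(Rng& rng, double d[3]) {
  double ct = 2.0 * rng.u() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 2.0 * M_PI * rng.u();
  d[0] = st * std::cos(ph); d[1] = st * std::sin(ph); d[2] = ct;
}

// rotate direction d by polar angle with cosine ct and random azimuth
inline void rotate(Rng& rng, double d[3], double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 2.0 * M_PI * rng.u();
  double sp = std::sin(ph), cp = std::cos(ph);
  double u = d[0], v = d[1], w = d[2];
  double s = std::sqrt(std::max(1e-30, 1.0 - w * w));
  double nx, ny, nz;
  if (s > 1e-10) {
    nx = u * ct + st * (u * w * cp - v * sp) / s;
    ny = v * ct + st * (v * w * cp + u * sp) / s;
    nz = w * ct - st * s * cp;
  } else {  // nearly parallel to z
    nx = st * cp; ny = st * sp; nz = (w > 0 ? ct : -ct);
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  d[0] = nx / norm; d[1] = ny / norm; d[2] = nz / norm;
}

// Kahn rejection sampling of the Klein-Nishina scattered-to-incident
// energy ratio; returns eps = E'/E for incident alpha = E/mec2.
inline double kahnEps(Rng& rng, double alpha) {
  double thresh = (2.0 * alpha + 1.0) / (2.0 * alpha + 9.0);
  for (int it = 0; it < 10000; ++it) {
    double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
    if (r1 <= thresh) {
      double x = 1.0 + 2.0 * alpha * r2;
      if (r3 <= 4.0 * (x - 1.0) / (x * x)) return 1.0 / x;
    } else {
      double x = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * r2);
      double ct = 1.0 - (x - 1.0) / alpha;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return 1.0 / x;
    }
  }
  return 1.0;  // unreachable in practice
}

}  // namespace

// [[Rcpp::export(name = ".mcEngine")]]
List mcEngine(NumericVector activity, NumericVector density,
              IntegerVector comp, IntegerVector dims, double voxel_cm,
              int n_hist, double seed,
              double beta_mean, double beta_yield, int beta_csda,
              NumericMatrix beta_icdf, NumericMatrix range_table,
              NumericMatrix photon_lines,
              List atten_tables, double cutoff, double density_floor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> tally(nvox, 0.0);
  double emitted = 0.0, escaped = 0.0;

  // cumulative activity for source sampling
  std::vector<double> cum(nvox);
  double tot = 0.0;
  for (R_xlen_t i = 0; i < nvox; ++i) { tot += activity[i]; cum[i] = tot; }
  if (tot <= 0.0) stop("total activity must be positive");

  // attenuation tables: soft_tissue, lung, bone (material codes 1..3)
  AttTable att[3];
  for (int m = 0; m < 3; ++m) {
    List t = atten_tables[m];
    NumericVector le = t["log_e"], lm = t["log_mu_rho"], pf = t["photo_fraction"];
    att[m].log_e.assign(le.begin(), le.end());
    att[m].log_mu.assign(lm.begin(), lm.end());
    att[m].pf.assign(pf.begin(), pf.end());
  }
  double rho_max = density_floor;
  for (R_xlen_t i = 0; i < nvox; ++i) rho_max = std::max(rho_max, density[i]);

  // beta spectrum inverse CDF and range-energy tables
  const int n_icdf = beta_icdf.nrow();
  std::vector<double> icdf_u(n_icdf), icdf_e(n_icdf);
  for (int i = 0; i < n_icdf; ++i) {
    icdf_u[i] = beta_icdf(i, 0); icdf_e[i] = beta_icdf(i, 1);
  }
  const int n_rt = range_table.nrow();
  std::vector<double> rt_e(n_rt), rt_r(n_rt);
  for (int i = 0; i < n_rt; ++i) {
    rt_e[i] = range_table(i, 0); rt_r[i] = range_table(i, 1);
  }
  const int n_lines = photon_lines.nrow();

  Rng rng((uint64_t)seed);
  const double mec2 = 0.51099895;
  const double ex = nx * voxel_cm, ey = ny * voxel_cm, ez = nz * voxel_cm;

  for (int h = 0; h < n_hist; ++h) {
    // decay voxel ~ activity, uniform position inside
    double target = rng.u() * tot;
    R_xlen_t v = std::lower_bound(cum.begin(), cum.end(), target) - cum.begin();
    if (v >= nvox) v = nvox - 1;
    R_xlen_t iz = v / ((R_xlen_t)nx * ny);
    R_xlen_t iy = (v - iz * nx * ny) / nx;
    R_xlen_t ix = v - iz * nx * ny - iy * nx;
    double pos0[3] = {(ix + rng.u()) * voxel_cm, (iy + rng.u()) * voxel_cm,
                      (iz + rng.u()) * voxel_cm};

    // ---- beta branch ----
    if (beta_yield > 0.0) {
      if (!beta_csda) {
        emitted += beta_mean * beta_yield;
        tally[v] += beta_mean * beta_yield;
      } else {
        double E = interp(icdf_u.data(), icdf_e.data(), n_icdf, rng.u());
        emitted += E * beta_yield;
        double dir[3]; isotropic(rng, dir);
        double pos[3] = {pos0[0], pos0[1], pos0[2]};
        double R = interp(rt_e.data(), rt_r.data(), n_rt, E);  // g/cm^2
        double step = voxel_cm / 4.0;
        double Eres = E;
        while (Eres > 0.0) {
          int cx = (int)std::floor(pos[0] / voxel_cm);
          int cy = (int)std::floor(pos[1] / voxel_cm);
          int cz = (int)std::floor(pos[2] / voxel_cm);
          if (cx < 0 || cy < 0 || cz < 0 || cx >= nx || cy >= ny || cz >= nz) {
            escaped += Eres * beta_yield;
            break;
          }
          R_xlen_t cv = (R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx;
          double rho = std::max(density[cv], density_floor);
          double ds = step * rho;
          if (ds >= R) {
            tally[cv] += Eres * beta_yield;
            Eres = 0.0;
          } else {
            R -= ds;
            double Enew = interp(rt_r.data(), rt_e.data(), n_rt, R);
            if (Enew > Eres) Enew = Eres;
            tally[cv] += (Eres - Enew) * beta_yield;
            Eres = Enew;
            if (Eres <= 1e-6) { tally[cv] += Eres * beta_yield; Eres = 0.0; }
            pos[0] += step * dir[0]; pos[1] += step * dir[1];
            pos[2] += step * dir[2];
          }
        }
      }
    }

    // ---- photon lines (each emitted with statistical weight = yield) ----
    for (int l = 0; l < n_lines; ++l) {
      double E = photon_lines(l, 0), w = photon_lines(l, 1);
      if (w <= 0.0) continue;
      emitted += E * w;
      double dir[3]; isotropic(rng, dir);
      double pos[3] = {pos0[0], pos0[1], pos0[2]};
      bool alive = true;
      while (alive) {
        double mu_maj = 0.0;
        for (int m = 0; m < 3; ++m)
          mu_maj = std::max(mu_maj, att[m].muRho(E));
        mu_maj *= rho_max;
        // Woodcock flight
        double s = -std::log(rng.u()) / mu_maj;
        pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
        if (pos[0] < 0 || pos[1] < 0 || pos[2] < 0 ||
            pos[0] >= ex || pos[1] >= ey || pos[2] >= ez) {
          escaped += E * w;
          break;
        }
        int cx = (int)(pos[0] / voxel_cm), cy = (int)(pos[1] / voxel_cm),
            cz = (int)(pos[2] / voxel_cm);
        R_xlen_t cv = (R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx;
        int mat = comp[cv] - 1;
        double mu_loc = att[mat].muRho(E) * density[cv];
        if (rng.u() * mu_maj > mu_loc) continue;  // virtual collision
        // real interaction
        if (rng.u() < att[mat].photoFrac(E)) {
          tally[cv] += E * w;
          alive = false;
        } else {
          double alpha = E / mec2;
          double eps = kahnEps(rng, alpha);
          double ct = 1.0 + 1.0 / alpha - 1.0 / (alpha * eps);
          if (ct < -1.0) ct = -1.0;
          if (ct > 1.0) ct = 1.0;
          tally[cv] += E * (1.0 - eps) * w;
          E *= eps;
          if (E < cutoff) {
            tally[cv] += E * w;
            alive = false;
          } else {
            rotate(rng, dir, ct);
          }
        }
      }
    }
  }

  double deposited = 0.0;
  NumericVector energy(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) {
    energy[i] = tally[i];
    deposited += tally[i];
  }
  return List::create(_["energy_MeV"] = energy, _["emitted_MeV"] = emitted,
                      _["deposited_MeV"] = deposited,
                      _["escaped_MeV"] = escaped);
}

// [[Rcpp::export(name = ".labelComponents6")]]
IntegerVector labelComponents6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(nvox, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t i = 0; i < nvox; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int iz = (int)(v / ((R_xlen_t)nx * ny));
      int iy = (int)((v - (R_xlen_t)iz * nx * ny) / nx);
      int ix = (int)(v - (R_xlen_t)iz * nx * ny - (R_xlen_t)iy * nx);
      for (int k = 0; k < 6; ++k) {
        int jx = ix + dx[k], jy = iy + dy[k], jz = iz + dz[k];
        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)jz * nx * ny + (R_xlen_t)jy * nx + jx;
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}
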