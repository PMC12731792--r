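// Layered Monte Carlo photon transport (hop-drop-spin with implicit
// capture), fiber-probe source and detector geometry.
//
// Geometry: planar slab stack along z, illuminated face at z = 0.
// Lengths in cm. Internal interfaces are index matched (single tissue
// refractive index); external faces see the ambient index through
// unpolarized Fresnel reflection. The source fiber is index matched to
// the tissue (contact probe), so there is no specular loss at launch.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: self-contained, fast, and
// deterministic for a given 64-bit seed across platforms.
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
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]: safe for -log(u)
  inline double unif_open0() { return 1.0 - unif(); }
};

// Henyey-Greenstein deflection cosine by inverse CDF.
inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// Unpolarized Fresnel reflectance for incidence cosine ci in [0,1].
inline double fresnel(double n_in, double n_out, double ci) {
  if (n_in == n_out) return 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n_in / n_out * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct);
  double rp = (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by deflection cosine ct and azimuth psi.
inline void spin(double &ux, double &uy, double &uz, double ct, double psi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  // renormalize occasionally drifting vectors
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

}  // namespace

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(NumericVector mu_a, NumericVector mu_s, NumericVector g,
               NumericVector d_cm, double n_tissue, double n_ambient,
               double n_photons, double seed,
               double src_radius_cm, double fiber_na,
               int refl_detector_shape,  // 0 = annulus, 1 = offset disc
               double det_r_inner_cm, double det_r_outer_cm,
               double det_disc_center_cm, double det_disc_radius_cm,
               double trans_radius_cm,
               bool na_test,
               double weight_threshold, double roulette_survival) {
  const int nl = mu_a.size();
  if (nl < 1 || mu_s.size() != nl || g.size() != nl || d_cm.size() != nl)
    stop("layer property vectors must have equal positive length");
  const long long N = (long long) n_photons;
  if (N < 1) stop("photon budget must be at least 1");
  for (int i = 0; i < nl; ++i) {
    if (!std::isfinite(mu_a[i]) || !std::isfinite(mu_s[i]) ||
        !std::isfinite(g[i]) || !std::isfinite(d_cm[i]))
      stop("non-finite layer properties");
    if (mu_a[i] < 0 || mu_s[i] <= 0 || std::fabs(g[i]) >= 1 || d_cm[i] <= 0)
      stop("require mu_a >= 0, mu_s > 0, |g| < 1, thickness > 0");
  }

  // layer boundaries
  std::vector<double> zb(nl + 1);
  zb[0] = 0.0;
  for (int i = 0; i < nl; ++i) zb[i + 1] = zb[i] + d_cm[i];
  const double L = zb[nl];

  // launch cone half-angle inside the tissue
  const double sin_max = fiber_na / n_tissue;
  const double cos_max = std::sqrt(std::max(0.0, 1.0 - sin_max * sin_max));
  // detector NA acceptance, expressed as the in-tissue sine limit
  const double sin_acc_tissue = fiber_na * n_ambient / n_tissue;

  double rd_total = 0.0, td_total = 0.0, absorbed = 0.0;
  double rd_det = 0.0, td_det = 0.0;
  double rd_det_w2 = 0.0, td_det_w2 = 0.0;
  long long rd_count = 0, td_count = 0, capped = 0;
  const long long max_steps = 2000000;
  const double two_pi = 6.283185307179586476925286766559;

  for (long long ph = 0; ph < N; ++ph) {
    // Counter-based seeding: each photon gets its own deterministic
    // stream, so paired runs with a shared seed are photon-wise common
    // random numbers regardless of where trajectories diverge.
    Rng rng(((uint64_t) seed << 24) ^ (uint64_t) ph);
    // launch: uniform over the source-fiber face, direction uniform in
    // solid angle within the NA cone (index-matched entry, weight 1)
    double r = src_radius_cm * std::sqrt(rng.unif());
    double phi = two_pi * rng.unif();
    double x = r * std::cos(phi), y = r * std::sin(phi), z = 0.0;
    double uz = cos_max + (1.0 - cos_max) * rng.unif();
    double st0 = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double psi = two_pi * rng.unif();
    double ux = st0 * std::cos(psi), uy = st0 * std::sin(psi);
    double w = 1.0;
    int layer = 0;
    bool alive = true;
    long long steps = 0;

    while (alive) {
      if (++steps > max_steps) { absorbed += w; ++capped; break; }
      double mut = mu_a[layer] + mu_s[layer];
      double s = -std::log(rng.unif_open0()) / mut;

      // distance to the layer boundary along the flight direction
      double db = R_PosInf;
      int toward = 0;  // +1 lower boundary (z increasing), -1 upper
      if (uz > 0.0) { db = (zb[layer + 1] - z) / uz; toward = 1; }
      else if (uz < 0.0) { db = (zb[layer] - z) / uz; toward = -1; }

      if (s < db) {
        // hop to the interaction site, drop, spin
        x += s * ux; y += s * uy; z += s * uz;
        absorbed += w * mu_a[layer] / mut;
        w *= mu_s[layer] / mut;
        double ct = hg_cos(g[layer], rng.unif());
        spin(ux, uy, uz, ct, two_pi * rng.unif());
        if (w < weight_threshold) {
          if (rng.unif() < roulette_survival) w /= roulette_survival;
          else { alive = false; }  // weight already accounted in expectation
        }
        continue;
      }

      // move to the boundary (memoryless step: redraw in the next medium)
      x += db * ux; y += db * uy;
      if (toward == 1) {
        z = zb[layer + 1];
        if (layer + 1 < nl) { ++layer; continue; }  // index-matched interface
        // bottom external face
        double ci = std::fabs(uz);
        if (rng.unif() < fresnel(n_tissue, n_ambient, ci)) { uz = -uz; continue; }
        td_total += w;
        double rr = std::sqrt(x * x + y * y);
        double sin_t = std::sqrt(std::max(0.0, 1.0 - uz * uz));
        bool ang_ok = !na_test || sin_t <= sin_acc_tissue;
        if (rr <= trans_radius_cm && ang_ok) {
          td_det += w; td_det_w2 += w * w; ++td_count;
        }
        alive = false;
      } else {
        z = zb[layer];
        if (layer > 0) { --layer; continue; }
        // top external face (illuminated side)
        double ci = std::fabs(uz);
        if (rng.unif() < fresnel(n_tissue, n_ambient, ci)) { uz = -uz; continue; }
        rd_total += w;
        double rr, sin_t = std::sqrt(std::max(0.0, 1.0 - uz * uz));
        bool pos_ok;
        if (refl_detector_shape == 0) {
          rr = std::sqrt(x * x + y * y);
          pos_ok = (rr >= det_r_inner_cm && rr <= det_r_outer_cm);
        } else {
          double dx = x - det_disc_center_cm;
          rr = std::sqrt(dx * dx + y * y);
          pos_ok = (rr <= det_disc_radius_cm);
        }
        bool ang_ok = !na_test || sin_t <= sin_acc_tissue;
        if (pos_ok && ang_ok) {
          rd_det += w; rd_det_w2 += w * w; ++rd_count;
        }
        alive = false;
      }
    }
  }

  return List::create(
    _["rd_total"] = rd_total / N,
    _["td_total"] = td_total / N,
    _["absorbed"] = absorbed / N,
    _["rd_det"] = rd_det / N,
    _["td_det"] = td_det / N,
    _["rd_det_w2"] = rd_det_w2,
    _["td_det_w2"] = td_det_w2,
    _["rd_det_sum"] = rd_det,
    _["td_det_sum"] = td_det,
    _["rd_count"] = (double) rd_count,
    _["td_count"] = (double) td_count,
    _["capped"] = (double) capped,
    _["n_photons"] = (double) N
  );
}

// [[Rcpp::export(name = ".hg_cos_cpp")]]
NumericVector hg_cos_cpp(double g, NumericVector u) {
  NumericVector out(u.size());
  for (int i = 0; i < u.size(); ++i) out[i] = hg_cos(g, u[i]);
  return out;
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double n_in, double n_out, double ci) {
  return fresnel(n_in, n_out, ci);
}
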