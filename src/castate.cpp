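// Numerical core: Houart Ca2+ oscillation model (deterministic RK4),
// chemical Langevin equation (Euler-Maruyama, 12 birth-death channels),
// and a Benettin two-trajectory largest-Lyapunov estimator.
//
// A package-internal counter-seeded RNG (splitmix64 -> xoshiro256++ with a
// ziggurat normal sampler) is used instead of R's RNG: one Euler-Maruyama
// trajectory consumes ~1.5e7 Gaussian draws, which must be cheap and must be
// reproducible from a single recorded integer seed independent of R's RNG
// state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeding, xoshiro256++ stream, ziggurat normals
// ---------------------------------------------------------------------------

namespace rng {

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
    // avoid the (astronomically unlikely) all-zero state
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x1ULL;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline uint32_t next32() { return (uint32_t)(next() >> 32); }

  // uniform in (0,1), 53-bit resolution, never exactly 0 or 1
  inline double unif() {
    return (double)((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia-Tsang 128-layer ziggurat for the standard normal.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3, q;
    q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro256pp &g) const {
    for (;;) {
      int32_t hz = (int32_t)g.next32();
      uint32_t iz = (uint32_t)hz & 127U;
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      // slow path
      const double r = 3.442619855899;
      for (;;) {
        double x = hz * wn[iz];
        if (iz == 0) {  // base-strip tail
          double y;
          do {
            x = -std::log(g.unif()) * (1.0 / r);
            y = -std::log(g.unif());
          } while (y + y < x * x);
          return (hz > 0) ? r + x : -r - x;
        }
        if (fn[iz] + g.unif() * (fn[iz - 1] - fn[iz]) <
            std::exp(-0.5 * x * x))
          return x;
        hz = (int32_t)g.next32();
        iz = (uint32_t)hz & 127U;
        ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
        if (ahz < kn[iz]) return hz * wn[iz];
      }
    }
  }
};

static const Ziggurat ZIG;

}  // namespace rng

// [[Rcpp::export(name = ".rng_normal_cpp")]]
NumericVector rng_normal_cpp(int n, double seed) {
  rng::Xoshiro256pp g((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng::ZIG.draw(g);
  return out;
}

// ---------------------------------------------------------------------------
// Houart model
// ---------------------------------------------------------------------------

struct HouartParams {
  double beta, eps, V0, V1, VM2, k2, VM3, kx, ky, kz, VM5, k5, kd, kf, k_out,
      V4;
  int m, p, n;
  // precomputed threshold powers
  double k2_2, kx_m, ky_2, kz_4, k5_p, kd_n;
};

static inline double ipow(double x, int e) {
  double r = 1.0;
  while (e-- > 0) r *= x;
  return r;
}

// params must arrive in this fixed order (kept in step with R-side
// .param_order): beta, eps, V0, V1, VM2, k2, VM3, kx, ky, kz, VM5, k5, kd,
// kf, k_out, V4, m, p, n
static HouartParams parse_params(const NumericVector &p) {
  if (p.size() != 19) stop("parameter vector must have 19 elements");
  HouartParams q;
  q.beta = p[0]; q.eps = p[1]; q.V0 = p[2]; q.V1 = p[3]; q.VM2 = p[4];
  q.k2 = p[5]; q.VM3 = p[6]; q.kx = p[7]; q.ky = p[8]; q.kz = p[9];
  q.VM5 = p[10]; q.k5 = p[11]; q.kd = p[12]; q.kf = p[13]; q.k_out = p[14];
  q.V4 = p[15];
  q.m = (int)p[16]; q.p = (int)p[17]; q.n = (int)p[18];
  q.k2_2 = q.k2 * q.k2;
  q.kx_m = ipow(q.kx, q.m);
  q.ky_2 = q.ky * q.ky;
  q.kz_4 = ipow(q.kz, 4);
  q.k5_p = ipow(q.k5, q.p);
  q.kd_n = ipow(q.kd, q.n);
  return q;
}

struct Rates {
  double V2, V3, V5;
};

static inline Rates rates(const HouartParams &q, double x, double y,
                          double z) {
  Rates r;
  double x2 = x * x;
  r.V2 = q.VM2 * x2 / (q.k2_2 + x2);
  double xm = ipow(x, q.m), y2 = y * y, z4 = ipow(z, 4);
  r.V3 = q.VM3 * (xm / (q.kx_m + xm)) * (y2 / (q.ky_2 + y2)) *
         (z4 / (q.kz_4 + z4));
  double zp = ipow(z, q.p), xn = ipow(x, q.n);
  r.V5 = q.VM5 * (zp / (q.k5_p + zp)) * (xn / (q.kd_n + xn));
  return r;
}

static inline void drift(const HouartParams &q, double x, double y, double z,
                         double &fx, double &fy, double &fz) {
  Rates r = rates(q, x, y, z);
  fx = q.V0 + q.V1 * q.beta - r.V2 + r.V3 + q.kf * y - q.k_out * x;
  fy = r.V2 - r.V3 - q.kf * y;
  fz = q.beta * q.V4 - r.V5 - q.eps * z;
}

// [[Rcpp::export(name = ".houart_drift_cpp")]]
NumericVector houart_drift_cpp(NumericVector state, NumericVector params) {
  HouartParams q = parse_params(params);
  double fx, fy, fz;
  drift(q, state[0], state[1], state[2], fx, fy, fz);
  return NumericVector::create(fx, fy, fz);
}

// ---------------------------------------------------------------------------
// Deterministic integration (fixed-step RK4)
// ---------------------------------------------------------------------------

static inline void rk4_step(const HouartParams &q, double dt, double &x,
                            double &y, double &z) {
  double k1x, k1y, k1z, k2x, k2y, k2z, k3x, k3y, k3z, k4x, k4y, k4z;
  drift(q, x, y, z, k1x, k1y, k1z);
  drift(q, x + 0.5 * dt * k1x, y + 0.5 * dt * k1y, z + 0.5 * dt * k1z, k2x,
        k2y, k2z);
  drift(q, x + 0.5 * dt * k2x, y + 0.5 * dt * k2y, z + 0.5 * dt * k2z, k3x,
        k3y, k3z);
  drift(q, x + dt * k3x, y + dt * k3y, z + dt * k3z, k4x, k4y, k4z);
  x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
  y += dt / 6.0 * (k1y + 2 * k2y + 2 * k3y + k4y);
  z += dt / 6.0 * (k1z + 2 * k2z + 2 * k3z + k4z);
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (z < 0) z = 0;
}

// [[Rcpp::export(name = ".houart_rk4_cpp")]]
NumericMatrix houart_rk4_cpp(NumericVector params, NumericVector init,
                             double dt, double duration,
                             double sample_interval, double record_from) {
  HouartParams q = parse_params(params);
  long nsteps = (long)std::lround(duration / dt);
  long si = (long)std::lround(sample_interval / dt);
  long nb = (long)std::lround(record_from / dt);
  if (si < 1) stop("sample_interval must be >= dt");
  long nrec = (nsteps - nb) / si;
  if (nrec < 1) stop("no samples in the recording window");
  NumericMatrix out(nrec, 4);
  double x = init[0], y = init[1], z = init[2];
  long k = 0;
  for (long s = 1; s <= nsteps; ++s) {
    rk4_step(q, dt, x, y, z);
    if (!(std::isfinite(x) && std::isfinite(y) && std::isfinite(z)))
      stop("integration failure (non-finite state) at t = %f min", s * dt);
    if (s > nb && (s - nb) % si == 0 && k < nrec) {
      out(k, 0) = s * dt;
      out(k, 1) = x;
      out(k, 2) = y;
      out(k, 3) = z;
      ++k;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Chemical Langevin equation, Euler-Maruyama
// ---------------------------------------------------------------------------
//
// 12 birth-death channels at concentration scale (propensity a_j / V):
//   x: +V0, +V1*beta, -V2, +V3, +kf*y, -k_out*x
//   y: +V2, -V3, -kf*y
//   z: +beta*V4, -V5, -eps*z
// step: s' = s + F dt + sqrt(dt/V) * sum_j nu_j sqrt(r_j) eta_j, r_j >= 0,
// with the state clamped at 0 component-wise after each step.

// [[Rcpp::export(name = ".houart_cle_cpp")]]
NumericMatrix houart_cle_cpp(NumericVector params, NumericVector init,
                             double V, double dt, double duration,
                             double burn_in, double sample_interval,
                             double seed) {
  HouartParams q = parse_params(params);
  const bool noisy = std::isfinite(V);
  if (noisy && V <= 0) stop("system size V must be positive or infinite");
  long nsteps = (long)std::lround(duration / dt);
  long si = (long)std::lround(sample_interval / dt);
  long nb = (long)std::lround(burn_in / dt);
  if (si < 1) stop("sample_interval must be >= dt");
  long nrec = (nsteps - nb) / si;
  if (nrec < 1) stop("no samples after burn-in");
  NumericMatrix out(nrec, 4);

  rng::Xoshiro256pp g((uint64_t)seed);
  const double amp = noisy ? std::sqrt(dt / V) : 0.0;
  const double c1 = q.V0, c2 = q.V1 * q.beta, c10 = q.beta * q.V4;
  const double sq_c1 = std::sqrt(c1 > 0 ? c1 : 0.0);
  const double sq_c2 = std::sqrt(c2 > 0 ? c2 : 0.0);
  const double sq_c10 = std::sqrt(c10 > 0 ? c10 : 0.0);

  double x = init[0], y = init[1], z = init[2];
  long k = 0;
  for (long s = 1; s <= nsteps; ++s) {
    Rates r = rates(q, x, y, z);
    double kfy = q.kf * y, kox = q.k_out * x, epz = q.eps * z;
    double fx = c1 + c2 - r.V2 + r.V3 + kfy - kox;
    double fy = r.V2 - r.V3 - kfy;
    double fz = c10 - r.V5 - epz;
    x += fx * dt;
    y += fy * dt;
    z += fz * dt;
    if (noisy) {
      double sV2 = std::sqrt(r.V2 > 0 ? r.V2 : 0.0);
      double sV3 = std::sqrt(r.V3 > 0 ? r.V3 : 0.0);
      double sV5 = std::sqrt(r.V5 > 0 ? r.V5 : 0.0);
      double skfy = std::sqrt(kfy > 0 ? kfy : 0.0);
      double skox = std::sqrt(kox > 0 ? kox : 0.0);
      double sepz = std::sqrt(epz > 0 ? epz : 0.0);
      // 12 mutually independent Gaussian draws, one per channel
      double gx = sq_c1 * rng::ZIG.draw(g) + sq_c2 * rng::ZIG.draw(g) -
                  sV2 * rng::ZIG.draw(g) + sV3 * rng::ZIG.draw(g) +
                  skfy * rng::ZIG.draw(g) - skox * rng::ZIG.draw(g);
      double gy = sV2 * rng::ZIG.draw(g) - sV3 * rng::ZIG.draw(g) -
                  skfy * rng::ZIG.draw(g);
      double gz = sq_c10 * rng::ZIG.draw(g) - sV5 * rng::ZIG.draw(g) -
                  sepz * rng::ZIG.draw(g);
      x += amp * gx;
      y += amp * gy;
      z += amp * gz;
    }
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (z < 0) z = 0;
    if (!(std::isfinite(x) && std::isfinite(y) && std::isfinite(z)))
      stop("integration failure (non-finite state) at t = %f min", s * dt);
    if (s > nb && (s - nb) % si == 0 && k < nrec) {
      out(k, 0) = s * dt;
      out(k, 1) = x;
      out(k, 2) = y;
      out(k, 3) = z;
      ++k;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Largest Lyapunov exponent (Benettin two-trajectory renormalization)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".benettin_lyap_cpp")]]
double benettin_lyap_cpp(NumericVector params, NumericVector init, double dt,
                         double transient, double horizon,
                         double renorm_interval, double d0) {
  HouartParams q = parse_params(params);
  double x = init[0], y = init[1], z = init[2];
  long ntrans = (long)std::lround(transient / dt);
  for (long s = 0; s < ntrans; ++s) {
    rk4_step(q, dt, x, y, z);
    if (!(std::isfinite(x) && std::isfinite(y) && std::isfinite(z)))
      stop("reference orbit diverged during transient");
  }
  double px = x + d0, py = y, pz = z;
  long nren = (long)std::lround(renorm_interval / dt);
  long nblocks = (long)std::lround(horizon / renorm_interval);
  double acc = 0.0;
  for (long b = 0; b < nblocks; ++b) {
    for (long s = 0; s < nren; ++s) {
      rk4_step(q, dt, x, y, z);
      rk4_step(q, dt, px, py, pz);
    }
    if (!(std::isfinite(x) && std::isfinite(px)))
      stop("orbit diverged during Lyapunov estimation");
    double dx = px - x, dy = py - y, dz = pz - z;
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= 0) d = 1e-300;
    acc += std::log(d / d0);
    double f = d0 / d;
    px = x + dx * f;
    py = y + dy * f;
    pz = z + dz * f;
  }
  return acc / (nblocks * renorm_interval);
}
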