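// Langevin + well-tempered metadynamics + stochastic-resetting engine.
//
// Single 2D particle, BAOAB splitting, committor-style stop criterion on x,
// optional bias along a linear CV s = x cos(theta) + y sin(theta), optional
// Poisson or sharp resetting (bias zeroed at every reset).
//
// Units: lengths in Angstrom, time in fs, mass in g/mol.  Potential and bias
// energies are expressed in units of kBT at 300 K; the mechanical energy unit
// is kB*300K = 2.4943e-4 g A^2 fs^-2 mol^-1.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double KB_KJ_MOL_K = 8.31446261815324e-3; // kJ/mol/K
static const double KJ_MOL_TO_MECH = 1e-4;             // g A^2 fs^-2 mol^-1 per kJ/mol
static const double EUNIT300 = KB_KJ_MOL_K * 300.0 * KJ_MOL_TO_MECH; // kBT(300K), mech

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64; one independent stream per
// purpose (dynamics noise, velocity initialisation, reset times) so that
// switching resetting on or off leaves the dynamics stream untouched.

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];
  void seed(uint64_t x) {
    SplitMix64 sm(x);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1]
  double unif() { return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0); }
  // standard normal, polar Box-Muller with cache
  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f; have_spare = true;
    return u * f;
  }
  double rexp(double mean) { return -mean * std::log(unif()); }
};

static uint64_t stream_seed(double base_seed, double traj_id, uint64_t purpose) {
  uint64_t b = (uint64_t)((int64_t)base_seed);
  uint64_t t = (uint64_t)((int64_t)traj_id);
  SplitMix64 sm(b ^ (t * 0x9E3779B97F4A7C15ULL) ^ (purpose * 0xD1B54A32D192ED03ULL));
  sm.next();
  return sm.next();
}

// ---------------------------------------------------------------------------
// Potentials (energies in kBT, gradients in kBT/A)

enum Family { TWO_WELLS = 0, FARADJIAN_ELBER = 1, HARMONIC1D = 2 };

struct Potential {
  int family;
  // two_wells: A1, A2, B, C
  // faradjian_elber: A1, A2, B, sigma1, sigma2, y_scale
  // harmonic1d: k (kBT/A^2) on x only
  double p[6];

  inline void grad(double x, double y, double &gx, double &gy) const {
    switch (family) {
    case TWO_WELLS: {
      const double A1 = p[0], A2 = p[1], B = p[2], C = p[3];
      gx = 2.0 * A1 * x - 2.0 * B * C * x * std::exp(-C * x * x);
      gy = 2.0 * A2 * y;
      break;
    }
    case FARADJIAN_ELBER: {
      const double A1 = p[0], A2 = p[1], B = p[2];
      const double s1 = p[3], s2 = p[4], ys = p[5];
      const double yp = ys * y;
      const double ex = std::exp(-x * x / (s1 * s1));
      const double ey = std::exp(-yp * yp / (s2 * s2));
      gx = 6.0 * A1 * x * x * x * x * x
         - 2.0 * A2 * x / (s1 * s1) * ex * (1.0 - B * ey);
      // d/dy = d/dyp * ys
      const double gyp = 6.0 * A1 * yp * yp * yp * yp * yp
         + A2 * ex * B * ey * 2.0 * yp / (s2 * s2);
      gy = ys * gyp;
      break;
    }
    default: { // HARMONIC1D
      gx = p[0] * x;
      gy = 0.0;
    }
    }
  }

  inline double energy(double x, double y) const {
    switch (family) {
    case TWO_WELLS: {
      const double A1 = p[0], A2 = p[1], B = p[2], C = p[3];
      return A1 * x * x + A2 * y * y + B * std::exp(-C * x * x);
    }
    case FARADJIAN_ELBER: {
      const double A1 = p[0], A2 = p[1], B = p[2];
      const double s1 = p[3], s2 = p[4], ys = p[5];
      const double yp = ys * y;
      const double x2 = x * x, yp2 = yp * yp;
      return A1 * (x2 * x2 * x2 + yp2 * yp2 * yp2)
           + A2 * std::exp(-x2 / (s1 * s1))
             * (1.0 - B * std::exp(-yp2 / (s2 * s2)));
    }
    default:
      return 0.5 * p[0] * x * x;
    }
  }
};

// [[Rcpp::export]]
NumericVector potential_energy_cpp(int family, NumericVector par,
                                   NumericVector x, NumericVector y) {
  Potential pot; pot.family = family;
  for (int i = 0; i < par.size() && i < 6; ++i) pot.p[i] = par[i];
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = pot.energy(x[i], y[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix potential_grad_cpp(int family, NumericVector par,
                                 NumericVector x, NumericVector y) {
  Potential pot; pot.family = family;
  for (int i = 0; i < par.size() && i < 6; ++i) pot.p[i] = par[i];
  R_xlen_t n = x.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    double gx, gy;
    pot.grad(x[i], y[i], gx, gy);
    out(i, 0) = gx; out(i, 1) = gy;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Metadynamics bias grid along the CV.  Value and analytic derivative of the
// hill sum are both accumulated on the grid (PLUMED-style) so that energy and
// force queries are O(1); hills are truncated at 6 sigma.

struct BiasGrid {
  double gmin, gmax, spacing;
  int n;
  std::vector<double> v;   // kBT
  std::vector<double> dv;  // kBT/A
  int lo_touched, hi_touched;

  void init(double a, double b, double h) {
    gmin = a; gmax = b; spacing = h;
    n = (int)std::floor((b - a) / h + 0.5) + 1;
    v.assign(n, 0.0); dv.assign(n, 0.0);
    lo_touched = n; hi_touched = -1;
  }
  void clear() {
    if (hi_touched >= lo_touched) {
      std::fill(v.begin() + lo_touched, v.begin() + hi_touched + 1, 0.0);
      std::fill(dv.begin() + lo_touched, dv.begin() + hi_touched + 1, 0.0);
    }
    lo_touched = n; hi_touched = -1;
  }
  inline double value(double s) const {
    double u = (s - gmin) / spacing;
    int i = (int)u;
    if (u < 0.0 || i >= n - 1) stop("CV value %f outside the bias grid [%f, %f]", s, gmin, gmax);
    double f = u - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
  inline double deriv(double s) const {
    double u = (s - gmin) / spacing;
    int i = (int)u;
    if (u < 0.0 || i >= n - 1) stop("CV value %f outside the bias grid [%f, %f]", s, gmin, gmax);
    double f = u - i;
    return dv[i] * (1.0 - f) + dv[i + 1] * f;
  }
  // add Gaussian hill w * exp(-(s-c)^2 / (2 sig^2)), truncated at 6 sigma
  void add_hill(double c, double sig, double w) {
    double cut = 6.0 * sig;
    int i0 = (int)std::ceil((c - cut - gmin) / spacing);
    int i1 = (int)std::floor((c + cut - gmin) / spacing);
    if (i0 < 0) i0 = 0;
    if (i1 > n - 1) i1 = n - 1;
    const double inv2s2 = 1.0 / (2.0 * sig * sig);
    const double invs2 = 1.0 / (sig * sig);
    for (int i = i0; i <= i1; ++i) {
      double d = gmin + i * spacing - c;
      double g = w * std::exp(-d * d * inv2s2);
      v[i] += g;
      dv[i] += -g * d * invs2;
    }
    if (i0 < lo_touched) lo_touched = i0;
    if (i1 > hi_touched) hi_touched = i1;
  }
};

// ---------------------------------------------------------------------------
// Main driver.
//
// stop_type: 0 -> x <= c1 ; 1 -> x < c1 ; 2 -> c1 < x < c2
// reset_mode: 0 none ; 1 Poisson(rate_ns) ; 2 sharp(period_ns)

// [[Rcpp::export]]
List run_trajectory_cpp(int family, NumericVector pot_par,
                        double x0, double y0,
                        double temperature, double mass, double gamma,
                        double dt,
                        int stop_type, double stop_c1, double stop_c2,
                        bool metad_on, double theta, double height,
                        double sigma, double bias_factor, int pace,
                        double grid_min, double grid_max, double grid_spacing,
                        int reset_mode, double reset_rate_ns,
                        double reset_period_ns,
                        double max_steps,
                        double base_seed, double traj_id,
                        int sample_every = 0,
                        bool return_hills = false,
                        bool return_bias_grid = false,
                        bool record_segments = false) {
  Potential pot; pot.family = family;
  for (int i = 0; i < pot_par.size() && i < 6; ++i) pot.p[i] = pot_par[i];

  const double kBT_mech = KB_KJ_MOL_K * temperature * KJ_MOL_TO_MECH;
  const double eunit = EUNIT300; // potential/bias energies are kBT(300 K)
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(kBT_mech / mass * (1.0 - c1 * c1));
  const double vsd = std::sqrt(kBT_mech / mass);
  const double half_dt = 0.5 * dt;

  Xoshiro256pp rng_dyn, rng_vel, rng_rst;
  rng_dyn.seed(stream_seed(base_seed, traj_id, 1));
  rng_vel.seed(stream_seed(base_seed, traj_id, 2));
  rng_rst.seed(stream_seed(base_seed, traj_id, 3));

  const double ct = std::cos(theta), st = std::sin(theta);

  BiasGrid grid;
  if (metad_on) grid.init(grid_min, grid_max, grid_spacing);

  std::vector<double> hills_t, hills_c, hills_w;
  std::vector<double> seg_dur, seg_exp;
  std::vector<int> seg_hit;

  double x = x0, y = y0;
  double vx = vsd * rng_vel.norm(), vy = vsd * rng_vel.norm();
  double gx, gy; pot.grad(x, y, gx, gy);
  double fx = -gx * eunit, fy = -gy * eunit;
  if (metad_on) {
    double s = x * ct + y * st;
    double db = grid.deriv(s) * eunit;
    fx -= db * ct; fy -= db * st;
  }

  auto stop_hit = [&](double xx) -> bool {
    switch (stop_type) {
    case 0: return xx <= stop_c1;
    case 1: return xx < stop_c1;
    default: return xx > stop_c1 && xx < stop_c2;
    }
  };

  // degenerate input: criterion already true at initialisation
  if (stop_hit(x)) {
    return List::create(_["fpt_steps"] = 0.0, _["n_resets"] = 0,
                        _["censored"] = false,
                        _["segments"] = R_NilValue, _["hills"] = R_NilValue,
                        _["bias_grid"] = R_NilValue, _["samples"] = R_NilValue);
  }

  double elapsed = 0.0;     // steps, total (never reset)
  double seg_step = 0.0;    // steps since last reset
  double seg_I_fs = 0.0;    // exposure integral, fs
  long long n_resets = 0;
  bool censored = false, transited = false;

  // next reset, in segment steps
  double next_reset = R_PosInf;
  auto draw_reset = [&]() {
    if (reset_mode == 1) {
      double mean_fs = 1.0 / (reset_rate_ns * 1e-6);
      next_reset = std::ceil(rng_rst.rexp(mean_fs) / dt);
      if (next_reset < 1.0) next_reset = 1.0;
    } else if (reset_mode == 2) {
      next_reset = std::ceil(reset_period_ns * 1e6 / dt);
      if (next_reset < 1.0) next_reset = 1.0;
    } else {
      next_reset = R_PosInf;
    }
  };
  draw_reset();

  std::vector<double> samp;
  auto take_sample = [&]() {
    samp.push_back(elapsed * dt); samp.push_back(x); samp.push_back(y);
    samp.push_back(vx); samp.push_back(vy);
  };
  if (sample_every > 0) take_sample();

  while (elapsed < max_steps) {
    // BAOAB step (B A O A, force refresh, closing B)
    vx += half_dt * fx / mass; vy += half_dt * fy / mass;
    x += half_dt * vx; y += half_dt * vy;
    vx = c1 * vx + c2 * rng_dyn.norm();
    vy = c1 * vy + c2 * rng_dyn.norm();
    x += half_dt * vx; y += half_dt * vy;
    pot.grad(x, y, gx, gy);
    fx = -gx * eunit; fy = -gy * eunit;

    elapsed += 1.0; seg_step += 1.0;

    double s = 0.0;
    if (metad_on) {
      s = x * ct + y * st;
      // exposure integral for iMetaD rescaling, using the bias before any
      // deposition at this step
      double vb = grid.value(s);
      seg_I_fs += dt * std::exp(vb);
      // hill deposition on the per-segment clock
      if (pace > 0 && ((long long)seg_step % pace) == 0) {
        double w = height * std::exp(-vb / (bias_factor - 1.0));
        grid.add_hill(s, sigma, w);
        if (return_hills) {
          hills_t.push_back(elapsed * dt);
          hills_c.push_back(s);
          hills_w.push_back(w);
        }
      }
      double db = grid.deriv(s) * eunit;
      fx -= db * ct; fy -= db * st;
    }

    // closing half kick with the refreshed total force
    vx += half_dt * fx / mass; vy += half_dt * fy / mass;

    if (sample_every > 0 && ((long long)elapsed % sample_every) == 0)
      take_sample();

    if (!std::isfinite(x) || !std::isfinite(vx) ||
        !std::isfinite(y) || !std::isfinite(vy))
      stop("non-finite state at step %.0f; timestep too large for the forces", elapsed);

    // first passage wins over a reset scheduled for the same step
    if (stop_hit(x)) {
      transited = true;
      if (record_segments) {
        seg_dur.push_back(seg_step);
        seg_exp.push_back(metad_on ? seg_I_fs : seg_step * dt);
        seg_hit.push_back(1);
      }
      break;
    }

    if (seg_step >= next_reset) {
      if (record_segments) {
        seg_dur.push_back(seg_step);
        seg_exp.push_back(metad_on ? seg_I_fs : seg_step * dt);
        seg_hit.push_back(0);
      }
      x = x0; y = y0;
      vx = vsd * rng_vel.norm(); vy = vsd * rng_vel.norm();
      if (metad_on) grid.clear();
      seg_step = 0.0; seg_I_fs = 0.0;
      ++n_resets;
      draw_reset();
      pot.grad(x, y, gx, gy);
      fx = -gx * eunit; fy = -gy * eunit;
      // bias force is zero right after a reset (grid cleared)
    }
  }

  if (!transited) {
    censored = true;
    if (record_segments && seg_step > 0) {
      seg_dur.push_back(seg_step);
      seg_exp.push_back(metad_on ? seg_I_fs : seg_step * dt);
      seg_hit.push_back(0);
    }
  }

  List out = List::create(
    _["fpt_steps"] = transited ? elapsed : NA_REAL,
    _["n_resets"] = (double)n_resets,
    _["censored"] = censored,
    _["segments"] = R_NilValue,
    _["hills"] = R_NilValue,
    _["bias_grid"] = R_NilValue,
    _["samples"] = R_NilValue);

  if (record_segments) {
    size_t m = seg_dur.size();
    NumericMatrix segs(m, 3);
    for (size_t i = 0; i < m; ++i) {
      segs(i, 0) = seg_dur[i];
      segs(i, 1) = seg_exp[i] * 1e-6; // fs -> ns
      segs(i, 2) = seg_hit[i];
    }
    colnames(segs) = CharacterVector::create("duration_steps", "rescaled_ns",
                                             "transition");
    out["segments"] = segs;
  }
  if (return_hills) {
    size_t m = hills_t.size();
    NumericMatrix hm(m, 3);
    for (size_t i = 0; i < m; ++i) {
      hm(i, 0) = hills_t[i]; hm(i, 1) = hills_c[i]; hm(i, 2) = hills_w[i];
    }
    colnames(hm) = CharacterVector::create("time_fs", "center", "height");
    out["hills"] = hm;
  }
  if (return_bias_grid && metad_on) {
    NumericMatrix bg(grid.n, 3);
    for (int i = 0; i < grid.n; ++i) {
      bg(i, 0) = grid.gmin + i * grid.spacing;
      bg(i, 1) = grid.v[i];
      bg(i, 2) = grid.dv[i];
    }
    colnames(bg) = CharacterVector::create("cv", "bias", "dbias");
    out["bias_grid"] = bg;
  }
  if (sample_every > 0) {
    size_t m = samp.size() / 5;
    NumericMatrix sm(m, 5);
    for (size_t i = 0; i < m; ++i)
      for (int j = 0; j < 5; ++j) sm(i, j) = samp[5 * i + j];
    colnames(sm) = CharacterVector::create("time_fs", "x", "y", "vx", "vy");
    out["samples"] = sm;
  }
  return out;
}

// Maxwell-Boltzmann velocity draws from the engine's own velocity stream,
// exposed so that the R-level contract can be tested against the exact
// generator the integrator uses.

// [[Rcpp::export]]
NumericMatrix sample_velocities_cpp(int n, double temperature, double mass,
                                    double base_seed, double traj_id) {
  const double vsd = std::sqrt(KB_KJ_MOL_K * temperature * KJ_MOL_TO_MECH / mass);
  Xoshiro256pp rng;
  rng.seed(stream_seed(base_seed, traj_id, 2));
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = vsd * rng.norm();
    out(i, 1) = vsd * rng.norm();
  }
  return out;
}
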