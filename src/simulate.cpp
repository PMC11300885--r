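#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (PCG32 + Box-Muller). The dynamical noise must be
// reproducible from an integer seed independently of R's global RNG state,
// so realizations can be re-generated bit-identically from a run manifest.
// ---------------------------------------------------------------------------

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = static_cast<uint32_t>(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = static_cast<uint32_t>(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform in (0, 1): never exactly 0 so log() below is safe
  double runif() {
    return (static_cast<double>(next()) + 0.5) * (1.0 / 4294967296.0);
  }
};

struct Gauss {
  Pcg32 rng;
  bool has_spare;
  double spare;
  Gauss(uint64_t seed) : rng(seed), has_spare(false), spare(0.0) {}
  double next() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = rng.runif();
    double u2 = rng.runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// splitmix64: used for deriving independent child seeds from a master seed
// and a label hash.
static uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
NumericVector cpp_seed_tree(double master_seed, CharacterVector labels) {
  int n = labels.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string lab = as<std::string>(labels[i]);
    uint64_t h = static_cast<uint64_t>(master_seed);
    for (size_t j = 0; j < lab.size(); ++j) {
      h = splitmix64(h ^ static_cast<uint64_t>(static_cast<unsigned char>(lab[j])) << (8 * (j % 8)));
    }
    h = splitmix64(h);
    // keep child seeds positive and below 2^31 so they are valid R integers
    out[i] = static_cast<double>(h % 2147483647ULL) + 1.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// PRC evaluation: 0 = sine, 1 = second-order Fourier series (g0..g4),
// 2 = tabulated 2*pi-periodic curve with linear interpolation.
// ---------------------------------------------------------------------------
struct Prc {
  int kind;
  NumericVector g;      // Fourier coefficients when kind == 1
  NumericVector tab_y;  // table values on a uniform grid over [0, 2pi)
  double inv_step;
  int n_tab;
  Prc(int kind_, NumericVector g_, NumericVector tab_y_)
      : kind(kind_), g(g_), tab_y(tab_y_) {
    n_tab = tab_y.size();
    inv_step = n_tab > 0 ? n_tab / (2.0 * M_PI) : 0.0;
  }
  inline double eval(double theta, double s, double c) const {
    if (kind == 0) return s;
    if (kind == 1) {
      double c2 = c * c - s * s;
      double s2 = 2.0 * s * c;
      return g[0] + g[1] * c + g[2] * s + g[3] * c2 + g[4] * s2;
    }
    // tabulated, linear interpolation on the periodic grid
    double x = theta - 2.0 * M_PI * std::floor(theta / (2.0 * M_PI));
    double u = x * inv_step;
    int i0 = static_cast<int>(u);
    if (i0 >= n_tab) i0 = n_tab - 1;
    double w = u - i0;
    int i1 = (i0 + 1) % n_tab;
    return tab_y[i0] * (1.0 - w) + tab_y[i1] * w;
  }
};

// ---------------------------------------------------------------------------
// Full coupled simulation: N phase oscillators (Euler-Maruyama) + three
// vesicle pools (exact exponential replenishment between pulses, impulsive
// depletion at pulse times) + dominant-pool coupling strength.
//
// Per-step event order (documented package convention):
//   1. if the step is a pulse step: deplete each pool by its (amplitude
//      scaled) release probability,
//   2. compute k(t) = kmu * max(M_pool * n_pool) from the just-updated pools,
//   3. advance phases using that k and the pulse's stimulation intensity,
//   4. replenish pools continuously over dt with the exact exponential map.
//
// pulse_steps: sorted 0-based step indices at which a stimulation pulse
// occurs; pulse_ifact: amplitude factor of each pulse (scales both the
// stimulation intensity I and the per-pulse release probabilities).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate(NumericVector omega,       // rad/s, length N
                  NumericVector theta0,      // rad, length N
                  double dt,
                  int n_steps,
                  double kmu,
                  double zeta,
                  double I,
                  NumericVector fcoef,       // f0..f4
                  int prc_kind,
                  NumericVector prc_g,
                  NumericVector prc_tab,
                  NumericVector pool_tau,    // RRP, RP, RtP
                  NumericVector pool_p,
                  NumericVector pool_M,
                  NumericVector n_init,      // initial occupancies
                  IntegerVector pulse_steps,
                  NumericVector pulse_ifact,
                  double noise_seed,
                  int record_stride) {
  const int N = omega.size();
  const double twopi = 2.0 * M_PI;
  const double sqrtdt = std::sqrt(dt);
  const double f0 = fcoef[0], f1 = fcoef[1], f2 = fcoef[2],
               f3 = fcoef[3], f4 = fcoef[4];

  std::vector<double> theta(theta0.begin(), theta0.end());
  double n_pool[3] = { n_init[0], n_init[1], n_init[2] };
  double repl[3];
  for (int p = 0; p < 3; ++p) repl[p] = std::exp(-dt / pool_tau[p]);

  Gauss gauss(static_cast<uint64_t>(noise_seed));
  Prc prc(prc_kind, prc_g, prc_tab);

  const int n_rec = (n_steps + record_stride - 1) / record_stride;
  NumericVector rec_t(n_rec), rec_re(n_rec), rec_im(n_rec), rec_k(n_rec),
      rec_n1(n_rec), rec_n2(n_rec), rec_n3(n_rec);
  IntegerVector rec_dom(n_rec), rec_pulse(n_rec);

  int next_pulse_idx = 0;
  const int n_pulses = pulse_steps.size();
  int rec_i = 0;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;

    // 1. impulsive depletion + stimulation intensity for this step
    double I_t = 0.0;
    bool is_pulse = false;
    if (next_pulse_idx < n_pulses && pulse_steps[next_pulse_idx] == s) {
      double ifact = pulse_ifact[next_pulse_idx];
      for (int p = 0; p < 3; ++p) n_pool[p] *= (1.0 - pool_p[p] * ifact);
      I_t = I * ifact;
      is_pulse = true;
      ++next_pulse_idx;
    }

    // 2. dominant-pool coupling strength (ties break toward the more
    // readily releasable pool, i.e. the lower index)
    int dom = 0;
    double best = pool_M[0] * n_pool[0];
    for (int p = 1; p < 3; ++p) {
      double v = pool_M[p] * n_pool[p];
      if (v > best) { best = v; dom = p; }
    }
    double k_t = kmu * best;

    // circular moments (used both for recording Z and for the O(N)
    // mean-field coupling drive)
    double C1 = 0.0, S1 = 0.0, C2 = 0.0, S2 = 0.0;
    std::vector<double> cs(N), sn(N);
    for (int i = 0; i < N; ++i) {
      double c = std::cos(theta[i]);
      double si = std::sin(theta[i]);
      cs[i] = c; sn[i] = si;
      C1 += c; S1 += si;
      C2 += c * c - si * si;
      S2 += 2.0 * si * c;
    }
    C1 /= N; S1 /= N; C2 /= N; S2 /= N;

    // 3. record the pre-update state at this grid time
    if (s % record_stride == 0) {
      rec_t[rec_i] = t;
      rec_re[rec_i] = C1;
      rec_im[rec_i] = S1;
      rec_k[rec_i] = k_t;
      rec_n1[rec_i] = n_pool[0];
      rec_n2[rec_i] = n_pool[1];
      rec_n3[rec_i] = n_pool[2];
      rec_dom[rec_i] = dom + 1;
      rec_pulse[rec_i] = is_pulse ? 1 : 0;
      if (!std::isfinite(C1) || !std::isfinite(S1)) {
        stop("numerical instability: non-finite phases at t = %f "
             "(kmu = %f, zeta = %f, I = %f)", t, kmu, zeta, I);
      }
      ++rec_i;
    }

    // 4. Euler-Maruyama phase update with the mean-field drive
    for (int i = 0; i < N; ++i) {
      double c = cs[i], si = sn[i];
      double c2 = c * c - si * si;
      double s2 = 2.0 * si * c;
      double drive = f0
        + f1 * (C1 * c + S1 * si)
        + f2 * (S1 * c - C1 * si)
        + f3 * (C2 * c2 + S2 * s2)
        + f4 * (S2 * c2 - C2 * s2);
      double g_i = (I_t != 0.0) ? prc.eval(theta[i], si, c) : 0.0;
      double th = theta[i]
        + (omega[i] + k_t * drive + I_t * g_i) * dt
        + zeta * sqrtdt * gauss.next();
      // keep phases wrapped so trig stays accurate over long runs
      theta[i] = th - twopi * std::floor(th / twopi);
    }

    // 5. exact exponential replenishment over dt
    for (int p = 0; p < 3; ++p) n_pool[p] = 1.0 - (1.0 - n_pool[p]) * repl[p];
  }

  NumericVector theta_out(theta.begin(), theta.end());
  return List::create(
      _["time_s"] = rec_t, _["re_z"] = rec_re, _["im_z"] = rec_im,
      _["k"] = rec_k, _["n_rrp"] = rec_n1, _["n_rp"] = rec_n2,
      _["n_rtp"] = rec_n3, _["dominant_pool"] = rec_dom,
      _["pulse"] = rec_pulse, _["theta_final"] = theta_out);
}

// Standard normal draws from the package RNG; exposed so R code (initial
// phases, natural frequencies, measurement noise) shares one deterministic
// generator with the C++ core.
// [[Rcpp::export]]
NumericVector cpp_rnorm_seeded(int n, double seed) {
  Gauss gauss(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gauss.next();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_runif_seeded(int n, double seed) {
  Pcg32 rng(static_cast<uint64_t>(seed) ^ 0xA5A5A5A5ULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.runif();
  return out;
}
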