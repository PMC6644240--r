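#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64). Each trial gets its
// own stream keyed by (seed, trial index) only, so the same seed yields the
// same noise for a trial regardless of congruency or model parameters:
// this is what makes common-random-number objectives deterministic and lets
// a zeta = 0 model produce bit-identical congruent/incongruent output.
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  return mix64(x);
}

// starting state for trial i: double-hashed so that different trials land
// in disjoint regions of the Weyl orbit (a plain xor with a multiple of the
// Weyl constant makes trial orbits overlap and correlates their noise)
static inline uint64_t trial_state(uint64_t seed, uint64_t i) {
  return mix64(mix64(seed + 0xD2B74407B1CE6E93ULL) ^
               mix64(i + 0x8BB84B93962EACC9ULL));
}

struct TrialRng {
  uint64_t s;
  bool has_cached;
  double cached;
  explicit TrialRng(uint64_t seed) : s(seed), has_cached(false), cached(0.0) {}
  // uniform on (0, 1]
  double unif_pos() {
    uint64_t z = splitmix64(s);
    return ((z >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform on [0, 1)
  double unif() {
    uint64_t z = splitmix64(s);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
  // standard normal via Box-Muller (cached pair)
  double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = unif_pos(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586 * u2;
    cached = r * std::sin(th);
    has_cached = true;
    return r * std::cos(th);
  }
};

// expected automatic activation E[X_a(t)] = zeta * (t e / ((alpha-1) tau))^(alpha-1) * exp(-t/tau)
static inline double activation(double t, double zeta, double alpha, double tau) {
  if (t <= 0.0) return 0.0;
  double tmax = (alpha - 1.0) * tau;
  return zeta * std::exp((alpha - 1.0) * (std::log(t) + 1.0 - std::log(tmax)) - t / tau);
}

// [[Rcpp::export]]
NumericVector dmc_activation_cpp(NumericVector t, double zeta, double alpha, double tau) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = activation(t[i], zeta, alpha, tau);
  return out;
}

// Simulate n DMC trials: Euler scheme on X_k = X_{k-1} + mu_c dt
// +/- [E[X_a(k dt)] - E[X_a((k-1) dt)]] + sigma sqrt(dt) N(0,1),
// absorbing at +a (correct) and -a (error); residual ~ N(ter, sr) with
// negative draws rejected. Unabsorbed trials are flagged and scored as
// errors with decision time = max_time.
// [[Rcpp::export]]
List dmc_simulate_cpp(double a, double mu_c, double zeta, double alpha,
                      double tau, double ter, double sr, bool congruent,
                      int n, double dt, double sigma, double max_time,
                      double seed) {
  int n_steps = (int)std::ceil(max_time / dt - 1e-9);
  double sign = congruent ? 1.0 : -1.0;
  double sdt = sigma * std::sqrt(dt);

  // telescoping increments of the expected automatic activation
  std::vector<double> inc(n_steps);
  double prev = 0.0;
  for (int k = 0; k < n_steps; ++k) {
    double cur = activation((k + 1) * dt, zeta, alpha, tau);
    inc[k] = cur - prev;
    prev = cur;
  }

  NumericVector decision(n), residual(n), rt(n);
  LogicalVector correct(n), absorbed(n);
  uint64_t s0 = (uint64_t)seed;

  for (int i = 0; i < n; ++i) {
    TrialRng rng(trial_state(s0, (uint64_t)(i + 1)));
    double X = 0.0, D = max_time;
    bool corr = false, abs_flag = false;
    for (int k = 0; k < n_steps; ++k) {
      X += mu_c * dt + sign * inc[k] + sdt * rng.norm();
      if (X >= a)  { corr = true;  abs_flag = true; D = (k + 1) * dt; break; }
      if (X <= -a) { corr = false; abs_flag = true; D = (k + 1) * dt; break; }
    }
    double R;
    if (sr <= 0.0) {
      R = ter;
    } else {
      int tries = 0;
      do { R = ter + sr * rng.norm(); ++tries; } while (R < 0.0 && tries < 10000);
      if (R < 0.0) R = 0.0;
    }
    decision[i] = D;
    residual[i] = R;
    rt[i] = D + R;
    correct[i] = abs_flag ? corr : false;
    absorbed[i] = abs_flag;
  }

  return List::create(_["decision"] = decision, _["residual"] = residual,
                      _["rt"] = rt, _["correct"] = correct,
                      _["absorbed"] = absorbed);
}
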