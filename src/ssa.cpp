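#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Counter-based substream RNG (splitmix64).  Each trajectory owns a stream
// keyed by (seed, time index, trajectory index), so datasets are reproducible
// and enlarging N or adding time points never reshuffles earlier trajectories.

static inline uint64_t sm64_next(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// uniform in (0,1); never exactly 0 or 1, safe for log()
static inline double sm64_unif(uint64_t &s) {
  return (double)((sm64_next(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline uint64_t stream_init(int seed, int time_idx, int traj) {
  uint64_t s = (uint64_t)(uint32_t)seed;
  s = s * 0x9E3779B97F4A7C15ULL + 0x165667B19E3779F9ULL;
  s ^= ((uint64_t)(uint32_t)time_idx) << 32;
  s = s * 0xBF58476D1CE4E5B9ULL + (uint64_t)(uint32_t)traj;
  sm64_next(s);
  sm64_next(s);
  return s;
}

// mass-action propensity: rate * product of falling-factorial reactant
// combinations (x for order 1, x*(x-1)/2 for a homodimer pair)
static inline double propensity_at(const IntegerMatrix &reac,
                                   const NumericVector &rates,
                                   const std::vector<int> &x, int j, int n) {
  double a = rates[j];
  for (int i = 0; i < n; ++i) {
    int r = reac(j, i);
    if (r == 1) {
      a *= x[i];
    } else if (r == 2) {
      a *= 0.5 * (double)x[i] * (double)(x[i] - 1);
    }
    if (a <= 0.0) return 0.0;
  }
  return a;
}

// Gillespie direct method from t = 0 to t_end, in place
static void ssa_run(const IntegerMatrix &reac, const IntegerMatrix &net,
                    const NumericVector &rates, std::vector<int> &x,
                    double t_end, uint64_t &s) {
  const int m = reac.nrow(), n = reac.ncol();
  std::vector<double> a(m);
  double t = 0.0;
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      a[j] = propensity_at(reac, rates, x, j, n);
      a0 += a[j];
    }
    if (a0 <= 0.0) break;
    t += -std::log(sm64_unif(s)) / a0;
    if (t > t_end) break;
    double u = sm64_unif(s) * a0, c = 0.0;
    int jsel = m - 1;
    for (int j = 0; j < m; ++j) {
      c += a[j];
      if (u <= c) { jsel = j; break; }
    }
    for (int i = 0; i < n; ++i) x[i] += net(jsel, i);
  }
}

// [[Rcpp::export]]
IntegerVector ssa_final_state_cpp(IntegerMatrix reac, IntegerMatrix net,
                                  NumericVector rates, IntegerVector x0,
                                  double t_end, int seed, int time_idx,
                                  int traj) {
  const int n = reac.ncol();
  std::vector<int> x(x0.begin(), x0.end());
  uint64_t s = stream_init(seed, time_idx, traj);
  ssa_run(reac, net, rates, x, t_end, s);
  return IntegerVector(x.begin(), x.begin() + n);
}

// One fresh trajectory per (time point, sample): across-time samples are
// statistically independent, as the multi-time GMM objective assumes.
// [[Rcpp::export]]
List ssa_snapshots_cpp(IntegerMatrix reac, IntegerMatrix net,
                       NumericVector rates, IntegerVector x0,
                       NumericVector times, IntegerVector observed0,
                       int n_samples, int seed) {
  const int n = reac.ncol();
  const int T = times.size(), K = observed0.size();
  List out(T);
  for (int ti = 0; ti < T; ++ti) {
    IntegerMatrix Y(n_samples, K);
    for (int ell = 0; ell < n_samples; ++ell) {
      std::vector<int> x(x0.begin(), x0.end());
      uint64_t s = stream_init(seed, ti, ell);
      ssa_run(reac, net, rates, x, times[ti], s);
      for (int k = 0; k < K; ++k) Y(ell, k) = x[observed0[k]];
      if ((ell & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
    out[ti] = Y;
  }
  return out;
}
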