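// Rejection-free (Gillespie / BKL) kinetic Monte Carlo over a dense rate
// matrix. Each trajectory owns an mt19937_64 stream seeded from
// (master seed, trajectory index), so results do not depend on execution
// order. Uniform and exponential variates are generated by inverse
// transform rather than std:: distributions to keep the draws
// platform-deterministic.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline std::uint64_t mix(std::uint64_t z) {
  // splitmix64 finaliser
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double u01(std::mt19937_64 &g) {
  // (0, 1]: never 0 so -log(u) is finite
  return (static_cast<double>(g() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
}

struct NetTables {
  int n;
  std::vector<double> total;               // escape rate per state
  std::vector<std::vector<int>> nbr;       // successor indices (0-based)
  std::vector<std::vector<double>> cum;    // cumulative rates
};

static NetTables build_tables(const NumericMatrix &K) {
  NetTables t;
  t.n = K.nrow();
  t.total.assign(t.n, 0.0);
  t.nbr.resize(t.n);
  t.cum.resize(t.n);
  for (int i = 0; i < t.n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < t.n; ++j) {
      if (i == j) continue;
      double k = K(i, j);
      if (k > 0.0) {
        acc += k;
        t.nbr[i].push_back(j);
        t.cum[i].push_back(acc);
      }
    }
    t.total[i] = acc;
  }
  return t;
}

static inline int pick_successor(const NetTables &t, int s, double u) {
  const std::vector<double> &c = t.cum[s];
  double x = u * t.total[s];
  // binary search for first cum >= x
  int lo = 0, hi = static_cast<int>(c.size()) - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (c[mid] < x) lo = mid + 1; else hi = mid;
  }
  return t.nbr[s][lo];
}

// Batch first-passage sampler. starts: 1-based initial states per
// trajectory. is_target marks the target absorbing set; any other state
// with zero escape rate terminates the trajectory as a competing trap.
// group: 1-based dwell-aggregation group per state (0 = do not record).
// Returns per-trajectory FPT (time to termination), terminal state,
// censoring flag (max_time exceeded), step count, and the dwell matrix
// (n_traj x n_groups) when n_groups > 0.
// [[Rcpp::export]]
List kmc_batch(const NumericMatrix &K, const IntegerVector &starts,
               const LogicalVector &is_target, double max_time,
               double seed, const IntegerVector &group, int n_groups) {
  NetTables t = build_tables(K);
  int ntraj = starts.size();
  NumericVector fpt(ntraj);
  IntegerVector terminal(ntraj);
  LogicalVector censored(ntraj);
  IntegerVector steps(ntraj);
  NumericMatrix dwell = (n_groups > 0) ? NumericMatrix(ntraj, n_groups)
                                       : NumericMatrix(0, 0);
  std::uint64_t master = static_cast<std::uint64_t>(seed);

  for (int tr = 0; tr < ntraj; ++tr) {
    std::mt19937_64 g(mix(master * 0x9e3779b97f4a7c15ULL + 0xda3e39cb94b95bdbULL +
                          static_cast<std::uint64_t>(tr)));
    int s = starts[tr] - 1;
    double tt = 0.0;
    int nstep = 0;
    bool cens = false;
    while (true) {
      if (is_target[s]) break;                 // absorbed in target set
      if (t.total[s] <= 0.0) break;            // competing trap
      double dt = -std::log(u01(g)) / t.total[s];
      if (tt + dt > max_time) { cens = true; tt = max_time; break; }
      tt += dt;
      if (n_groups > 0 && group[s] > 0) dwell(tr, group[s] - 1) += dt;
      s = pick_successor(t, s, u01(g));
      ++nstep;
      if (nstep % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    fpt[tr] = tt;
    terminal[tr] = s + 1;
    censored[tr] = cens;
    steps[tr] = nstep;
  }
  return List::create(_["fpt"] = fpt, _["terminal"] = terminal,
                      _["censored"] = censored, _["steps"] = steps,
                      _["dwell"] = dwell);
}

// Single trajectory with the full (state, dwell) visit record.
// traj_index selects the per-trajectory RNG stream, matching kmc_batch.
// [[Rcpp::export]]
List kmc_trajectory(const NumericMatrix &K, int start,
                    const LogicalVector &is_target, double max_time,
                    double seed, int traj_index) {
  NetTables t = build_tables(K);
  std::mt19937_64 g(mix(static_cast<std::uint64_t>(seed) * 0x9e3779b97f4a7c15ULL +
                        0xda3e39cb94b95bdbULL +
                        static_cast<std::uint64_t>(traj_index)));
  std::vector<int> states;
  std::vector<double> dwells;
  int s = start - 1;
  double tt = 0.0;
  bool cens = false;
  long ndraw = 0;
  while (true) {
    if (is_target[s]) break;
    if (t.total[s] <= 0.0) break;
    double dt = -std::log(u01(g)) / t.total[s];
    ++ndraw;
    if (tt + dt > max_time) { cens = true; tt = max_time; break; }
    states.push_back(s + 1);
    dwells.push_back(dt);
    tt += dt;
    s = pick_successor(t, s, u01(g));
    ++ndraw;
    if (states.size() % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["states"] = wrap(states), _["dwells"] = wrap(dwells),
                      _["terminal"] = s + 1, _["fpt"] = tt,
                      _["censored"] = cens, _["draws"] = ndraw);
}
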