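// Greenberg-Hastings three-state excitable dynamics on a weighted directed
// graph (row-normalized incoming weights), with per-step connected-component
// bookkeeping on the undirected structural adjacency.
//
// State coding: 0 = inactive (I), 1 = active (A), 2 = refractory (R).
// Synchronous update from the previous step's states:
//   I -> A with probability 1 if sum_j Wt[i,j] * s_j > T, else with prob r1
//   A -> R with probability 1
//   R -> I with probability r2
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent, size;
  UnionFind(int n) : parent(n), size(n, 1) {}
  void reset(const std::vector<int> &nodes) {
    for (int v : nodes) { parent[v] = v; size[v] = 1; }
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
};

inline std::mt19937 make_rng(int seed, int a, int b) {
  std::seed_seq ss{seed, a, b};
  return std::mt19937(ss);
}

// One synchronous step. `input` and `next_state` are scratch buffers.
inline void gh_step(std::vector<uint8_t> &state,
                    const std::vector<int> &out_ptr,
                    const std::vector<int> &out_idx,
                    const std::vector<double> &out_w,
                    double T, double r1, double r2,
                    std::mt19937 &rng,
                    std::uniform_real_distribution<double> &unif,
                    std::vector<double> &input,
                    std::vector<uint8_t> &next_state) {
  const int N = (int)state.size();
  std::fill(input.begin(), input.end(), 0.0);
  for (int j = 0; j < N; ++j) {
    if (state[j] == 1) {
      for (int k = out_ptr[j]; k < out_ptr[j + 1]; ++k)
        input[out_idx[k]] += out_w[k];
    }
  }
  for (int i = 0; i < N; ++i) {
    switch (state[i]) {
    case 0:
      if (input[i] > T) next_state[i] = 1;
      else next_state[i] = (unif(rng) < r1) ? 1 : 0;
      break;
    case 1:
      next_state[i] = 2;
      break;
    default:
      next_state[i] = (unif(rng) < r2) ? 0 : 2;
    }
  }
  state = next_state;
}

// Component sizes of the subgraph induced by currently active nodes.
// Returns sizes sorted descending in `sizes`.
inline void active_components(const std::vector<uint8_t> &state,
                              const std::vector<int> &adj_ptr,
                              const std::vector<int> &adj_idx,
                              UnionFind &uf,
                              std::vector<int> &active,
                              std::vector<int> &sizes) {
  active.clear();
  const int N = (int)state.size();
  for (int i = 0; i < N; ++i)
    if (state[i] == 1) active.push_back(i);
  uf.reset(active);
  for (int i : active) {
    for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) {
      int j = adj_idx[k];
      if (j > i && state[j] == 1) uf.unite(i, j);
    }
  }
  sizes.clear();
  for (int i : active)
    if (uf.find(i) == i) sizes.push_back(uf.size[i]);
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());
}

} // namespace

// Threshold sweep: for each T in T_grid run n_reps independent trajectories,
// discard burn_in steps, and accumulate <A>, sigma_A, time-averaged S1, S2.
// Replicate RNG streams are seeded from (seed, T index, replicate) so results
// do not depend on loop order. If collect_t (1-based index into T_grid) is
// positive, all per-step component sizes at that threshold are pooled and
// returned (for avalanche-exponent fitting).
// [[Rcpp::export]]
List gh_sweep_cpp(IntegerVector out_ptr_, IntegerVector out_idx_, NumericVector out_w_,
                  IntegerVector adj_ptr_, IntegerVector adj_idx_,
                  NumericVector T_grid, double r1, double r2,
                  int t_s, int burn_in, int n_reps, int seed,
                  int collect_t = 0) {
  const std::vector<int> out_ptr(out_ptr_.begin(), out_ptr_.end());
  const std::vector<int> out_idx(out_idx_.begin(), out_idx_.end());
  const std::vector<double> out_w(out_w_.begin(), out_w_.end());
  const std::vector<int> adj_ptr(adj_ptr_.begin(), adj_ptr_.end());
  const std::vector<int> adj_idx(adj_idx_.begin(), adj_idx_.end());
  const int N = (int)out_ptr.size() - 1;
  const int nT = T_grid.size();
  const int n_rec = t_s - burn_in;

  NumericVector meanA(nT), sdA(nT), S1(nT), S2(nT), repSd1(nT), repSd2(nT);
  std::vector<int> pooled;

  std::vector<uint8_t> state(N), next_state(N);
  std::vector<double> input(N);
  UnionFind uf(N);
  std::vector<int> active, sizes;

  for (int ti = 0; ti < nT; ++ti) {
    const double T = T_grid[ti];
    double accA = 0, accSd = 0, accS1 = 0, accS2 = 0;
    double accS1sq = 0, accS2sq = 0;
    for (int rep = 0; rep < n_reps; ++rep) {
      std::mt19937 rng = make_rng(seed, ti, rep);
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      std::uniform_int_distribution<int> three(0, 2);
      for (int i = 0; i < N; ++i) state[i] = (uint8_t)three(rng);
      double sumA = 0, sumA2 = 0, sumS1 = 0, sumS2 = 0;
      for (int t = 0; t < t_s; ++t) {
        gh_step(state, out_ptr, out_idx, out_w, T, r1, r2, rng, unif,
                input, next_state);
        if (t >= burn_in) {
          active_components(state, adj_ptr, adj_idx, uf, active, sizes);
          const double A = (double)active.size();
          sumA += A; sumA2 += A * A;
          sumS1 += sizes.size() > 0 ? sizes[0] : 0;
          sumS2 += sizes.size() > 1 ? sizes[1] : 0;
          if (collect_t == ti + 1)
            pooled.insert(pooled.end(), sizes.begin(), sizes.end());
        }
      }
      const double mA = sumA / n_rec;
      accA += mA;
      double var = sumA2 / n_rec - mA * mA;
      accSd += var > 0 ? std::sqrt(var) : 0.0;
      const double m1 = sumS1 / n_rec, m2 = sumS2 / n_rec;
      accS1 += m1; accS2 += m2;
      accS1sq += m1 * m1; accS2sq += m2 * m2;
    }
    meanA[ti] = accA / n_reps;
    sdA[ti] = accSd / n_reps;
    S1[ti] = accS1 / n_reps;
    S2[ti] = accS2 / n_reps;
    double v1 = accS1sq / n_reps - S1[ti] * S1[ti];
    double v2 = accS2sq / n_reps - S2[ti] * S2[ti];
    repSd1[ti] = v1 > 0 ? std::sqrt(v1) : 0.0;
    repSd2[ti] = v2 > 0 ? std::sqrt(v2) : 0.0;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["mean_A"] = meanA, _["sd_A"] = sdA,
                      _["S1"] = S1, _["S2"] = S2,
                      _["rep_sd_S1"] = repSd1, _["rep_sd_S2"] = repSd2,
                      _["pooled_sizes"] = wrap(pooled));
}

// Single trajectory at a fixed threshold; returns the t_s x N state matrix
// (0 = I, 1 = A, 2 = R). Used for BOLD synthesis and rule-level tests.
// init (length N, values 0/1/2) overrides the random initial configuration.
// [[Rcpp::export]]
IntegerMatrix gh_trajectory_cpp(IntegerVector out_ptr_, IntegerVector out_idx_,
                                NumericVector out_w_,
                                double T, double r1, double r2,
                                int t_s, int seed,
                                Nullable<IntegerVector> init = R_NilValue) {
  const std::vector<int> out_ptr(out_ptr_.begin(), out_ptr_.end());
  const std::vector<int> out_idx(out_idx_.begin(), out_idx_.end());
  const std::vector<double> out_w(out_w_.begin(), out_w_.end());
  const int N = (int)out_ptr.size() - 1;

  std::mt19937 rng = make_rng(seed, 0, 0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> three(0, 2);

  std::vector<uint8_t> state(N), next_state(N);
  std::vector<double> input(N);
  if (init.isNotNull()) {
    IntegerVector iv(init);
    for (int i = 0; i < N; ++i) state[i] = (uint8_t)iv[i];
  } else {
    for (int i = 0; i < N; ++i) state[i] = (uint8_t)three(rng);
  }

  IntegerMatrix out(t_s, N);
  for (int t = 0; t < t_s; ++t) {
    gh_step(state, out_ptr, out_idx, out_w, T, r1, r2, rng, unif,
            input, next_state);
    for (int i = 0; i < N; ++i) out(t, i) = state[i];
  }
  return out;
}
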