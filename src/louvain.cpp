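#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Louvain-style greedy optimisation of a (possibly signed) symmetric quality
// matrix B: maximise sum_c sum_{i,j in c} B[i][j] over partitions.
//
// This generalises modularity optimisation to the time-dependent stability
// matrix B(t) = Pi P(t) - pi pi^T, whose entries can be negative, so all
// merge gains are computed directly from aggregated B entries rather than
// through degree-product shortcuts.
//
// Local moves start from singletons and sweep nodes in the supplied order;
// the node order is the only source of randomness (ensemble initialisation
// is driven by shuffling it in R). Ties in the best move are broken toward
// the smallest community label; a node only moves on a strictly positive
// gain, so the result is deterministic given the order.

namespace {

const double GAIN_TOL = 1e-12;

// one resolution level: local moves until no improvement, on dense M (n x n)
// order: 0-based node visiting order. Returns membership (0-based, compact).
std::vector<int> local_moves(const std::vector<double>& M, int n,
                             const std::vector<int>& order) {
  std::vector<int> memb(n);
  for (int i = 0; i < n; ++i) memb[i] = i;

  std::vector<double> s; // scratch: link strength from node i to each community
  bool improved = true;
  while (improved) {
    improved = false;
    for (int idx = 0; idx < n; ++idx) {
      int i = order[idx];
      int a = memb[i];
      s.assign(n, 0.0);
      const double* Mi = &M[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        if (j != i) s[memb[j]] += Mi[j];
      // gain of moving i from a to c: 2*(s[c] - s[a]); c may be a fresh
      // empty community (s = 0), i.e. leaving to a singleton.
      double best_gain = 0.0;
      int best_c = a;
      for (int c = 0; c < n; ++c) {
        if (c == a) continue;
        double g = 2.0 * (s[c] - s[a]);
        if (g > best_gain + GAIN_TOL ||
            (g > GAIN_TOL && std::abs(g - best_gain) <= GAIN_TOL && c < best_c)) {
          best_gain = g; best_c = c;
        }
      }
      // moving to an empty community == isolating i
      {
        double g = 2.0 * (0.0 - s[a]);
        bool a_nonsingleton = false;
        for (int j = 0; j < n && !a_nonsingleton; ++j)
          if (j != i && memb[j] == a) a_nonsingleton = true;
        if (a_nonsingleton && g > best_gain + GAIN_TOL) {
          // find smallest empty label
          std::vector<char> used(n, 0);
          for (int j = 0; j < n; ++j) used[memb[j]] = 1;
          for (int c = 0; c < n; ++c)
            if (!used[c]) { best_gain = g; best_c = c; break; }
        }
      }
      if (best_c != a) { memb[i] = best_c; improved = true; }
    }
  }
  // compact labels in order of first appearance
  std::vector<int> map(n, -1);
  int nc = 0;
  for (int i = 0; i < n; ++i) {
    if (map[memb[i]] < 0) map[memb[i]] = nc++;
    memb[i] = map[memb[i]];
  }
  return memb;
}

} // namespace

// [[Rcpp::export(name = ".louvain_signed_cpp")]]
IntegerVector louvain_signed_cpp(NumericMatrix B, IntegerVector order0) {
  int n = B.nrow();
  std::vector<double> M((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      M[(size_t)i * n + j] = B(i, j);

  std::vector<int> node2final(n);
  for (int i = 0; i < n; ++i) node2final[i] = i;

  std::vector<int> order(order0.begin(), order0.end());
  int cur_n = n;
  while (true) {
    std::vector<int> memb = local_moves(M, cur_n, order);
    int nc = *std::max_element(memb.begin(), memb.end()) + 1;
    // compose with current mapping
    for (int i = 0; i < n; ++i) node2final[i] = memb[node2final[i]];
    if (nc == cur_n) break; // no aggregation happened; converged
    // aggregate M' = H^T M H
    std::vector<double> M2((size_t)nc * nc, 0.0);
    for (int i = 0; i < cur_n; ++i)
      for (int j = 0; j < cur_n; ++j)
        M2[(size_t)memb[i] * nc + memb[j]] += M[(size_t)i * cur_n + j];
    M.swap(M2);
    cur_n = nc;
    order.resize(cur_n);
    for (int i = 0; i < cur_n; ++i) order[i] = i; // deterministic upper levels
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = node2final[i];
  return out;
}
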