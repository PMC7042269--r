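#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving randomization of a simple undirected graph by repeated
// double-edge swaps: pick two edges (a,b), (c,d) and rewire to (a,d), (c,b)
// or (a,c), (b,d) (variant chosen uniformly), rejecting proposals that would
// create a self-loop or a multi-edge. Edge attributes travel with the edge
// slot, so each original correlation stays attached to one endpoint pair of
// its swap. Uses R's RNG, so results are reproducible under set.seed().
//
// edges: 2-column integer matrix of 1-based vertex ids.
// n_attempts: number of proposed swaps (typically 10 * |E|).
// Returns the rewired edge matrix (same row order; attribute vectors aligned
// by row remain valid).
// [[Rcpp::export(name = ".double_edge_swap")]]
IntegerMatrix double_edge_swap(IntegerMatrix edges, int n_attempts) {
  int m = edges.nrow();
  if (m < 2) return edges;
  std::vector<int> a(m), b(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  auto key = [](int x, int y) {
    if (x > y) std::swap(x, y);
    return (long long)x << 32 | (unsigned int)y;
  };
  for (int i = 0; i < m; i++) {
    a[i] = edges(i, 0);
    b[i] = edges(i, 1);
    present.insert(key(a[i], b[i]));
  }
  for (int t = 0; t < n_attempts; t++) {
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i == j) continue;
    int ai = a[i], bi = b[i], aj = a[j], bj = b[j];
    // uniformly pick one of the two rewiring variants
    if (unif_rand() < 0.5) { std::swap(aj, bj); }
    // proposal: (ai, bj) and (aj, bi)
    if (ai == bj || aj == bi) continue;
    long long k1 = key(ai, bj), k2 = key(aj, bi);
    if (k1 == k2) continue;
    if (present.count(k1) || present.count(k2)) continue;
    present.erase(key(a[i], b[i]));
    present.erase(key(a[j], b[j]));
    a[i] = ai; b[i] = bj;
    a[j] = aj; b[j] = bi;
    present.insert(k1);
    present.insert(k2);
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; i++) {
    out(i, 0) = a[i];
    out(i, 1) = b[i];
  }
  return out;
}
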