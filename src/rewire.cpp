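#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization by Maslov-Sneppen double-edge swaps on a
// symmetric weight matrix. Weights travel with their edge: a swap of
// (a,b),(c,d) -> (a,d),(c,b) moves w_ab onto (a,d) and w_cd onto (c,b), so
// both the degree sequence and the multiset of edge weights are invariant.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
List rewire_swap(NumericMatrix W, int n_attempts) {
  int n = W.nrow();
  NumericMatrix M = clone(W);
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (M(i, j) > 0) { ei.push_back(i); ej.push_back(j); }
  int m = (int) ei.size();
  int successes = 0;
  if (m < 2)
    return List::create(_["weights"] = M, _["swaps"] = successes);
  RNGScope scope;
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int) (unif_rand() * m); if (e1 == m) e1 = m - 1;
    int e2 = (int) (unif_rand() * m); if (e2 == m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposal: replace (a,b),(c,d) with (a,d),(c,b)
    if (a == d || c == b) continue;           // self-loop
    if (M(a, d) > 0 || M(c, b) > 0) continue; // multi-edge
    double w1 = M(a, b), w2 = M(c, d);
    M(a, b) = M(b, a) = 0.0;
    M(c, d) = M(d, c) = 0.0;
    M(a, d) = M(d, a) = w1;
    M(c, b) = M(b, c) = w2;
    ei[e1] = std::min(a, d); ej[e1] = std::max(a, d);
    ei[e2] = std::min(c, b); ej[e2] = std::max(c, b);
    ++successes;
  }
  return List::create(_["weights"] = M, _["swaps"] = successes);
}
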