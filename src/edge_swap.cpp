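#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving randomization of a directed graph by edge switching:
// repeatedly pick two edges (a->b, c->d) and rewire to (a->d, c->b) unless
// that would create a self-loop or a duplicate edge.  In- and out-degrees
// of every node are invariant.  Uses R's RNG so results are reproducible
// under set.seed().
// [[Rcpp::export]]
IntegerMatrix edge_swap_cpp(IntegerMatrix adj, int attempts) {
  IntegerMatrix a = clone(adj);
  const int n = a.nrow();
  std::vector<int> src, tgt;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (a(i, j)) { src.push_back(i); tgt.push_back(j); }
  const int m = src.size();
  if (m < 2) return a;
  for (int it = 0; it < attempts; ++it) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int s1 = src[e1], t1 = tgt[e1], s2 = src[e2], t2 = tgt[e2];
    if (s1 == t2 || s2 == t1) continue;           // would create self-loop
    if (a(s1, t2) || a(s2, t1)) continue;         // would duplicate an edge
    a(s1, t1) = 0; a(s2, t2) = 0;
    a(s1, t2) = 1; a(s2, t1) = 1;
    tgt[e1] = t2; tgt[e2] = t1;
  }
  return a;
}
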