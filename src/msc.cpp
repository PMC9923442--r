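#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo sampler of unrooted gene-tree topology frequencies for a
// rooted 5-taxon species tree under the multispecies coalescent.
//
// The species tree is passed as parent pointers with branch lengths in
// coalescent units. Within each branch, k lineages coalesce at rate
// k(k-1)/2; lineages that reach the root keep coalescing in an
// unbounded root branch (free coalescence above the root). Each tip
// carries one sampled lineage, identified by a 5-bit mask.
//
// A simulated gene tree's unrooted topology is identified by its two
// cherry pairs: every clade of size 2 is a cherry, and a clade of size
// 3 marks the complementary pair. `pair_index` maps the two pair masks
// (smaller mask first) to a catalog index in [0, 15).

// [[Rcpp::export]]
IntegerVector msc_quintet_counts_cpp(IntegerVector parent,
                                     NumericVector blen,
                                     IntegerVector node_order,
                                     IntegerVector tip_mask,
                                     IntegerMatrix pair_index,
                                     int nsim) {
  const int M = parent.size();
  std::vector<std::vector<int>> lin(M);
  IntegerVector counts(15);
  RNGScope scope;

  for (int s = 0; s < nsim; ++s) {
    int pairs[2] = {0, 0};
    int npairs = 0;
    for (int oi = 0; oi < M; ++oi) {
      int v = node_order[oi];
      std::vector<int> &L = lin[v];
      L.clear();
      if (tip_mask[v] > 0) {
        L.push_back(tip_mask[v]);
      } else {
        for (int u = 0; u < M; ++u) {
          if (parent[u] == v) {
            L.insert(L.end(), lin[u].begin(), lin[u].end());
          }
        }
      }
      bool is_root = parent[v] < 0;
      double remain = is_root ? R_PosInf : blen[v];
      double t = 0.0;
      int k = (int)L.size();
      while (k > 1) {
        double rate = k * (k - 1) / 2.0;
        t += exp_rand() / rate;
        if (!is_root && t > remain) break;
        // uniform unordered pair (i, j), i < j
        int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        if (i > j) std::swap(i, j);
        int merged = L[i] | L[j];
        int pc = __builtin_popcount(merged);
        int pm = -1;
        if (pc == 2) pm = merged;
        else if (pc == 3) pm = 31 & ~merged;
        if (pm > 0) {
          bool seen = false;
          for (int q = 0; q < npairs; ++q) if (pairs[q] == pm) seen = true;
          if (!seen && npairs < 2) pairs[npairs++] = pm;
        }
        L[i] = merged;
        L.erase(L.begin() + j);
        --k;
      }
    }
    if (npairs == 2) {
      int a = std::min(pairs[0], pairs[1]);
      int b = std::max(pairs[0], pairs[1]);
      int idx = pair_index(a, b);
      if (idx >= 0) counts[idx]++;
    }
  }
  return counts;
}
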