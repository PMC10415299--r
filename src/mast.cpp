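#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rooted maximum agreement subtree by dynamic programming over node
// pairs.  Trees arrive as postorder child arrays (children before
// parents, root last): left/right hold 0-based node indices (-1 at
// leaves), leaf holds the 0-based leaf id in a shared label ordering
// (-1 at internal nodes).  Leaf clades are kept as 64-bit masks, which
// caps trees at 64 leaves.

static int mast_core(const IntegerVector& l1, const IntegerVector& r1,
                     const std::vector<int>& leaf1,
                     const IntegerVector& l2, const IntegerVector& r2,
                     const std::vector<int>& leaf2,
                     std::vector<int>& M) {
  const int m1 = l1.size(), m2 = l2.size();
  std::vector<uint64_t> c1(m1), c2(m2);
  for (int u = 0; u < m1; ++u)
    c1[u] = (l1[u] < 0) ? (1ULL << leaf1[u]) : (c1[l1[u]] | c1[r1[u]]);
  for (int v = 0; v < m2; ++v)
    c2[v] = (l2[v] < 0) ? (1ULL << leaf2[v]) : (c2[l2[v]] | c2[r2[v]]);
  for (int u = 0; u < m1; ++u) {
    const bool uleaf = l1[u] < 0;
    for (int v = 0; v < m2; ++v) {
      int res;
      if (uleaf && l2[v] < 0)
        res = (leaf1[u] == leaf2[v]) ? 1 : 0;
      else if (uleaf)
        res = ((c2[v] >> leaf1[u]) & 1ULL) ? 1 : 0;
      else if (l2[v] < 0)
        res = ((c1[u] >> leaf2[v]) & 1ULL) ? 1 : 0;
      else {
        int best = std::max(std::max(M[l1[u] * m2 + v], M[r1[u] * m2 + v]),
                            std::max(M[u * m2 + l2[v]], M[u * m2 + r2[v]]));
        best = std::max(best,
                        M[l1[u] * m2 + l2[v]] + M[r1[u] * m2 + r2[v]]);
        best = std::max(best,
                        M[l1[u] * m2 + r2[v]] + M[r1[u] * m2 + l2[v]]);
        res = best;
      }
      M[u * m2 + v] = res;
    }
  }
  return M[(m1 - 1) * m2 + (m2 - 1)];
}

// [[Rcpp::export]]
int mast_size_cpp(IntegerVector l1, IntegerVector r1, IntegerVector leaf1,
                  IntegerVector l2, IntegerVector r2, IntegerVector leaf2) {
  std::vector<int> lf1(leaf1.begin(), leaf1.end());
  std::vector<int> lf2(leaf2.begin(), leaf2.end());
  std::vector<int> M(l1.size() * l2.size());
  return mast_core(l1, r1, lf1, l2, r2, lf2, M);
}

// MAST of tree1 against tree2 under each leaf-label permutation of
// tree2.  perms is n_perm x n, each row a 0-based permutation applied
// to tree2's leaf ids.
// [[Rcpp::export]]
IntegerVector mast_perm_cpp(IntegerVector l1, IntegerVector r1,
                            IntegerVector leaf1,
                            IntegerVector l2, IntegerVector r2,
                            IntegerVector leaf2, IntegerMatrix perms) {
  std::vector<int> lf1(leaf1.begin(), leaf1.end());
  const int m2 = l2.size();
  std::vector<int> M(l1.size() * m2);
  IntegerVector out(perms.nrow());
  std::vector<int> lf2(m2);
  for (int p = 0; p < perms.nrow(); ++p) {
    for (int v = 0; v < m2; ++v)
      lf2[v] = (leaf2[v] < 0) ? -1 : perms(p, leaf2[v]);
    out[p] = mast_core(l1, r1, lf1, l2, r2, lf2, M);
  }
  return out;
}
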