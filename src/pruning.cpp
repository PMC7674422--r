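#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for a reversible 4-state model, averaging over discrete
// gamma rate categories with equal weights. Transition matrices come from the
// eigendecomposition Q = U diag(eval) Uinv passed in (Q scaled to mean rate
// 1, so branch lengths are expected substitutions per site).
//
// edge: 2-column integer matrix (parent, child), 1-based ape numbering,
// ordered so that every child row appears before the row where that child is
// a parent (postorder). Tips are 1..n_tip. blen: per-edge expected
// substitutions. patterns: n_tip x n_pat codes 0..3 = ACGT, 4 = missing/gap.
// [[Rcpp::export]]
double pruning_loglik_cpp(IntegerMatrix edge, NumericVector blen,
                          IntegerMatrix patterns, NumericVector weights,
                          NumericVector pi, NumericMatrix U,
                          NumericMatrix Uinv, NumericVector eval,
                          NumericVector rates, int n_tip) {
  const int n_edge = edge.nrow();
  const int n_pat = patterns.ncol();
  const int n_cat = rates.size();
  int n_node = n_tip;
  for (int e = 0; e < n_edge; ++e) {
    if (edge(e, 0) > n_node) n_node = edge(e, 0);
    if (edge(e, 1) > n_node) n_node = edge(e, 1);
  }
  int root = edge(n_edge - 1, 0);  // parent of the last postorder edge

  std::vector<double> sitelik(n_pat, 0.0);
  std::vector<double> P(n_edge * 16);
  std::vector<double> part(n_node * 4);
  std::vector<char> seen(n_node);

  for (int c = 0; c < n_cat; ++c) {
    // per-edge transition matrices at this category's rate
    for (int e = 0; e < n_edge; ++e) {
      double t = blen[e] * rates[c];
      double ev[4];
      for (int i = 0; i < 4; ++i) ev[i] = std::exp(eval[i] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += U(i, k) * ev[k] * Uinv(k, j);
          P[e * 16 + i * 4 + j] = (s > 0.0) ? s : 0.0;
        }
    }
    for (int p = 0; p < n_pat; ++p) {
      std::fill(seen.begin(), seen.end(), 0);
      for (int e = 0; e < n_edge; ++e) {
        int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
        double cp[4];
        if (ch < n_tip) {
          int st = patterns(ch, p);
          for (int i = 0; i < 4; ++i)
            cp[i] = (st > 3 || st == i) ? 1.0 : 0.0;
        } else {
          for (int i = 0; i < 4; ++i) cp[i] = part[ch * 4 + i];
        }
        double down[4];
        const double *Pe = &P[e * 16];
        for (int i = 0; i < 4; ++i) {
          double s = 0.0;
          for (int j = 0; j < 4; ++j) s += Pe[i * 4 + j] * cp[j];
          down[i] = s;
        }
        if (!seen[par]) {
          for (int i = 0; i < 4; ++i) part[par * 4 + i] = down[i];
          seen[par] = 1;
        } else {
          for (int i = 0; i < 4; ++i) part[par * 4 + i] *= down[i];
        }
      }
      double l = 0.0;
      for (int i = 0; i < 4; ++i) l += pi[i] * part[(root - 1) * 4 + i];
      sitelik[p] += l / (double)n_cat;
    }
  }
  double ll = 0.0;
  for (int p = 0; p < n_pat; ++p) {
    if (sitelik[p] <= 0.0) return R_NegInf;
    ll += weights[p] * std::log(sitelik[p]);
  }
  return ll;
}
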