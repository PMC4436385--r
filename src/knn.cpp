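#include <Rcpp.h>
using namespace Rcpp;

// Deterministic k-nearest-neighbour classification.
//
// Neighbours are ordered by (squared distance, training row index) ascending,
// so ties at the k-th distance resolve to the lowest training index; vote
// ties resolve to the class of the single nearest neighbour.

// Predict labels (1/2) for test rows given training matrix and labels.
// [[Rcpp::export]]
IntegerVector cpp_knn_predict(NumericMatrix xtr, IntegerVector ytr,
                              NumericMatrix xte, int k) {
  int ntr = xtr.nrow(), nte = xte.nrow(), d = xtr.ncol();
  if (k > ntr) k = ntr;
  IntegerVector pred(nte);
  std::vector<std::pair<double, int> > nb(ntr);
  for (int i = 0; i < nte; ++i) {
    for (int t = 0; t < ntr; ++t) {
      double s = 0.0;
      for (int f = 0; f < d; ++f) {
        double diff = xte(i, f) - xtr(t, f);
        s += diff * diff;
      }
      nb[t] = std::make_pair(s, t);
    }
    std::partial_sort(nb.begin(), nb.begin() + k, nb.end());
    int c1 = 0, c2 = 0;
    for (int j = 0; j < k; ++j) {
      if (ytr[nb[j].second] == 1) ++c1; else ++c2;
    }
    pred[i] = (c1 > c2) ? 1 : (c2 > c1 ? 2 : ytr[nb[0].second]);
  }
  return pred;
}

// Error rate of a kNN classifier trained on a subset of a training pool,
// evaluated against all test rows, from a precomputed squared-distance
// matrix D (n_test x n_pool).
//
// `sub` holds 1-based pool column indices (any order; sorted ascending here,
// so tie-breaking is by original pool row). Training labels come from, in
// order of precedence:
//   - `ylab` (length = subset size): explicit labels for the sorted subset;
//   - `perm` (length = subset size): a permutation applied to the pool
//     labels of the sorted subset (the label-shuffling null);
//   - otherwise the pool labels of the sorted subset (the actual replicate).
// [[Rcpp::export]]
double cpp_knn_error_pool(NumericMatrix D, IntegerVector sub,
                          IntegerVector ypool, IntegerVector perm,
                          IntegerVector ylab, IntegerVector yte, int k) {
  int nte = D.nrow(), ns = sub.size();
  if (k > ns) k = ns;
  std::vector<int> s(sub.begin(), sub.end());
  std::sort(s.begin(), s.end());
  std::vector<int> y(ns);
  if (ylab.size() == ns) {
    for (int t = 0; t < ns; ++t) y[t] = ylab[t];
  } else if (perm.size() == ns) {
    for (int t = 0; t < ns; ++t) y[t] = ypool[s[perm[t] - 1] - 1];
  } else {
    for (int t = 0; t < ns; ++t) y[t] = ypool[s[t] - 1];
  }
  int wrong = 0;
  std::vector<std::pair<double, int> > nb(ns);
  for (int i = 0; i < nte; ++i) {
    for (int t = 0; t < ns; ++t) {
      nb[t] = std::make_pair(D(i, s[t] - 1), t);
    }
    // pair comparison: distance first, then subset position, which after the
    // ascending sort of `s` is the original pool row order
    std::partial_sort(nb.begin(), nb.begin() + k, nb.end());
    int c1 = 0, c2 = 0;
    for (int j = 0; j < k; ++j) {
      if (y[nb[j].second] == 1) ++c1; else ++c2;
    }
    int pred = (c1 > c2) ? 1 : (c2 > c1 ? 2 : y[nb[0].second]);
    if (pred != yte[i]) ++wrong;
  }
  return (double)wrong / (double)nte;
}
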