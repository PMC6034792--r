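#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Random-forest classifier for pixel classification (two classes, 0/1).
// Bootstrap aggregation of CART trees, Gini split criterion, per-node feature
// subsampling, majority-vote leaves (ties -> class 0). Uses R's RNG so that
// set.seed() in R makes training fully reproducible.

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // split: x <= threshold goes left
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (majority vote)

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);
    return (int)feature.size() - 1;
  }
};

inline int r_int(int n) { // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

int grow(Tree& tr, const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi, int depth,
         int mtry, int max_depth, int min_split,
         std::vector<int>& featbuf) {
  const int node = tr.new_node();
  const int n = hi - lo;
  int n1 = 0;
  for (int t = lo; t < hi; ++t) n1 += y[idx[t]];
  const int n0 = n - n1;
  // majority with tie to class 0 (avascular)
  tr.pred[node] = (n1 > n0) ? 1 : 0;
  if (n0 == 0 || n1 == 0 || n < min_split ||
      (max_depth > 0 && depth >= max_depth))
    return node;

  const int p = X.ncol();
  // partial Fisher-Yates for mtry distinct features
  for (int f = 0; f < p; ++f) featbuf[f] = f;
  const int m = std::min(mtry, p);
  for (int f = 0; f < m; ++f) {
    int j = f + r_int(p - f);
    std::swap(featbuf[f], featbuf[j]);
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  const double imp_parent =
      1.0 - ((double)n0 * n0 + (double)n1 * n1) / ((double)n * n);
  std::vector<std::pair<double, int> > vals(n);
  for (int fi = 0; fi < m; ++fi) {
    const int f = featbuf[fi];
    for (int t = 0; t < n; ++t) {
      const int s = idx[lo + t];
      vals[t] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int t = 0; t < n - 1; ++t) {
      l1 += vals[t].second;
      if (vals[t].first == vals[t + 1].first) continue;
      const int nl = t + 1, nr = n - nl;
      const int l0 = nl - l1, r1 = n1 - l1, r0 = nr - r1;
      const double imp_l = 1.0 - ((double)l0 * l0 + (double)l1 * l1) /
                                     ((double)nl * nl);
      const double imp_r = 1.0 - ((double)r0 * r0 + (double)r1 * r1) /
                                     ((double)nr * nr);
      const double gain =
          imp_parent - ((double)nl / n) * imp_l - ((double)nr / n) * imp_r;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node; // numerically degenerate

  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  const int l = grow(tr, X, y, idx, lo, mid, depth + 1, mtry, max_depth,
                     min_split, featbuf);
  const int r = grow(tr, X, y, idx, mid, hi, depth + 1, mtry, max_depth,
                     min_split, featbuf);
  tr.left[node] = l;
  tr.right[node] = r;
  return node;
}

inline int tree_predict(const IntegerVector& feature,
                        const NumericVector& threshold,
                        const IntegerVector& left, const IntegerVector& right,
                        const IntegerVector& pred, const NumericMatrix& X,
                        int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  return pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(const NumericMatrix& X, const IntegerVector& y, int ntree,
            int mtry, int max_depth, int min_split) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 training samples");
  List trees(ntree);
  std::vector<int> featbuf(p);
  std::vector<int> idx(n);
  std::vector<std::vector<bool> > inbag(ntree, std::vector<bool>(n, false));
  for (int b = 0; b < ntree; ++b) {
    for (int t = 0; t < n; ++t) {
      const int s = r_int(n);
      idx[t] = s;
      inbag[b][s] = true;
    }
    Tree tr;
    grow(tr, X, y, idx, 0, n, 0, mtry, max_depth, min_split, featbuf);
    trees[b] = List::create(_["feature"] = wrap(tr.feature),
                            _["threshold"] = wrap(tr.threshold),
                            _["left"] = wrap(tr.left),
                            _["right"] = wrap(tr.right),
                            _["pred"] = wrap(tr.pred));
  }
  // out-of-bag majority-vote accuracy
  std::vector<int> v0(n, 0), v1(n, 0);
  for (int b = 0; b < ntree; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int s = 0; s < n; ++s) {
      if (inbag[b][s]) continue;
      if (tree_predict(feature, threshold, left, right, pred, X, s) == 0)
        ++v0[s];
      else
        ++v1[s];
    }
  }
  int n_scored = 0, n_correct = 0;
  for (int s = 0; s < n; ++s) {
    if (v0[s] + v1[s] == 0) continue;
    ++n_scored;
    const int vote = (v1[s] > v0[s]) ? 1 : 0;
    if (vote == y[s]) ++n_correct;
  }
  const double oob = (n_scored > 0) ? (double)n_correct / n_scored : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_accuracy"] = oob);
}

// Fraction of trees voting class 0 (avascular) for each row of X.
// [[Rcpp::export(name = ".rf_predict_prob0")]]
NumericVector rf_predict_prob0(const List& trees, const NumericMatrix& X) {
  const int n = X.nrow(), ntree = trees.size();
  std::vector<int> votes0(n, 0);
  for (int b = 0; b < ntree; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int s = 0; s < n; ++s)
      if (tree_predict(feature, threshold, left, right, pred, X, s) == 0)
        ++votes0[s];
  }
  NumericVector out(n);
  for (int s = 0; s < n; ++s) out[s] = (double)votes0[s] / ntree;
  return out;
}
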