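#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Depth-limited least-squares regression trees for stochastic gradient
// boosting. Split search is greedy variance reduction with deterministic
// tie-breaking: features are scanned in column order and split candidates in
// ascending order, and a candidate replaces the incumbent only on a strict
// improvement, so ties resolve to the lowest feature index, then the lowest
// split value.

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int max_depth, min_node;
  std::vector<int> feature, left, right;
  std::vector<double> split, value;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_,
              int max_depth_, int min_node_)
    : X(X_), y(y_), max_depth(max_depth_), min_node(min_node_) {}

  int build(std::vector<int>& rows, int depth) {
    int node = feature.size();
    feature.push_back(-1);
    split.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    int n = rows.size();
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += y[rows[i]];
    double mean = sum / n;
    value.push_back(mean);
    if (depth >= max_depth || n < 2 * min_node) return node;

    double base = sum * sum / n;
    double best_gain = 0.0, best_split = 0.0;
    int best_feat = -1;
    int p = X.ncol();
    std::vector<int> ord(n);
    std::vector<double> xv(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) xv[i] = X(rows[i], j);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return xv[a] < xv[b]; });
      double sl = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        sl += y[rows[ord[k]]];
        if (xv[ord[k]] == xv[ord[k + 1]]) continue;
        int nl = k + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - base;
        if (gain > best_gain * (1.0 + 1e-12) + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_split = 0.5 * (xv[ord[k]] + xv[ord[k + 1]]);
        }
      }
    }
    if (best_feat < 0) return node;

    std::vector<int> lrows, rrows;
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_feat) < best_split) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    if ((int)lrows.size() < min_node || (int)rrows.size() < min_node) return node;
    feature[node] = best_feat;
    split[node] = best_split;
    int l = build(lrows, depth + 1);
    int r = build(rrows, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int max_depth, int min_node) {
  std::vector<int> rws(rows.begin(), rows.end()); // 0-based
  TreeBuilder tb(X, y, max_depth, min_node);
  tb.build(rws, 0);
  return List::create(_["feature"] = wrap(tb.feature),
                      _["split"] = wrap(tb.split),
                      _["left"] = wrap(tb.left),
                      _["right"] = wrap(tb.right),
                      _["value"] = wrap(tb.value));
}

static double predict_one(const IntegerVector& feature, const NumericVector& split,
                          const IntegerVector& left, const IntegerVector& right,
                          const NumericVector& value, const NumericMatrix& X, int i) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(i, feature[node]) < split[node]) ? left[node] : right[node];
  }
  return value[node];
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector split = tree["split"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = predict_one(feature, split, left, right, value, X, i);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X, double f0, double nu) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n, f0);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
    NumericVector split = tree["split"], value = tree["value"];
    for (int i = 0; i < n; ++i)
      out[i] += nu * predict_one(feature, split, left, right, value, X, i);
  }
  return out;
}
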