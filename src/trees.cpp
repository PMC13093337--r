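#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Flat-array CART regression tree. Split search minimises within-node SSE;
// mtry candidate features are drawn per node with R's RNG so that set.seed()
// in the calling R session fully determines the forest.

struct TreeBuf {
  std::vector<int> var;
  std::vector<double> split;
  std::vector<int> left, right;
  std::vector<double> pred;
};

static int build_node(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& rows, int lo, int hi, int depth,
                      int mtry, int minsplit, int maxdepth, TreeBuf& T) {
  int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    double v = y[rows[i]];
    sum += v;
    sum2 += v * v;
  }
  double sse = sum2 - sum * sum / n;
  int node = (int)T.var.size();
  T.var.push_back(-1);
  T.split.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back(sum / n);
  if (n < minsplit || depth >= maxdepth || sse <= 1e-12) return node;

  int p = X.ncol();
  int m = std::min(mtry, p);
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < m; ++j) {  // partial Fisher-Yates
    int k = j + (int)(R::unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double best_gain = 1e-12, best_split = 0.0;
  int best_var = -1;
  std::vector<std::pair<double, double> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int j = feats[jj];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[lo + i], j), y[rows[lo + i]]);
    std::sort(vals.begin(), vals.end());
    double lsum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += vals[i].second;
      if (vals[i + 1].first <= vals[i].first) continue;
      int nl = i + 1, nr = n - nl;
      double rsum = sum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_var = j;
        best_split = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_var < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_var) <= best_split) std::swap(rows[mid++], rows[i]);
  if (mid == lo || mid == hi) return node;

  T.var[node] = best_var;
  T.split[node] = best_split;
  T.left[node] = build_node(X, y, rows, lo, mid, depth + 1, mtry, minsplit,
                            maxdepth, T);
  T.right[node] = build_node(X, y, rows, mid, hi, depth + 1, mtry, minsplit,
                             maxdepth, T);
  return node;
}

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows1,
                   int mtry, int minsplit, int maxdepth) {
  std::vector<int> rows(rows1.size());
  for (int i = 0; i < rows1.size(); ++i) rows[i] = rows1[i] - 1;
  TreeBuf T;
  build_node(X, y, rows, 0, (int)rows.size(), 0, mtry, minsplit, maxdepth, T);
  return List::create(_["var"] = T.var, _["split"] = T.split,
                      _["left"] = T.left, _["right"] = T.right,
                      _["pred"] = T.pred);
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"];
  NumericVector split = tree["split"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector pred = tree["pred"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0)
      node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
    out[i] = pred[node];
  }
  return out;
}
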