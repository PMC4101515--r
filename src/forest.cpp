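#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Regression random forest (CART trees, bootstrap resampling, random feature
// subsets at each split), used by the iterative random-forest imputer.
// Uses R's RNG so results are reproducible via set.seed() on the R side.

namespace {

struct Tree {
  // flat node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct Data {  // column-major predictor matrix
  const double *x;
  int n, p;
  double at(int row, int col) const { return x[(size_t)col * n + row]; }
};

int rand_int(int n) {  // uniform on 0..n-1 from R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Grower {
  const Data &X;
  const double *y;
  int mtry, min_node;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, double> > vals;  // (x, y) scratch

  Grower(const Data &X_, const double *y_, int mtry_, int min_node_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), feat_pool(X_.p),
        vals(X_.n) {}

  void grow(Tree &tree, int node, std::vector<int> &idx, int lo, int hi) {
    const int n = hi - lo;
    double sum = 0.0;
    for (int i = lo; i < hi; ++i) sum += y[idx[i]];
    tree.value[node] = sum / n;

    if (n <= min_node) return;
    bool constant_y = true;
    for (int i = lo + 1; i < hi; ++i)
      if (y[idx[i]] != y[idx[lo]]) { constant_y = false; break; }
    if (constant_y) return;

    const int p = X.p;
    for (int i = 0; i < p; ++i) feat_pool[i] = i;
    int best_feat = -1;
    double best_score = -1.0, best_thr = 0.0;

    for (int m = 0; m < mtry; ++m) {
      int r = m + rand_int(p - m);  // partial Fisher-Yates over features
      std::swap(feat_pool[m], feat_pool[r]);
      int j = feat_pool[m];
      for (int i = 0; i < n; ++i) {
        int row = idx[lo + i];
        vals[i] = std::make_pair(X.at(row, j), y[row]);
      }
      std::sort(vals.begin(), vals.begin() + n);
      if (vals[0].first == vals[n - 1].first) continue;  // constant feature
      double sum_left = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sum_left += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        double nl = i + 1, nr = n - i - 1;
        double sr = sum - sum_left;
        double score = sum_left * sum_left / nl + sr * sr / nr;
        if (score > best_score) {
          best_score = score;
          best_feat = j;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_feat < 0) return;  // no valid split among tried features

    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X.at(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == lo || mid == hi) return;  // degenerate; keep as leaf

    tree.feature[node] = best_feat;
    tree.threshold[node] = best_thr;
    int l = tree.new_node();
    tree.left[node] = l;
    grow(tree, l, idx, lo, mid);
    int r2 = tree.new_node();
    tree.right[node] = r2;
    grow(tree, r2, idx, mid, hi);
  }
};

double predict_one(const Tree &tree, const Data &X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X.at(row, tree.feature[node]) <= tree.threshold[node])
               ? tree.left[node]
               : tree.right[node];
  }
  return tree.value[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_regress")]]
NumericVector rf_regress(NumericMatrix X, NumericVector y, NumericMatrix Xtest,
                         int n_trees, int mtry, int min_node) {
  const int n = X.nrow(), p = X.ncol(), nt = Xtest.nrow();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (min_node < 1) min_node = 1;
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  Data dx;  dx.x = X.begin();     dx.n = n;  dx.p = p;
  Data dte; dte.x = Xtest.begin(); dte.n = nt; dte.p = p;

  NumericVector pred(nt, 0.0);
  std::vector<int> idx(n);
  Grower grower(dx, y.begin(), mtry, min_node);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);  // bootstrap rows
    Tree tree;
    int root = tree.new_node();
    grower.grow(tree, root, idx, 0, n);
    for (int i = 0; i < nt; ++i) pred[i] += predict_one(tree, dte, i);
  }
  for (int i = 0; i < nt; ++i) pred[i] /= n_trees;
  return pred;
}
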