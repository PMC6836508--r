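// Random forest classifier (bagged CART trees, Gini impurity, mtry feature
// subsampling). Implemented here because the deployment environment provides
// no tree-ensemble package; the surface mirrors the usual fit/predict pair.
//
// A tree is stored as a numeric matrix with one row per node and columns
// {feat, thr, left, right, prob}: feat == -1 marks a leaf, whose prob is the
// fraction of positive training labels in the node; internal nodes send
// x[feat] <= thr to `left`, else `right` (0-based node indices).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct NodeRec {
  int feat;
  double thr;
  int left;
  int right;
  double prob;
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry;
  int max_depth;  // <= 0 means unbounded
  std::mt19937& rng;
  std::vector<NodeRec> nodes;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int max_depth_, std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), rng(rng_) {}

  int leaf(const std::vector<int>& idx) {
    int pos = 0;
    for (int i : idx) pos += y[i];
    nodes.push_back({-1, 0.0, -1, -1, (double)pos / idx.size()});
    return (int)nodes.size() - 1;
  }

  // returns node index
  int grow(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    if (n < 2 || pos == 0 || pos == n ||
        (max_depth > 0 && depth >= max_depth))
      return leaf(idx);

    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);
    int ntry = std::min(mtry, p);

    double parent_gini = 1.0 - std::pow((double)pos / n, 2) -
                         std::pow(1.0 - (double)pos / n, 2);
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals;
    vals.reserve(n);
    int tried = 0;
    for (int fi = 0; fi < p && tried < ntry; ++fi) {
      int f = feats[fi];
      vals.clear();
      for (int i : idx) vals.emplace_back(X(i, f), y[i]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      ++tried;
      int left_n = 0, left_pos = 0;
      for (int k = 0; k < n - 1; ++k) {
        ++left_n;
        left_pos += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        int right_n = n - left_n;
        int right_pos = pos - left_pos;
        double gl = 1.0 - std::pow((double)left_pos / left_n, 2) -
                    std::pow(1.0 - (double)left_pos / left_n, 2);
        double gr = 1.0 - std::pow((double)right_pos / right_n, 2) -
                    std::pow(1.0 - (double)right_pos / right_n, 2);
        double gain = parent_gini -
                      ((double)left_n / n) * gl - ((double)right_n / n) * gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) return leaf(idx);

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return leaf(idx);

    int me = (int)nodes.size();
    nodes.push_back({best_feat, best_thr, -1, -1, (double)pos / n});
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

double tree_predict(const NumericMatrix& tree, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = X(row, f) <= tree(node, 1) ? (int)tree(node, 2)
                                      : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_grow_cpp")]]
List rf_grow_cpp(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
                 int mtry, int seed) {
  int n = X.nrow();
  if (n == 0) stop("empty training matrix");
  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Grower g(X, y, mtry, max_depth, rng);
    g.grow(idx, 0);
    NumericMatrix tree((int)g.nodes.size(), 5);
    for (size_t k = 0; k < g.nodes.size(); ++k) {
      tree(k, 0) = g.nodes[k].feat;
      tree(k, 1) = g.nodes[k].thr;
      tree(k, 2) = g.nodes[k].left;
      tree(k, 3) = g.nodes[k].right;
      tree(k, 4) = g.nodes[k].prob;
    }
    forest[t] = tree;
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow();
  int nt = forest.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
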