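// Bagged CART regression forest.
//
// Minimal, deterministic random-forest regressor: bootstrap-resampled
// variance-reduction CART trees with per-node feature subsampling (mtry).
// Self-contained RNG (mt19937) so results depend only on the seed argument,
// never on R's RNG state. Trees are returned as numeric node tables so a
// fitted forest survives serialization as plain data.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // node indices, -1 for leaf
  double value;     // mean of training y in node
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double score = -1.0; // variance reduction (>= 0 when valid)
};

// best split of `idx` on feature j by exhaustive sorted scan
void best_split_on_feature(const NumericMatrix &X, const NumericVector &y,
                           const std::vector<int> &idx, int j, int min_leaf,
                           SplitResult &best) {
  const int n = static_cast<int>(idx.size());
  // copy (x, y) pairs out of the matrix so the sort touches plain doubles
  static std::vector<std::pair<double, double>> vals;
  vals.clear();
  vals.reserve(n);
  for (int i : idx) vals.emplace_back(X(i, j), y[i]);
  std::sort(vals.begin(), vals.end(),
            [](const std::pair<double, double> &a,
               const std::pair<double, double> &b) { return a.first < b.first; });

  double sum_total = 0.0;
  for (const auto &v : vals) sum_total += v.second;

  double sum_left = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    sum_left += vals[k].second;
    // cannot split between tied x values
    if (vals[k].first == vals[k + 1].first) continue;
    const int nl = k + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    const double sum_right = sum_total - sum_left;
    // variance reduction up to constants: sum_l^2/n_l + sum_r^2/n_r
    const double score = sum_left * sum_left / nl + sum_right * sum_right / nr;
    if (score > best.score ||
        (score == best.score && best.feature >= 0 && j < best.feature)) {
      best.feature = j;
      best.threshold = 0.5 * (vals[k].first + vals[k + 1].first);
      best.score = score;
    }
  }
}

int grow(const NumericMatrix &X, const NumericVector &y,
         std::vector<int> &idx, int depth, int max_depth, int min_split,
         int min_leaf, int mtry, std::mt19937 &rng, std::vector<Node> &nodes) {
  const int n = static_cast<int>(idx.size());
  double mean = 0.0;
  for (int i : idx) mean += y[i];
  mean /= n;

  Node node{-1, 0.0, -1, -1, mean};
  const int me = static_cast<int>(nodes.size());
  nodes.push_back(node);

  if (n < min_split || (max_depth > 0 && depth >= max_depth)) return me;

  bool constant_y = true;
  for (int i : idx)
    if (y[i] != y[idx[0]]) { constant_y = false; break; }
  if (constant_y) return me;

  // sample mtry candidate features without replacement
  const int p = X.ncol();
  std::vector<int> feats(p);
  std::iota(feats.begin(), feats.end(), 0);
  for (int k = 0; k < mtry && k < p; ++k) {
    std::uniform_int_distribution<int> pick(k, p - 1);
    std::swap(feats[k], feats[pick(rng)]);
  }

  SplitResult best;
  for (int k = 0; k < mtry && k < p; ++k)
    best_split_on_feature(X, y, idx, feats[k], min_leaf, best);
  if (best.feature < 0) return me;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i : idx)
    (X(i, best.feature) <= best.threshold ? left_idx : right_idx).push_back(i);
  if (left_idx.empty() || right_idx.empty()) return me;

  idx.clear();
  idx.shrink_to_fit();

  nodes[me].feature = best.feature;
  nodes[me].threshold = best.threshold;
  const int l = grow(X, y, left_idx, depth + 1, max_depth, min_split,
                     min_leaf, mtry, rng, nodes);
  const int r = grow(X, y, right_idx, depth + 1, max_depth, min_split,
                     min_leaf, mtry, rng, nodes);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

NumericMatrix pack(const std::vector<Node> &nodes) {
  NumericMatrix out(static_cast<int>(nodes.size()), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].value;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value");
  return out;
}

double predict_one(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (true) {
    const int feature = static_cast<int>(tree(node, 0));
    if (feature < 0) return tree(node, 4);
    node = (X(row, feature) <= tree(node, 1))
               ? static_cast<int>(tree(node, 2))
               : static_cast<int>(tree(node, 3));
  }
}

} // namespace

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int max_depth, int min_split, int min_leaf, bool bootstrap,
                int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n < 1) stop("empty training set");
  if (mtry < 1) mtry = 1;
  if (mtry > X.ncol()) mtry = X.ncol();

  std::mt19937 rng(static_cast<unsigned>(seed));
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    idx.reserve(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> pick(0, n - 1);
      for (int i = 0; i < n; ++i) idx.push_back(pick(rng));
    } else {
      idx.resize(n);
      std::iota(idx.begin(), idx.end(), 0);
    }
    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    grow(X, y, idx, 0, max_depth, min_split, min_leaf, mtry, rng, nodes);
    trees[t] = pack(nodes);
  }
  return trees;
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  const int T = trees.size();
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
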