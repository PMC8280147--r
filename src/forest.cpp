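// Native random forest for binary outcomes.
//
// Per tree: bootstrap the training rows, grow a CART tree to purity with
// Gini-impurity splits searched over `mtry` features drawn uniformly at
// node level, leaf prediction = class-1 fraction of the node. Predicted
// probability for a row = mean of its leaf fractions over trees. All
// randomness comes from an internal splitmix64/xoroshiro stream seeded
// from (internal_seed, tree index), so fits are bit-reproducible and
// independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 to fill the xoroshiro128+ state
    auto sm = [&seed]() {
      uint64_t z = (seed += 0x9e3779b97f4a7c15ULL);
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = sm();
    s1 = sm();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = rotl(a, 24) ^ b ^ (b << 16);
    s1 = rotl(b, 37);
    return r;
  }
  // uniform integer in [0, n) by rejection (n << 2^64 so bias is nil anyway)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature;       // -1 for leaf
  double threshold;  // go left if x <= threshold
  int left, right;
  double pred;       // class-1 fraction (leaves)
};

struct Tree {
  std::vector<Node> nodes;
};

struct Forest {
  std::vector<Tree> trees;
  int p;
};

struct WorkItem {
  int node_id;
  int begin, end;  // range in the index buffer
};

// Grow one tree over idx[begin, end) (bootstrap indices into X rows).
void grow_tree(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
               std::vector<int> &idx, int mtry, int min_split, Rng &rng) {
  const int p = X.ncol();
  std::vector<int> feat_pool(p);
  std::vector<std::pair<double, int>> vals;  // (value, label)

  tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  std::vector<WorkItem> stack;
  stack.push_back({0, 0, static_cast<int>(idx.size())});

  while (!stack.empty()) {
    WorkItem w = stack.back();
    stack.pop_back();
    const int n = w.end - w.begin;
    int pos = 0;
    for (int i = w.begin; i < w.end; ++i) pos += y[idx[i]];
    const double frac = static_cast<double>(pos) / n;

    Node &node_init = tree.nodes[w.node_id];
    node_init.pred = frac;
    if (n < min_split || pos == 0 || pos == n) continue;  // leaf

    // draw mtry distinct candidate features (partial Fisher-Yates)
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    int best_feat = -1;
    double best_thr = 0.0;
    double best_score = -std::numeric_limits<double>::infinity();

    for (int d = 0; d < mtry; ++d) {
      int pick = d + rng.below(p - d);
      std::swap(feat_pool[d], feat_pool[pick]);
      const int f = feat_pool[d];

      vals.clear();
      for (int i = w.begin; i < w.end; ++i) {
        vals.emplace_back(X(idx[i], f), y[idx[i]]);
      }
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant

      // scan split points between distinct values; maximize the weighted
      // Gini decrease, equivalently minimize nL*gL + nR*gR
      int pos_left = 0;
      for (int i = 0; i + 1 < n; ++i) {
        pos_left += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int n_left = i + 1;
        const int n_right = n - n_left;
        const double pl = static_cast<double>(pos_left) / n_left;
        const double pr = static_cast<double>(pos - pos_left) / n_right;
        // score = -(weighted child impurity); larger is better
        const double score =
            -(n_left * 2.0 * pl * (1.0 - pl) + n_right * 2.0 * pr * (1.0 - pr));
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_feat < 0) continue;  // all candidates constant: leaf

    // partition idx[begin, end) in place
    int mid = w.begin;
    for (int i = w.begin; i < w.end; ++i) {
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == w.begin || mid == w.end) continue;  // numeric edge case: leaf

    const int left_id = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    const int right_id = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    Node &node = tree.nodes[w.node_id];  // re-borrow: vector may have grown
    node.feature = best_feat;
    node.threshold = best_thr;
    node.left = left_id;
    node.right = right_id;
    stack.push_back({right_id, mid, w.end});
    stack.push_back({left_id, w.begin, mid});
  }
}

double predict_row(const Tree &tree, const NumericMatrix &X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    const Node &nd = tree.nodes[cur];
    cur = (X(row, nd.feature) <= nd.threshold) ? nd.left : nd.right;
  }
  return tree.nodes[cur].pred;
}

}  // namespace

// [[Rcpp::export]]
SEXP rf_fit(NumericMatrix x, IntegerVector y, int n_trees, int mtry,
            int min_split, int seed) {
  const int n = x.nrow();
  if (n != y.size()) stop("row count mismatch");
  if (n < 2) stop("need at least 2 training rows");
  mtry = std::min(std::max(mtry, 1), static_cast<int>(x.ncol()));

  Rcpp::XPtr<Forest> forest(new Forest(), true);
  forest->p = x.ncol();
  forest->trees.resize(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    Rng rng(static_cast<uint64_t>(static_cast<int64_t>(seed)) * 0x100000001ULL +
            static_cast<uint64_t>(t));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);  // bootstrap
    grow_tree(forest->trees[t], x, y, idx, mtry, min_split, rng);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict(SEXP forest_ptr, NumericMatrix x) {
  Rcpp::XPtr<Forest> forest(forest_ptr);
  if (x.ncol() != forest->p) stop("feature count mismatch");
  const int n = x.nrow();
  NumericVector out(n);
  for (const Tree &tree : forest->trees) {
    for (int i = 0; i < n; ++i) out[i] += predict_row(tree, x, i);
  }
  const double k = static_cast<double>(forest->trees.size());
  for (int i = 0; i < n; ++i) out[i] /= k;
  return out;
}
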