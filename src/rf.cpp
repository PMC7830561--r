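// Random-forest classifier with per-tree out-of-bag permutation importance.
//
// No random-forest package ships in this environment, so the inner engine
// of the Boruta wrapper is implemented here: CART trees on bootstrap
// samples (stratified within class), Gini split criterion, mtry features
// per node, grown to purity. Importance of a feature in one tree is the
// drop in OOB accuracy after permuting that feature among the OOB rows;
// the z-score over trees (mean / sd) is computed on the R side.
//
// All randomness comes from a std::mt19937 seeded from R, so results are
// reproducible independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1 for a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int pred = 0;          // majority class at the node
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> used_features;
};

inline double gini(int n0, int n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int mtry,
          std::mt19937& rng)
    : X_(X), y_(y), p_(X.ncol()), mtry_(mtry), rng_(rng) {}

  Tree build(const std::vector<int>& rows) {
    tree_ = Tree();
    used_.assign(p_, false);
    feat_idx_.resize(p_);
    for (int j = 0; j < p_; ++j) feat_idx_[j] = j;
    grow(rows);
    for (int j = 0; j < p_; ++j)
      if (used_[j]) tree_.used_features.push_back(j);
    return tree_;
  }

private:
  int grow(const std::vector<int>& rows) {
    int id = (int)tree_.nodes.size();
    tree_.nodes.push_back(Node());
    int n1 = 0;
    for (int r : rows) n1 += y_[r];
    int n0 = (int)rows.size() - n1;
    tree_.nodes[id].pred = (n1 > n0) ? 1 : 0;
    if (n0 == 0 || n1 == 0 || rows.size() < 2) return id;

    // sample mtry candidate features without replacement
    for (int k = 0; k < mtry_; ++k) {
      std::uniform_int_distribution<int> d(k, p_ - 1);
      std::swap(feat_idx_[k], feat_idx_[d(rng_)]);
    }
    double parent = gini(n0, n1) * rows.size();
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    for (int k = 0; k < mtry_; ++k) {
      int f = feat_idx_[k];
      // one pass: class counts per distinct value, then prefix sums give
      // every threshold's left/right counts (genotypes have <= 3 values)
      dist_.clear();
      for (int r : rows) {
        double v = X_(r, f);
        size_t d = 0;
        for (; d < dist_.size(); ++d) if (dist_[d].v == v) break;
        if (d == dist_.size()) dist_.push_back({v, 0, 0});
        if (y_[r]) ++dist_[d].c1; else ++dist_[d].c0;
      }
      if (dist_.size() < 2) continue;
      std::sort(dist_.begin(), dist_.end(),
                [](const ValCnt& a, const ValCnt& b) { return a.v < b.v; });
      int l0 = 0, l1 = 0;
      for (size_t v = 0; v + 1 < dist_.size(); ++v) {
        l0 += dist_[v].c0; l1 += dist_[v].c1;
        double thr = 0.5 * (dist_[v].v + dist_[v + 1].v);
        int r0 = n0 - l0, r1 = n1 - l1;
        double child = gini(l0, l1) * (l0 + l1) + gini(r0, r1) * (r0 + r1);
        double gain = parent - child;
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_thr = thr;
        }
      }
    }
    if (best_f < 0) return id;
    std::vector<int> left, right;
    for (int r : rows)
      (X_(r, best_f) <= best_thr ? left : right).push_back(r);
    if (left.empty() || right.empty()) return id;
    used_[best_f] = true;
    tree_.nodes[id].feature = best_f;
    tree_.nodes[id].threshold = best_thr;
    int l = grow(left);
    int r = grow(right);
    tree_.nodes[id].left = l;
    tree_.nodes[id].right = r;
    return id;
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  int p_, mtry_;
  std::mt19937& rng_;
  Tree tree_;
  struct ValCnt { double v; int c0, c1; };
  std::vector<bool> used_;
  std::vector<int> feat_idx_;
  std::vector<ValCnt> dist_;
};

inline int predict_row(const Tree& t, const NumericMatrix& X, int row,
                       int perm_feature, double perm_value) {
  int id = 0;
  while (t.nodes[id].feature >= 0) {
    int f = t.nodes[id].feature;
    double x = (f == perm_feature) ? perm_value : X(row, f);
    id = (x <= t.nodes[id].threshold) ? t.nodes[id].left
                                      : t.nodes[id].right;
  }
  return t.nodes[id].pred;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix rf_per_tree_importance_cpp(NumericMatrix X, IntegerVector y,
                                         int n_trees, int mtry, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::vector<int> class0, class1;
  for (int i = 0; i < n; ++i) (y[i] ? class1 : class0).push_back(i);
  if (class0.empty() || class1.empty())
    stop("both classes must be present");

  std::mt19937 rng(static_cast<uint32_t>(seed));
  NumericMatrix imp(n_trees, p);
  std::vector<char> inbag(n);
  std::vector<int> rows, oob;
  std::vector<double> perm_vals;

  for (int t = 0; t < n_trees; ++t) {
    // stratified bootstrap: sample within each class with replacement
    std::fill(inbag.begin(), inbag.end(), 0);
    rows.clear();
    for (const std::vector<int>* cls : {&class0, &class1}) {
      std::uniform_int_distribution<int> d(0, (int)cls->size() - 1);
      for (size_t k = 0; k < cls->size(); ++k) {
        int r = (*cls)[d(rng)];
        rows.push_back(r);
        inbag[r] = 1;
      }
    }
    Builder b(X, y, mtry, rng);
    Tree tree = b.build(rows);

    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;  // importance row stays zero
    int base_correct = 0;
    for (int r : oob)
      if (predict_row(tree, X, r, -1, 0.0) == y[r]) ++base_correct;

    for (int f : tree.used_features) {
      // permute feature f among OOB rows
      perm_vals.resize(oob.size());
      for (size_t k = 0; k < oob.size(); ++k)
        perm_vals[k] = X(oob[k], f);
      for (size_t k = perm_vals.size(); k > 1; --k) {
        std::uniform_int_distribution<size_t> d(0, k - 1);
        std::swap(perm_vals[k - 1], perm_vals[d(rng)]);
      }
      int perm_correct = 0;
      for (size_t k = 0; k < oob.size(); ++k)
        if (predict_row(tree, X, oob[k], f, perm_vals[k]) == y[oob[k]])
          ++perm_correct;
      imp(t, f) = (double)(base_correct - perm_correct) / oob.size();
    }
  }
  return imp;
}
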