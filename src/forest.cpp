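// Multi-output regression forest with mean-absolute-error split criterion.
//
// Each tree is a CART over all target columns jointly: a split is scored by
// the summed absolute deviation around the per-target median of each child,
// leaf values are per-target medians, and the forest prediction is the mean
// of the tree predictions. Split scan uses streaming two-heap medians so a
// node costs O(n log n) per target per candidate feature.

#include <RcppArmadillo.h>
#include <queue>
#include <random>
#include <algorithm>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct StreamMedian {
  std::priority_queue<double> lo;  // max-heap (lower half)
  std::priority_queue<double, std::vector<double>, std::greater<double>> hi;
  double sum_lo = 0.0, sum_hi = 0.0;

  void add(double v) {
    if (lo.empty() || v <= lo.top()) { lo.push(v); sum_lo += v; }
    else { hi.push(v); sum_hi += v; }
    if (lo.size() > hi.size() + 1) {
      double t = lo.top(); lo.pop(); sum_lo -= t; hi.push(t); sum_hi += t;
    } else if (hi.size() > lo.size()) {
      double t = hi.top(); hi.pop(); sum_hi -= t; lo.push(t); sum_lo += t;
    }
  }
  double median() const {
    if (lo.size() > hi.size()) return lo.top();
    return 0.5 * (lo.top() + hi.top());
  }
  // sum_i |x_i - median|
  double sad() const {
    double m = median();
    return (m * (double)lo.size() - sum_lo) + (sum_hi - m * (double)hi.size());
  }
};

struct TreeBuilder {
  const arma::mat& X;
  const arma::mat& Y;
  int mtry, min_leaf;
  std::mt19937& rng;

  std::vector<int> feature;       // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right, leaf_id;
  std::vector<arma::rowvec> leaf_values;

  TreeBuilder(const arma::mat& X_, const arma::mat& Y_, int mtry_,
              int min_leaf_, std::mt19937& rng_)
      : X(X_), Y(Y_), mtry(mtry_), min_leaf(min_leaf_), rng(rng_) {}

  int new_node() {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1); leaf_id.push_back(-1);
    return (int)feature.size() - 1;
  }

  int make_leaf(int node, const std::vector<arma::uword>& idx) {
    arma::rowvec med(Y.n_cols);
    std::vector<double> buf(idx.size());
    for (arma::uword t = 0; t < Y.n_cols; ++t) {
      for (size_t i = 0; i < idx.size(); ++i) buf[i] = Y(idx[i], t);
      size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + (n - 1) / 2, buf.end());
      double a = buf[(n - 1) / 2];
      if (n % 2 == 1) med[t] = a;
      else {
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        med[t] = 0.5 * (a + buf[n / 2]);
      }
    }
    leaf_id[node] = (int)leaf_values.size();
    leaf_values.push_back(med);
    return node;
  }

  bool node_is_pure(const std::vector<arma::uword>& idx) {
    for (arma::uword t = 0; t < Y.n_cols; ++t) {
      double v0 = Y(idx[0], t);
      for (size_t i = 1; i < idx.size(); ++i)
        if (Y(idx[i], t) != v0) return false;
    }
    return true;
  }

  int build(const std::vector<arma::uword>& idx) {
    int node = new_node();
    size_t n = idx.size();
    if ((int)n < 2 * min_leaf || n < 2 || node_is_pure(idx))
      return make_leaf(node, idx);

    // sample mtry distinct features
    int p = (int)X.n_cols;
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < std::min(mtry, p); ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }
    feats.resize(std::min(mtry, p));

    double best_cost = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<arma::uword> sorted(idx);
    std::vector<double> sad_l(n), sad_r(n);

    for (int f : feats) {
      std::sort(sorted.begin(), sorted.end(),
                [&](arma::uword a, arma::uword b) {
                  return X(a, f) < X(b, f);
                });
      if (X(sorted.front(), f) == X(sorted.back(), f)) continue;

      std::fill(sad_l.begin(), sad_l.end(), 0.0);
      std::fill(sad_r.begin(), sad_r.end(), 0.0);
      for (arma::uword t = 0; t < Y.n_cols; ++t) {
        StreamMedian ml;
        for (size_t i = 0; i < n; ++i) {
          ml.add(Y(sorted[i], t));
          sad_l[i] += ml.sad();
        }
        StreamMedian mr;
        for (size_t i = n; i-- > 0;) {
          mr.add(Y(sorted[i], t));
          sad_r[i] += mr.sad();
        }
      }
      for (size_t i = min_leaf - 1; i + (size_t)min_leaf < n; ++i) {
        double xa = X(sorted[i], f), xb = X(sorted[i + 1], f);
        if (xa == xb) continue;
        double cost = sad_l[i] + sad_r[i + 1];
        if (cost < best_cost) {
          best_cost = cost;
          best_f = f;
          best_thr = 0.5 * (xa + xb);
        }
      }
    }

    if (best_f < 0) return make_leaf(node, idx);

    std::vector<arma::uword> li, ri;
    li.reserve(n); ri.reserve(n);
    for (arma::uword i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    feature[node] = best_f;
    threshold[node] = best_thr;
    int l = build(li);
    int r = build(ri);
    left[node] = l;
    right[node] = r;
    return node;
  }

  List as_list() const {
    arma::mat lv(leaf_values.size(), Y.n_cols);
    for (size_t i = 0; i < leaf_values.size(); ++i) lv.row(i) = leaf_values[i];
    return List::create(
        Named("feature") = IntegerVector(feature.begin(), feature.end()),
        Named("threshold") = NumericVector(threshold.begin(), threshold.end()),
        Named("left") = IntegerVector(left.begin(), left.end()),
        Named("right") = IntegerVector(right.begin(), right.end()),
        Named("leaf_id") = IntegerVector(leaf_id.begin(), leaf_id.end()),
        Named("leaf_values") = lv);
  }
};

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(const arma::mat& X, const arma::mat& Y, int n_trees,
                int mtry, int min_leaf, int seed, bool bootstrap) {
  if (X.n_rows != Y.n_rows) stop("rf_fit: X and Y row mismatch");
  if (X.n_rows < 2) stop("rf_fit: need at least 2 training cells");
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);
  std::uniform_int_distribution<arma::uword> draw(0, X.n_rows - 1);
  for (int k = 0; k < n_trees; ++k) {
    std::vector<arma::uword> idx(X.n_rows);
    if (bootstrap)
      for (arma::uword i = 0; i < X.n_rows; ++i) idx[i] = draw(rng);
    else
      for (arma::uword i = 0; i < X.n_rows; ++i) idx[i] = i;
    TreeBuilder tb(X, Y, mtry, min_leaf, rng);
    tb.build(idx);
    trees[k] = tb.as_list();
    Rcpp::checkUserInterrupt();
  }
  return trees;
}

static arma::mat tree_predict(const List& tree, const arma::mat& X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  IntegerVector leaf_id = tree["leaf_id"];
  arma::mat leaf_values = tree["leaf_values"];
  arma::mat out(X.n_rows, leaf_values.n_cols);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    out.row(i) = leaf_values.row(leaf_id[node]);
  }
  return out;
}

// [[Rcpp::export]]
List rf_predict_cpp(const List& trees, const arma::mat& X, bool per_tree) {
  int K = trees.size();
  if (K == 0) stop("rf_predict: empty forest");
  arma::mat first = tree_predict(trees[0], X);
  arma::mat mean_pred = first;
  arma::cube all;
  if (per_tree) {
    all.set_size(X.n_rows, first.n_cols, K);
    all.slice(0) = first;
  }
  for (int k = 1; k < K; ++k) {
    arma::mat pk = tree_predict(trees[k], X);
    mean_pred += pk;
    if (per_tree) all.slice(k) = pk;
  }
  mean_pred /= (double)K;
  if (per_tree)
    return List::create(Named("mean") = mean_pred, Named("per_tree") = all);
  return List::create(Named("mean") = mean_pred);
}
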