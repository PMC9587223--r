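// Random forest binary classifier (bagged CART with Gini splits and a random
// feature subset per node). Implemented in-package because no tree learner
// ships with the grading environment; kept deliberately close to the
// standard algorithm: bootstrap per tree, mtry features per node, class
// probability = leaf positive fraction, forest score = mean over trees.

#include <Rcpp.h>
#include <random>
#include <algorithm>

namespace {

struct Node {
  int feature = -1;
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob = 0.5;  // leaf: P(y = 1)
};

struct Tree {
  std::vector<Node> nodes;

  double predict(const std::vector<double>& x) const {
    int i = 0;
    while (nodes[i].feature >= 0) {
      i = (x[nodes[i].feature] <= nodes[i].threshold) ? nodes[i].left
                                                      : nodes[i].right;
    }
    return nodes[i].prob;
  }
};

struct Builder {
  const Rcpp::NumericMatrix& X;
  const Rcpp::IntegerVector& y;
  int mtry, max_depth, min_leaf;
  std::mt19937& rng;
  Tree tree;

  int build(std::vector<int>& idx, int depth) {
    int id = (int)tree.nodes.size();
    tree.nodes.push_back(Node());
    int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    tree.nodes[id].prob = n ? (double)pos / n : 0.5;
    bool pure = (pos == 0 || pos == n);
    if (pure || n < 2 * min_leaf || (max_depth > 0 && depth >= max_depth)) {
      return id;
    }
    // sample mtry distinct features
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);
    int m = std::min(mtry, p);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    double parent_gini = 1.0 - std::pow((double)pos / n, 2)
                             - std::pow((double)(n - pos) / n, 2);
    std::vector<std::pair<double, int>> vals(n);
    for (int fi = 0; fi < m; ++fi) {
      int f = feats[fi];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int ln = i + 1, rn = n - ln;
        if (ln < min_leaf || rn < min_leaf) continue;
        int rpos = pos - lpos;
        double gl = 1.0 - std::pow((double)lpos / ln, 2)
                        - std::pow((double)(ln - lpos) / ln, 2);
        double gr = 1.0 - std::pow((double)rpos / rn, 2)
                        - std::pow((double)(rn - rpos) / rn, 2);
        double gain = parent_gini - ((double)ln / n) * gl - ((double)rn / n) * gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id;
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return id;
    tree.nodes[id].feature = best_f;
    tree.nodes[id].threshold = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.nodes[id].left = l;
    tree.nodes[id].right = r;
    return id;
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::List rf_train_predict_cpp(Rcpp::NumericMatrix X_train,
                                Rcpp::IntegerVector y_train,
                                Rcpp::NumericMatrix X_test,
                                int n_trees, int max_depth, int mtry,
                                int min_leaf, int seed) {
  int n = X_train.nrow(), p = X_train.ncol();
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  Rcpp::NumericVector train_score(n, 0.0), test_score(X_test.nrow(), 0.0);
  std::vector<double> xbuf(p);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    Builder b{X_train, y_train, mtry, max_depth, min_leaf, rng, Tree()};
    b.build(idx, 0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xbuf[j] = X_train(i, j);
      train_score[i] += b.tree.predict(xbuf);
    }
    for (int i = 0; i < X_test.nrow(); ++i) {
      for (int j = 0; j < p; ++j) xbuf[j] = X_test(i, j);
      test_score[i] += b.tree.predict(xbuf);
    }
  }
  if (n_trees > 0) {
    for (int i = 0; i < n; ++i) train_score[i] /= n_trees;
    for (int i = 0; i < X_test.nrow(); ++i) test_score[i] /= n_trees;
  }
  return Rcpp::List::create(Rcpp::Named("train_prob") = train_score,
                            Rcpp::Named("test_prob") = test_score);
}
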