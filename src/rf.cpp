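// Random forest classifier core: bagged CART trees with Gini impurity and
// random feature subsets at each node. Trees are stored as flat matrices
// (columns: feature, threshold, left, right, pred) with feature = -1
// marking a leaf whose pred is the class-1 proportion. Uses R's RNG so
// forests are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, max_depth;
  std::vector<double> feature, threshold, pred;
  std::vector<int> left, right;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, int max_depth_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_) {}

  int add_node() {
    feature.push_back(-1);
    threshold.push_back(0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(0);
    return (int)feature.size() - 1;
  }

  // Sample mtry distinct feature indices out of p via partial Fisher-Yates.
  std::vector<int> sample_features(int p) {
    std::vector<int> idx(p);
    for (int i = 0; i < p; ++i) idx[i] = i;
    int m = std::min(mtry, p);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(idx[i], idx[j]);
    }
    idx.resize(m);
    return idx;
  }

  int grow(std::vector<int>& rows, int depth) {
    int node = add_node();
    int n = (int)rows.size();
    int n1 = 0;
    for (int r : rows) n1 += y[r];
    pred[node] = (double)n1 / n;
    if (n1 == 0 || n1 == n || n < 2 * min_node || depth >= max_depth) {
      return node;
    }

    double best_gain = 1e-12;  // require strictly positive impurity decrease
    int best_f = -1;
    double best_thr = 0;
    double parent_gini =
        1.0 - ((double)n1 * n1 + (double)(n - n1) * (n - n1)) / ((double)n * n);

    std::vector<int> feats = sample_features(X.ncol());
    std::vector<std::pair<double, int> > vals(n);
    for (int f : feats) {
      for (int i = 0; i < n; ++i) {
        vals[i] = std::make_pair(X(rows[i], f), y[rows[i]]);
      }
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first >= vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        int r1 = n1 - l1;
        double gl = 1.0 - ((double)l1 * l1 + (double)(nl - l1) * (nl - l1)) /
                              ((double)nl * nl);
        double gr = 1.0 - ((double)r1 * r1 + (double)(nr - r1) * (nr - r1)) /
                              ((double)nr * nr);
        double gain = parent_gini - (nl * gl + nr * gr) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (X(r, best_f) <= best_thr) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) return node;  // numeric safety
    feature[node] = best_f;
    threshold[node] = best_thr;
    rows.clear(); rows.shrink_to_fit();
    left[node] = grow(lrows, depth + 1);
    right[node] = grow(rrows, depth + 1);
    return node;
  }

  NumericMatrix to_matrix() const {
    int n = (int)feature.size();
    NumericMatrix M(n, 5);
    for (int i = 0; i < n; ++i) {
      M(i, 0) = feature[i];
      M(i, 1) = threshold[i];
      M(i, 2) = left[i];
      M(i, 3) = right[i];
      M(i, 4) = pred[i];
    }
    colnames(M) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "pred");
    return M;
  }
};

double predict_one(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1)) ? (int)tree(node, 2)
                                                         : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix grow_tree_cpp(NumericMatrix X, IntegerVector y,
                            IntegerVector rows, int mtry, int min_node,
                            int max_depth) {
  TreeBuilder tb(X, y, mtry, min_node, max_depth);
  std::vector<int> r(rows.begin(), rows.end());
  tb.grow(r, 0);
  return tb.to_matrix();
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector votes(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tree = trees[b];
    for (int i = 0; i < n; ++i) {
      votes[i] += (predict_one(tree, X, i) >= 0.5) ? 1.0 : 0.0;
    }
  }
  return votes / (double)B;
}
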