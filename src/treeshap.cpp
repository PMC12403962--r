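// Path-dependent TreeSHAP for binary-split decision forests, plus the tree
// traversal helpers needed to drive it from exported ranger tree structures.
//
// Trees are passed as parallel arrays per node: left/right child index
// (0-based, -1 for leaf), split feature (0-based, -1 for leaf), split
// threshold (rule: x[feature] <= threshold goes left), per-node cover
// (training sample count) and a nodes x nclass matrix of leaf values.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(std::vector<PathElement> &path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature) {
  path[unique_depth].feature = feature;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
                           static_cast<double>(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) /
                      static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(std::vector<PathElement> &path, int unique_depth,
                        int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1) /
                        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                                   (unique_depth - i) /
                                   static_cast<double>(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
                        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const std::vector<PathElement> &path,
                               int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
                                               ((unique_depth - i) /
                                                static_cast<double>(unique_depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left;
  const int *right;
  const int *feature;
  const double *threshold;
  const double *cover;
  const double *values;  // nodes x nclass, column-major
  int n_nodes;
  int n_class;
};

// phi: (n_features + 1) x n_class column-major accumulator for one sample;
// the last row collects the expected value (bias) term.
static void tree_shap_recursive(const Tree &tree, const double *x,
                                std::vector<PathElement> path,
                                int unique_depth, double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature, int node,
                                std::vector<double> &phi, int n_features) {
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature);
  if (tree.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      const PathElement &el = path[i];
      const double scale = w * (el.one_fraction - el.zero_fraction);
      for (int c = 0; c < tree.n_class; ++c)
        phi[el.feature + c * (n_features + 1)] +=
            scale * tree.values[node + c * tree.n_nodes];
    }
    return;
  }
  const int split_feature = tree.feature[node];
  int hot, cold;
  if (x[split_feature] <= tree.threshold[node]) {
    hot = tree.left[node];
    cold = tree.right[node];
  } else {
    hot = tree.right[node];
    cold = tree.left[node];
  }
  const double w = tree.cover[node];
  const double hot_zero_fraction = tree.cover[hot] / w;
  const double cold_zero_fraction = tree.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature == split_feature) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, path, unique_depth + 1,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature, hot, phi,
                      n_features);
  tree_shap_recursive(tree, x, path, unique_depth + 1,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_feature, cold, phi, n_features);
}

static Tree unpack_tree(const List &tr) {
  Tree t;
  t.left = INTEGER(as<IntegerVector>(tr["left"]));
  t.right = INTEGER(as<IntegerVector>(tr["right"]));
  t.feature = INTEGER(as<IntegerVector>(tr["feature"]));
  t.threshold = REAL(as<NumericVector>(tr["threshold"]));
  t.cover = REAL(as<NumericVector>(tr["cover"]));
  NumericMatrix vals = as<NumericMatrix>(tr["values"]);
  t.values = REAL(vals);
  t.n_nodes = vals.nrow();
  t.n_class = vals.ncol();
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_tree_covers(IntegerVector left, IntegerVector right,
                              IntegerVector feature, NumericVector threshold,
                              NumericMatrix X) {
  const int n_nodes = left.size();
  NumericVector cover(n_nodes);
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    for (;;) {
      cover[node] += 1.0;
      if (feature[node] < 0) break;
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    }
  }
  return cover;
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = forest.size();
  Tree t0 = unpack_tree(forest[0]);
  NumericMatrix out(n, t0.n_class);
  std::vector<double> row(X.ncol());
  for (int tix = 0; tix < n_trees; ++tix) {
    Tree t = unpack_tree(forest[tix]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (t.feature[node] >= 0)
        node = X(i, t.feature[node]) <= t.threshold[node] ? t.left[node]
                                                          : t.right[node];
      for (int c = 0; c < t.n_class; ++c)
        out(i, c) += t.values[node + c * t.n_nodes];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < t0.n_class; ++c) out(i, c) /= n_trees;
  return out;
}

// Returns an n x n_features x n_class array of per-sample SHAP values,
// summed over trees (each tree's contribution averaged by 1/n_trees so the
// attributions decompose the forest's averaged prediction).
// [[Rcpp::export]]
NumericVector cpp_forest_shap(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int n_features = X.ncol();
  const int n_trees = forest.size();
  Tree t0 = unpack_tree(forest[0]);
  const int n_class = t0.n_class;
  NumericVector out(static_cast<R_xlen_t>(n) * n_features * n_class);
  std::vector<double> x(n_features);
  std::vector<double> phi((n_features + 1) * n_class);
  int max_depth = 0;
  for (int tix = 0; tix < n_trees; ++tix) {
    Tree t = unpack_tree(forest[tix]);
    // depth bound for the path buffer
    std::vector<int> depth(t.n_nodes, 0);
    for (int nd = 0; nd < t.n_nodes; ++nd) {
      if (t.feature[nd] >= 0) {
        depth[t.left[nd]] = depth[nd] + 1;
        depth[t.right[nd]] = depth[nd] + 1;
        if (depth[nd] + 1 > max_depth) max_depth = depth[nd] + 1;
      }
    }
  }
  std::vector<PathElement> path(max_depth + 2);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n_features; ++j) x[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int tix = 0; tix < n_trees; ++tix) {
      Tree t = unpack_tree(forest[tix]);
      tree_shap_recursive(t, x.data(), path, 0, 1.0, 1.0, -1, 0, phi,
                          n_features);
    }
    for (int c = 0; c < n_class; ++c)
      for (int j = 0; j < n_features; ++j)
        out[i + static_cast<R_xlen_t>(j) * n +
            static_cast<R_xlen_t>(c) * n * n_features] =
            phi[j + c * (n_features + 1)] / n_trees;
  }
  out.attr("dim") = IntegerVector::create(n, n_features, n_class);
  return out;
}
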