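// Exact path-dependent TreeSHAP for gradient-boosted tree ensembles,
// computed in double precision. Attributions of each tree sum exactly to
// leaf(x) - E[tree], so base value + sum(phi) reproduces the ensemble
// margin to numerical precision.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *path, unsigned depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[depth].feature_index = feature_index;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1.0) / (depth + 1.0);
    path[i].pweight =
        zero_fraction * path[i].pweight * (depth - i) / (depth + 1.0);
  }
}

static void unwind_path(PathElement *path, unsigned depth,
                        unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight =
          next_one_portion * (depth + 1.0) / ((i + 1.0) * one_fraction);
      next_one_portion =
          tmp - path[i].pweight * zero_fraction * (depth - i) / (depth + 1.0);
    } else {
      path[i].pweight =
          (path[i].pweight * (depth + 1.0)) / (zero_fraction * (depth - i));
    }
  }
  for (unsigned i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, unsigned depth,
                               unsigned index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  double total = 0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp =
          next_one_portion * (depth + 1.0) / ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion =
          path[i].pweight - tmp * zero_fraction * (depth - i) / (depth + 1.0);
    } else {
      total +=
          (path[i].pweight / zero_fraction) / ((depth - i) / (depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  const int *feature;   // -1 for leaf
  const double *split;
  const int *yes;
  const int *no_;
  const double *value;  // leaf value
  const double *cover;
};

static void tree_shap_recursive(const Tree &tree, int node,
                                const NumericVector &x,
                                std::vector<PathElement> &parent_path,
                                unsigned unique_depth,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index, double *phi) {
  // each call works on its own copy of the path
  std::vector<PathElement> path(parent_path.begin(),
                                parent_path.begin() + unique_depth);
  path.resize(unique_depth + 2);
  extend_path(path.data(), unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  const int f = tree.feature[node];
  if (f < 0) { // leaf
    const double v = tree.value[node];
    for (unsigned i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path.data(), unique_depth, i);
      phi[path[i].feature_index] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * v;
    }
    return;
  }

  const int yes = tree.yes[node], no_ = tree.no_[node];
  const int hot = ((float)x[f] < (float)tree.split[node]) ? yes : no_;
  const int cold = (hot == yes) ? no_ : yes;
  const double w_node = tree.cover[node];
  const double hot_frac = tree.cover[hot] / w_node;
  const double cold_frac = tree.cover[cold] / w_node;

  double incoming_zero = 1.0, incoming_one = 1.0;
  unsigned path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (path[path_index].feature_index == f) break;
  }
  unsigned depth_here = unique_depth;
  if (path_index != unique_depth + 1) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    unwind_path(path.data(), depth_here, path_index);
    depth_here -= 1;
  }

  tree_shap_recursive(tree, hot, x, path, depth_here + 1,
                      hot_frac * incoming_zero, incoming_one, f, phi);
  tree_shap_recursive(tree, cold, x, path, depth_here + 1,
                      cold_frac * incoming_zero, 0.0, f, phi);
}

static double tree_expected(const Tree &tree, int node) {
  if (tree.feature[node] < 0) return tree.value[node];
  const int yes = tree.yes[node], no_ = tree.no_[node];
  const double w = tree.cover[node];
  return (tree.cover[yes] * tree_expected(tree, yes) +
          tree.cover[no_] * tree_expected(tree, no_)) / w;
}

static double tree_predict(const Tree &tree, int node,
                           const NumericVector &x) {
  while (tree.feature[node] >= 0) {
    node = ((float)x[tree.feature[node]] < (float)tree.split[node])
               ? tree.yes[node]
               : tree.no_[node];
  }
  return tree.value[node];
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(NumericMatrix X, IntegerVector tree_offset,
                  IntegerVector feature, NumericVector split,
                  IntegerVector yes, IntegerVector no_,
                  NumericVector value, NumericVector cover,
                  double base_margin) {
  const int n = X.nrow(), p = X.ncol();
  const int n_trees = tree_offset.size() - 1;
  NumericMatrix phi(n, p);
  NumericVector margin(n);

  // expected value per tree (cover-weighted leaf mean)
  double expected_sum = 0;
  std::vector<Tree> trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    trees[t] = Tree{feature.begin() + off, split.begin() + off,
                    yes.begin() + off,     no_.begin() + off,
                    value.begin() + off,   cover.begin() + off};
    expected_sum += tree_expected(trees[t], 0);
  }
  const double base_value = base_margin + expected_sum;

  std::vector<PathElement> scratch;
  for (int i = 0; i < n; ++i) {
    NumericVector xi = X(i, _);
    double *phi_row = new double[p]();
    double m = base_margin;
    for (int t = 0; t < n_trees; ++t) {
      scratch.clear();
      tree_shap_recursive(trees[t], 0, xi, scratch, 0, 1.0, 1.0, -1,
                          phi_row);
      m += tree_predict(trees[t], 0, xi);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phi_row[j];
    margin[i] = m;
    delete[] phi_row;
  }
  return List::create(_["phi"] = phi, _["base"] = base_value,
                      _["margin"] = margin);
}
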