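#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Double-precision evaluation and exact tree-path Shapley attribution for
// an additive tree ensemble. The ensemble is passed as flat node arrays
// (one entry per node across all trees): feature index (-1 for leaves),
// split threshold (go "yes" when x < threshold), yes/no child indices
// (global, -1 for leaves), leaf value, and node cover (training-sample
// weight), plus per-tree offsets.

struct PathElement {
  int d;        // feature index of the split that created this element
  double z;     // fraction of "zero" (feature-excluded) paths flowing through
  double o;     // fraction of "one" (feature-included) paths
  double w;     // permutation weight
};

static void extend_path(std::vector<PathElement>& m, double pz, double po,
                        int pi) {
  int l = (int)m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(l + 1);
    m[i].w = pz * m[i].w * (l - i) / (double)(l + 1);
  }
}

static std::vector<PathElement> unwind_path(const std::vector<PathElement>& m,
                                            int i) {
  int l = (int)m.size() - 1;           // index of last element
  double oz = m[i].z, oo = m[i].o;
  std::vector<PathElement> out(m.begin(), m.end() - 1);
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (oo != 0.0) {
      double t = out[j].w;
      out[j].w = n * (l + 1) / ((double)(j + 1) * oo);
      n = t - out[j].w * oz * (l - j) / (double)(l + 1);
    } else {
      out[j].w = out[j].w * (l + 1) / (oz * (double)(l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    out[j].d = m[j + 1].d;
    out[j].z = m[j + 1].z;
    out[j].o = m[j + 1].o;
  }
  return out;
}

static double unwound_sum(const std::vector<PathElement>& m, int i) {
  int l = (int)m.size() - 1;
  double oz = m[i].z, oo = m[i].o;
  double total = 0.0, n = m[l].w;
  if (oo != 0.0) {
    for (int j = l - 1; j >= 0; --j) {
      double t = n * (l + 1) / ((double)(j + 1) * oo);
      total += t;
      n = m[j].w - t * oz * (l - j) / (double)(l + 1);
    }
  } else {
    for (int j = l - 1; j >= 0; --j) {
      total += m[j].w * (l + 1) / (oz * (double)(l - j));
    }
  }
  return total;
}

struct Forest {
  const IntegerVector& feature;
  const NumericVector& threshold;
  const IntegerVector& yes;
  const IntegerVector& no;
  const NumericVector& value;
  const NumericVector& cover;
};

static void recurse(const Forest& f, const NumericVector& x, int node,
                    std::vector<PathElement> m, double pz, double po, int pi,
                    std::vector<double>& phi) {
  extend_path(m, pz, po, pi);
  int d = f.feature[node];
  if (d < 0) {                                   // leaf
    for (int i = 1; i < (int)m.size(); ++i) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * f.value[node];
    }
    return;
  }
  int hot = (x[d] < f.threshold[node]) ? f.yes[node] : f.no[node];
  int cold = (hot == f.yes[node]) ? f.no[node] : f.yes[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i) {
    if (m[i].d == d) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    m = unwind_path(m, k);
  }
  double rj = f.cover[node];
  recurse(f, x, hot, m, iz * f.cover[hot] / rj, io, d, phi);
  recurse(f, x, cold, m, iz * f.cover[cold] / rj, 0.0, d, phi);
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
NumericMatrix treeshap_cpp(NumericMatrix X, IntegerVector tree_root,
                           IntegerVector feature, NumericVector threshold,
                           IntegerVector yes, IntegerVector no,
                           NumericVector value, NumericVector cover,
                           int n_features) {
  int n = X.nrow();
  Forest f{feature, threshold, yes, no, value, cover};
  NumericMatrix out(n, n_features);
  for (int r = 0; r < n; ++r) {
    NumericVector x = X.row(r);
    std::vector<double> phi(n_features, 0.0);
    for (int t = 0; t < tree_root.size(); ++t) {
      recurse(f, x, tree_root[t], std::vector<PathElement>(), 1.0, 1.0, -1,
              phi);
    }
    for (int j = 0; j < n_features; ++j) out(r, j) = phi[j];
  }
  return out;
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
NumericVector tree_predict_cpp(NumericMatrix X, IntegerVector tree_root,
                               IntegerVector feature, NumericVector threshold,
                               IntegerVector yes, IntegerVector no,
                               NumericVector value, double base_score) {
  int n = X.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    double acc = base_score;
    for (int t = 0; t < tree_root.size(); ++t) {
      int node = tree_root[t];
      while (feature[node] >= 0) {
        node = (X(r, feature[node]) < threshold[node]) ? yes[node] : no[node];
      }
      acc += value[node];
    }
    out[r] = acc;
  }
  return out;
}

// Expected value of the ensemble under the training distribution encoded by
// the covers: cover-weighted mean of leaf values, summed over trees.
// [[Rcpp::export(name = ".tree_expected_cpp")]]
double tree_expected_cpp(IntegerVector tree_root, IntegerVector feature,
                         IntegerVector yes, IntegerVector no,
                         NumericVector value, NumericVector cover,
                         double base_score) {
  double total = base_score;
  std::vector<int> stack;
  for (int t = 0; t < tree_root.size(); ++t) {
    double root_cover = cover[tree_root[t]];
    stack.push_back(tree_root[t]);
    double acc = 0.0;
    while (!stack.empty()) {
      int node = stack.back();
      stack.pop_back();
      if (feature[node] < 0) {
        acc += value[node] * cover[node] / root_cover;
      } else {
        stack.push_back(yes[node]);
        stack.push_back(no[node]);
      }
    }
    total += acc;
  }
  return total;
}
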