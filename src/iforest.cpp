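// Isolation forest (Liu, Ting & Zhou): random binary partition trees on
// subsamples; anomalies isolate in short paths. Uses R's RNG, so results
// are reproducible under set.seed() on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Average unsuccessful-search path length of a BST with n points.
static double avg_path(double n) {
  if (n <= 1.0) return 0.0;
  if (n == 2.0) return 1.0;
  const double euler = 0.5772156649015329;
  return 2.0 * (std::log(n - 1.0) + euler) - 2.0 * (n - 1.0) / n;
}

struct ForestBuilder {
  const NumericMatrix& X;
  int depth_limit;
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left, right, size;

  ForestBuilder(const NumericMatrix& X_, int depth_limit_)
      : X(X_), depth_limit(depth_limit_) {}

  // Builds the subtree for rows[lo, hi) at `depth`; returns node index.
  int build(std::vector<int>& rows, int lo, int hi, int depth) {
    int node = feat.size();
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    size.push_back(hi - lo);
    if (hi - lo <= 1 || depth >= depth_limit) return node;

    // candidate features: non-constant over this node's rows
    int p = X.ncol();
    std::vector<int> cand;
    cand.reserve(p);
    for (int j = 0; j < p; ++j) {
      double mn = X(rows[lo], j), mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = X(rows[i], j);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx > mn) cand.push_back(j);
    }
    if (cand.empty()) return node; // duplicate rows: leaf

    int q = cand[(int)std::floor(unif_rand() * cand.size())];
    double mn = X(rows[lo], q), mx = mn;
    for (int i = lo + 1; i < hi; ++i) {
      double v = X(rows[i], q);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    double split = mn + unif_rand() * (mx - mn);

    // partition rows in place
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(rows[i], q) < split) std::swap(rows[mid++], rows[i]);
    }
    if (mid == lo || mid == hi) return node; // degenerate split: leaf

    feat[node] = q;
    thr[node] = split;
    int l = build(rows, lo, mid, depth + 1);
    int r = build(rows, mid, hi, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

// [[Rcpp::export]]
List iforest_build(NumericMatrix X, int n_trees, int sample_size) {
  int n = X.nrow();
  int psi = std::min(sample_size, n);
  int depth_limit = (int)std::ceil(std::log2((double)std::max(psi, 2)));
  ForestBuilder fb(X, depth_limit);
  IntegerVector roots(n_trees);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  GetRNGstate();
  for (int t = 0; t < n_trees; ++t) {
    // partial Fisher-Yates subsample without replacement
    std::vector<int> rows(all);
    for (int i = 0; i < psi; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      std::swap(rows[i], rows[j]);
    }
    rows.resize(psi);
    roots[t] = fb.build(rows, 0, psi, 0);
  }
  PutRNGstate();
  return List::create(
      _["feature"] = wrap(fb.feat), _["threshold"] = wrap(fb.thr),
      _["left"] = wrap(fb.left), _["right"] = wrap(fb.right),
      _["size"] = wrap(fb.size), _["roots"] = roots,
      _["sample_size"] = psi);
}

// [[Rcpp::export]]
NumericVector iforest_path_scores(List forest, NumericMatrix X) {
  IntegerVector feat = forest["feature"];
  NumericVector thr = forest["threshold"];
  IntegerVector left = forest["left"];
  IntegerVector right = forest["right"];
  IntegerVector size = forest["size"];
  IntegerVector roots = forest["roots"];
  int psi = forest["sample_size"];
  int n = X.nrow();
  int n_trees = roots.size();
  NumericVector out(n);
  double norm = avg_path((double)psi);
  if (norm <= 0.0) norm = 1.0;
  for (int i = 0; i < n; ++i) {
    double total = 0.0;
    for (int t = 0; t < n_trees; ++t) {
      int node = roots[t];
      int depth = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) < thr[node]) ? left[node] : right[node];
        ++depth;
      }
      total += depth + avg_path((double)size[node]);
    }
    out[i] = std::pow(2.0, -(total / n_trees) / norm);
  }
  return out;
}
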