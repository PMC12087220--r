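// Randomized regression-tree ensemble for TF -> target importance weights
// (GENIE3-style): bootstrap per tree, sqrt-mtry feature sampling per node,
// best SSE-reducing split; a feature's importance accumulates the variance
// reduction of its splits. Self-contained xorshift RNG keeps results
// deterministic given the seed and independent of R's RNG state.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 2685821657736338717ULL + 1ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Builder {
  const NumericMatrix& x;
  const std::vector<double>& y;
  int mtry, min_node;
  Rng& rng;
  std::vector<double>& importance;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& x_, const std::vector<double>& y_, int mtry_,
          int min_node_, Rng& rng_, std::vector<double>& imp_)
      : x(x_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_),
        importance(imp_), feat_pool(x_.ncol()) {
    for (int i = 0; i < x_.ncol(); ++i) feat_pool[i] = i;
  }

  void grow(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    if (n < 2 * min_node) return;
    double sum = 0, sum2 = 0;
    for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; sum2 += y[idx[i]] * y[idx[i]]; }
    double sse_parent = sum2 - sum * sum / n;
    if (sse_parent <= 1e-12) return;

    // partial fisher-yates for mtry candidate features
    for (int i = 0; i < mtry; ++i) {
      int j = i + rng.below((int)feat_pool.size() - i);
      std::swap(feat_pool[i], feat_pool[j]);
    }

    double best_gain = 0, best_thr = 0;
    int best_feat = -1;
    std::vector<std::pair<double, double>> vals(n);
    for (int f = 0; f < mtry; ++f) {
      int feat = feat_pool[f];
      for (int i = 0; i < n; ++i)
        vals[i] = {x(idx[lo + i], feat), y[idx[lo + i]]};
      std::sort(vals.begin(), vals.end());
      double ls = 0, ls2 = 0;
      for (int i = 0; i < n - 1; ++i) {
        ls += vals[i].second; ls2 += vals[i].second * vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double rs = sum - ls, rs2 = sum2 - ls2;
        double sse = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
        double gain = sse_parent - sse;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = feat;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return;
    importance[best_feat] += best_gain;

    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (x(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    grow(idx, lo, mid);
    grow(idx, mid, hi);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix x, NumericVector y,
                                int n_trees, int mtry, int min_node,
                                int seed) {
  int n = x.nrow(), p = x.ncol();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<double> importance(p, 0.0);
  Rng rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);  // bootstrap
    Builder b(x, yy, std::min(mtry, p), min_node, rng, importance);
    b.grow(idx, 0, n);
  }
  return wrap(importance);
}
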