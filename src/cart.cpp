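#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// CART (gini impurity) with per-split random feature subsampling: the tree
// grower behind the package's random forest. Uses R's RNG (so forests are
// reproducible under set.seed on the R side). Ties in split search break
// toward the lower feature index / lower threshold for determinism.

struct Node {
  int feature = -1;     // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;         // 1..K majority class
};

static double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double g = 1.0;
  for (double c : cnt) {
    double p = c / n;
    g -= p * p;
  }
  return g;
}

static int majority(const std::vector<double>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = (int)k;
  return best + 1;
}

// [[Rcpp::export]]
List cpp_cart_grow(NumericMatrix X, IntegerVector y, int K, IntegerVector rows,
                   int mtry, int maxdepth, int minleaf) {
  int p = X.ncol();
  double ntotal = rows.size();
  std::vector<Node> nodes;
  std::vector<double> importance(p, 0.0);

  struct Item {
    std::vector<int> idx;
    int depth;
    int node_id;
  };
  std::vector<Item> stack;
  {
    std::vector<int> all(rows.size());
    for (int i = 0; i < rows.size(); ++i) all[i] = rows[i] - 1;
    nodes.push_back(Node());
    stack.push_back({std::move(all), 0, 0});
  }

  std::vector<int> featpool(p);

  while (!stack.empty()) {
    Item it = std::move(stack.back());
    stack.pop_back();
    std::vector<int>& idx = it.idx;
    double n = idx.size();
    std::vector<double> cnt(K, 0.0);
    for (int i : idx) cnt[y[i] - 1] += 1.0;
    Node& nd = nodes[it.node_id];
    nd.pred = majority(cnt);
    double g0 = gini_from_counts(cnt, n);
    if (g0 <= 0.0 || it.depth >= maxdepth || n < 2.0 * minleaf) continue;

    // sample mtry features without replacement (partial Fisher-Yates, R RNG)
    for (int f = 0; f < p; ++f) featpool[f] = f;
    int m = std::min(mtry, p);
    for (int f = 0; f < m; ++f) {
      int j = f + (int)std::floor(unif_rand() * (p - f));
      if (j >= p) j = p - 1;
      std::swap(featpool[f], featpool[j]);
    }
    std::sort(featpool.begin(), featpool.begin() + m); // deterministic order

    double best_gain = 0.0, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int>> vals(idx.size());
    for (int fi = 0; fi < m; ++fi) {
      int f = featpool[fi];
      for (size_t i = 0; i < idx.size(); ++i)
        vals[i] = {X(idx[i], f), y[idx[i]] - 1};
      std::sort(vals.begin(), vals.end());
      std::vector<double> lcnt(K, 0.0), rcnt(cnt);
      double nl = 0.0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        lcnt[vals[i].second] += 1.0;
        rcnt[vals[i].second] -= 1.0;
        nl += 1.0;
        if (vals[i].first == vals[i + 1].first) continue;
        double nr = n - nl;
        if (nl < minleaf || nr < minleaf) continue;
        double gain = g0 - (nl / n) * gini_from_counts(lcnt, nl) -
                      (nr / n) * gini_from_counts(rcnt, nr);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue;

    importance[best_f] += (n / ntotal) * best_gain;
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) continue;
    int lid = (int)nodes.size();
    nodes.push_back(Node());
    int rid = (int)nodes.size();
    nodes.push_back(Node());
    Node& nd2 = nodes[it.node_id]; // re-reference (vector may have grown)
    nd2.feature = best_f;
    nd2.thr = best_thr;
    nd2.left = lid;
    nd2.right = rid;
    stack.push_back({std::move(ri), it.depth + 1, rid});
    stack.push_back({std::move(li), it.depth + 1, lid});
  }

  int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), pred(nn);
  NumericVector thr(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    thr[i] = nodes[i].thr;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["thr"] = thr,
                      _["left"] = left, _["right"] = right, _["pred"] = pred,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export]]
IntegerVector cpp_cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector thr = tree["thr"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
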