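#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Multiresolution region merging (Baatz-Schaepe style heterogeneity).
//
// Each region tracks per-layer sum / sum-of-squares, pixel count, boundary
// length and bounding box.  The merge cost of an adjacent pair is
//   f = w_color * sum_l w_l * (n_m*sd_m - n_a*sd_a - n_b*sd_b)
//     + w_shape * (cmpct * d_compact + (1-cmpct) * d_smooth)
// with compact(r) = sqrt(n)*perimeter and smooth(r) = n*perimeter/bboxperim.
// Pairs are merged cheapest-first (the global minimum pair is always a
// mutual best fit); merging stops when the cheapest valid cost >= scale^2,
// so scale = 0 performs no merges at all.
// Tie-break: (cost, min id, max id), ids in row-major pixel order, so runs
// are deterministic.

struct Region {
  double n = 0.0;
  std::vector<double> sum, ssq;
  double perim = 0.0;
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  int version = 0;
  bool alive = true;
  std::unordered_map<int, double> nbr; // neighbour id -> shared boundary length
};

struct PairItem {
  double cost;
  int a, b, va, vb;
};
struct PairCmp {
  bool operator()(const PairItem& x, const PairItem& y) const {
    if (x.cost != y.cost) return x.cost > y.cost;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

static inline double color_h(const Region& r, const std::vector<double>& w) {
  double h = 0.0;
  for (size_t l = 0; l < r.sum.size(); ++l) {
    double mean = r.sum[l] / r.n;
    double var = r.ssq[l] / r.n - mean * mean;
    if (var < 0) var = 0;
    h += w[l] * r.n * std::sqrt(var);
  }
  return h;
}

static inline double bbox_perim(int rmin, int rmax, int cmin, int cmax) {
  return 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
}

static double merge_cost(const Region& a, const Region& b, double shared,
                         const std::vector<double>& w, double w_color,
                         double cmpct) {
  size_t L = a.sum.size();
  double n_m = a.n + b.n;
  double dcol = 0.0;
  for (size_t l = 0; l < L; ++l) {
    double s = a.sum[l] + b.sum[l];
    double q = a.ssq[l] + b.ssq[l];
    double mean = s / n_m;
    double var = q / n_m - mean * mean;
    if (var < 0) var = 0;
    dcol += w[l] * n_m * std::sqrt(var);
  }
  dcol -= color_h(a, w) + color_h(b, w);
  if (dcol < 0) dcol = 0; // numerical guard; merging cannot reduce n*sd

  double dshape = 0.0;
  if (w_color < 1.0) {
    double perim_m = a.perim + b.perim - 2.0 * shared;
    int rmin = std::min(a.rmin, b.rmin), rmax = std::max(a.rmax, b.rmax);
    int cmin = std::min(a.cmin, b.cmin), cmax = std::max(a.cmax, b.cmax);
    double hc = std::sqrt(n_m) * perim_m -
      (std::sqrt(a.n) * a.perim + std::sqrt(b.n) * b.perim);
    double hs = n_m * perim_m / bbox_perim(rmin, rmax, cmin, cmax) -
      (a.n * a.perim / bbox_perim(a.rmin, a.rmax, a.cmin, a.cmax) +
       b.n * b.perim / bbox_perim(b.rmin, b.rmax, b.cmin, b.cmax));
    dshape = cmpct * hc + (1.0 - cmpct) * hs;
  }
  return w_color * dcol + (1.0 - w_color) * dshape;
}

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerMatrix cpp_segment(NumericVector stack, int nrow, int ncol, int nlayer,
                          NumericVector weights, double shape_factor,
                          double compactness, double scale) {
  const double thresh = scale * scale;
  const double w_color = 1.0 - shape_factor;
  const int npix = nrow * ncol;
  std::vector<double> w(weights.begin(), weights.end());

  std::vector<Region> reg(npix);
  std::vector<int> parent(npix);
  for (int i = 0; i < npix; ++i) parent[i] = i;

  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int id = r * ncol + c;
      Region& g = reg[id];
      g.n = 1.0;
      g.sum.resize(nlayer);
      g.ssq.resize(nlayer);
      for (int l = 0; l < nlayer; ++l) {
        // stack is R-column-major within each layer: [r + c*nrow + l*npix]
        double v = stack[r + c * nrow + l * npix];
        g.sum[l] = v;
        g.ssq[l] = v * v;
      }
      g.perim = 4.0;
      g.rmin = g.rmax = r;
      g.cmin = g.cmax = c;
      if (c + 1 < ncol) g.nbr[id + 1] = 1.0;
      if (c > 0) g.nbr[id - 1] = 1.0;
      if (r + 1 < nrow) g.nbr[id + ncol] = 1.0;
      if (r > 0) g.nbr[id - ncol] = 1.0;
    }
  }

  std::priority_queue<PairItem, std::vector<PairItem>, PairCmp> pq;
  if (thresh > 0) {
    for (int id = 0; id < npix; ++id)
      for (auto& kv : reg[id].nbr)
        if (kv.first > id)
          pq.push({merge_cost(reg[id], reg[kv.first], kv.second, w, w_color,
                              compactness),
                   id, kv.first, 0, 0});
  }

  while (!pq.empty()) {
    PairItem it = pq.top();
    pq.pop();
    Region& A = reg[it.a];
    Region& B = reg[it.b];
    if (!A.alive || !B.alive) continue;
    if (A.version != it.va || B.version != it.vb) continue;
    auto f = A.nbr.find(it.b);
    if (f == A.nbr.end()) continue;
    if (it.cost >= thresh) break; // cheapest valid pair too costly: done

    double shared = f->second;
    A.perim = A.perim + B.perim - 2.0 * shared;
    A.n += B.n;
    for (int l = 0; l < nlayer; ++l) {
      A.sum[l] += B.sum[l];
      A.ssq[l] += B.ssq[l];
    }
    A.rmin = std::min(A.rmin, B.rmin);
    A.rmax = std::max(A.rmax, B.rmax);
    A.cmin = std::min(A.cmin, B.cmin);
    A.cmax = std::max(A.cmax, B.cmax);
    A.nbr.erase(it.b);
    for (auto& kv : B.nbr) {
      if (kv.first == it.a) continue;
      Region& C = reg[kv.first];
      C.nbr.erase(it.b);
      auto g = A.nbr.find(kv.first);
      if (g != A.nbr.end()) g->second += kv.second;
      else A.nbr[kv.first] = kv.second;
      auto h = C.nbr.find(it.a);
      if (h != C.nbr.end()) h->second += kv.second;
      else C.nbr[it.a] = kv.second;
    }
    parent[it.b] = it.a;
    B.alive = false;
    B.nbr.clear();
    B.sum.clear();
    B.ssq.clear();
    A.version++;
    for (auto& kv : A.nbr) {
      int lo = std::min(it.a, kv.first), hi = std::max(it.a, kv.first);
      pq.push({merge_cost(A, reg[kv.first], kv.second, w, w_color,
                          compactness),
               lo, hi, reg[lo].version, reg[hi].version});
    }
  }

  // relabel region roots to 1..n in raster-scan order of first occurrence
  IntegerMatrix out(nrow, ncol);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int root = uf_find(parent, r * ncol + c);
      auto e = remap.find(root);
      int lab;
      if (e == remap.end()) {
        lab = ++next;
        remap[root] = lab;
      } else lab = e->second;
      out(r, c) = lab;
    }
  }
  return out;
}

// Per-object GLCM contrast and entropy on a quantized layer.
// q: integer matrix of grey levels 1..nlevels (same shape as labels).
// Symmetric GLCM, distance 1, averaged over 0/45/90/135 degrees; only pixel
// pairs lying in the same object contribute. Entropy uses natural log.

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerMatrix labels, IntegerMatrix q, int nobj,
                       int nlevels) {
  int nrow = labels.nrow(), ncol = labels.ncol();
  int nl2 = nlevels * nlevels;
  std::vector<double> counts((size_t)nobj * nl2, 0.0);
  const int dr[4] = {0, 1, 1, 1};
  const int dc[4] = {1, 0, 1, -1};
  for (int r = 0; r < nrow; ++r) {
    for (int c = 0; c < ncol; ++c) {
      int lab = labels(r, c);
      if (lab == NA_INTEGER || lab < 1) continue;
      int qi = q(r, c);
      if (qi == NA_INTEGER) continue;
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nrow || c2 < 0 || c2 >= ncol) continue;
        if (labels(r2, c2) != lab) continue;
        int qj = q(r2, c2);
        if (qj == NA_INTEGER) continue;
        size_t base = (size_t)(lab - 1) * nl2;
        counts[base + (qi - 1) * nlevels + (qj - 1)] += 1.0;
        counts[base + (qj - 1) * nlevels + (qi - 1)] += 1.0;
      }
    }
  }
  NumericMatrix out(nobj, 2);
  for (int o = 0; o < nobj; ++o) {
    size_t base = (size_t)o * nl2;
    double tot = 0.0;
    for (int k = 0; k < nl2; ++k) tot += counts[base + k];
    double contrast = 0.0, entropy = 0.0;
    if (tot > 0) {
      for (int i = 0; i < nlevels; ++i) {
        for (int j = 0; j < nlevels; ++j) {
          double p = counts[base + i * nlevels + j] / tot;
          if (p > 0) {
            contrast += p * (i - j) * (i - j);
            entropy -= p * std::log(p);
          }
        }
      }
    }
    out(o, 0) = contrast;
    out(o, 1) = entropy;
  }
  return out;
}
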