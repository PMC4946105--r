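#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-pass union-find connected-component labeling, 4-connectivity.
// mask: integer matrix, nonzero = foreground. Returns integer labels 1..n.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up = (i > 0) ? lab(i - 1, j) : 0;
      int left = (j > 0) ? lab(i, j - 1) : 0;
      if (!up && !left) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else if (up && left) {
        int ru = uf_find(parent, up), rl = uf_find(parent, left);
        if (ru != rl) parent[std::max(ru, rl)] = std::min(ru, rl);
        lab(i, j) = std::min(ru, rl);
      } else {
        lab(i, j) = up ? up : left;
      }
    }
  }
  // flatten + relabel consecutively
  std::vector<int> newlab(next, 0);
  int n = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!lab(i, j)) continue;
      int r = uf_find(parent, lab(i, j));
      if (!newlab[r]) newlab[r] = ++n;
      lab(i, j) = newlab[r];
    }
  lab.attr("n") = n;
  return lab;
}

// Chamfer (3,4)-style distance transform scaled to ~Euclidean pixel units.
// Distance to nearest zero pixel; foreground = nonzero.
// [[Rcpp::export(name = ".chamfer_dist")]]
NumericMatrix chamfer_dist(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e9, W1 = 1.0, W2 = 1.41421356237;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;
  // forward pass
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0) v = std::min(v, d(i - 1, j) + W1);
      if (j > 0) v = std::min(v, d(i, j - 1) + W1);
      if (i > 0 && j > 0) v = std::min(v, d(i - 1, j - 1) + W2);
      if (i < nr - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + W2);
      d(i, j) = v;
    }
  // backward pass
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1) v = std::min(v, d(i + 1, j) + W1);
      if (j < nc - 1) v = std::min(v, d(i, j + 1) + W1);
      if (i < nr - 1 && j < nc - 1) v = std::min(v, d(i + 1, j + 1) + W2);
      if (i > 0 && j < nc - 1) v = std::min(v, d(i - 1, j + 1) + W2);
      d(i, j) = v;
    }
  return d;
}

// Seeded watershed by priority flood: grow markers over mask in order of
// increasing elevation. Unseeded mask pixels join the first marker to reach
// them. elevation typically = -distance transform.
struct PixNode {
  double elev; int order; int idx; int label;
  bool operator<(const PixNode& o) const {
    if (elev != o.elev) return elev > o.elev;  // min-heap
    return order > o.order;
  }
};

// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerMatrix watershed_seeded(const NumericMatrix& elev,
                               const IntegerMatrix& markers,
                               const IntegerMatrix& mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<PixNode> pq;
  int ord = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({elev(i, j), ord++, i + j * nr, markers(i, j)});
      }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    PixNode p = pq.top(); pq.pop();
    int pi = p.idx % nr, pj = p.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ni = pi + di[k], nj = pj + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj)) continue;
      lab(ni, nj) = p.label;
      pq.push({elev(ni, nj), ord++, ni + nj * nr, p.label});
    }
  }
  return lab;
}

// Separable Gaussian blur, replicate boundary.
// [[Rcpp::export(name = ".blur_gauss")]]
NumericMatrix blur_gauss(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    k[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + rad];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* src = REAL(img);
  double* tm = REAL(tmp);
  double* ot = REAL(out);
  // vertical pass: per-tap shifted AXPY over each (contiguous) column
  for (int j = 0; j < nc; ++j) {
    const double* s = src + (R_xlen_t)j * nr;
    double* o = tm + (R_xlen_t)j * nr;
    for (int t = -rad; t <= rad; ++t) {
      const double w = k[t + rad];
      int i0 = std::max(0, -t), i1 = std::min(nr, nr - t);
      for (int i = i0; i < i1; ++i) o[i] += w * s[i + t];
      for (int i = 0; i < i0; ++i) o[i] += w * s[0];          // replicate top
      for (int i = i1; i < nr; ++i) o[i] += w * s[nr - 1];    // replicate bottom
    }
  }
  // horizontal pass: per-tap AXPY of whole shifted (clamped) columns
  for (int j = 0; j < nc; ++j) {
    double* o = ot + (R_xlen_t)j * nr;
    for (int t = -rad; t <= rad; ++t) {
      const double w = k[t + rad];
      int jj = std::min(std::max(j + t, 0), nc - 1);
      const double* s = tm + (R_xlen_t)jj * nr;
      for (int i = 0; i < nr; ++i) o[i] += w * s[i];
    }
  }
  return out;
}

// Square max filter of radius r (window 2r+1).
// [[Rcpp::export(name = ".max_filter")]]
NumericMatrix max_filter(const NumericMatrix& img, int rad) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = img(i, j);
      for (int t = -rad; t <= rad; ++t) {
        int ii = std::min(std::max(i + t, 0), nr - 1);
        if (img(ii, j) > m) m = img(ii, j);
      }
      tmp(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = tmp(i, j);
      for (int t = -rad; t <= rad; ++t) {
        int jj = std::min(std::max(j + t, 0), nc - 1);
        if (tmp(i, jj) > m) m = tmp(i, jj);
      }
      out(i, j) = m;
    }
  return out;
}
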