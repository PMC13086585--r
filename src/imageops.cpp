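// Low-level pixel operations shared by the segmentation, morphometry and
// dynamics code.  All matrices are R numeric matrices in (row, col) order,
// 0-based indices on the C++ side.  Border handling is replicate (clamp)
// unless stated otherwise.

#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------------
// Separable convolution with a 1-D kernel, horizontal then vertical pass.
// Kernel length must be odd; edges replicate.
// [[Rcpp::export(name = ".cpp_sep_convolve")]]
NumericMatrix cpp_sep_convolve(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int k = kernel.size();
  if (k % 2 == 0) stop("kernel length must be odd");
  const int h = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // horizontal (along columns index j)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) {
        int jj = clampi(j + t, 0, nc - 1);
        acc += img(i, jj) * kernel[t + h];
      }
      tmp(i, j) = acc;
    }
  }
  // vertical
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) {
        int ii = clampi(i + t, 0, nr - 1);
        acc += tmp(ii, j) * kernel[t + h];
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Median filter over a pixelated disc of the given radius (offsets with
// dx^2 + dy^2 <= r^2 + 1, the ImageJ rank-filter disc; radius 2 -> 13 px).
// [[Rcpp::export(name = ".cpp_median_disc")]]
NumericMatrix cpp_median_disc(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::ceil(radius);
  const double r2 = radius * radius + 1.0;
  std::vector<int> dys, dxs;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if ((double)(dy * dy + dx * dx) <= r2) { dys.push_back(dy); dxs.push_back(dx); }
  const int m = (int)dys.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(m);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      for (int t = 0; t < m; ++t) {
        int ii = clampi(i + dys[t], 0, nr - 1);
        int jj = clampi(j + dxs[t], 0, nc - 1);
        buf[t] = img(ii, jj);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m / 2 - 1, buf.begin() + m / 2);
        med = 0.5 * (med + buf[m / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 1-D parabolic erosion:  e(i) = min_j f(j) + c (i-j)^2  computed with the
// lower-envelope algorithm of Felzenszwalb & Huttenlocher (O(n) per line).
static void parab_erode_line(const double* f, double* out, int n, double c,
                             std::vector<int>& v, std::vector<double>& z) {
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + c * q * q) - (f[p] + c * p * p)) / (2.0 * c * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    out[q] = f[p] + c * (double)(q - p) * (q - p);
  }
}

static void parab_erode_mat(NumericMatrix& m, double c) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<int> v; std::vector<double> z;
  std::vector<double> line(std::max(nr, nc)), res(std::max(nr, nc));
  for (int i = 0; i < nr; ++i) {           // along rows
    for (int j = 0; j < nc; ++j) line[j] = m(i, j);
    parab_erode_line(line.data(), res.data(), nc, c, v, z);
    for (int j = 0; j < nc; ++j) m(i, j) = res[j];
  }
  for (int j = 0; j < nc; ++j) {           // along cols
    for (int i = 0; i < nr; ++i) line[i] = m(i, j);
    parab_erode_line(line.data(), res.data(), nr, c, v, z);
    for (int i = 0; i < nr; ++i) m(i, j) = res[i];
  }
}

// Grey-scale opening with the paraboloid structuring function
// z(d) = d^2 / (2 r): the "sliding paraboloid" background.  The 2-D
// paraboloid separates into 1-D parabolas, so erosion and dilation are two
// 1-D envelope passes each.  Returns the background (lower envelope of all
// paraboloid placements that fit under the surface).
// [[Rcpp::export(name = ".cpp_paraboloid_background")]]
NumericMatrix cpp_paraboloid_background(NumericMatrix img, double radius) {
  if (radius <= 0) stop("radius must be > 0");
  const double c = 1.0 / (2.0 * radius);
  NumericMatrix e = clone(img);
  parab_erode_mat(e, c);                   // erosion
  // dilation: max_j e(j) - c d^2  ==  -( min_j (-e(j)) + c d^2 )
  const int nr = e.nrow(), nc = e.ncol();
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) e(i, j) = -e(i, j);
  parab_erode_mat(e, c);
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) e(i, j) = -e(i, j);
  return e;
}

// Grey-scale opening with a spherical ball cap z(d) = r - sqrt(r^2 - d^2),
// support d <= r.  Brute-force window; intended for small radii.
// [[Rcpp::export(name = ".cpp_ball_background")]]
NumericMatrix cpp_ball_background(NumericMatrix img, double radius) {
  if (radius <= 0) stop("radius must be > 0");
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> dys, dxs; std::vector<double> dep;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double d2 = (double)(dy * dy + dx * dx);
      if (d2 <= radius * radius) {
        dys.push_back(dy); dxs.push_back(dx);
        dep.push_back(radius - std::sqrt(radius * radius - d2));
      }
    }
  const int m = (int)dys.size();
  NumericMatrix ero(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double mn = std::numeric_limits<double>::infinity();
      for (int t = 0; t < m; ++t) {
        int ii = clampi(i + dys[t], 0, nr - 1), jj = clampi(j + dxs[t], 0, nc - 1);
        double v = img(ii, jj) + dep[t];
        if (v < mn) mn = v;
      }
      ero(i, j) = mn;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int t = 0; t < m; ++t) {
        int ii = clampi(i + dys[t], 0, nr - 1), jj = clampi(j + dxs[t], 0, nc - 1);
        double v = ero(ii, jj) - dep[t];
        if (v > mx) mx = v;
      }
      out(i, j) = mx;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a logical/0-1 mask.  Labels are positive
// consecutive integers in row-major first-encounter order (deterministic).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int* dx = connectivity == 8 ? dx8 : dx4;
  const int nn = connectivity;
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      // column-major scan matches R's linear indexing; first-encounter order
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear(); stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < nn; ++t) {
          int qi = pi + dy[t], qj = pj + dx[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Prominence-based local-maxima detection (persistence / union-find).
// Pixels are processed in decreasing intensity; when two summit regions meet
// at a saddle of height s, the lower summit dies with prominence
// peak - s.  The globally highest summit gets prominence peak - min(image).
// Returns all summits with their prominence; thresholding happens in R.
// Equal-value plateaus collapse onto a single summit.  8-connectivity.
// [[Rcpp::export(name = ".cpp_maxima_prominence")]]
DataFrame cpp_maxima_prominence(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double* v = img.begin();
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  std::vector<int> parent(n, -1);          // union-find; -1 = unprocessed
  std::vector<int> peak_px(n, -1);         // for roots: summit pixel
  std::vector<double> prom(n, -1.0);       // summit death prominence
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  double vmin = *std::min_element(v, v + n);
  std::vector<int> roots;
  for (int t = 0; t < n; ++t) {
    int p = order[t];
    int pi = p % nr, pj = p / nr;
    roots.clear();
    for (int q = 0; q < 8; ++q) {
      int qi = pi + dy8[q], qj = pj + dx8[q];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      int pq = qi + qj * nr;
      if (parent[pq] < 0) continue;        // not processed yet
      int r = find(pq);
      if (std::find(roots.begin(), roots.end(), r) == roots.end())
        roots.push_back(r);
    }
    if (roots.empty()) {
      parent[p] = p; peak_px[p] = p;       // new summit
      continue;
    }
    // winner: root with highest summit value (ties: earliest summit pixel)
    int win = roots[0];
    for (size_t q = 1; q < roots.size(); ++q) {
      int r = roots[q];
      double vw = v[peak_px[win]], vr = v[peak_px[r]];
      if (vr > vw || (vr == vw && peak_px[r] < peak_px[win])) win = r;
    }
    parent[p] = win;
    for (size_t q = 0; q < roots.size(); ++q) {
      int r = roots[q];
      if (r == win) continue;
      prom[peak_px[r]] = v[peak_px[r]] - v[p];   // summit r dies here
      parent[r] = win;
    }
  }
  // surviving root: prominence relative to the image minimum
  int root = find(order[0]);
  prom[peak_px[root]] = v[peak_px[root]] - vmin;
  std::vector<int> rows, cols; std::vector<double> vals, proms;
  for (int p = 0; p < n; ++p) {
    if (peak_px[p] == p && prom[p] >= 0.0) {
      rows.push_back(p % nr); cols.push_back(p / nr);
      vals.push_back(v[p]); proms.push_back(prom[p]);
    }
  }
  return DataFrame::create(_["row"] = rows, _["col"] = cols,
                           _["value"] = vals, _["prominence"] = proms);
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed (Meyer's flooding) on `input`, ascending
// values, restricted to `mask`.  `markers` holds positive seed labels.
// Ties are resolved first-come-first-served with a FIFO counter, so the
// flooding front with the lower entry order (and hence, for equal levels at
// seeding, the lower label) wins deterministically.  8-connectivity.
// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerMatrix cpp_watershed(NumericMatrix input, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int nr = input.nrow(), nc = input.ncol();
  IntegerMatrix lab(nr, nc);
  struct Node { double v; long long ord; int px; };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.v != b.v) return a.v > b.v;    // min-heap on value
      return a.ord > b.ord;                // FIFO on ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long counter = 0;
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({input(i, j), counter++, i + j * nr});
      }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int pi = nd.px % nr, pj = nd.px / nr;
    int l = lab(pi, pj);
    for (int t = 0; t < 8; ++t) {
      int qi = pi + dy8[t], qj = pj + dx8[t];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (!mask(qi, qj) || lab(qi, qj) != 0) continue;
      lab(qi, qj) = l;
      pq.push({input(qi, qj), counter++, qi + qj * nr});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Integer rigid translation with constant fill.  Content moves by (+dy, +dx).
// [[Rcpp::export(name = ".cpp_translate_int")]]
NumericMatrix cpp_translate_int(NumericMatrix img, int dy, int dx, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), fill);
  for (int j = 0; j < nc; ++j) {
    int js = j - dx;
    if (js < 0 || js >= nc) continue;
    for (int i = 0; i < nr; ++i) {
      int is = i - dy;
      if (is < 0 || is >= nr) continue;
      out(i, j) = img(is, js);
    }
  }
  return out;
}
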