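#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Grid-bucketed DBSCAN on 2D points. Bucket width == eps so all neighbours of
// a point lie in its 3x3 cell block. Semantics are the textbook algorithm:
//  - core point: >= minPts neighbours within eps (self included, Euclidean);
//  - clusters are expanded from cores in index order with a FIFO seed list;
//  - border points take the label of the first core that reaches them.
// Callers pre-sort points by (x, y); neighbour lists are returned in index
// order, so labels are fully deterministic and reproducible by a naive O(n^2)
// implementation that follows the same rules.

static inline int64_t cell_key(int64_t cx, int64_t cy) {
  return (cx << 32) ^ (cy & 0xffffffffLL);
}

// [[Rcpp::export(name = ".dbscan_grid")]]
IntegerVector dbscan_grid(NumericVector x, NumericVector y, double eps,
                          int minPts) {
  const int n = x.size();
  IntegerVector label(n, NA_INTEGER);  // NA = noise / unassigned
  if (n == 0) return label;

  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<int64_t> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int64_t)std::floor(x[i] / eps);
    cy[i] = (int64_t)std::floor(y[i] / eps);
    grid[cell_key(cx[i], cy[i])].push_back(i);  // ascending index per cell
  }

  const double eps2 = eps * eps;
  std::vector<int> nb;  // neighbour scratch
  std::vector<char> visited(n, 0);
  std::vector<int> seeds;

  auto region_query = [&](int i, std::vector<int>& out) {
    out.clear();
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cell_key(cx[i] + dx, cy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          const double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy <= eps2) out.push_back(j);
        }
      }
    }
    std::sort(out.begin(), out.end());
  };

  int cluster = 0;
  std::vector<int> nb2;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    region_query(i, nb);
    if ((int)nb.size() < minPts) continue;  // noise (may become border later)
    ++cluster;
    label[i] = cluster;
    seeds.assign(nb.begin(), nb.end());
    for (size_t k = 0; k < seeds.size(); ++k) {
      const int q = seeds[k];
      if (label[q] == NA_INTEGER) label[q] = cluster;  // noise -> border
      if (visited[q]) continue;
      visited[q] = 1;
      region_query(q, nb2);
      if ((int)nb2.size() >= minPts) {
        for (int j : nb2) seeds.push_back(j);
      }
    }
  }
  return label;
}

// Batch 2D rectangle counts. xs must be sorted ascending with ys aligned.
// Window semantics are half-open [x1, x2) x [y1, y2), matching BED intervals
// applied to end midpoints.
// [[Rcpp::export(name = ".count_rect")]]
IntegerVector count_rect(NumericVector xs, NumericVector ys, NumericVector x1,
                         NumericVector x2, NumericVector y1,
                         NumericVector y2) {
  const int m = x1.size();
  IntegerVector out(m);
  const double* xb = xs.begin();
  const double* xe = xs.end();
  for (int k = 0; k < m; ++k) {
    const double* lo = std::lower_bound(xb, xe, x1[k]);
    const double* hi = std::lower_bound(xb, xe, x2[k]);
    int c = 0;
    for (const double* p = lo; p < hi; ++p) {
      const double yy = ys[p - xb];
      if (yy >= y1[k] && yy < y2[k]) ++c;
    }
    out[k] = c;
  }
  return out;
}
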