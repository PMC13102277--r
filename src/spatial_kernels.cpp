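#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Uniform grid over 2-D points for radius queries. Cell side = the query
// radius, so a radius search only touches the 3x3 cell neighbourhood.
struct Grid {
  double cell, x0, y0;
  std::unordered_map<int64_t, std::vector<int>> cells;
  int64_t key(int ix, int iy) const {
    return (static_cast<int64_t>(ix) << 32) ^ (static_cast<int64_t>(iy) & 0xffffffffLL);
  }
  Grid(const NumericVector& x, const NumericVector& y, double cell_) : cell(cell_) {
    x0 = x.size() ? Rcpp::min(x) : 0.0;
    y0 = y.size() ? Rcpp::min(y) : 0.0;
    for (int i = 0; i < x.size(); ++i) {
      int ix = static_cast<int>(std::floor((x[i] - x0) / cell));
      int iy = static_cast<int>(std::floor((y[i] - y0) / cell));
      cells[key(ix, iy)].push_back(i);
    }
  }
  // indices within `r` of (px, py); r must be <= cell
  void query(double px, double py, double r,
             const NumericVector& x, const NumericVector& y,
             std::vector<int>& out) const {
    out.clear();
    double r2 = r * r;
    int ix = static_cast<int>(std::floor((px - x0) / cell));
    int iy = static_cast<int>(std::floor((py - y0) / cell));
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = cells.find(key(ix + dx, iy + dy));
        if (it == cells.end()) continue;
        for (int j : it->second) {
          double ddx = x[j] - px, ddy = y[j] - py;
          if (ddx * ddx + ddy * ddy <= r2) out.push_back(j);
        }
      }
    std::sort(out.begin(), out.end());
  }
};

// DBSCAN labels: 0 = noise, 1..k cluster ids. A point is core when its
// eps-neighbourhood (including itself) holds >= min_pts points. Expansion is
// breadth-first in ascending index order, so labels are deterministic for a
// given row order.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps, int min_pts) {
  int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid grid(x, y, eps);
  std::vector<bool> visited(n, false);
  std::vector<int> nb, nb2;
  int cid = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    grid.query(x[i], y[i], eps, x, y, nb);
    if (static_cast<int>(nb.size()) < min_pts) continue;  // not core; may become border later
    ++cid;
    labels[i] = cid;
    std::vector<int> seeds(nb.begin(), nb.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      int j = seeds[s];
      if (labels[j] == 0) labels[j] = cid;  // border or newly reached
      if (visited[j]) continue;
      visited[j] = true;
      grid.query(x[j], y[j], eps, x, y, nb2);
      if (static_cast<int>(nb2.size()) >= min_pts) {
        for (int q : nb2)
          if (!visited[q] || labels[q] == 0) seeds.push_back(q);
      }
    }
  }
  return labels;
}

struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int a) { while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; } return a; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[std::max(a,b)] = std::min(a,b); }
};

// Transitive linking of localizations: points in frames f and f' with
// 1 <= f' - f <= max_dark + 1 and distance <= radius belong to one emitter
// event. Returns 1-based group ids (union-find roots, renumbered by first
// appearance).
// [[Rcpp::export]]
IntegerVector cpp_link_groups(NumericVector x, NumericVector y, IntegerVector frame,
                              double radius, int max_dark) {
  int n = x.size();
  DSU dsu(n);
  if (n > 0) {
    // bucket indices per frame
    std::unordered_map<int, std::vector<int>> by_frame;
    for (int i = 0; i < n; ++i) by_frame[frame[i]].push_back(i);
    double r2 = radius * radius;
    for (auto& kv : by_frame) {
      int f = kv.first;
      for (int d = 1; d <= max_dark + 1; ++d) {
        auto it = by_frame.find(f + d);
        if (it == by_frame.end()) continue;
        for (int i : kv.second)
          for (int j : it->second) {
            double dx = x[i] - x[j], dy = y[i] - y[j];
            if (dx * dx + dy * dy <= r2) dsu.unite(i, j);
          }
      }
    }
  }
  IntegerVector out(n);
  std::unordered_map<int, int> renum;
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int r = dsu.find(i);
    auto it = renum.find(r);
    if (it == renum.end()) { renum[r] = ++next_id; out[i] = next_id; }
    else out[i] = it->second;
  }
  return out;
}

// For each point of A, Euclidean distance to nearest point of B.
// self = true means A and B are the same set: the identical index is skipped.
// Expanding grid-ring search.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector ax, NumericVector ay,
                          NumericVector bx, NumericVector by, bool self) {
  int na = ax.size(), nb = bx.size();
  NumericVector out(na, NA_REAL);
  if (nb == 0 || (self && nb < 2)) return out;
  double xmin = Rcpp::min(bx), xmax = Rcpp::max(bx);
  double ymin = Rcpp::min(by), ymax = Rcpp::max(by);
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = span > 0 ? span / std::max(1.0, std::sqrt((double)nb)) : 1.0;
  if (cell <= 0) cell = 1.0;
  std::unordered_map<int64_t, std::vector<int>> cells;
  auto key = [](int ix, int iy) {
    return (static_cast<int64_t>(ix) << 32) ^ (static_cast<int64_t>(iy) & 0xffffffffLL);
  };
  for (int j = 0; j < nb; ++j) {
    int ix = (int)std::floor((bx[j] - xmin) / cell);
    int iy = (int)std::floor((by[j] - ymin) / cell);
    cells[key(ix, iy)].push_back(j);
  }
  int max_ring = (int)std::ceil(span / cell) + 2;
  for (int i = 0; i < na; ++i) {
    int ix = (int)std::floor((ax[i] - xmin) / cell);
    int iy = (int)std::floor((ay[i] - ymin) / cell);
    double best = R_PosInf;
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once a candidate is found, search one more ring than needed to be safe
      if (best < R_PosInf && (double)(ring - 1) * cell > std::sqrt(best)) break;
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          auto it = cells.find(key(ix + dx, iy + dy));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (self && j == i) continue;
            double ddx = bx[j] - ax[i], ddy = by[j] - ay[i];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best) best = d2;
          }
        }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Cumulative radial counts: out(i, k) = #{ p : |p - center_i| <= edges[k] }.
// edges must be sorted ascending; grid cell = max edge.
// [[Rcpp::export]]
NumericMatrix cpp_count_within(NumericVector cx, NumericVector cy,
                               NumericVector px, NumericVector py,
                               NumericVector edges) {
  int nc = cx.size(), ne = edges.size();
  NumericMatrix out(nc, ne);
  if (px.size() == 0 || nc == 0 || ne == 0) return out;
  double rmax = edges[ne - 1];
  Grid grid(px, py, std::max(rmax, 1e-9));
  std::vector<int> nb;
  for (int i = 0; i < nc; ++i) {
    grid.query(cx[i], cy[i], rmax, px, py, nb);
    for (int j : nb) {
      double dx = px[j] - cx[i], dy = py[j] - cy[i];
      double d = std::sqrt(dx * dx + dy * dy);
      // first edge >= d gets this point; counts are cumulative over edges
      int k = std::lower_bound(edges.begin(), edges.end(), d) - edges.begin();
      if (k < ne) out(i, k) += 1.0;
    }
  }
  // prefix-sum across edges
  for (int i = 0; i < nc; ++i)
    for (int k = 1; k < ne; ++k) out(i, k) += out(i, k - 1);
  return out;
}
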