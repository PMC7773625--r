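#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Closest point on 2D segment ab to p; returns parameter t in [0,1].
static inline double seg_param(double px, double py, double ax, double ay,
                               double bx, double by) {
  double abx = bx - ax, aby = by - ay;
  double len2 = abx * abx + aby * aby;
  if (len2 <= 0.0) return 0.0;
  double t = ((px - ax) * abx + (py - ay) * aby) / len2;
  return std::min(1.0, std::max(0.0, t));
}

// Barycentric weights of point p in triangle (a,b,c); may be negative outside.
static inline void bary2(double px, double py,
                         double ax, double ay, double bx, double by,
                         double cx, double cy, double w[3]) {
  double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
  if (std::fabs(d) < 1e-300) { w[0] = w[1] = w[2] = 1.0 / 3.0; return; }
  w[0] = ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d;
  w[1] = ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d;
  w[2] = 1.0 - w[0] - w[1];
}

// Squared distance from p to triangle, and barycentric weights of the closest
// point (clamped to the triangle).
static double tri_dist2(double px, double py,
                        double ax, double ay, double bx, double by,
                        double cx, double cy, double w[3]) {
  bary2(px, py, ax, ay, bx, by, cx, cy, w);
  if (w[0] >= 0 && w[1] >= 0 && w[2] >= 0) return 0.0;
  // closest point lies on an edge
  double best = std::numeric_limits<double>::infinity();
  double bw[3] = {0, 0, 0};
  const double vx[3] = {ax, bx, cx}, vy[3] = {ay, by, cy};
  for (int e = 0; e < 3; ++e) {
    int i = e, j = (e + 1) % 3;
    double t = seg_param(px, py, vx[i], vy[i], vx[j], vy[j]);
    double qx = vx[i] + t * (vx[j] - vx[i]);
    double qy = vy[i] + t * (vy[j] - vy[i]);
    double d2 = (px - qx) * (px - qx) + (py - qy) * (py - qy);
    if (d2 < best) {
      best = d2;
      bw[0] = bw[1] = bw[2] = 0.0;
      bw[i] = 1.0 - t; bw[j] = t;
    }
  }
  w[0] = bw[0]; w[1] = bw[1]; w[2] = bw[2];
  return best;
}

// Locate 2D query points in a triangulation. Returns (tri index 1-based,
// w1,w2,w3, snapped flag, snap distance). Points not inside any triangle are
// assigned the nearest triangle with clamped weights.
// [[Rcpp::export]]
List cpp_locate_2d(NumericVector px, NumericVector py,
                   IntegerMatrix tri, NumericVector vx, NumericVector vy,
                   double tol) {
  const int m = tri.nrow(), nq = px.size();
  // uniform grid over triangle bboxes
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < vx.size(); ++i) {
    xmin = std::min(xmin, vx[i]); xmax = std::max(xmax, vx[i]);
    ymin = std::min(ymin, vy[i]); ymax = std::max(ymax, vy[i]);
  }
  double dx = xmax - xmin, dy = ymax - ymin;
  if (dx <= 0) dx = 1e-9; if (dy <= 0) dy = 1e-9;
  int ng = std::max(1, (int)std::floor(std::sqrt((double)m / 2.0)));
  ng = std::min(ng, 512);
  double hx = dx / ng, hy = dy / ng;
  std::vector<std::vector<int> > cells((size_t)ng * ng);
  for (int t = 0; t < m; ++t) {
    double txmin = R_PosInf, txmax = R_NegInf, tymin = R_PosInf, tymax = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      int v = tri(t, k) - 1;
      txmin = std::min(txmin, vx[v]); txmax = std::max(txmax, vx[v]);
      tymin = std::min(tymin, vy[v]); tymax = std::max(tymax, vy[v]);
    }
    int i0 = std::max(0, std::min(ng - 1, (int)((txmin - xmin) / hx)));
    int i1 = std::max(0, std::min(ng - 1, (int)((txmax - xmin) / hx)));
    int j0 = std::max(0, std::min(ng - 1, (int)((tymin - ymin) / hy)));
    int j1 = std::max(0, std::min(ng - 1, (int)((tymax - ymin) / hy)));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        cells[(size_t)i * ng + j].push_back(t);
  }

  IntegerVector out_tri(nq);
  NumericMatrix out_w(nq, 3);
  LogicalVector snapped(nq);
  NumericVector snap_d(nq);
  std::vector<int> stamp((size_t)m, -1);

  for (int q = 0; q < nq; ++q) {
    double p0 = px[q], p1 = py[q];
    int qi = std::max(0, std::min(ng - 1, (int)((p0 - xmin) / hx)));
    int qj = std::max(0, std::min(ng - 1, (int)((p1 - ymin) / hy)));
    int best_t = -1;
    double best_d2 = std::numeric_limits<double>::infinity();
    double best_w[3] = {0, 0, 0};
    bool inside = false;
    int max_ring = 2 * ng;
    for (int ring = 0; ring <= max_ring && !inside; ++ring) {
      bool any = false;
      for (int i = qi - ring; i <= qi + ring && !inside; ++i) {
        if (i < 0 || i >= ng) continue;
        for (int j = qj - ring; j <= qj + ring; ++j) {
          if (j < 0 || j >= ng) continue;
          if (ring > 0 && std::abs(i - qi) != ring && std::abs(j - qj) != ring)
            continue;
          const std::vector<int>& cell = cells[(size_t)i * ng + j];
          for (size_t c = 0; c < cell.size(); ++c) {
            int t = cell[c];
            if (stamp[t] == q) continue;
            stamp[t] = q;
            any = true;
            int a = tri(t, 0) - 1, b = tri(t, 1) - 1, cc = tri(t, 2) - 1;
            double w[3];
            double d2 = tri_dist2(p0, p1, vx[a], vy[a], vx[b], vy[b],
                                  vx[cc], vy[cc], w);
            if (d2 < best_d2) {
              best_d2 = d2; best_t = t;
              best_w[0] = w[0]; best_w[1] = w[1]; best_w[2] = w[2];
            }
            if (d2 == 0.0) { inside = true; break; }
          }
          if (inside) break;
        }
      }
      // after first ring with candidates, allow one extra ring then stop if
      // the best distance cannot improve (cells farther than best distance)
      if (!inside && best_t >= 0) {
        double reach = (ring > 0 ? (ring - 1) : 0) * std::min(hx, hy);
        if (any && reach * reach > best_d2) break;
      }
    }
    if (best_t < 0) { // pathological: brute force
      for (int t = 0; t < m; ++t) {
        int a = tri(t, 0) - 1, b = tri(t, 1) - 1, cc = tri(t, 2) - 1;
        double w[3];
        double d2 = tri_dist2(p0, p1, vx[a], vy[a], vx[b], vy[b],
                              vx[cc], vy[cc], w);
        if (d2 < best_d2) {
          best_d2 = d2; best_t = t;
          best_w[0] = w[0]; best_w[1] = w[1]; best_w[2] = w[2];
        }
      }
    }
    out_tri[q] = best_t + 1;
    out_w(q, 0) = best_w[0]; out_w(q, 1) = best_w[1]; out_w(q, 2) = best_w[2];
    double d = std::sqrt(best_d2);
    snap_d[q] = d;
    snapped[q] = d > tol;
  }
  return List::create(_["triangle"] = out_tri, _["weights"] = out_w,
                      _["snapped"] = snapped, _["distance"] = snap_d);
}

// Nearest neighbour among 3D points (grid-accelerated). Returns 1-based index.
// [[Rcpp::export]]
IntegerVector cpp_nearest_3d(NumericVector qx, NumericVector qy, NumericVector qz,
                             NumericVector px, NumericVector py, NumericVector pz) {
  const int n = px.size(), nq = qx.size();
  IntegerVector out(nq);
  if (n == 0) return out;
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    mn[0] = std::min(mn[0], px[i]); mx[0] = std::max(mx[0], px[i]);
    mn[1] = std::min(mn[1], py[i]); mx[1] = std::max(mx[1], py[i]);
    mn[2] = std::min(mn[2], pz[i]); mx[2] = std::max(mx[2], pz[i]);
  }
  double ext[3];
  for (int k = 0; k < 3; ++k) {
    ext[k] = mx[k] - mn[k];
    if (ext[k] <= 0) ext[k] = 1e-9;
  }
  double vol = ext[0] * ext[1] * ext[2];
  double h = std::cbrt(vol / std::max(1, n)) * 2.0;
  if (h <= 0 || !std::isfinite(h)) h = 1.0;
  int ng[3];
  int cap = std::max(1, std::min(256, (int)std::ceil(
      4.0 * std::cbrt((double)n))));
  for (int k = 0; k < 3; ++k)
    ng[k] = std::max(1, std::min(cap, (int)std::ceil(ext[k] / h)));
  std::vector<std::vector<int> > cells((size_t)ng[0] * ng[1] * ng[2]);
  double hh[3];
  for (int k = 0; k < 3; ++k) hh[k] = ext[k] / ng[k];
  // ring-search termination scale: smallest cell size over the
  // non-degenerate dimensions (a flat cloud must not stall the search)
  double hmin = std::numeric_limits<double>::infinity();
  for (int k = 0; k < 3; ++k)
    if (ng[k] > 1) hmin = std::min(hmin, hh[k]);
  if (!std::isfinite(hmin)) hmin = std::max(hh[0], std::max(hh[1], hh[2]));
  for (int i = 0; i < n; ++i) {
    int ci = std::max(0, std::min(ng[0] - 1, (int)((px[i] - mn[0]) / hh[0])));
    int cj = std::max(0, std::min(ng[1] - 1, (int)((py[i] - mn[1]) / hh[1])));
    int ck = std::max(0, std::min(ng[2] - 1, (int)((pz[i] - mn[2]) / hh[2])));
    cells[((size_t)ci * ng[1] + cj) * ng[2] + ck].push_back(i);
  }
  int max_ring = ng[0] + ng[1] + ng[2];
  for (int q = 0; q < nq; ++q) {
    double p0 = qx[q], p1 = qy[q], p2 = qz[q];
    int ci = std::max(0, std::min(ng[0] - 1, (int)((p0 - mn[0]) / hh[0])));
    int cj = std::max(0, std::min(ng[1] - 1, (int)((p1 - mn[1]) / hh[1])));
    int ck = std::max(0, std::min(ng[2] - 1, (int)((p2 - mn[2]) / hh[2])));
    int best = -1;
    double best_d2 = std::numeric_limits<double>::infinity();
    for (int ring = 0; ring <= max_ring; ++ring) {
      bool found_any = false;
      for (int i = ci - ring; i <= ci + ring; ++i) {
        if (i < 0 || i >= ng[0]) continue;
        for (int j = cj - ring; j <= cj + ring; ++j) {
          if (j < 0 || j >= ng[1]) continue;
          for (int k = ck - ring; k <= ck + ring; ++k) {
            if (k < 0 || k >= ng[2]) continue;
            if (ring > 0 && std::abs(i - ci) != ring &&
                std::abs(j - cj) != ring && std::abs(k - ck) != ring)
              continue;
            const std::vector<int>& cell =
              cells[((size_t)i * ng[1] + j) * ng[2] + k];
            for (size_t c = 0; c < cell.size(); ++c) {
              int t = cell[c];
              double d2 = (px[t] - p0) * (px[t] - p0) +
                          (py[t] - p1) * (py[t] - p1) +
                          (pz[t] - p2) * (pz[t] - p2);
              if (d2 < best_d2) { best_d2 = d2; best = t; }
              found_any = true;
            }
          }
        }
      }
      if (best >= 0) {
        double reach = (ring > 0 ? ring - 1 : 0) * hmin;
        if (reach * reach > best_d2) break;
      }
    }
    if (best < 0) { // fallback
      for (int t = 0; t < n; ++t) {
        double d2 = (px[t] - p0) * (px[t] - p0) + (py[t] - p1) * (py[t] - p1) +
                    (pz[t] - p2) * (pz[t] - p2);
        if (d2 < best_d2) { best_d2 = d2; best = t; }
      }
    }
    out[q] = best + 1;
  }
  return out;
}
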