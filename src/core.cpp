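#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Polygon primitives. Polygons are passed as x/y vertex vectors (not closed:
// last vertex != first; closure is implicit). Coordinates are physical µm.
// ---------------------------------------------------------------------------

static inline double signed_area(const NumericVector& px, const NumericVector& py) {
  const int n = px.size();
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += px[j] * py[i] - px[i] * py[j];
  return 0.5 * a;
}

// Even-odd point-in-polygon with closed boundary convention (on-edge counts
// as inside, within tolerance eps).
// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector x, NumericVector y,
                                 NumericVector px, NumericVector py,
                                 double eps = 1e-9) {
  const int np = x.size(), nv = px.size();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    const double X = x[p], Y = y[p];
    bool inside = false, onedge = false;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      const double xi = px[i], yi = py[i], xj = px[j], yj = py[j];
      // on-edge test
      const double dx = xj - xi, dy = yj - yi;
      const double len2 = dx * dx + dy * dy;
      if (len2 > 0) {
        double t = ((X - xi) * dx + (Y - yi) * dy) / len2;
        t = std::max(0.0, std::min(1.0, t));
        const double qx = xi + t * dx - X, qy = yi + t * dy - Y;
        if (qx * qx + qy * qy <= eps * eps) { onedge = true; break; }
      }
      if (((yi > Y) != (yj > Y)) &&
          (X < (xj - xi) * (Y - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[p] = onedge || inside;
  }
  return out;
}

// Minimum distance from each point to the polygon boundary (polyline of the
// closed polygon). Distance is 0 only for points exactly on the boundary;
// callers combine with cpp_points_in_poly for signed logic.
// [[Rcpp::export]]
NumericVector cpp_dist_to_poly(NumericVector x, NumericVector y,
                               NumericVector px, NumericVector py) {
  const int np = x.size(), nv = px.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double X = x[p], Y = y[p];
    double best = R_PosInf;
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      const double xi = px[i], yi = py[i], xj = px[j], yj = py[j];
      const double dx = xj - xi, dy = yj - yi;
      const double len2 = dx * dx + dy * dy;
      double t = len2 > 0 ? ((X - xi) * dx + (Y - yi) * dy) / len2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      const double qx = xi + t * dx - X, qy = yi + t * dy - Y;
      const double d2 = qx * qx + qy * qy;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact circle-polygon intersection area via Green's theorem: each polygon
// edge contributes either a triangle (sub-segment inside the disc) or a
// circular sector (sub-segment outside), relative to the circle center.
// Vectorized over circles (cx, cy, r recycled to common length).
// ---------------------------------------------------------------------------

static double circle_poly_area_one(double cx, double cy, double r,
                                   const NumericVector& px, const NumericVector& py) {
  const int n = px.size();
  const double r2 = r * r;
  double acc = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    // edge from A=v[j] to B=v[i], translated so the circle center is origin
    const double ax = px[j] - cx, ay = py[j] - cy;
    const double bx = px[i] - cx, by = py[i] - cy;
    const double dx = bx - ax, dy = by - ay;
    const double a = dx * dx + dy * dy;
    if (a == 0) continue;
    // |A + t D|^2 = r^2
    const double b = 2.0 * (ax * dx + ay * dy);
    const double c = ax * ax + ay * ay - r2;
    double ts[4]; int nt = 0;
    ts[nt++] = 0.0;
    const double disc = b * b - 4.0 * a * c;
    if (disc > 0) {
      const double sq = std::sqrt(disc);
      const double t1 = (-b - sq) / (2.0 * a), t2 = (-b + sq) / (2.0 * a);
      if (t1 > 0.0 && t1 < 1.0) ts[nt++] = t1;
      if (t2 > 0.0 && t2 < 1.0) ts[nt++] = t2;
    }
    ts[nt++] = 1.0;
    for (int k = 0; k + 1 < nt; ++k) {
      const double t0 = ts[k], t1 = ts[k + 1];
      if (t1 <= t0) continue;
      const double tm = 0.5 * (t0 + t1);
      const double mx = ax + tm * dx, my = ay + tm * dy;
      const double p0x = ax + t0 * dx, p0y = ay + t0 * dy;
      const double p1x = ax + t1 * dx, p1y = ay + t1 * dy;
      // strict test: a tangent segment's midpoint lies exactly on the circle
      // and must count as outside (sector), not inside (triangle)
      if (mx * mx + my * my < r2 * (1.0 - 1e-12)) {
        acc += 0.5 * (p0x * p1y - p1x * p0y);           // triangle with center
      } else {
        const double cross = p0x * p1y - p1x * p0y;
        const double dot = p0x * p1x + p0y * p1y;
        acc += 0.5 * r2 * std::atan2(cross, dot);       // circular sector
      }
    }
  }
  // orientation: match sign of the polygon itself
  return signed_area(px, py) >= 0 ? std::max(0.0, acc) : std::max(0.0, -acc);
}

// [[Rcpp::export]]
NumericVector cpp_circle_poly_area(NumericVector cx, NumericVector cy,
                                   NumericVector r,
                                   NumericVector px, NumericVector py) {
  const int n = std::max(cx.size(), std::max(cy.size(), r.size()));
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = circle_poly_area_one(cx[i % cx.size()], cy[i % cy.size()],
                                  r[i % r.size()], px, py);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling on a binary matrix (flood fill), 8- or
// 4-connectivity. Returns an integer matrix of labels (0 = background).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix m, bool eight = true) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = { 0, 0,-1, 1};
  const int nd = eight ? 8 : 4;
  const int* dr = eight ? dr8 : dr4;
  const int* dc = eight ? dc8 : dc4;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    if (!m(r, c) || lab(r, c)) continue;
    ++next;
    stack.push_back(r + c * nr);
    lab(r, c) = next;
    while (!stack.empty()) {
      const int idx = stack.back(); stack.pop_back();
      const int cr = idx % nr, cc = idx / nr;
      for (int k = 0; k < nd; ++k) {
        const int r2 = cr + dr[k], c2 = cc + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (m(r2, c2) && !lab(r2, c2)) {
          lab(r2, c2) = next;
          stack.push_back(r2 + c2 * nr);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Neighbor counts within each radius (excluding self) -- Ripley support.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_count_within(NumericVector x, NumericVector y,
                               NumericVector radii) {
  const int n = x.size(), m = radii.size();
  std::vector<double> r2(m);
  for (int k = 0; k < m; ++k) r2[k] = radii[k] * radii[k];
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      for (int k = 0; k < m; ++k)
        if (d2 <= r2[k]) ++out(i, k);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force exact kNN (excluding self). Returns 1-based index matrix and
// distances, neighbors in increasing distance order (ties: lower index).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow(), d = X.ncol();
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dd = X(i, c) - X(j, c);
        s += dd * dd;
      }
      cand[j] = std::make_pair(i == j ? R_PosInf : s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = cand[m].second + 1;
      dist(i, m) = std::sqrt(cand[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// DBSCAN (classic, O(n^2) region queries). Returns 0 for noise, 1..K labels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix X, double eps, int minPts) {
  const int n = X.nrow(), d = X.ncol();
  const double eps2 = eps * eps;
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dd = X(i, c) - X(j, c);
        s += dd * dd;
        if (s > eps2) break;
      }
      if (s <= eps2) nb[i].push_back(j);  // includes self
    }
  }
  IntegerVector lab(n, 0);
  std::vector<bool> visited(n, false);
  int cl = 0;
  std::vector<int> seeds;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    if ((int)nb[i].size() < minPts) continue;  // noise unless claimed later
    ++cl;
    lab[i] = cl;
    seeds = nb[i];
    for (size_t s = 0; s < seeds.size(); ++s) {
      const int q = seeds[s];
      if (lab[q] == 0) lab[q] = cl;  // border point
      if (visited[q]) continue;
      visited[q] = true;
      if ((int)nb[q].size() >= minPts)
        seeds.insert(seeds.end(), nb[q].begin(), nb[q].end());
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay triangulation. Returns an integer matrix of triangle
// vertex indices (1-based). Collinear input yields zero triangles.
// ---------------------------------------------------------------------------

struct Tri {
  int a, b, c;
  double cx, cy, r2;
  bool dead;
};

static void circumcircle(double ax, double ay, double bx, double by,
                         double cx_, double cy_, Tri& t) {
  const double dx1 = bx - ax, dy1 = by - ay;
  const double dx2 = cx_ - ax, dy2 = cy_ - ay;
  const double d = 2.0 * (dx1 * dy2 - dy1 * dx2);
  if (std::fabs(d) < 1e-300) { t.cx = t.cy = 0; t.r2 = R_PosInf; return; }
  const double l1 = dx1 * dx1 + dy1 * dy1;
  const double l2 = dx2 * dx2 + dy2 * dy2;
  const double ux = (dy2 * l1 - dy1 * l2) / d;
  const double uy = (dx1 * l2 - dx2 * l1) / d;
  t.cx = ax + ux;
  t.cy = ay + uy;
  t.r2 = ux * ux + uy * uy;
}

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) return IntegerMatrix(0, 3);
  // normalize coordinates for numerical stability
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) return IntegerMatrix(0, 3);
  std::vector<double> X(n + 3), Y(n + 3);
  for (int i = 0; i < n; ++i) {
    X[i] = (x[i] - xmin) / span;
    Y[i] = (y[i] - ymin) / span;
  }
  // super-triangle well outside [0,1]^2
  X[n] = -50.0;  Y[n] = -50.0;
  X[n + 1] = 50.0; Y[n + 1] = -50.0;
  X[n + 2] = 0.5;  Y[n + 2] = 80.0;
  std::vector<Tri> tris;
  Tri t0; t0.a = n; t0.b = n + 1; t0.c = n + 2; t0.dead = false;
  circumcircle(X[t0.a], Y[t0.a], X[t0.b], Y[t0.b], X[t0.c], Y[t0.c], t0);
  tris.push_back(t0);
  std::vector<std::pair<int,int> > edges;
  for (int p = 0; p < n; ++p) {
    edges.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (tris[t].dead) continue;
      const double dx = X[p] - tris[t].cx, dy = Y[p] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 * (1.0 + 1e-12)) {
        tris[t].dead = true;
        edges.push_back(std::make_pair(tris[t].a, tris[t].b));
        edges.push_back(std::make_pair(tris[t].b, tris[t].c));
        edges.push_back(std::make_pair(tris[t].c, tris[t].a));
      }
    }
    // boundary edges appear exactly once (ignoring direction)
    for (size_t i = 0; i < edges.size(); ++i) {
      bool dup = false;
      for (size_t j = 0; j < edges.size(); ++j) {
        if (i == j) continue;
        if ((edges[i].first == edges[j].first && edges[i].second == edges[j].second) ||
            (edges[i].first == edges[j].second && edges[i].second == edges[j].first)) {
          dup = true; break;
        }
      }
      if (dup) continue;
      Tri nt; nt.a = edges[i].first; nt.b = edges[i].second; nt.c = p; nt.dead = false;
      circumcircle(X[nt.a], Y[nt.a], X[nt.b], Y[nt.b], X[nt.c], Y[nt.c], nt);
      tris.push_back(nt);
    }
    // periodic compaction keeps the scan cheap
    if (tris.size() > 4000) {
      std::vector<Tri> keep;
      keep.reserve(tris.size());
      for (size_t t = 0; t < tris.size(); ++t)
        if (!tris[t].dead) keep.push_back(tris[t]);
      tris.swap(keep);
    }
  }
  std::vector<int> out;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (tris[t].dead) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    out.push_back(tris[t].a + 1);
    out.push_back(tris[t].b + 1);
    out.push_back(tris[t].c + 1);
  }
  const int m = out.size() / 3;
  IntegerMatrix res(m, 3);
  for (int i = 0; i < m; ++i) {
    res(i, 0) = out[3 * i];
    res(i, 1) = out[3 * i + 1];
    res(i, 2) = out[3 * i + 2];
  }
  return res;
}

// ---------------------------------------------------------------------------
// UMAP stochastic gradient optimizer (reference layout algorithm: sampled
// attractive updates along graph edges, uniform negative sampling). Own
// xorshift RNG so results are fully reproducible for a given seed.
// ---------------------------------------------------------------------------

static inline uint64_t xorshift64(uint64_t& s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double clip4(double v) {
  return v > 4.0 ? 4.0 : (v < -4.0 ? -4.0 : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_umap_optimize(IntegerVector head, IntegerVector tail,
                                NumericVector epochs_per_sample,
                                NumericMatrix init,
                                double a, double b, double gamma,
                                int n_epochs, double initial_alpha,
                                int negative_sample_rate, int seed) {
  const int n = init.nrow();
  const int ne = head.size();
  NumericMatrix emb = clone(init);
  std::vector<double> eons(ne), eonsn(ne);
  for (int e = 0; e < ne; ++e) {
    eons[e] = epochs_per_sample[e];
    eonsn[e] = epochs_per_sample[e] / negative_sample_rate;
  }
  uint64_t rng = (uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL;
  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double alpha = initial_alpha * (1.0 - (double)(epoch - 1) / n_epochs);
    for (int e = 0; e < ne; ++e) {
      if (eons[e] > epoch) continue;
      const int i = head[e] - 1, j = tail[e] - 1;
      double dx = emb(i, 0) - emb(j, 0);
      double dy = emb(i, 1) - emb(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 > 0) {
        const double pd = std::pow(d2, b - 1.0);
        const double grad = (-2.0 * a * b * pd) / (a * pd * d2 + 1.0);
        const double gx = clip4(grad * dx), gy = clip4(grad * dy);
        emb(i, 0) += alpha * gx; emb(i, 1) += alpha * gy;
        emb(j, 0) -= alpha * gx; emb(j, 1) -= alpha * gy;
      }
      eons[e] += epochs_per_sample[e];
      const double epn = epochs_per_sample[e] / negative_sample_rate;
      int n_neg = (int)((epoch - eonsn[e]) / epn);
      if (n_neg < 0) n_neg = 0;
      for (int s = 0; s < n_neg; ++s) {
        const int k = (int)(xorshift64(rng) % (uint64_t)n);
        if (k == i) continue;
        dx = emb(i, 0) - emb(k, 0);
        dy = emb(i, 1) - emb(k, 1);
        d2 = dx * dx + dy * dy;
        double gx, gy;
        if (d2 > 0) {
          const double grad = (2.0 * gamma * b) /
            ((0.001 + d2) * (a * std::pow(d2, b) + 1.0));
          gx = clip4(grad * dx); gy = clip4(grad * dy);
        } else {
          gx = 4.0; gy = 4.0;
        }
        emb(i, 0) += alpha * gx; emb(i, 1) += alpha * gy;
      }
      eonsn[e] += epn * n_neg;
    }
  }
  return emb;
}
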