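#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>

using namespace Rcpp;

// Incremental 3-D convex hull over a point cloud.
//
// Facets are kept as outward-oriented triangles.  A point is considered
// strictly outside a facet plane when its signed distance exceeds `eps`
// (absolute, same units as the coordinates); points within `eps` of the
// hull surface are treated as on-hull and never become vertices.  After
// construction, edges interior to a coplanar facet patch (dihedral angle
// between adjacent facet normals below `merge_tol` radians) are dropped so
// the reported edge set is that of the hull *polygon*, not of an arbitrary
// triangulation.

struct Facet {
  int a, b, c;       // 0-based point indices
  double nx, ny, nz; // outward unit normal
  double off;        // plane offset: n . x = off
  bool alive;
};

static inline double dot3(double x1, double y1, double z1,
                          double x2, double y2, double z2) {
  return x1 * x2 + y1 * y2 + z1 * z2;
}

static void facet_plane(const NumericMatrix &P, Facet &f,
                        double ix, double iy, double iz) {
  // normal from the triangle, oriented away from interior point (ix,iy,iz)
  double ux = P(f.b, 0) - P(f.a, 0), uy = P(f.b, 1) - P(f.a, 1),
         uz = P(f.b, 2) - P(f.a, 2);
  double vx = P(f.c, 0) - P(f.a, 0), vy = P(f.c, 1) - P(f.a, 1),
         vz = P(f.c, 2) - P(f.a, 2);
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nrm <= 0) stop("degenerate facet encountered during hull construction");
  nx /= nrm; ny /= nrm; nz /= nrm;
  double off = dot3(nx, ny, nz, P(f.a, 0), P(f.a, 1), P(f.a, 2));
  if (dot3(nx, ny, nz, ix, iy, iz) > off) { // flip outward
    nx = -nx; ny = -ny; nz = -nz; off = -off;
    std::swap(f.b, f.c);
  }
  f.nx = nx; f.ny = ny; f.nz = nz; f.off = off;
}

static inline double signed_dist(const Facet &f, const NumericMatrix &P, int i) {
  return dot3(f.nx, f.ny, f.nz, P(i, 0), P(i, 1), P(i, 2)) - f.off;
}

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix P, double eps = 1e-9, double merge_tol = 1e-6) {
  const int n = P.nrow();
  if (P.ncol() != 3) stop("point matrix must have 3 columns");
  if (n < 4) stop("degenerate point cloud: need at least 4 points (rank at most %d)", n > 0 ? n - 1 : 0);

  // --- initial simplex: maximally spread points ---
  int i0 = 0, i1 = 0;
  {
    double best = -1.0;
    for (int ax = 0; ax < 3; ++ax) {
      int lo = 0, hi = 0;
      for (int i = 1; i < n; ++i) {
        if (P(i, ax) < P(lo, ax)) lo = i;
        if (P(i, ax) > P(hi, ax)) hi = i;
      }
      double d = P(hi, ax) - P(lo, ax);
      if (d > best) { best = d; i0 = lo; i1 = hi; }
    }
    if (best <= eps) stop("degenerate point cloud: all points coincide (rank 0)");
  }
  double ax_ = P(i1, 0) - P(i0, 0), ay_ = P(i1, 1) - P(i0, 1), az_ = P(i1, 2) - P(i0, 2);
  double alen2 = ax_ * ax_ + ay_ * ay_ + az_ * az_;
  int i2 = -1; double best2 = eps;
  for (int i = 0; i < n; ++i) {
    double wx = P(i, 0) - P(i0, 0), wy = P(i, 1) - P(i0, 1), wz = P(i, 2) - P(i0, 2);
    double t = dot3(wx, wy, wz, ax_, ay_, az_) / alen2;
    double dx = wx - t * ax_, dy = wy - t * ay_, dz = wz - t * az_;
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d > best2) { best2 = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point cloud: all points collinear (rank 1)");
  // plane through i0,i1,i2
  double ux = P(i1, 0) - P(i0, 0), uy = P(i1, 1) - P(i0, 1), uz = P(i1, 2) - P(i0, 2);
  double vx = P(i2, 0) - P(i0, 0), vy = P(i2, 1) - P(i0, 1), vz = P(i2, 2) - P(i0, 2);
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  nx /= nrm; ny /= nrm; nz /= nrm;
  double off0 = dot3(nx, ny, nz, P(i0, 0), P(i0, 1), P(i0, 2));
  int i3 = -1; double best3 = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot3(nx, ny, nz, P(i, 0), P(i, 1), P(i, 2)) - off0);
    if (d > best3) { best3 = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point cloud: all points coplanar (rank 2)");

  // interior reference point: centroid of initial simplex
  double cx = (P(i0, 0) + P(i1, 0) + P(i2, 0) + P(i3, 0)) / 4.0;
  double cy = (P(i0, 1) + P(i1, 1) + P(i2, 1) + P(i3, 1)) / 4.0;
  double cz = (P(i0, 2) + P(i1, 2) + P(i2, 2) + P(i3, 2)) / 4.0;

  std::vector<Facet> facets;
  facets.reserve(8 * n);
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int k = 0; k < 4; ++k) {
    Facet f; f.a = tet[k][0]; f.b = tet[k][1]; f.c = tet[k][2]; f.alive = true;
    facet_plane(P, f, cx, cy, cz);
    facets.push_back(f);
  }

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    visible.clear();
    for (size_t k = 0; k < facets.size(); ++k) {
      if (facets[k].alive && signed_dist(facets[k], P, p) > eps) visible.push_back((int)k);
    }
    if (visible.empty()) continue; // inside or on the hull

    // horizon = edges of visible facets whose twin facet is not visible
    std::map<std::pair<int, int>, int> edge_count; // undirected edge -> count among visible
    std::map<std::pair<int, int>, std::pair<int, int>> edge_dir; // keep one orientation
    for (int k : visible) {
      const Facet &f = facets[k];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        int u = e[j][0], v = e[j][1];
        std::pair<int, int> key = u < v ? std::make_pair(u, v) : std::make_pair(v, u);
        edge_count[key]++;
        edge_dir[key] = std::make_pair(u, v);
      }
    }
    for (int k : visible) facets[k].alive = false;
    for (std::map<std::pair<int, int>, int>::const_iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue; // interior to the visible region
      Facet f;
      f.a = p; f.b = it->first.first; f.c = it->first.second; f.alive = true;
      facet_plane(P, f, cx, cy, cz);
      facets.push_back(f);
    }
  }

  // --- collect live facets ---
  std::vector<int> live;
  for (size_t k = 0; k < facets.size(); ++k) if (facets[k].alive) live.push_back((int)k);
  const int nf = (int)live.size();

  // safety: no point may lie strictly outside the final hull
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < nf; ++k) {
      if (signed_dist(facets[live[k]], P, i) > 10 * eps)
        stop("internal hull inconsistency: point %d lies outside the final hull", i + 1);
    }
  }

  // --- edge extraction with coplanar-facet merging ---
  std::map<std::pair<int, int>, std::vector<int>> edge_facets;
  for (int k = 0; k < nf; ++k) {
    const Facet &f = facets[live[k]];
    int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
    for (int j = 0; j < 3; ++j) {
      int u = e[j][0], v = e[j][1];
      std::pair<int, int> key = u < v ? std::make_pair(u, v) : std::make_pair(v, u);
      edge_facets[key].push_back(k);
    }
  }
  std::vector<int> ea, eb;
  for (std::map<std::pair<int, int>, std::vector<int>>::const_iterator it = edge_facets.begin();
       it != edge_facets.end(); ++it) {
    const std::vector<int> &fs = it->second;
    if (fs.size() != 2) stop("internal hull inconsistency: non-manifold edge");
    const Facet &f1 = facets[live[fs[0]]];
    const Facet &f2 = facets[live[fs[1]]];
    double c = dot3(f1.nx, f1.ny, f1.nz, f2.nx, f2.ny, f2.nz);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    if (std::acos(c) > merge_tol) { // true polytope edge
      ea.push_back(it->first.first + 1);
      eb.push_back(it->first.second + 1);
    }
  }

  // vertices: endpoints of polygon edges
  std::vector<bool> isv(n, false);
  for (size_t k = 0; k < ea.size(); ++k) { isv[ea[k] - 1] = true; isv[eb[k] - 1] = true; }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (isv[i]) verts.push_back(i + 1);

  IntegerMatrix edges((int)ea.size(), 2);
  for (size_t k = 0; k < ea.size(); ++k) { edges(k, 0) = ea[k]; edges(k, 1) = eb[k]; }
  IntegerMatrix tris(nf, 3);
  for (int k = 0; k < nf; ++k) {
    tris(k, 0) = facets[live[k]].a + 1;
    tris(k, 1) = facets[live[k]].b + 1;
    tris(k, 2) = facets[live[k]].c + 1;
  }
  return List::create(_["vertices"] = wrap(verts),
                      _["edges"] = edges,
                      _["facets"] = tris);
}
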