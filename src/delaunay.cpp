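// Incremental Bowyer-Watson Delaunay triangulation with walk-based point
// location, plus linear (barycentric) interpolation of scattered elevations
// onto arbitrary query points. This backs the TIN rasterization of first/last
// LiDAR returns into surface and terrain models.
//
// No external geometry library is linked: the triangulator is self-contained
// and uses tolerance-guarded double predicates. Inputs are projected planar
// coordinates in meters; typical magnitudes (<= 1e7) keep the predicates well
// within double precision.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// strictly-inside-circumcircle test for CCW triangle (a,b,c)
inline bool in_circle(double ax, double ay, double bx, double by,
                      double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  const double det = adx * (bdy * cd - bd * cdy)
                   - ady * (bdx * cd - bd * cdx)
                   + ad * (bdx * cdy - bdy * cdx);
  // relative tolerance: cocircular points (regular grids) must not enter the
  // cavity, otherwise the cavity can lose star-shapedness
  const double mag = (ad + bd + cd) *
      (std::fabs(adx) + std::fabs(ady) + std::fabs(bdx) +
       std::fabs(bdy) + std::fabs(cdx) + std::fabs(cdy) + 1.0);
  return det > 1e-12 * mag;
}

struct Tri {
  int v[3];   // vertex ids, CCW
  int nb[3];  // nb[k] = triangle across edge opposite v[k], -1 if none
  bool alive;
};

struct Triangulation {
  std::vector<double> px, py;  // n real points + 3 super vertices
  int n = 0;                   // number of real points
  std::vector<Tri> tris;
  double scale = 1.0;          // bbox span, for tolerances

  bool is_super(int v) const { return v >= n; }

  int locate(int start, double x, double y) const {
    int t = start;
    const double tol = -1e-12 * scale * scale;
    size_t guard = 10 * tris.size() + 100;
    while (guard--) {
      const Tri &tr = tris[t];
      int next = -1;
      for (int k = 0; k < 3; ++k) {
        const int a = tr.v[(k + 1) % 3], b = tr.v[(k + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < tol) {
          next = tr.nb[k];
          break;
        }
      }
      if (next < 0) return t;
      t = next;
    }
    // pathological walk: fall back to linear scan
    for (size_t i = 0; i < tris.size(); ++i) {
      if (!tris[i].alive) continue;
      const Tri &tr = tris[i];
      bool inside = true;
      for (int k = 0; k < 3 && inside; ++k) {
        const int a = tr.v[(k + 1) % 3], b = tr.v[(k + 2) % 3];
        if (orient2d(px[a], py[a], px[b], py[b], x, y) < tol) inside = false;
      }
      if (inside) return static_cast<int>(i);
    }
    return t;
  }
};

// neighbor slot of triangle `t` that points across edge {a,b}
inline int edge_slot(const Tri &t, int a, int b) {
  for (int k = 0; k < 3; ++k) {
    const int u = t.v[(k + 1) % 3], w = t.v[(k + 2) % 3];
    if ((u == a && w == b) || (u == b && w == a)) return k;
  }
  return -1;
}

Triangulation build_triangulation(const NumericVector &x,
                                  const NumericVector &y) {
  const int n = x.size();
  if (n < 3) stop("Delaunay triangulation needs at least 3 points");

  Triangulation T;
  T.n = n;
  T.px.assign(x.begin(), x.end());
  T.py.assign(y.begin(), y.end());

  double minx = T.px[0], maxx = T.px[0], miny = T.py[0], maxy = T.py[0];
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, T.px[i]); maxx = std::max(maxx, T.px[i]);
    miny = std::min(miny, T.py[i]); maxy = std::max(maxy, T.py[i]);
  }
  const double span = std::max({maxx - minx, maxy - miny, 1.0});
  T.scale = span;

  // collinearity check
  double maxor = 0.0;
  for (int i = 2; i < n; ++i) {
    maxor = std::max(maxor, std::fabs(orient2d(T.px[0], T.py[0],
                                               T.px[1], T.py[1],
                                               T.px[i], T.py[i])));
    if (maxor > 1e-9 * span * span) break;
  }
  if (maxor <= 1e-9 * span * span)
    stop("Delaunay triangulation needs at least 3 non-collinear points");

  // super-triangle far outside the data
  const double cx = 0.5 * (minx + maxx), cy = 0.5 * (miny + maxy);
  const double s = 30.0 * span;
  T.px.push_back(cx - s); T.py.push_back(cy - s);
  T.px.push_back(cx + s); T.py.push_back(cy - s);
  T.px.push_back(cx);     T.py.push_back(cy + s);
  Tri super; super.v[0] = n; super.v[1] = n + 1; super.v[2] = n + 2;
  super.nb[0] = super.nb[1] = super.nb[2] = -1; super.alive = true;
  T.tris.push_back(super);

  // serpentine bucket order keeps consecutive insertions spatially close so
  // the walk from the previously used triangle is short
  const int nb = std::max(1, static_cast<int>(std::ceil(std::sqrt(n / 4.0))));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double dy = (maxy - miny) > 0 ? (maxy - miny) : 1.0;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    int ra = std::min(nb - 1, static_cast<int>((T.py[a] - miny) / dy * nb));
    int rb = std::min(nb - 1, static_cast<int>((T.py[b] - miny) / dy * nb));
    if (ra != rb) return ra < rb;
    const bool rev = ra & 1;
    return rev ? (T.px[a] > T.px[b]) : (T.px[a] < T.px[b]);
  });

  std::vector<int> bad, boundary_a, boundary_b, boundary_out, stack_;
  std::vector<uint8_t> in_bad;
  int last = 0;

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const double pxx = T.px[p], pyy = T.py[p];
    int tloc = T.locate(last, pxx, pyy);

    // skip (near-)duplicate of an existing vertex
    bool dup = false;
    for (int k = 0; k < 3; ++k) {
      const int v = T.tris[tloc].v[k];
      const double dx = T.px[v] - pxx, dyv = T.py[v] - pyy;
      if (dx * dx + dyv * dyv < 1e-20 * span * span) { dup = true; break; }
    }
    if (dup) { last = tloc; continue; }

    // grow cavity of triangles whose circumcircle contains p
    bad.clear(); stack_.clear();
    in_bad.assign(T.tris.size(), 0);
    bad.push_back(tloc); in_bad[tloc] = 1; stack_.push_back(tloc);
    while (!stack_.empty()) {
      const int t = stack_.back(); stack_.pop_back();
      for (int k = 0; k < 3; ++k) {
        const int nbt = T.tris[t].nb[k];
        if (nbt < 0 || in_bad[nbt]) continue;
        const Tri &tr = T.tris[nbt];
        if (in_circle(T.px[tr.v[0]], T.py[tr.v[0]],
                      T.px[tr.v[1]], T.py[tr.v[1]],
                      T.px[tr.v[2]], T.py[tr.v[2]], pxx, pyy)) {
          in_bad[nbt] = 1; bad.push_back(nbt); stack_.push_back(nbt);
        }
      }
    }

    // cavity boundary (directed CCW as edges of bad triangles)
    auto collect_boundary = [&]() {
      boundary_a.clear(); boundary_b.clear(); boundary_out.clear();
      bool star = true;
      for (int t : bad) {
        for (int k = 0; k < 3; ++k) {
          const int nbt = T.tris[t].nb[k];
          if (nbt >= 0 && in_bad[nbt]) continue;
          const int a = T.tris[t].v[(k + 1) % 3];
          const int b = T.tris[t].v[(k + 2) % 3];
          boundary_a.push_back(a); boundary_b.push_back(b);
          boundary_out.push_back(nbt);
          if (orient2d(T.px[a], T.py[a], T.px[b], T.py[b], pxx, pyy) <= 0.0)
            star = false;
        }
      }
      return star;
    };
    if (!collect_boundary()) {
      // numerically awkward cavity: retreat to the containing triangle only
      for (int t : bad) in_bad[t] = 0;
      bad.assign(1, tloc); in_bad[tloc] = 1;
      if (!collect_boundary()) { last = tloc; continue; }
    }

    for (int t : bad) T.tris[t].alive = false;

    // fan of new triangles (p, a, b); link to outer neighbors and each other
    const int base = static_cast<int>(T.tris.size());
    const int m = static_cast<int>(boundary_a.size());
    std::vector<int> by_a(m), by_b(m);
    for (int e = 0; e < m; ++e) {
      Tri t;
      t.v[0] = p; t.v[1] = boundary_a[e]; t.v[2] = boundary_b[e];
      t.nb[0] = boundary_out[e]; t.nb[1] = -1; t.nb[2] = -1;
      t.alive = true;
      T.tris.push_back(t);
      if (boundary_out[e] >= 0) {
        const int slot = edge_slot(T.tris[boundary_out[e]],
                                   boundary_a[e], boundary_b[e]);
        if (slot >= 0) T.tris[boundary_out[e]].nb[slot] = base + e;
      }
    }
    // match edge (b, p) of triangle e with edge (p, a') of the triangle whose
    // a' equals b
    for (int e = 0; e < m; ++e) {
      for (int f = 0; f < m; ++f) {
        if (boundary_a[f] == boundary_b[e]) { by_a[e] = f; break; }
      }
    }
    for (int e = 0; e < m; ++e) {
      T.tris[base + e].nb[1] = base + by_a[e];          // across (b, p)
      T.tris[base + by_a[e]].nb[2] = base + e;          // across (p, a')
    }
    last = base;
  }
  return T;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_delaunay_triangles")]]
IntegerMatrix cpp_delaunay_triangles(NumericVector x, NumericVector y) {
  Triangulation T = build_triangulation(x, y);
  std::vector<int> keep;
  for (size_t i = 0; i < T.tris.size(); ++i) {
    const Tri &t = T.tris[i];
    if (!t.alive) continue;
    if (T.is_super(t.v[0]) || T.is_super(t.v[1]) || T.is_super(t.v[2]))
      continue;
    keep.push_back(static_cast<int>(i));
  }
  IntegerMatrix out(keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int k = 0; k < 3; ++k)
      out(i, k) = T.tris[keep[i]].v[k] + 1;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_tin_interpolate")]]
NumericVector cpp_tin_interpolate(NumericVector x, NumericVector y,
                                  NumericVector z,
                                  NumericVector qx, NumericVector qy) {
  if (x.size() != y.size() || x.size() != z.size())
    stop("x, y and z must have equal length");
  Triangulation T = build_triangulation(x, y);
  const int nq = qx.size();
  NumericVector out(nq, NA_REAL);
  int last = 0;
  for (size_t i = 0; i < T.tris.size(); ++i)
    if (T.tris[i].alive) { last = static_cast<int>(i); break; }
  for (int q = 0; q < nq; ++q) {
    const double qxx = qx[q], qyy = qy[q];
    const int t = T.locate(last, qxx, qyy);
    last = t;
    const Tri &tr = T.tris[t];
    if (T.is_super(tr.v[0]) || T.is_super(tr.v[1]) || T.is_super(tr.v[2]))
      continue;  // outside convex hull -> NA
    const int a = tr.v[0], b = tr.v[1], c = tr.v[2];
    const double det = orient2d(T.px[a], T.py[a], T.px[b], T.py[b],
                                T.px[c], T.py[c]);
    if (det == 0.0) continue;
    const double wa = orient2d(T.px[b], T.py[b], T.px[c], T.py[c], qxx, qyy);
    const double wb = orient2d(T.px[c], T.py[c], T.px[a], T.py[a], qxx, qyy);
    const double wc = orient2d(T.px[a], T.py[a], T.px[b], T.py[b], qxx, qyy);
    out[q] = (wa * z[a] + wb * z[b] + wc * z[c]) / det;
  }
  return out;
}
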