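#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Low-level mesh geometry kernels. Vertices are passed as an n x 3 numeric
// matrix, faces as an m x 3 integer matrix of 1-based (R) vertex indices.
// All coordinates are millimetres.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(const NumericMatrix &M, int i) {
  return Vec3{M(i, 0), M(i, 1), M(i, 2)};
}

inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return Vec3{a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 add(const Vec3 &a, const Vec3 &b) { return Vec3{a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 scale(const Vec3 &a, double s) { return Vec3{a.x * s, a.y * s, a.z * s}; }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Moeller-Trumbore. Returns true and fills t (parameter along dir, which
// need not be unit length) when the line origin + t*dir crosses the
// triangle, with a small barycentric slack so hits exactly on a shared
// edge are reported by both incident faces (deduplicated by the caller).
inline bool tri_intersect(const Vec3 &orig, const Vec3 &dir,
                          const Vec3 &a, const Vec3 &b, const Vec3 &c,
                          double &t, double bary_eps = 1e-10) {
  const Vec3 e1 = sub(b, a), e2 = sub(c, a);
  const Vec3 p = cross(dir, e2);
  const double det = dot(e1, p);
  if (std::fabs(det) < 1e-14) return false; // parallel / grazing in-plane
  const double inv = 1.0 / det;
  const Vec3 s = sub(orig, a);
  const double u = dot(s, p) * inv;
  if (u < -bary_eps || u > 1.0 + bary_eps) return false;
  const Vec3 q = cross(s, e1);
  const double v = dot(dir, q) * inv;
  if (v < -bary_eps || u + v > 1.0 + bary_eps) return false;
  t = dot(e2, q) * inv;
  return true;
}

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time
// Collision Detection, 5.1.5.
inline Vec3 closest_point_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  const Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  const Vec3 bp = sub(p, b);
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    return add(a, scale(ab, v));
  }

  const Vec3 cp = sub(p, c);
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    return add(a, scale(ac, w));
  }

  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scale(sub(c, b), w));
  }

  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  return add(a, add(scale(ab, v), scale(ac, w)));
}

// Squared distance between segments p1+s*d1 (s in [0,1]) and p2+t*d2.
// Ericson 5.1.9.
inline double segment_segment_dist2(const Vec3 &p1, const Vec3 &q1,
                                    const Vec3 &p2, const Vec3 &q2) {
  const Vec3 d1 = sub(q1, p1), d2 = sub(q2, p2), r = sub(p1, p2);
  const double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) {
    const Vec3 d = sub(p1, p2);
    return dot(d, d);
  }
  if (a <= EPS) {
    s = 0.0;
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    const double c = dot(d1, r);
    if (e <= EPS) {
      t = 0.0;
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      const double b = dot(d1, d2);
      const double denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  const Vec3 c1 = add(p1, scale(d1, s));
  const Vec3 c2 = add(p2, scale(d2, t));
  const Vec3 d = sub(c1, c2);
  return dot(d, d);
}

// Minimum distance between segment [p0,p1] and triangle (a,b,c):
// zero on a transversal crossing, else the minimum over the two
// endpoint-to-triangle distances and the three segment-to-edge distances.
inline double segment_triangle_distance_impl(const Vec3 &p0, const Vec3 &p1,
                                             const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  const Vec3 dir = sub(p1, p0);
  double t;
  if (tri_intersect(p0, dir, a, b, c, t, 0.0) && t >= 0.0 && t <= 1.0) return 0.0;
  double best = std::numeric_limits<double>::infinity();
  Vec3 cp = closest_point_triangle(p0, a, b, c);
  Vec3 d = sub(p0, cp);
  best = std::min(best, dot(d, d));
  cp = closest_point_triangle(p1, a, b, c);
  d = sub(p1, cp);
  best = std::min(best, dot(d, d));
  best = std::min(best, segment_segment_dist2(p0, p1, a, b));
  best = std::min(best, segment_segment_dist2(p0, p1, b, c));
  best = std::min(best, segment_segment_dist2(p0, p1, c, a));
  return std::sqrt(best);
}

} // namespace

// [[Rcpp::export(name = ".cpp_line_hits")]]
NumericMatrix cpp_line_hits(NumericVector origin, NumericVector dir,
                            NumericMatrix V, IntegerMatrix F) {
  const Vec3 o{origin[0], origin[1], origin[2]};
  const Vec3 d{dir[0], dir[1], dir[2]};
  std::vector<double> ts;
  std::vector<int> faces;
  const int m = F.nrow();
  for (int i = 0; i < m; ++i) {
    double t;
    if (tri_intersect(o, d, v3(V, F(i, 0) - 1), v3(V, F(i, 1) - 1), v3(V, F(i, 2) - 1), t)) {
      ts.push_back(t);
      faces.push_back(i);
    }
  }
  NumericMatrix out(ts.size(), 2);
  for (size_t i = 0; i < ts.size(); ++i) {
    out(i, 0) = ts[i];
    out(i, 1) = faces[i] + 1; // 1-based for R
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_segment_mesh_distance")]]
double cpp_segment_mesh_distance(NumericVector p0v, NumericVector p1v,
                                 NumericMatrix V, IntegerMatrix F) {
  const Vec3 p0{p0v[0], p0v[1], p0v[2]};
  const Vec3 p1{p1v[0], p1v[1], p1v[2]};
  double best = std::numeric_limits<double>::infinity();
  const int m = F.nrow();
  for (int i = 0; i < m; ++i) {
    const double d = segment_triangle_distance_impl(
        p0, p1, v3(V, F(i, 0) - 1), v3(V, F(i, 1) - 1), v3(V, F(i, 2) - 1));
    if (d < best) best = d;
    if (best == 0.0) break;
  }
  return best;
}

// For each row of A, index (1-based) of the nearest row of B and the
// distance. Brute force; adequate at planner scale.
// [[Rcpp::export(name = ".cpp_nearest_point")]]
List cpp_nearest_point(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = NA_INTEGER;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j + 1; }
    }
    idx[i] = bj;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
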