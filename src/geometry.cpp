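#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pt_seg_dist2(double px, double py, double pz, double ax,
                                  double ay, double az, double bx, double by,
                                  double bz) {
  double vx = bx - ax, vy = by - ay, vz = bz - az;
  double wx = px - ax, wy = py - ay, wz = pz - az;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double dx = px - (ax + t * vx), dy = py - (ay + t * vy),
         dz = pz - (az + t * vz);
  return dx * dx + dy * dy + dz * dz;
}

// Minimum distance from each point (rows of pts, um) to a polyline given as
// an ordered m x 3 matrix of vertices.
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_polyline(NumericMatrix pts, NumericMatrix poly) {
  int n = pts.nrow(), m = poly.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (m == 1) {
      double dx = px - poly(0, 0), dy = py - poly(0, 1), dz = pz - poly(0, 2);
      best = dx * dx + dy * dy + dz * dz;
    }
    for (int s = 0; s + 1 < m; ++s) {
      double d2 = pt_seg_dist2(px, py, pz, poly(s, 0), poly(s, 1), poly(s, 2),
                               poly(s + 1, 0), poly(s + 1, 1), poly(s + 1, 2));
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Nearest polyline id (1-based) and distance for each point; polylines are
// stacked in `verts` (k x 3) with `starts`/`ends` 1-based row ranges.
// [[Rcpp::export]]
List cpp_assign_points_to_polylines(NumericMatrix pts, NumericMatrix verts,
                                    IntegerVector starts, IntegerVector ends) {
  int n = pts.nrow(), ne = starts.size();
  IntegerVector which(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bw = 0;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int e = 0; e < ne; ++e) {
      int a = starts[e] - 1, b = ends[e] - 1;
      double loc = R_PosInf;
      if (a == b) {
        double dx = px - verts(a, 0), dy = py - verts(a, 1),
               dz = pz - verts(a, 2);
        loc = dx * dx + dy * dy + dz * dz;
      }
      for (int s = a; s < b; ++s) {
        double d2 =
            pt_seg_dist2(px, py, pz, verts(s, 0), verts(s, 1), verts(s, 2),
                         verts(s + 1, 0), verts(s + 1, 1), verts(s + 1, 2));
        if (d2 < loc) loc = d2;
      }
      if (loc < best) {
        best = loc;
        bw = e + 1;
      }
    }
    which[i] = bw;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["edge"] = which, _["dist"] = dist);
}

static inline double clamp01(double t) {
  return t < 0 ? 0 : (t > 1 ? 1 : t);
}

// Minimum distance between two 3D segments (robust standard algorithm).
static double seg_seg_dist(const double *p1, const double *q1,
                           const double *p2, const double *q2) {
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = q1[i] - p1[i];
    d2[i] = q2[i] - p2[i];
    r[i] = p1[i] - p2[i];
  }
  double a = d1[0]*d1[0]+d1[1]*d1[1]+d1[2]*d1[2];
  double e = d2[0]*d2[0]+d2[1]*d2[1]+d2[2]*d2[2];
  double f = d2[0]*r[0]+d2[1]*r[1]+d2[2]*r[2];
  double s, t;
  if (a <= 1e-300 && e <= 1e-300) { s = t = 0; }
  else if (a <= 1e-300) { s = 0; t = clamp01(f / e); }
  else {
    double c = d1[0]*r[0]+d1[1]*r[1]+d1[2]*r[2];
    if (e <= 1e-300) { t = 0; s = clamp01(-c / a); }
    else {
      double b = d1[0]*d2[0]+d1[1]*d2[1]+d1[2]*d2[2];
      double denom = a * e - b * b;
      s = denom > 1e-300 ? clamp01((b * f - c * e) / denom) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = clamp01(-c / a); }
      else if (t > 1) { t = 1; s = clamp01((b - c) / a); }
    }
  }
  double c1[3], c2[3];
  for (int i = 0; i < 3; ++i) {
    c1[i] = p1[i] + s * d1[i];
    c2[i] = p2[i] + t * d2[i];
  }
  double dx = c1[0]-c2[0], dy = c1[1]-c2[1], dz = c1[2]-c2[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// Pairwise distances between segments; S is n x 6 (x1,y1,z1,x2,y2,z2).
// [[Rcpp::export]]
NumericMatrix cpp_segseg_dist(NumericMatrix S) {
  int n = S.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    double p1[3] = {S(i,0), S(i,1), S(i,2)}, q1[3] = {S(i,3), S(i,4), S(i,5)};
    for (int j = i; j < n; ++j) {
      double p2[3] = {S(j,0), S(j,1), S(j,2)},
             q2[3] = {S(j,3), S(j,4), S(j,5)};
      double d = (i == j) ? 0.0 : seg_seg_dist(p1, q1, p2, q2);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// Rasterize tube segments into a voxel mask. segs: n x 7
// (x1,y1,z1,x2,y2,z2,radius) in um; voxel (i,j,k) center at
// ((i-0.5)*sx, (j-0.5)*sy, (k-0.5)*sz), i = 1..nx.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tubes(NumericMatrix segs, IntegerVector dim,
                                  NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r = segs(s, 6);
    double r2 = r * r;
    int i0 = (int)std::floor((std::min(ax, bx) - r) / sx - 0.5);
    int i1 = (int)std::ceil((std::max(ax, bx) + r) / sx + 0.5);
    int j0 = (int)std::floor((std::min(ay, by) - r) / sy - 0.5);
    int j1 = (int)std::ceil((std::max(ay, by) + r) / sy + 0.5);
    int k0 = (int)std::floor((std::min(az, bz) - r) / sz - 0.5);
    int k1 = (int)std::ceil((std::max(az, bz) + r) / sz + 0.5);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      double pz = (k + 0.5) * sz;
      for (int j = j0; j <= j1; ++j) {
        double py = (j + 0.5) * sy;
        for (int i = i0; i <= i1; ++i) {
          double px = (i + 0.5) * sx;
          if (pt_seg_dist2(px, py, pz, ax, ay, az, bx, by, bz) <= r2)
            out[i + (size_t)nx * (j + (size_t)ny * k)] = true;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
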