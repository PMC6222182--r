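// Rasterization of capsule (cylinder-with-round-caps) branches into a label
// grid: 0 background, 1 airway wall, 2 lumen. Lumen always wins over wall so
// one branch's wall never occludes another's lumen at bifurcations.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_rasterize_tubes(IntegerVector dims, NumericVector spacing,
                                  NumericVector origin, NumericMatrix seg) {
  // seg columns: x0 y0 z0 x1 y1 z1 radius wall_thickness
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const long sy = nx, sz = (long)nx * ny;
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];

  for (int b = 0; b < seg.nrow(); ++b) {
    double x0 = seg(b, 0), y0 = seg(b, 1), z0 = seg(b, 2);
    double x1 = seg(b, 3), y1 = seg(b, 4), z1 = seg(b, 5);
    double r = seg(b, 6), wall = seg(b, 7);
    double rw = r + wall;
    double ax = x1 - x0, ay = y1 - y0, az = z1 - z0;
    double len2 = ax * ax + ay * ay + az * az;

    int i0 = std::max(0, (int)std::floor((std::min(x0, x1) - rw - origin[0]) / dx));
    int i1 = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + rw - origin[0]) / dx));
    int j0 = std::max(0, (int)std::floor((std::min(y0, y1) - rw - origin[1]) / dy));
    int j1 = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + rw - origin[1]) / dy));
    int k0 = std::max(0, (int)std::floor((std::min(z0, z1) - rw - origin[2]) / dz));
    int k1 = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + rw - origin[2]) / dz));

    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + k * dz;
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + j * dy;
        for (int i = i0; i <= i1; ++i) {
          double px = origin[0] + i * dx;
          double wx = px - x0, wy = py - y0, wz = pz - z0;
          double t = len2 > 0 ? (wx * ax + wy * ay + wz * az) / len2 : 0.0;
          if (t < 0) t = 0; if (t > 1) t = 1;
          double qx = wx - t * ax, qy = wy - t * ay, qz = wz - t * az;
          double d2 = qx * qx + qy * qy + qz * qz;
          long p = i + (long)j * sy + (long)k * sz;
          if (d2 <= r * r) lab[p] = 2;
          else if (d2 <= rw * rw && lab[p] < 1) lab[p] = 1;
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Minimum distance from each query point to a set of 3D segments (rows of
// seg: x0 y0 z0 x1 y1 z1). Used for centerline accuracy scoring.
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_segments(NumericMatrix pts, NumericMatrix seg) {
  int np = pts.nrow(), ns = seg.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double best = R_PosInf;
    for (int b = 0; b < ns; ++b) {
      double x0 = seg(b, 0), y0 = seg(b, 1), z0 = seg(b, 2);
      double ax = seg(b, 3) - x0, ay = seg(b, 4) - y0, az = seg(b, 5) - z0;
      double len2 = ax * ax + ay * ay + az * az;
      double wx = px - x0, wy = py - y0, wz = pz - z0;
      double t = len2 > 0 ? (wx * ax + wy * ay + wz * az) / len2 : 0.0;
      if (t < 0) t = 0; if (t > 1) t = 1;
      double qx = wx - t * ax, qy = wy - t * ay, qz = wz - t * az;
      double d2 = qx * qx + qy * qy + qz * qz;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
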