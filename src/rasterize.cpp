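// Voxelization of phantom vessel centerlines as (optionally elliptical)
// capsule tubes. A voxel belongs to the solid tube union when its scaled
// radial distance to some segment is <= the outer radius, and to the lumen
// when it is inside the wall by more than wall_thickness; the rendered
// "stain" is solid minus lumen, which keeps junction interiors clean.
//
// Segment matrix columns: x1 y1 z1 x2 y2 z2 r_outer wall e1x e1y e1z flat
// (e1 = flattening axis, unit, perpendicular to the segment; flat >= 1
// shrinks the cross-section to minor radius r/flat along e1; p1 == p2
// gives a sphere, used for isolated cells).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_rasterize_tubes(NumericMatrix segs, int nz, int ny, int nx,
                         double sz, double sy, double sx) {
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector solid(n), lumen(n);
  int* S = INTEGER(solid);
  int* L = INTEGER(lumen);
  for (int s = 0; s < segs.nrow(); ++s) {
    const double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
    const double x2 = segs(s, 3), y2 = segs(s, 4), z2 = segs(s, 5);
    const double r = segs(s, 6), wall = segs(s, 7);
    const double e1x = segs(s, 8), e1y = segs(s, 9), e1z = segs(s, 10);
    const double flat = segs(s, 11);
    const double rin = r - wall;
    const double ux = x2 - x1, uy = y2 - y1, uz = z2 - z1;
    const double L2 = ux * ux + uy * uy + uz * uz;
    const double bx0 = std::min(x1, x2) - r, bx1 = std::max(x1, x2) + r;
    const double by0 = std::min(y1, y2) - r, by1 = std::max(y1, y2) + r;
    const double bz0 = std::min(z1, z2) - r, bz1 = std::max(z1, z2) + r;
    const int i0 = std::max(0, (int)std::floor(bx0 / sx));
    const int i1 = std::min(nx - 1, (int)std::ceil(bx1 / sx));
    const int j0 = std::max(0, (int)std::floor(by0 / sy));
    const int j1 = std::min(ny - 1, (int)std::ceil(by1 / sy));
    const int k0 = std::max(0, (int)std::floor(bz0 / sz));
    const int k1 = std::min(nz - 1, (int)std::ceil(bz1 / sz));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k) {
          const double qx = i * sx, qy = j * sy, qz = k * sz;
          double wx = qx - x1, wy = qy - y1, wz = qz - z1;
          if (L2 > 0) {
            double a = (wx * ux + wy * uy + wz * uz) / L2;
            a = std::max(0.0, std::min(1.0, a));
            wx -= a * ux; wy -= a * uy; wz -= a * uz;
          }
          const double f1 = wx * e1x + wy * e1y + wz * e1z;
          const double rest2 =
              std::max(0.0, wx * wx + wy * wy + wz * wz - f1 * f1);
          const double rho = std::sqrt(f1 * f1 * flat * flat + rest2);
          if (rho <= r) {
            const R_xlen_t idx = k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
            S[idx] = 255;
            if (rin > 0 && rho < rin) L[idx] = 255;
          }
        }
  }
  solid.attr("dim") = IntegerVector::create(nz, ny, nx);
  lumen.attr("dim") = IntegerVector::create(nz, ny, nx);
  return List::create(Named("solid") = solid, Named("lumen") = lumen);
}

// For each query point: index (1-based) of the nearest segment and the
// distance to it (unscaled euclidean distance to the capsule axis).
// [[Rcpp::export]]
List cpp_nearest_segment(NumericMatrix pts, NumericMatrix segs) {
  const int np = pts.nrow(), ns = segs.nrow();
  IntegerVector idx(np);
  NumericVector dist(np);
  for (int p = 0; p < np; ++p) {
    const double qx = pts(p, 0), qy = pts(p, 1), qz = pts(p, 2);
    double best = R_PosInf;
    int bi = NA_INTEGER;
    for (int s = 0; s < ns; ++s) {
      const double x1 = segs(s, 0), y1 = segs(s, 1), z1 = segs(s, 2);
      const double ux = segs(s, 3) - x1, uy = segs(s, 4) - y1, uz = segs(s, 5) - z1;
      double wx = qx - x1, wy = qy - y1, wz = qz - z1;
      const double L2 = ux * ux + uy * uy + uz * uz;
      if (L2 > 0) {
        double a = (wx * ux + wy * uy + wz * uz) / L2;
        a = std::max(0.0, std::min(1.0, a));
        wx -= a * ux; wy -= a * uy; wz -= a * uz;
      }
      const double d = wx * wx + wy * wy + wz * wz;
      if (d < best) { best = d; bi = s + 1; }
    }
    idx[p] = bi;
    dist[p] = std::sqrt(best);
  }
  return List::create(Named("index") = idx, Named("distance") = dist);
}
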