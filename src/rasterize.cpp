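#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Rasterize capsules (radius-r tubes with spherical caps around line segments)
// into a voxel grid. Physical coordinate of voxel (i,j,k), 0-based, is
// (i*sx, j*sy, k*sz). segs is an n x 7 matrix: x1 y1 z1 x2 y2 z2 r (mm).
//' @noRd
// [[Rcpp::export(name = ".rasterize_capsules_cpp")]]
LogicalVector rasterize_capsules_cpp(IntegerVector dim, NumericVector spacing,
                                     NumericMatrix segs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);

  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r = segs(s, 6);
    if (r <= 0) continue;
    double r2 = r * r;
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double len2 = ux * ux + uy * uy + uz * uz;

    int i0 = std::max(0, (int)std::floor((std::min(ax, bx) - r) / sx));
    int i1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + r) / sx));
    int j0 = std::max(0, (int)std::floor((std::min(ay, by) - r) / sy));
    int j1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + r) / sy));
    int k0 = std::max(0, (int)std::floor((std::min(az, bz) - r) / sz));
    int k1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + r) / sz));

    for (int k = k0; k <= k1; ++k) {
      double pz = k * sz;
      for (int j = j0; j <= j1; ++j) {
        double py = j * sy;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          double px = i * sx;
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = 0.0;
          if (len2 > 0) {
            t = (wx * ux + wy * uy + wz * uz) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double dx = wx - t * ux, dy = wy - t * uy, dz = wz - t * uz;
          if (dx * dx + dy * dy + dz * dz <= r2) out[base + i] = TRUE;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
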