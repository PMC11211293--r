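#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform.
// f holds squared distances sampled at x = i * s; overwritten with the result.
// Large finite stand-in for infinity keeps the parabola intersections
// finite on empty scan lines (true Inf would produce NaN arithmetic).
static const double BIG = 1e20;

static void dt1d(std::vector<double> &f, int n, double s,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sden = 2.0 * (xq - xv);
      double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / sden;
      if (sint <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sint;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

//' @noRd
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = f[k];
    }
  out.attr("dim") = dim;
  return out;
}
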