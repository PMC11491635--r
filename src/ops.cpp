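// Low-level 3D image / vector-field operations.
// Conventions: volumes are R arrays dim (nx,ny,nz), column-major; vector
// fields are dim (nx,ny,nz,3) in voxel units, 0-based index space.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Trilinear sample of a scalar volume at continuous 0-based (px,py,pz).
// mode 0: out-of-bounds -> background; mode 1: clamp to border.
static double sample_tri(const double* v, int nx, int ny, int nz,
                         double px, double py, double pz,
                         int mode, double background) {
  if (mode == 0) {
    if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 || pz > nz - 1)
      return background;
  } else {
    px = std::min(std::max(px, 0.0), (double)(nx - 1));
    py = std::min(std::max(py, 0.0), (double)(ny - 1));
    pz = std::min(std::max(pz, 0.0), (double)(nz - 1));
  }
  int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  double fx = px - x0, fy = py - y0, fz = pz - z0;
  double c000 = v[idx3(x0,y0,z0,nx,ny)], c100 = v[idx3(x1,y0,z0,nx,ny)];
  double c010 = v[idx3(x0,y1,z0,nx,ny)], c110 = v[idx3(x1,y1,z0,nx,ny)];
  double c001 = v[idx3(x0,y0,z1,nx,ny)], c101 = v[idx3(x1,y0,z1,nx,ny)];
  double c011 = v[idx3(x0,y1,z1,nx,ny)], c111 = v[idx3(x1,y1,z1,nx,ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_warp_volume(NumericVector vol, NumericVector disp,
                              double background) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(vol.size());
  out.attr("dim") = d;
  const double* v = vol.begin();
  const double* dp = disp.begin();
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        double px = x + dp[i], py = y + dp[i + n], pz = z + dp[i + 2 * n];
        out[i] = sample_tri(v, nx, ny, nz, px, py, pz, 0, background);
      }
  return out;
}

// Composition of displacement fields: apply a first, then b.
// (b o a)(x) = a(x) + b(x + a(x)); b sampled with border clamp.
// [[Rcpp::export]]
NumericVector cpp_compose_disp(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(a.size());
  out.attr("dim") = d;
  const double* pa = a.begin();
  const double* pb = b.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        double px = x + pa[i], py = y + pa[i + n], pz = z + pa[i + 2 * n];
        for (int c = 0; c < 3; ++c)
          out[i + c * n] = pa[i + c * n] +
            sample_tri(pb + c * n, nx, ny, nz, px, py, pz, 1, 0.0);
      }
  return out;
}

// Separable Gaussian smoothing, zero boundary, kernel truncated at 4 sigma.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  if (sigma <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& w : k) w /= s;
  NumericVector a = clone(vol), b(vol.size());
  b.attr("dim") = d;
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  double* src = a.begin();
  double* dst = b.begin();
  for (int ax = 0; ax < 3; ++ax) {
    R_xlen_t st = strides[ax];
    int len = dims[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int pos[3] = {x, y, z};
          R_xlen_t i = idx3(x, y, z, nx, ny);
          double acc = 0;
          int p = pos[ax];
          int lo = std::max(-r, -p), hi = std::min(r, len - 1 - p);
          for (int o = lo; o <= hi; ++o) acc += k[o + r] * src[i + (R_xlen_t)o * st];
          dst[i] = acc;
        }
    std::swap(src, dst);
  }
  // after the final swap 'src' points at the buffer holding the result
  return (src == a.begin()) ? a : b;
}

// Jacobian determinant of phi(x) = x + disp(x), central differences in the
// interior, one-sided at the boundary.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector disp) {
  IntegerVector d = disp.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* p = disp.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double J[3][3];
        int pos[3] = {x, y, z};
        int dims[3] = {nx, ny, nz};
        R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
        R_xlen_t i = idx3(x, y, z, nx, ny);
        for (int c = 0; c < 3; ++c) {     // component
          for (int ax = 0; ax < 3; ++ax) { // derivative axis
            int pm = pos[ax];
            double num, den;
            if (pm > 0 && pm < dims[ax] - 1) {
              num = p[i + strides[ax] + c * n] - p[i - strides[ax] + c * n];
              den = 2.0;
            } else if (pm == 0) {
              num = p[i + strides[ax] + c * n] - p[i + c * n];
              den = 1.0;
            } else {
              num = p[i + c * n] - p[i - strides[ax] + c * n];
              den = 1.0;
            }
            J[c][ax] = num / den + (c == ax ? 1.0 : 0.0);
          }
        }
        out[i] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
               - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
               + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// Chebyshev (box) binary dilation by radius r via separable max filter.
// [[Rcpp::export]]
NumericVector cpp_dilate(NumericVector mask, int r) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector a = clone(mask), b(mask.size());
  b.attr("dim") = d;
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  double* src = a.begin();
  double* dst = b.begin();
  for (int ax = 0; ax < 3; ++ax) {
    R_xlen_t st = strides[ax];
    int len = dims[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int pos[3] = {x, y, z};
          R_xlen_t i = idx3(x, y, z, nx, ny);
          int p = pos[ax];
          int lo = std::max(-r, -p), hi = std::min(r, len - 1 - p);
          double m = 0;
          for (int o = lo; o <= hi; ++o) m = std::max(m, src[i + (R_xlen_t)o * st]);
          dst[i] = m;
        }
    std::swap(src, dst);
  }
  return (src == a.begin()) ? a : b;
}
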