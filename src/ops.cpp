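// 3x3x3 convolution primitives for the segmentation network.
//
// Volumes are stored as (n_voxel x n_channel) matrices; voxels are ordered
// column-major over the grid (x fastest), matching R's array(dim = c(nx, ny,
// nz)) flattening. im2col3 gathers the 27 zero-padded neighbour shifts into a
// wide matrix so that convolution forward/backward are plain BLAS gemms on
// the R side; col2im3 is its adjoint (scatter-add). Every output entry is
// written exactly once (valid runs memcpy'd, padding memset to zero), so no
// separate zero-initialization pass is needed.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& X, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != X.nrow()) stop("im2col3: dims do not match number of rows");
  const int nc = X.ncol();
  NumericMatrix out(Rf_allocMatrix(REALSXP, X.nrow(), 27 * nc));
  const double* xp = REAL(X);
  double* op = REAL(out);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        const int len = x1 - x0;
        for (int c = 0; c < nc; ++c) {
          const double* src = xp + (R_xlen_t)c * n;
          double* dst = op + ((R_xlen_t)k * nc + c) * n;
          for (int z = 0; z < nz; ++z) {
            const int zs = z + dz;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              double* d = dst + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
              if (zs < 0 || zs >= nz || ys < 0 || ys >= ny || len <= 0) {
                std::memset(d, 0, sizeof(double) * nx);
                continue;
              }
              if (x0 > 0) std::memset(d, 0, sizeof(double) * x0);
              std::memcpy(d + x0,
                          src + (R_xlen_t)(x0 + dx)
                            + (R_xlen_t)nx * (ys + (R_xlen_t)ny * zs),
                          sizeof(double) * len);
              if (x1 < nx) std::memset(d + x1, 0, sizeof(double) * (nx - x1));
            }
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& G, IntegerVector dims,
                      int n_channels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (n != G.nrow()) stop("col2im3: dims do not match number of rows");
  if (G.ncol() != 27 * n_channels)
    stop("col2im3: column count must be 27 * n_channels");
  NumericMatrix dX(Rf_allocMatrix(REALSXP, n, n_channels));
  std::memset(REAL(dX), 0, sizeof(double) * n * n_channels);
  const double* gp = REAL(G);
  double* dp = REAL(dX);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        const int len = x1 - x0;
        if (len <= 0) continue;
        for (int c = 0; c < n_channels; ++c) {
          const double* src = gp + ((R_xlen_t)k * n_channels + c) * n;
          double* dst = dp + (R_xlen_t)c * n;
          for (int z = 0; z < nz; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= ny) continue;
              const double* s = src + (R_xlen_t)x0
                + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
              double* d = dst + (R_xlen_t)(x0 + dx)
                + (R_xlen_t)nx * (ys + (R_xlen_t)ny * zs);
              for (int i = 0; i < len; ++i) d[i] += s[i];
            }
          }
        }
      }
  return dX;
}
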