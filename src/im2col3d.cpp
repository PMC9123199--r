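#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction / scattering for strided 3D convolution.
//
// Volumes are R arrays with dims (X, Y, Z, C) in column-major order.
// im2col_3d unrolls every kernel window into one column of a
// (k^3 * C) x (ox * oy * oz) matrix; rows vary kx fastest, then ky, kz,
// then channel; columns vary ox fastest. col2im_3d is its exact adjoint
// (scatter-add), which makes <im2col(x), M> == <x, col2im(M)> and gives the
// gradient of the convolution for free.

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_3d(NumericVector x, IntegerVector dims,
                        int k, int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int ox = out_size(X, k, stride, pad);
  const int oy = out_size(Y, k, stride, pad);
  const int oz = out_size(Z, k, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1)
    stop("kernel does not fit input: output size would be non-positive");
  const int P = ox * oy * oz;
  const int R = k * k * k * C;
  NumericMatrix cols(R, P);
  const double *xp = x.begin();
  double *cp = cols.begin();

  for (int iz = 0; iz < oz; ++iz) {
    for (int iy = 0; iy < oy; ++iy) {
      for (int ix = 0; ix < ox; ++ix) {
        const int col = ix + ox * (iy + oy * iz);
        double *dst = cp + (R_xlen_t)col * R;
        for (int c = 0; c < C; ++c) {
          for (int kz = 0; kz < k; ++kz) {
            const int zz = iz * stride - pad + kz;
            for (int ky = 0; ky < k; ++ky) {
              const int yy = iy * stride - pad + ky;
              for (int kx = 0; kx < k; ++kx) {
                const int xx = ix * stride - pad + kx;
                const int r = kx + k * (ky + k * (kz + k * c));
                if (xx >= 0 && xx < X && yy >= 0 && yy < Y &&
                    zz >= 0 && zz < Z) {
                  dst[r] = xp[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y *
                              (zz + (R_xlen_t)Z * c))];
                } else {
                  dst[r] = 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_3d(NumericMatrix cols, IntegerVector dims,
                        int k, int stride, int pad) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int ox = out_size(X, k, stride, pad);
  const int oy = out_size(Y, k, stride, pad);
  const int oz = out_size(Z, k, stride, pad);
  const int R = k * k * k * C;
  if (cols.nrow() != R || cols.ncol() != ox * oy * oz)
    stop("col2im_3d: matrix shape inconsistent with dims/kernel/stride/pad");
  NumericVector out((R_xlen_t)X * Y * Z * C);
  double *op = out.begin();
  const double *cp = cols.begin();

  for (int iz = 0; iz < oz; ++iz) {
    for (int iy = 0; iy < oy; ++iy) {
      for (int ix = 0; ix < ox; ++ix) {
        const int col = ix + ox * (iy + oy * iz);
        const double *src = cp + (R_xlen_t)col * R;
        for (int c = 0; c < C; ++c) {
          for (int kz = 0; kz < k; ++kz) {
            const int zz = iz * stride - pad + kz;
            if (zz < 0 || zz >= Z) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int yy = iy * stride - pad + ky;
              if (yy < 0 || yy >= Y) continue;
              for (int kx = 0; kx < k; ++kx) {
                const int xx = ix * stride - pad + kx;
                if (xx < 0 || xx >= X) continue;
                const int r = kx + k * (ky + k * (kz + k * c));
                op[xx + (R_xlen_t)X * (yy + (R_xlen_t)Y *
                   (zz + (R_xlen_t)Z * c))] += src[r];
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
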