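// Volumetric (3D) convolution primitives for the CPU network engine.
//
// Array layout follows R column-major convention: a volume with R dim
// c(d1, d2, d3, C) is addressed as x[i + d1*(j + d2*(k + d3*c))].
// Weights arrive as a matrix with rows indexed by (ki, kj, kk, cin) in
// column-major order (i.e. the flattening of an R array with dim
// c(k1, k2, k3, Cin)) and one column per output channel, so that the
// convolution is an im2col gather followed by a single BLAS matmul.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Gather the im2col matrix: one row per output voxel, one column per
// (kernel offset, input channel) pair. Out-of-range taps read zero.
static arma::mat im2col3d(const arma::vec& x, const IntegerVector& xdim,
                          const IntegerVector& kdim, const IntegerVector& stride,
                          const IntegerVector& pad) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], cin = xdim[3];
  const int k1 = kdim[0], k2 = kdim[1], k3 = kdim[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = out_extent(d1, k1, s1, p1);
  const int o2 = out_extent(d2, k2, s2, p2);
  const int o3 = out_extent(d3, k3, s3, p3);
  const int nout = o1 * o2 * o3;

  arma::mat cols(nout, (arma::uword)(k1 * k2 * k3 * cin), arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x.memptr() + (size_t)c * d1 * d2 * d3;
    for (int kk = 0; kk < k3; ++kk) {
      for (int kj = 0; kj < k2; ++kj) {
        for (int ki = 0; ki < k1; ++ki) {
          const int col = ki + k1 * (kj + k2 * (kk + k3 * c));
          double* dst = cols.colptr(col);
          for (int ok = 0; ok < o3; ++ok) {
            const int iz = ok * s3 - p3 + kk;
            if (iz < 0 || iz >= d3) continue;
            for (int oj = 0; oj < o2; ++oj) {
              const int iy = oj * s2 - p2 + kj;
              if (iy < 0 || iy >= d2) continue;
              const int ix0 = -p1 + ki;
              const size_t src_base = (size_t)iz * d1 * d2 + (size_t)iy * d1;
              const size_t dst_base = (size_t)ok * o1 * o2 + (size_t)oj * o1;
              for (int oi = 0; oi < o1; ++oi) {
                const int ix = oi * s1 + ix0;
                if (ix < 0 || ix >= d1) continue;
                dst[dst_base + oi] = xc[src_base + ix];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add transpose of im2col3d: accumulate column gradients back
// onto the (padded-cropped) input grid.
static arma::vec col2im3d(const arma::mat& cols, const IntegerVector& xdim,
                          const IntegerVector& kdim, const IntegerVector& stride,
                          const IntegerVector& pad) {
  const int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], cin = xdim[3];
  const int k1 = kdim[0], k2 = kdim[1], k3 = kdim[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = out_extent(d1, k1, s1, p1);
  const int o2 = out_extent(d2, k2, s2, p2);
  const int o3 = out_extent(d3, k3, s3, p3);

  arma::vec dx((arma::uword)d1 * d2 * d3 * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    double* xc = dx.memptr() + (size_t)c * d1 * d2 * d3;
    for (int kk = 0; kk < k3; ++kk) {
      for (int kj = 0; kj < k2; ++kj) {
        for (int ki = 0; ki < k1; ++ki) {
          const int col = ki + k1 * (kj + k2 * (kk + k3 * c));
          const double* src = cols.colptr(col);
          for (int ok = 0; ok < o3; ++ok) {
            const int iz = ok * s3 - p3 + kk;
            if (iz < 0 || iz >= d3) continue;
            for (int oj = 0; oj < o2; ++oj) {
              const int iy = oj * s2 - p2 + kj;
              if (iy < 0 || iy >= d2) continue;
              const int ix0 = -p1 + ki;
              const size_t src_base = (size_t)ok * o1 * o2 + (size_t)oj * o1;
              const size_t dst_base = (size_t)iz * d1 * d2 + (size_t)iy * d1;
              for (int oi = 0; oi < o1; ++oi) {
                const int ix = oi * s1 + ix0;
                if (ix < 0 || ix >= d1) continue;
                xc[dst_base + ix] += src[src_base + oi];
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
List cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                        NumericMatrix w, NumericVector b,
                        IntegerVector kdim, IntegerVector stride,
                        IntegerVector pad, bool return_cols) {
  const arma::vec xv(x.begin(), x.size(), false);
  const arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat cols = im2col3d(xv, xdim, kdim, stride, pad);
  arma::mat y = cols * wm;
  y.each_row() += arma::rowvec(b.begin(), b.size(), false);
  const int o1 = out_extent(xdim[0], kdim[0], stride[0], pad[0]);
  const int o2 = out_extent(xdim[1], kdim[1], stride[1], pad[1]);
  const int o3 = out_extent(xdim[2], kdim[2], stride[2], pad[2]);
  NumericVector yv(y.begin(), y.end());
  yv.attr("dim") = IntegerVector::create(o1, o2, o3, (int)wm.n_cols);
  List out = List::create(_["y"] = yv);
  if (return_cols)
    out["cols"] = NumericMatrix(cols.n_rows, cols.n_cols, cols.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, NumericVector dy,
                         IntegerVector kdim, IntegerVector stride,
                         IntegerVector pad, bool need_dx,
                         Nullable<NumericMatrix> cached_cols = R_NilValue) {
  const arma::vec xv(x.begin(), x.size(), false);
  const arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  const int o1 = out_extent(xdim[0], kdim[0], stride[0], pad[0]);
  const int o2 = out_extent(xdim[1], kdim[1], stride[1], pad[1]);
  const int o3 = out_extent(xdim[2], kdim[2], stride[2], pad[2]);
  const int nout = o1 * o2 * o3;
  const arma::mat dym(const_cast<double*>(dy.begin()), nout, wm.n_cols, false);

  arma::mat cols;
  if (cached_cols.isNotNull()) {
    NumericMatrix cc(cached_cols);
    cols = arma::mat(cc.begin(), cc.nrow(), cc.ncol(), false);
  } else {
    cols = im2col3d(xv, xdim, kdim, stride, pad);
  }
  arma::mat dw = cols.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);

  List out = List::create(
    _["dw"] = NumericMatrix(dw.n_rows, dw.n_cols, dw.begin()),
    _["db"] = NumericVector(db.begin(), db.end()));
  if (need_dx) {
    arma::mat dcols = dym * wm.t();
    arma::vec dx = col2im3d(dcols, xdim, kdim, stride, pad);
    NumericVector dxv(dx.begin(), dx.end());
    dxv.attr("dim") = xdim;
    out["dx"] = dxv;
  }
  return out;
}
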