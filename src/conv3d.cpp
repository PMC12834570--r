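// 3D convolution primitives for the translation-regression network.
// Feature tensors are flat numeric vectors in column-major order with dims
// (d1, d2, d3, channels, batch). Weights are (c_out x c_in*k^3) matrices
// whose column index r encodes r = ci*k^3 + (kx + k*(ky + k*kz)).
// Forward/backward use an im2col buffer stored transposed (voxels x r) so
// the innermost loop writes contiguously, then GEMM via BLAS.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int d, int k, int stride, int pad) {
  return (d + 2 * pad - k) / stride + 1;
}

// colT: (o1*o2*o3) x (cin*k^3)
static void im2colT(const double* x, int d1, int d2, int d3, int cin,
                    int k, int stride, int pad,
                    int o1, int o2, int o3, arma::mat& colT) {
  const size_t vin = (size_t)d1 * d2 * d3;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + ci * vin;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          int r = ci * k * k * k + (kx + k * (ky + k * kz));
          double* dst = colT.colptr(r);
          for (int oz = 0; oz < o3; ++oz) {
            int iz = oz * stride - pad + kz;
            if (iz < 0 || iz >= d3) {
              for (int oy = 0; oy < o2; ++oy)
                for (int ox = 0; ox < o1; ++ox) *dst++ = 0.0;
              continue;
            }
            const double* xz = xc + (size_t)d1 * d2 * iz;
            for (int oy = 0; oy < o2; ++oy) {
              int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= d2) {
                for (int ox = 0; ox < o1; ++ox) *dst++ = 0.0;
                continue;
              }
              const double* xy = xz + (size_t)d1 * iy;
              int ix = -pad + kx;
              for (int ox = 0; ox < o1; ++ox, ix += stride)
                *dst++ = (ix >= 0 && ix < d1) ? xy[ix] : 0.0;
            }
          }
        }
  }
}

static void col2imT(const arma::mat& colT, int d1, int d2, int d3, int cin,
                    int k, int stride, int pad,
                    int o1, int o2, int o3, double* x) {
  const size_t vin = (size_t)d1 * d2 * d3;
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = x + ci * vin;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          int r = ci * k * k * k + (kx + k * (ky + k * kz));
          const double* src = colT.colptr(r);
          for (int oz = 0; oz < o3; ++oz) {
            int iz = oz * stride - pad + kz;
            if (iz < 0 || iz >= d3) { src += (size_t)o1 * o2; continue; }
            double* xz = xc + (size_t)d1 * d2 * iz;
            for (int oy = 0; oy < o2; ++oy) {
              int iy = oy * stride - pad + ky;
              if (iy < 0 || iy >= d2) { src += o1; continue; }
              double* xy = xz + (size_t)d1 * iy;
              int ix = -pad + kx;
              for (int ox = 0; ox < o1; ++ox, ix += stride, ++src)
                if (ix >= 0 && ix < d1) xy[ix] += *src;
            }
          }
        }
  }
}

// [[Rcpp::export]]
List conv3d_fwd_cpp(NumericVector x, IntegerVector xdim, arma::mat w,
                    NumericVector b, int k, int stride, int pad) {
  int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], cin = xdim[3], n = xdim[4];
  int o1 = out_len(d1, k, stride, pad);
  int o2 = out_len(d2, k, stride, pad);
  int o3 = out_len(d3, k, stride, pad);
  int cout = w.n_rows;
  size_t vin = (size_t)d1 * d2 * d3 * cin;
  size_t vout = (size_t)o1 * o2 * o3;
  NumericVector y(vout * cout * n);
  arma::mat colT(vout, (size_t)cin * k * k * k);
  arma::mat wt = w.t();                 // (cin*k3) x cout
  arma::rowvec bv(b.begin(), cout);
  for (int s = 0; s < n; ++s) {
    im2colT(x.begin() + s * vin, d1, d2, d3, cin, k, stride, pad,
            o1, o2, o3, colT);
    arma::mat Yt(y.begin() + s * vout * cout, vout, cout, false, true);
    Yt = colT * wt;                     // vout x cout, channel-major layout
    Yt.each_row() += bv;
  }
  IntegerVector odim = IntegerVector::create(o1, o2, o3, cout, n);
  return List::create(_["y"] = y, _["dim"] = odim);
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim, NumericVector dy,
                    arma::mat w, int k, int stride, int pad) {
  int d1 = xdim[0], d2 = xdim[1], d3 = xdim[2], cin = xdim[3], n = xdim[4];
  int o1 = out_len(d1, k, stride, pad);
  int o2 = out_len(d2, k, stride, pad);
  int o3 = out_len(d3, k, stride, pad);
  int cout = w.n_rows;
  size_t vin = (size_t)d1 * d2 * d3 * cin;
  size_t vout = (size_t)o1 * o2 * o3;
  size_t nr = (size_t)cin * k * k * k;
  NumericVector dx(vin * n);
  arma::mat dwT(nr, cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);
  arma::mat colT(vout, nr);
  for (int s = 0; s < n; ++s) {
    im2colT(x.begin() + s * vin, d1, d2, d3, cin, k, stride, pad,
            o1, o2, o3, colT);
    // dy sample s is stored (vout x cout) channel-major
    arma::mat dYt(const_cast<double*>(dy.begin()) + s * vout * cout,
                  vout, cout, false, true);
    dwT += colT.t() * dYt;
    db += arma::sum(dYt, 0);
    arma::mat dcolT = dYt * w;          // vout x (cin*k3)
    col2imT(dcolT, d1, d2, d3, cin, k, stride, pad, o1, o2, o3,
            dx.begin() + s * vin);
  }
  arma::mat dw = dwT.t();
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
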