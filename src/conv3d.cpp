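// 3D convolution kernels for the volumetric network.
//
// Array layout follows the R convention used throughout the package:
// feature volumes are column-major arrays of dim (D, H, W, C); convolution
// weights are 5-d arrays of dim (K, K, K, Cin, Cout), viewed here as a
// (K^3*Cin) x Cout matrix whose row index enumerates (kd, kh, kw, cin) with
// kd fastest -- exactly the column-major flattening of the first four
// dimensions. Forward/backward use im2col/col2im plus BLAS GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix column by column (one column per output voxel) so
// writes are contiguous; interior voxels take a bounds-check-free fast path.
static void im2col(const double* x, int D, int H, int W, int Cin,
                   int K, int stride, int pad, arma::mat& cols) {
  const int Do = conv_out_dim(D, K, stride, pad);
  const int Ho = conv_out_dim(H, K, stride, pad);
  const int Wo = conv_out_dim(W, K, stride, pad);
  const int N = Do * Ho * Wo;
  const size_t plane = (size_t)D * H;
  cols.set_size((size_t)K * K * K * Cin, N);
  double* cp = cols.memptr();
  for (int ow = 0; ow < Wo; ++ow) {
    const int w0 = ow * stride - pad;
    for (int oh = 0; oh < Ho; ++oh) {
      const int h0 = oh * stride - pad;
      for (int od = 0; od < Do; ++od) {
        const int d0 = od * stride - pad;
        double* col = cp + ((size_t)od + (size_t)Do * (oh + (size_t)Ho * ow)) *
                           cols.n_rows;
        const bool interior = d0 >= 0 && d0 + K <= D && h0 >= 0 &&
                              h0 + K <= H && w0 >= 0 && w0 + K <= W;
        size_t r = 0;
        if (interior) {
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = x + (size_t)ci * plane * W;
            for (int kw = 0; kw < K; ++kw) {
              const double* xw = xc + (size_t)(w0 + kw) * plane;
              for (int kh = 0; kh < K; ++kh) {
                const double* xh = xw + (size_t)(h0 + kh) * D + d0;
                for (int kd = 0; kd < K; ++kd) col[r++] = xh[kd];
              }
            }
          }
        } else {
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = x + (size_t)ci * plane * W;
            for (int kw = 0; kw < K; ++kw) {
              const int iw = w0 + kw;
              for (int kh = 0; kh < K; ++kh) {
                const int ih = h0 + kh;
                for (int kd = 0; kd < K; ++kd) {
                  const int id = d0 + kd;
                  col[r++] = (id >= 0 && id < D && ih >= 0 && ih < H &&
                              iw >= 0 && iw < W)
                    ? xc[id + (size_t)D * (ih + (size_t)H * iw)] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int D, int H, int W, int Cin,
                   int K, int stride, int pad, double* dx) {
  const int Do = conv_out_dim(D, K, stride, pad);
  const int Ho = conv_out_dim(H, K, stride, pad);
  const int Wo = conv_out_dim(W, K, stride, pad);
  const size_t plane = (size_t)D * H;
  std::fill(dx, dx + (size_t)D * H * W * Cin, 0.0);
  const double* cp = cols.memptr();
  for (int ow = 0; ow < Wo; ++ow) {
    const int w0 = ow * stride - pad;
    for (int oh = 0; oh < Ho; ++oh) {
      const int h0 = oh * stride - pad;
      for (int od = 0; od < Do; ++od) {
        const int d0 = od * stride - pad;
        const double* col = cp +
          ((size_t)od + (size_t)Do * (oh + (size_t)Ho * ow)) * cols.n_rows;
        const bool interior = d0 >= 0 && d0 + K <= D && h0 >= 0 &&
                              h0 + K <= H && w0 >= 0 && w0 + K <= W;
        size_t r = 0;
        if (interior) {
          for (int ci = 0; ci < Cin; ++ci) {
            double* xc = dx + (size_t)ci * plane * W;
            for (int kw = 0; kw < K; ++kw) {
              double* xw = xc + (size_t)(w0 + kw) * plane;
              for (int kh = 0; kh < K; ++kh) {
                double* xh = xw + (size_t)(h0 + kh) * D + d0;
                for (int kd = 0; kd < K; ++kd) xh[kd] += col[r++];
              }
            }
          }
        } else {
          for (int ci = 0; ci < Cin; ++ci) {
            double* xc = dx + (size_t)ci * plane * W;
            for (int kw = 0; kw < K; ++kw) {
              const int iw = w0 + kw;
              for (int kh = 0; kh < K; ++kh) {
                const int ih = h0 + kh;
                for (int kd = 0; kd < K; ++kd) {
                  const int id = d0 + kd;
                  if (id >= 0 && id < D && ih >= 0 && ih < H && iw >= 0 && iw < W)
                    xc[id + (size_t)D * (ih + (size_t)H * iw)] += col[r];
                  ++r;
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericMatrix w, NumericVector b,
                                 int K, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int Cout = w.ncol();
  if ((int)w.nrow() != K * K * K * Cin)
    stop("weight rows (%d) do not match K^3*Cin (%d)", (int)w.nrow(), K * K * K * Cin);
  const int Do = conv_out_dim(D, K, stride, pad);
  const int Ho = conv_out_dim(H, K, stride, pad);
  const int Wo = conv_out_dim(W, K, stride, pad);
  const arma::mat wm(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::mat out;
  if (K == 1 && stride == 1 && pad == 0) {
    // pointwise conv: the volume memory already is the (N x Cin) matrix
    const arma::mat xm(x.begin(), (size_t)D * H * W, Cin, false, true);
    out = xm * wm;
  } else {
    arma::mat cols;
    im2col(x.begin(), D, H, W, Cin, K, stride, pad, cols);
    out = cols.t() * wm;                  // N x Cout, voxel index d-fastest
  }
  for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return res;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, NumericVector dy,
                         int K, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int Cout = w.ncol();
  const int Do = conv_out_dim(D, K, stride, pad);
  const int Ho = conv_out_dim(H, K, stride, pad);
  const int Wo = conv_out_dim(W, K, stride, pad);
  const size_t N = (size_t)Do * Ho * Wo;
  const arma::mat dym(dy.begin(), N, Cout, false, true);
  const arma::mat wm(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::rowvec db = arma::sum(dym, 0);
  arma::mat dw;
  NumericVector dx((size_t)D * H * W * Cin);
  if (K == 1 && stride == 1 && pad == 0) {
    const arma::mat xm(x.begin(), N, Cin, false, true);
    dw = xm.t() * dym;
    arma::mat dxm(dx.begin(), N, Cin, false, true);
    dxm = dym * wm.t();
  } else {
    arma::mat cols;
    im2col(x.begin(), D, H, W, Cin, K, stride, pad, cols);
    dw = cols * dym;                      // (K^3*Cin) x Cout
    arma::mat dcols = wm * dym.t();       // (K^3*Cin) x N
    col2im(dcols, D, H, W, Cin, K, stride, pad, dx.begin());
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, Cin);

  NumericMatrix dwr(dw.n_rows, dw.n_cols);
  std::copy(dw.begin(), dw.end(), dwr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Transposed convolution with kernel 2 and stride 2 (the upsampling operator):
// every output voxel is written by exactly one input voxel, so it reduces to a
// GEMM plus a deterministic scatter. Weights: dim (2,2,2,Cin,Cout) flattened
// to an (8*Cin) x Cout matrix with the same row enumeration as above.

// [[Rcpp::export(name = ".upconv2_forward")]]
NumericVector upconv2_forward_cpp(NumericVector x, IntegerVector xdim,
                                  NumericMatrix w, NumericVector b) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int Cout = w.ncol();
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Do * Ho * Wo * Cout);
  double* o = out.begin();
  const double* xp = x.begin();
  for (int co = 0; co < Cout; ++co) {
    double* oc = o + (size_t)co * Do * Ho * Wo;
    const size_t nvox = (size_t)Do * Ho * Wo;
    for (size_t i = 0; i < nvox; ++i) oc[i] = b[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (size_t)ci * D * H * W;
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          for (int kd = 0; kd < 2; ++kd) {
            const double wv = w(kd + 2 * (kh + 2 * (kw + 2 * ci)), co);
            if (wv == 0.0) continue;
            for (int iw = 0; iw < W; ++iw)
              for (int ih = 0; ih < H; ++ih)
                for (int id = 0; id < D; ++id) {
                  const size_t oi = (2 * id + kd) +
                    (size_t)Do * ((2 * ih + kh) + (size_t)Ho * (2 * iw + kw));
                  oc[oi] += wv * xc[id + (size_t)D * (ih + (size_t)H * iw)];
                }
          }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".upconv2_backward")]]
List upconv2_backward_cpp(NumericVector x, IntegerVector xdim,
                          NumericMatrix w, NumericVector dy) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int Cout = w.ncol();
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)D * H * W * Cin);
  NumericMatrix dw(8 * Cin, Cout);
  NumericVector db(Cout);
  const double* dyp = dy.begin();
  const double* xp = x.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dyp + (size_t)co * Do * Ho * Wo;
    double acc = 0.0;
    const size_t nvox = (size_t)Do * Ho * Wo;
    for (size_t i = 0; i < nvox; ++i) acc += dyc[i];
    db[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (size_t)ci * D * H * W;
      double* dxc = dx.begin() + (size_t)ci * D * H * W;
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          for (int kd = 0; kd < 2; ++kd) {
            const int r = kd + 2 * (kh + 2 * (kw + 2 * ci));
            const double wv = w(r, co);
            double dwacc = 0.0;
            for (int iw = 0; iw < W; ++iw)
              for (int ih = 0; ih < H; ++ih)
                for (int id = 0; id < D; ++id) {
                  const size_t oi = (2 * id + kd) +
                    (size_t)Do * ((2 * ih + kh) + (size_t)Ho * (2 * iw + kw));
                  const double g = dyc[oi];
                  dwacc += g * xc[id + (size_t)D * (ih + (size_t)H * iw)];
                  dxc[id + (size_t)D * (ih + (size_t)H * iw)] += g * wv;
                }
            dw(r, co) += dwacc;
          }
    }
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, Cin);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
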