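// 3D convolution kernels for the U-Net backbone.
//
// Layout convention (matches R arrays, column-major):
//   feature map x : dim (C, P, H, W)  -- channels fastest, then cardiac
//   phase, then row, then column.  A voxel index is v = p + P*(h + H*w).
//
// Padding: circular along the phase axis (cine loops are periodic),
// zero along the two spatial axes.  Kernel size is ks x ks x ks with
// ks in {1, 3}.
//
// Weight matrix w : (Cout, Cin*ks^3), column index
//   c + Cin*(kp + ks*(kh + ks*kw)).
//
// The convolution is evaluated tap by tap: for each of the ks^3 kernel
// taps the input is shifted (circularly in phase, zero-padded in-plane)
// into a (Cin, N) buffer by contiguous (C x P)-tile copies, then a GEMM
// accumulates Wtap * buffer into the output.  This keeps all heavy work
// in BLAS and bulk memcpy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Copy x shifted by (dp, dh, dw) into buf (both C x P*H*W).  A voxel
// (p,h,w) of buf receives x at (p+dp mod P, h+dh, w+dw), zero outside.
static void shift_into(const double* x, double* buf,
                       int C, int P, int H, int W,
                       int dp, int dh, int dw) {
  const size_t tile = (size_t)C * P;        // one (h,w) tile
  const int dpp = ((dp % P) + P) % P;       // normalized phase shift
  for (int w = 0; w < W; ++w) {
    const int ww = w + dw;
    for (int h = 0; h < H; ++h) {
      const int hh = h + dh;
      double* dst = buf + tile * (h + (size_t)H * w);
      if (hh < 0 || hh >= H || ww < 0 || ww >= W) {
        std::fill(dst, dst + tile, 0.0);
        continue;
      }
      const double* src = x + tile * (hh + (size_t)H * ww);
      if (dpp == 0) {
        std::copy(src, src + tile, dst);
      } else {
        // dest phase p draws source phase p + dpp (wrapped)
        std::copy(src + (size_t)C * dpp, src + tile, dst);
        std::copy(src, src + (size_t)C * dpp, dst + (size_t)C * (P - dpp));
      }
    }
  }
}

// Scatter-add the reverse: dx at (p+dp mod P, h+dh, w+dw) += buf at (p,h,w).
static void shift_add_back(const double* buf, double* dx,
                           int C, int P, int H, int W,
                           int dp, int dh, int dw) {
  const size_t tile = (size_t)C * P;
  const int dpp = ((dp % P) + P) % P;
  for (int w = 0; w < W; ++w) {
    const int ww = w + dw;
    if (ww < 0 || ww >= W) continue;
    for (int h = 0; h < H; ++h) {
      const int hh = h + dh;
      if (hh < 0 || hh >= H) continue;
      const double* src = buf + tile * (h + (size_t)H * w);
      double* dst = dx + tile * (hh + (size_t)H * ww);
      if (dpp == 0) {
        for (size_t i = 0; i < tile; ++i) dst[i] += src[i];
      } else {
        // dest phase (p + dpp) mod P accumulates source phase p
        const size_t off = (size_t)C * dpp;
        for (size_t i = 0; i < tile - off; ++i) dst[i + off] += src[i];
        for (size_t i = tile - off; i < tile; ++i) dst[i - (tile - off)] += src[i];
      }
    }
  }
}

// Forward pass: y = conv(x, w) + b, returned as a (Cout, P, H, W) array.
// [[Rcpp::export]]
NumericVector cb_conv3d_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector b, int ks) {
  const int C = dims[0], P = dims[1], H = dims[2], W = dims[3];
  const int N = P * H * W;
  const int Cout = w.nrow();
  const int pad = ks / 2;
  arma::mat wm(w.begin(), Cout, w.ncol(), false);
  arma::mat buf(C, N);
  arma::mat y(Cout, N);
  arma::colvec bv(b.begin(), Cout, false);
  y.each_col() = bv;
  for (int kw = 0; kw < ks; ++kw) {
    for (int kh = 0; kh < ks; ++kh) {
      for (int kp = 0; kp < ks; ++kp) {
        const int t = kp + ks * (kh + ks * kw);
        shift_into(x.begin(), buf.memptr(), C, P, H, W,
                   kp - pad, kh - pad, kw - pad);
        y += wm.cols(t * C, t * C + C - 1) * buf;
      }
    }
  }
  NumericVector yout(y.begin(), y.end());
  yout.attr("dim") = IntegerVector::create(Cout, P, H, W);
  return yout;
}

// Backward pass: given the layer input x and upstream gradient dy,
// return dW, db and dx.
// [[Rcpp::export]]
List cb_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                   NumericVector dy, int ks) {
  const int C = dims[0], P = dims[1], H = dims[2], W = dims[3];
  const int N = P * H * W;
  const int Cout = w.nrow();
  const int pad = ks / 2;
  arma::mat wm(w.begin(), Cout, w.ncol(), false);
  arma::mat dym(dy.begin(), Cout, N, false);
  arma::mat buf(C, N);
  arma::mat dW(Cout, w.ncol());
  NumericVector dx((size_t)C * N);
  for (int kw = 0; kw < ks; ++kw) {
    for (int kh = 0; kh < ks; ++kh) {
      for (int kp = 0; kp < ks; ++kp) {
        const int t = kp + ks * (kh + ks * kw);
        const int dp = kp - pad, dh = kh - pad, dw_ = kw - pad;
        shift_into(x.begin(), buf.memptr(), C, P, H, W, dp, dh, dw_);
        dW.cols(t * C, t * C + C - 1) = dym * buf.t();
        // gradient flowing to the shifted input, pushed back in place
        buf = wm.cols(t * C, t * C + C - 1).t() * dym;
        shift_add_back(buf.memptr(), dx.begin(), C, P, H, W, dp, dh, dw_);
      }
    }
  }
  arma::colvec db = arma::sum(dym, 1);
  dx.attr("dim") = IntegerVector::create(C, P, H, W);
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db), _["dx"] = dx);
}
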