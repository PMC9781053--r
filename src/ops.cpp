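// Low-level spatial ops for the CNN engine.
//
// Activation layout: numeric array dim (H, W, C, N), column-major.
// Convolution weight layout: (kh, kw, Cin, Cout).
// Convolutions are computed per sample as im2col followed by one GEMM;
// the im2col feature order (dh fastest, then dw, then input channel)
// matches the column-major layout of the weight array, so the reshaped
// weight matrix is used without copying indices around.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C,
                               int k, int stride, int pad, int H2, int W2) {
  arma::mat col(static_cast<arma::uword>(H2) * W2,
                static_cast<arma::uword>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        arma::uword q = static_cast<arma::uword>(dh) + k * dw +
                        static_cast<arma::uword>(k) * k * c;
        double* dst = col.colptr(q);
        for (int w2 = 0; w2 < W2; ++w2) {
          int wsrc = w2 * stride - pad + dw;
          bool wok = (wsrc >= 0 && wsrc < W);
          for (int h2 = 0; h2 < H2; ++h2) {
            int hsrc = h2 * stride - pad + dh;
            double v = 0.0;
            if (wok && hsrc >= 0 && hsrc < H)
              v = xc[hsrc + static_cast<size_t>(wsrc) * H];
            dst[h2 + static_cast<size_t>(w2) * H2] = v;
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_acc(const arma::mat& col, double* dx,
                              int H, int W, int C,
                              int k, int stride, int pad, int H2, int W2) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + static_cast<size_t>(c) * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        arma::uword q = static_cast<arma::uword>(dh) + k * dw +
                        static_cast<arma::uword>(k) * k * c;
        const double* src = col.colptr(q);
        for (int w2 = 0; w2 < W2; ++w2) {
          int wsrc = w2 * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int h2 = 0; h2 < H2; ++h2) {
            int hsrc = h2 * stride - pad + dh;
            if (hsrc < 0 || hsrc >= H) continue;
            xc[hsrc + static_cast<size_t>(wsrc) * H] +=
              src[h2 + static_cast<size_t>(w2) * H2];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("conv2d: non-square kernel");
  if (Cin != C)
    stop("conv2d: input has %d channels but weight expects %d", C, Cin);
  int H2 = (H + 2 * pad - k) / stride + 1;
  int W2 = (W + 2 * pad - k) / stride + 1;
  if (H2 < 1 || W2 < 1) stop("conv2d: output would be empty");

  const arma::mat wm(const_cast<double*>(w.begin()),
                     static_cast<arma::uword>(k) * k * Cin, Cout, false, true);
  NumericVector out(static_cast<R_xlen_t>(H2) * W2 * Cout * N);
  out.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  size_t xstep = static_cast<size_t>(H) * W * C;
  size_t ostep = static_cast<size_t>(H2) * W2 * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + n * xstep, H, W, C, k, stride, pad, H2, W2);
    arma::mat on(out.begin() + n * ostep,
                 static_cast<arma::uword>(H2) * W2, Cout, false, true);
    on = col * wm;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  int H2 = od[0], W2 = od[1];

  const arma::mat wm(const_cast<double*>(w.begin()),
                     static_cast<arma::uword>(k) * k * Cin, Cout, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  arma::mat dwm(dw.begin(), static_cast<arma::uword>(k) * k * Cin, Cout,
                false, true);
  size_t xstep = static_cast<size_t>(H) * W * C;
  size_t ostep = static_cast<size_t>(H2) * W2 * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + n * xstep, H, W, C, k, stride, pad, H2, W2);
    const arma::mat dn(const_cast<double*>(dout.begin()) + n * ostep,
                       static_cast<arma::uword>(H2) * W2, Cout, false, true);
    dwm += col.t() * dn;
    arma::mat dcol = dn * wm.t();
    col2im_acc(dcol, dx.begin() + n * xstep, H, W, C, k, stride, pad, H2, W2);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int H2 = (H + 2 * pad - k) / stride + 1;
  int W2 = (W + 2 * pad - k) / stride + 1;
  if (H2 < 1 || W2 < 1) stop("maxpool: output would be empty");
  R_xlen_t osz = static_cast<R_xlen_t>(H2) * W2 * C * N;
  NumericVector out(osz);
  IntegerVector arg(osz); // 1-based linear index into x of each max
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  size_t oi = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() +
        (static_cast<size_t>(n) * C + c) * H * W;
      size_t base = (static_cast<size_t>(n) * C + c) * H * W;
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int dw = 0; dw < k; ++dw) {
            int wsrc = w2 * stride - pad + dw;
            if (wsrc < 0 || wsrc >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hsrc = h2 * stride - pad + dh;
              if (hsrc < 0 || hsrc >= H) continue;
              double v = xc[hsrc + static_cast<size_t>(wsrc) * H];
              if (v > best) { best = v; besti = base + hsrc + static_cast<size_t>(wsrc) * H; }
            }
          }
          // output is written in (h2, w2, c, n) column-major order
          size_t pos = static_cast<size_t>(h2) + static_cast<size_t>(H2) * w2 +
            static_cast<size_t>(H2) * W2 * (c + static_cast<size_t>(C) * n);
          out[pos] = best;
          arg[pos] = static_cast<int>(besti) + 1;
          (void)oi;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector argmax,
                          IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i] - 1] += dout[i];
  return dx;
}
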