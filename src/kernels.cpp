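// Low-level tensor kernels for the network forward/backward passes.
//
// Tensor layout convention (column-major, matching the R side):
//   activations  : dim = c(C, H, W, N)
//   conv weights : matrix (Cin*k*k) x Cout, row index r = c + Cin*(ki + k*kj)
//   depthwise    : dim = c(k, k, C)
//
// im2col column index = ho + Ho*(wo + Wo*n), so a conv output written
// column-wise lands directly in a (Cout, Ho, Wo, N) array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

static arma::mat im2col_core(const double* x, int C, int H, int W, int N,
                             int k, int s, int p, int Ho, int Wo) {
  arma::mat cols(static_cast<arma::uword>(C) * k * k,
                 static_cast<arma::uword>(Ho) * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + static_cast<size_t>(C) * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword col = ho + static_cast<arma::uword>(Ho) * (wo + static_cast<arma::uword>(Wo) * n);
        double* dst = cols.colptr(col);
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * s - p + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * s - p + ki;
            if (h < 0 || h >= H) continue;
            const double* src = xn + static_cast<size_t>(C) * (h + static_cast<size_t>(H) * w);
            std::copy(src, src + C, dst + static_cast<size_t>(C) * (ki + k * kj));
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_core(const arma::mat& cols, double* dx, int C, int H, int W,
                        int N, int k, int s, int p, int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* xn = dx + static_cast<size_t>(C) * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword col = ho + static_cast<arma::uword>(Ho) * (wo + static_cast<arma::uword>(Wo) * n);
        const double* src = cols.colptr(col);
        for (int kj = 0; kj < k; ++kj) {
          int w = wo * s - p + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int h = ho * s - p + ki;
            if (h < 0 || h >= H) continue;
            double* dst = xn + static_cast<size_t>(C) * (h + static_cast<size_t>(H) * w);
            const double* s2 = src + static_cast<size_t>(C) * (ki + k * kj);
            for (int c = 0; c < C; ++c) dst[c] += s2[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, IntegerVector xdim,
                               NumericMatrix wmat, Nullable<NumericVector> bias,
                               int k, int s, int p) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  int Cout = wmat.ncol();
  arma::mat cols = im2col_core(x.begin(), C, H, W, N, k, s, p, Ho, Wo);
  arma::mat wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false);
  arma::mat out = wm.t() * cols;  // Cout x (Ho*Wo*N)
  if (bias.isNotNull()) {
    NumericVector b(bias);
    arma::colvec bv(b.begin(), b.size(), false);
    out.each_col() += bv;
  }
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  return res;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, IntegerVector xdim, NumericMatrix wmat,
                       NumericVector dout, int k, int s, int p, bool has_bias) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  int Cout = wmat.ncol();
  arma::mat cols = im2col_core(x.begin(), C, H, W, N, k, s, p, Ho, Wo);
  arma::mat dm(dout.begin(), Cout, static_cast<arma::uword>(Ho) * Wo * N, false);
  arma::mat dw = cols * dm.t();          // (C*k*k) x Cout
  arma::mat wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false);
  arma::mat dcols = wm * dm;             // (C*k*k) x (Ho*Wo*N)
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  col2im_core(dcols, dx.begin(), C, H, W, N, k, s, p, Ho, Wo);
  dx.attr("dim") = xdim;
  NumericMatrix dwR(dw.n_rows, dw.n_cols);
  std::copy(dw.begin(), dw.end(), dwR.begin());
  List res = List::create(_["dx"] = dx, _["dw"] = dwR);
  if (has_bias) {
    arma::colvec db = arma::sum(dm, 1);
    res["db"] = NumericVector(db.begin(), db.end());
  }
  return res;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, int k, int s, int p) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector out(static_cast<R_xlen_t>(C) * Ho * Wo * N);
  const double* xp = x.begin();
  const double* wp = w.begin();  // (k, k, C)
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + static_cast<size_t>(C) * H * W * n;
    double* on = op + static_cast<size_t>(C) * Ho * Wo * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* dst = on + static_cast<size_t>(C) * (ho + static_cast<size_t>(Ho) * wo);
        for (int kj = 0; kj < k; ++kj) {
          int ww = wo * s - p + kj;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hh = ho * s - p + ki;
            if (hh < 0 || hh >= H) continue;
            const double* src = xn + static_cast<size_t>(C) * (hh + static_cast<size_t>(H) * ww);
            const double* wk = wp + static_cast<size_t>(k) * k * 0 + (ki + k * kj);
            // weight for channel c at w[ki, kj, c] = wp[ki + k*kj + k*k*c]
            for (int c = 0; c < C; ++c)
              dst[c] += src[c] * wp[ki + k * kj + static_cast<size_t>(k) * k * c];
            (void)wk;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_backward(NumericVector x, IntegerVector xdim, NumericVector w,
                         NumericVector dout, int k, int s, int p) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  NumericVector dx(static_cast<R_xlen_t>(C) * H * W * N);
  NumericVector dw(static_cast<R_xlen_t>(k) * k * C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dp = dout.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + static_cast<size_t>(C) * H * W * n;
    double* dxn = dxp + static_cast<size_t>(C) * H * W * n;
    const double* dn = dp + static_cast<size_t>(C) * Ho * Wo * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* g = dn + static_cast<size_t>(C) * (ho + static_cast<size_t>(Ho) * wo);
        for (int kj = 0; kj < k; ++kj) {
          int ww = wo * s - p + kj;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hh = ho * s - p + ki;
            if (hh < 0 || hh >= H) continue;
            const double* src = xn + static_cast<size_t>(C) * (hh + static_cast<size_t>(H) * ww);
            double* dsrc = dxn + static_cast<size_t>(C) * (hh + static_cast<size_t>(H) * ww);
            for (int c = 0; c < C; ++c) {
              double wv = wp[ki + k * kj + static_cast<size_t>(k) * k * c];
              dsrc[c] += wv * g[c];
              dwp[ki + k * kj + static_cast<size_t>(k) * k * c] += src[c] * g[c];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling; ties resolved to the first element in (ki, kj) scan order.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim, int k, int s, int p) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  R_xlen_t olen = static_cast<R_xlen_t>(C) * Ho * Wo * N;
  NumericVector out(olen);
  IntegerVector idx(olen);  // 1-based linear index into x
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            int ww = wo * s - p + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hh = ho * s - p + ki;
              if (hh < 0 || hh >= H) continue;
              size_t xi = c + static_cast<size_t>(C) * (hh + static_cast<size_t>(H) * (ww + static_cast<size_t>(W) * n));
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          size_t oi = c + static_cast<size_t>(C) * (ho + static_cast<size_t>(Ho) * (wo + static_cast<size_t>(Wo) * n));
          op[oi] = best;
          ip[oi] = static_cast<int>(besti) + 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector idx,
                                   IntegerVector xdim) {
  R_xlen_t n = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  double* dxp = dx.begin();
  const double* dp = dout.begin();
  const int* ip = idx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) dxp[ip[i] - 1] += dp[i];
  dx.attr("dim") = xdim;
  return dx;
}
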