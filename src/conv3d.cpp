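// 3-D convolution with "same" zero padding, stride 1, as blocked
// im2col + BLAS matrix products. Tensor layout is the R array
// (T, H, W, C), column-major, so T is the fastest index; kernels are
// (kt, kh, kw, Cin, Cout). Blocking over output voxels bounds the
// im2col buffer at BLOCK columns regardless of image size.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int BLOCK = 8192;

// Fill one im2col block: columns v0..v1-1 (output voxels, flattened
// t + T*(h + H*w)), rows kt*kh*kw*Cin in kernel flatten order.
static void fill_cols(arma::mat &cols, const double *x,
                      int T, int H, int W, int Cin,
                      int kt, int kh, int kw,
                      int pt, int ph, int pw,
                      int v0, int v1) {
  const int HW = H * W;
  for (int v = v0; v < v1; ++v) {
    const int col = v - v0;
    const int t = v % T;
    const int hw = v / T;
    const int h = hw % H;
    const int w = hw / H;
    double *dst = cols.colptr(col);
    int row = 0;
    for (int c = 0; c < Cin; ++c) {
      const double *xc = x + (size_t)c * T * HW;
      for (int dw = 0; dw < kw; ++dw) {
        const int wi = w + dw - pw;
        const bool wok = wi >= 0 && wi < W;
        for (int dh = 0; dh < kh; ++dh) {
          const int hi = h + dh - ph;
          const bool hok = hi >= 0 && hi < H;
          const double *xcol = (wok && hok) ? xc + (size_t)(hi + H * wi) * T : nullptr;
          for (int dt = 0; dt < kt; ++dt, ++row) {
            const int ti = t + dt - pt;
            dst[row] = (xcol && ti >= 0 && ti < T) ? xcol[ti] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         Nullable<NumericVector> bias) {
  const int T = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int kt = wdim[0], kh = wdim[1], kw = wdim[2], Cout = wdim[4];
  if (wdim[3] != Cin) stop("kernel Cin mismatch");
  const int pt = (kt - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kt * kh * kw * Cin;
  const int nvox = T * H * W;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector y((size_t)nvox * Cout);
  arma::mat cols(K, std::min(BLOCK, nvox));

  for (int v0 = 0; v0 < nvox; v0 += BLOCK) {
    const int v1 = std::min(v0 + BLOCK, nvox);
    const int nb = v1 - v0;
    arma::mat cb(cols.memptr(), K, nb, false, true);
    fill_cols(cb, x.begin(), T, H, W, Cin, kt, kh, kw, pt, ph, pw, v0, v1);
    arma::mat yb = Wm.t() * cb;  // Cout x nb
    for (int c = 0; c < Cout; ++c) {
      double *yc = y.begin() + (size_t)c * nvox + v0;
      for (int j = 0; j < nb; ++j) yc[j] = yb(c, j);
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < Cout; ++c) {
      double *yc = y.begin() + (size_t)c * nvox;
      const double bc = b[c];
      for (int j = 0; j < nvox; ++j) yc[j] += bc;
    }
  }
  y.attr("dim") = IntegerVector::create(T, H, W, Cout);
  return y;
}

// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericVector w, IntegerVector wdim,
                NumericVector dy, bool need_dx, bool has_bias) {
  const int T = xdim[0], H = xdim[1], W = xdim[2], Cin = xdim[3];
  const int kt = wdim[0], kh = wdim[1], kw = wdim[2], Cout = wdim[4];
  const int pt = (kt - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int K = kt * kh * kw * Cin;
  const int nvox = T * H * W;
  const int HW = H * W;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(K, Cout, arma::fill::zeros);
  NumericVector db(Cout);
  NumericVector dx(need_dx ? x.size() : 1);
  arma::mat cols(K, std::min(BLOCK, nvox));

  for (int v0 = 0; v0 < nvox; v0 += BLOCK) {
    const int v1 = std::min(v0 + BLOCK, nvox);
    const int nb = v1 - v0;
    arma::mat dyb(Cout, nb);
    for (int c = 0; c < Cout; ++c) {
      const double *dc = dy.begin() + (size_t)c * nvox + v0;
      for (int j = 0; j < nb; ++j) dyb(c, j) = dc[j];
    }
    if (has_bias) for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dyb.row(c));

    arma::mat cb(cols.memptr(), K, nb, false, true);
    fill_cols(cb, x.begin(), T, H, W, Cin, kt, kh, kw, pt, ph, pw, v0, v1);
    dWm += cb * dyb.t();

    if (need_dx) {
      arma::mat dcols = Wm * dyb;  // K x nb, scatter-add into dx
      for (int v = v0; v < v1; ++v) {
        const int col = v - v0;
        const int t = v % T;
        const int hw = v / T;
        const int h = hw % H;
        const int wv = hw / H;
        const double *src = dcols.colptr(col);
        int row = 0;
        for (int c = 0; c < Cin; ++c) {
          double *xc = dx.begin() + (size_t)c * T * HW;
          for (int dw2 = 0; dw2 < kw; ++dw2) {
            const int wi = wv + dw2 - pw;
            const bool wok = wi >= 0 && wi < W;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h + dh - ph;
              const bool ok = wok && hi >= 0 && hi < H;
              double *xcol = ok ? xc + (size_t)(hi + H * wi) * T : nullptr;
              for (int dt = 0; dt < kt; ++dt, ++row) {
                const int ti = t + dt - pt;
                if (xcol && ti >= 0 && ti < T) xcol[ti] += src[row];
              }
            }
          }
        }
      }
    }
  }

  NumericVector dw(dWm.memptr(), dWm.memptr() + (size_t)K * Cout);
  dw.attr("dim") = wdim;
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dw"] = dw,
                      _["db"] = has_bias ? (SEXP)db : R_NilValue);
}
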