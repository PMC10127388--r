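// Grouped 2-D convolution via im2col + GEMM, with the exact backward pass.
// Feature maps are R arrays dim c(H, W, C); weights dim c(k, k, Cin/groups, Cout).
// Column-major layout makes the flattened first three weight dims the rows of
// a (k*k*Cin_g) x Cout matrix, so no transposition is needed on either side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fill `col` ((k*k*cin_g) x (ho*wo)) for one channel group of x (H x W x C).
static void im2col_group(const cube &x, int c0, int cin_g, int k, int stride,
                         int pad, int ho, int wo, mat &col) {
  const int H = x.n_rows, W = x.n_cols;
  const int kk = k * k;
  for (int ci = 0; ci < cin_g; ++ci) {
    const mat &xs = x.slice(c0 + ci);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int row = kr + k * kc + kk * ci;
        double *dst = col.memptr() + row; // stride col.n_rows between cols
        const int nrow = col.n_rows;
        for (int ow = 0; ow < wo; ++ow) {
          const int iw = ow * stride + kc - pad;
          const bool wok = (iw >= 0 && iw < W);
          for (int oh = 0; oh < ho; ++oh) {
            const int ih = oh * stride + kr - pad;
            double v = 0.0;
            if (wok && ih >= 0 && ih < H) v = xs.at(ih, iw);
            dst[(size_t)(oh + ho * ow) * nrow] = v;
          }
        }
      }
    }
  }
}

// Scatter-add of gcol (same layout as im2col output) back into gx.
static void col2im_group(const mat &gcol, int c0, int cin_g, int k, int stride,
                         int pad, int ho, int wo, cube &gx) {
  const int H = gx.n_rows, W = gx.n_cols;
  const int kk = k * k;
  for (int ci = 0; ci < cin_g; ++ci) {
    mat &gs = gx.slice(c0 + ci);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int row = kr + k * kc + kk * ci;
        const double *src = gcol.memptr() + row;
        const int nrow = gcol.n_rows;
        for (int ow = 0; ow < wo; ++ow) {
          const int iw = ow * stride + kc - pad;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < ho; ++oh) {
            const int ih = oh * stride + kr - pad;
            if (ih < 0 || ih >= H) continue;
            gs.at(ih, iw) += src[(size_t)(oh + ho * ow) * nrow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                               Rcpp::NumericVector b_, int stride, int pad,
                               int groups) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  Rcpp::IntegerVector wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], cin_g = wd[2], cout = wd[3];
  if (C != cin_g * groups) Rcpp::stop("input channels do not match weight/groups");
  if (cout % groups != 0) Rcpp::stop("output channels not divisible by groups");
  const int cout_g = cout / groups;
  const int ho = (H + 2 * pad - k) / stride + 1;
  const int wo = (W + 2 * pad - k) / stride + 1;

  cube x(x_.begin(), H, W, C, false);
  mat Wm(w_.begin(), (size_t)k * k * cin_g, cout, false);
  cube out(ho, wo, cout);
  mat col((size_t)k * k * cin_g, (size_t)ho * wo);

  for (int g = 0; g < groups; ++g) {
    im2col_group(x, g * cin_g, cin_g, k, stride, pad, ho, wo, col);
    mat og = col.t() * Wm.cols(g * cout_g, (g + 1) * cout_g - 1);
    for (int co = 0; co < cout_g; ++co) {
      out.slice(g * cout_g + co) =
          reshape(og.col(co), ho, wo) + b_[g * cout_g + co];
    }
  }

  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = Rcpp::IntegerVector::create(ho, wo, cout);
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                               Rcpp::NumericVector gy_, int stride, int pad,
                               int groups, bool need_gx) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  Rcpp::IntegerVector wd = w_.attr("dim");
  Rcpp::IntegerVector gd = gy_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], cin_g = wd[2], cout = wd[3];
  const int ho = gd[0], wo = gd[1];
  const int cout_g = cout / groups;

  cube x(x_.begin(), H, W, C, false);
  mat Wm(w_.begin(), (size_t)k * k * cin_g, cout, false);
  cube gy(gy_.begin(), ho, wo, cout, false);

  cube gx(need_gx ? H : 0, need_gx ? W : 0, need_gx ? C : 0, fill::zeros);
  Rcpp::NumericVector gw_(w_.size());
  mat Gw(gw_.begin(), (size_t)k * k * cin_g, cout, false);
  Rcpp::NumericVector gb_(cout);
  mat col((size_t)k * k * cin_g, (size_t)ho * wo);

  for (int g = 0; g < groups; ++g) {
    im2col_group(x, g * cin_g, cin_g, k, stride, pad, ho, wo, col);
    mat Gy((size_t)ho * wo, cout_g);
    for (int co = 0; co < cout_g; ++co) {
      const mat &s = gy.slice(g * cout_g + co);
      Gy.col(co) = vectorise(s);
      gb_[g * cout_g + co] = accu(s);
    }
    Gw.cols(g * cout_g, (g + 1) * cout_g - 1) = col * Gy;
    if (need_gx) {
      mat gcol = Wm.cols(g * cout_g, (g + 1) * cout_g - 1) * Gy.t();
      col2im_group(gcol, g * cin_g, cin_g, k, stride, pad, ho, wo, gx);
    }
  }

  Rcpp::NumericVector gxv(gx.begin(), gx.end());
  if (need_gx) gxv.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  gw_.attr("dim") = Rcpp::IntegerVector::create(k, k, cin_g, cout);
  return Rcpp::List::create(Rcpp::Named("gx") = gxv, Rcpp::Named("gw") = gw_,
                            Rcpp::Named("gb") = gb_);
}
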