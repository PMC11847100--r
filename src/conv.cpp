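// Grouped 2-D convolution, forward and backward, via im2col + BLAS gemm.
// Activation layout throughout: column-major R array (H, W, C, N).
// Weight layout: (kh, kw, cin/groups, cout); flattening this column-major
// gives the (kh*kw*cin_g) x cout weight matrix used below.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using Rcpp::NumericVector;

static void out_dims(int H, int W, int kh, int kw, int s, bool same,
                     int &Ho, int &Wo, int &pt, int &pl) {
  if (same) {
    Ho = (H + s - 1) / s;
    Wo = (W + s - 1) / s;
    int ph = std::max((Ho - 1) * s + kh - H, 0);
    int pw = std::max((Wo - 1) * s + kw - W, 0);
    pt = ph / 2;
    pl = pw / 2;
  } else {
    Ho = (H - kh) / s + 1;
    Wo = (W - kw) / s + 1;
    pt = pl = 0;
  }
}

// Gather one image's channels [c0, c0+cin_g) into K: (kh*kw*cin_g) x (Ho*Wo),
// columns ordered ho-fastest so K.t()*Wm drops straight into the output block.
static void im2col(const double *x, int H, int W, int c0, int cin_g,
                   int kh, int kw, int s, int pt, int pl, int Ho, int Wo,
                   arma::mat &K) {
  for (int ci = 0; ci < cin_g; ++ci) {
    const double *xc = x + (size_t)(c0 + ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wim = wo * s + j - pl;
          bool wok = wim >= 0 && wim < W;
          for (int ho = 0; ho < Ho; ++ho) {
            int him = ho * s + i - pt;
            double v = (wok && him >= 0 && him < H) ? xc[him + (size_t)H * wim] : 0.0;
            K.at(row, ho + Ho * wo) = v;
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient back onto the (padded) input.
static void col2im_add(const arma::mat &dK, int H, int W, int c0, int cin_g,
                       int kh, int kw, int s, int pt, int pl, int Ho, int Wo,
                       double *dx) {
  for (int ci = 0; ci < cin_g; ++ci) {
    double *xc = dx + (size_t)(c0 + ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wim = wo * s + j - pl;
          if (wim < 0 || wim >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int him = ho * s + i - pt;
            if (him < 0 || him >= H) continue;
            xc[him + (size_t)H * wim] += dK.at(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, bool same, int groups) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cin_g = wd[2], Cout = wd[3];
  if (Cin / groups != cin_g)
    Rcpp::stop("conv2d_fwd: input channels (%d) / groups (%d) != kernel depth (%d)",
               Cin, groups, cin_g);
  int cout_g = Cout / groups;
  int Ho, Wo, pt, pl;
  out_dims(H, W, kh, kw, stride, same, Ho, Wo, pt, pl);
  if (Ho < 1 || Wo < 1) Rcpp::stop("conv2d_fwd: non-positive output size");

  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * Cout * N));
  y.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat K(kh * kw * cin_g, Ho * Wo);
  const arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * cin_g, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * H * W * Cin;
    double *yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * cin_g, cin_g, kh, kw, stride, pt, pl, Ho, Wo, K);
      arma::mat Yg(yn + (size_t)g * cout_g * Ho * Wo, Ho * Wo, cout_g, false, true);
      Yg = K.t() * Wm.cols(g * cout_g, (g + 1) * cout_g - 1);
      for (int co = 0; co < cout_g; ++co) Yg.col(co) += b[g * cout_g + co];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, bool same, int groups, bool need_dx) {
  Rcpp::IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cin_g = wd[2], Cout = wd[3];
  int cout_g = Cout / groups;
  int Ho, Wo, pt, pl;
  out_dims(H, W, kh, kw, stride, same, Ho, Wo, pt, pl);

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * Cin * N);
    dx.attr("dim") = xd;
  }

  arma::mat K(kh * kw * cin_g, Ho * Wo);
  const arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * cin_g, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * cin_g, Cout, false, true);

  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)n * H * W * Cin;
    const double *dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * cin_g, cin_g, kh, kw, stride, pt, pl, Ho, Wo, K);
      const arma::mat dYg(const_cast<double *>(dyn) + (size_t)g * cout_g * Ho * Wo,
                          Ho * Wo, cout_g, false, true);
      dWm.cols(g * cout_g, (g + 1) * cout_g - 1) += K * dYg;
      for (int co = 0; co < cout_g; ++co)
        db[g * cout_g + co] += arma::accu(dYg.col(co));
      if (need_dx) {
        arma::mat dK = Wm.cols(g * cout_g, (g + 1) * cout_g - 1) * dYg.t();
        col2im_add(dK, H, W, g * cin_g, cin_g, kh, kw, stride, pt, pl, Ho, Wo,
                   dx.begin() + (size_t)n * H * W * Cin);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
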