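// Minimal CPU convolution kernels for the GAN engine.
//
// Tensor layout everywhere: R arrays with dim = c(H, W, C, N), column-major,
// so a single (channel, sample) plane is a contiguous H x W arma::mat.
// Convolution weights:            dim = c(k, k, Cin, Cout)
// Transposed-convolution weights: dim = c(k, k, Cout, Cin)
// im2col row order is (ki, kj, c) fastest-to-slowest, matching the
// column-major flattening of the weight arrays, so the GEMMs below need no
// reordering.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_dim(int H, int k, int s, int p) {
  return (H + 2 * p - k) / s + 1;
}

// gather patches of one sample (C planes at x) into (k*k*C, Ho*Wo)
static void im2col(const double* x, int H, int W, int C, int k, int s, int p,
                   mat& out) {
  const int Ho = out_dim(H, k, s, p);
  const int Wo = out_dim(W, k, s, p);
  out.zeros(k * k * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * s - p;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * s - p;
        double* ocol = out.colptr(ho + Ho * wo) + (std::size_t)k * k * c;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = w0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hi = h0 + ki;
            if (hi < 0 || hi >= H) continue;
            ocol[ki + k * kj] = xc[hi + (std::size_t)H * wi];
          }
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back onto the (H, W, C) planes
static void col2im(const mat& cols, int H, int W, int C, int k, int s, int p,
                   double* x) {
  const int Ho = out_dim(H, k, s, p);
  const int Wo = out_dim(W, k, s, p);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)H * W * c;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = wo * s - p;
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * s - p;
        const double* icol = cols.colptr(ho + Ho * wo) + (std::size_t)k * k * c;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = w0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hi = h0 + ki;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (std::size_t)H * wi] += icol[ki + k * kj];
          }
        }
      }
    }
  }
}

static Rcpp::IntegerVector dims4(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// [[Rcpp::export(name = ".nn_conv_fwd")]]
Rcpp::NumericVector nn_conv_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                Rcpp::NumericVector b, int stride, int pad) {
  Rcpp::IntegerVector xd = dims4(x), wd = dims4(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != C) Rcpp::stop("weight/input channel mismatch");
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) Rcpp::stop("input smaller than filter footprint");

  const mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  const rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  Rcpp::NumericVector out((std::size_t)Ho * Wo * Cout * N);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, N);
  mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride, pad, cols);
    mat y = cols.t() * Wm;                    // (Ho*Wo, Cout)
    y.each_row() += bv;
    std::copy(y.begin(), y.end(), out.begin() + (std::size_t)Ho * Wo * Cout * n);
  }
  return out;
}

// [[Rcpp::export(name = ".nn_conv_bwd")]]
Rcpp::List nn_conv_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                       Rcpp::NumericVector gy, int stride, int pad) {
  Rcpp::IntegerVector xd = dims4(x), wd = dims4(w), gd = dims4(gy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];

  const mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  Rcpp::NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  mat gW(k * k * C, Cout, fill::zeros);
  rowvec gb(Cout, fill::zeros);

  mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride, pad, cols);
    const mat G(const_cast<double*>(gy.begin()) + (std::size_t)Ho * Wo * Cout * n,
                Ho * Wo, Cout, false, true);
    gW += cols * G;
    gb += sum(G, 0);
    mat gcols = Wm * G.t();                   // (k*k*C, Ho*Wo)
    col2im(gcols, H, W, C, k, stride, pad, gx.begin() + (std::size_t)H * W * C * n);
  }

  Rcpp::NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = Rcpp::IntegerVector::create(k, k, C, Cout);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gwv,
                            Rcpp::Named("gb") = Rcpp::NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export(name = ".nn_convt_fwd")]]
Rcpp::NumericVector nn_convt_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                 Rcpp::NumericVector b, int stride, int pad,
                                 int opad) {
  Rcpp::IntegerVector xd = dims4(x), wd = dims4(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  if (wd[3] != C) Rcpp::stop("weight/input channel mismatch");
  const int Ho = (H - 1) * stride - 2 * pad + k + opad;
  const int Wo = (W - 1) * stride - 2 * pad + k + opad;
  if (Ho < 1 || Wo < 1) Rcpp::stop("degenerate transposed-conv output");

  const mat Wm(const_cast<double*>(w.begin()), k * k * Cout, C, false, true);
  Rcpp::NumericVector out((std::size_t)Ho * Wo * Cout * N);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    const mat X(const_cast<double*>(x.begin()) + (std::size_t)H * W * C * n,
                H * W, C, false, true);
    mat cols = Wm * X.t();                    // (k*k*Cout, H*W)
    double* on = out.begin() + (std::size_t)Ho * Wo * Cout * n;
    col2im(cols, Ho, Wo, Cout, k, stride, pad, on);
    for (int c = 0; c < Cout; ++c) {
      double* oc = on + (std::size_t)Ho * Wo * c;
      const double bc = b[c];
      for (int i = 0; i < Ho * Wo; ++i) oc[i] += bc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_convt_bwd")]]
Rcpp::List nn_convt_bwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                        Rcpp::NumericVector gy, int stride, int pad, int opad) {
  Rcpp::IntegerVector xd = dims4(x), wd = dims4(w), gd = dims4(gy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Ho = gd[0], Wo = gd[1];
  (void)opad;

  const mat Wm(const_cast<double*>(w.begin()), k * k * Cout, C, false, true);
  Rcpp::NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  mat gW(k * k * Cout, C, fill::zeros);
  vec gb(Cout, fill::zeros);

  mat cols;
  for (int n = 0; n < N; ++n) {
    const double* gn = gy.begin() + (std::size_t)Ho * Wo * Cout * n;
    im2col(gn, Ho, Wo, Cout, k, stride, pad, cols);  // (k*k*Cout, H*W)
    const mat X(const_cast<double*>(x.begin()) + (std::size_t)H * W * C * n,
                H * W, C, false, true);
    gW += cols * X;
    mat gX = cols.t() * Wm;                   // (H*W, C)
    std::copy(gX.begin(), gX.end(), gx.begin() + (std::size_t)H * W * C * n);
    for (int c = 0; c < Cout; ++c) {
      const double* gc = gn + (std::size_t)Ho * Wo * c;
      for (int i = 0; i < Ho * Wo; ++i) gb[c] += gc[i];
    }
  }

  Rcpp::NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = Rcpp::IntegerVector::create(k, k, Cout, C);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gwv,
                            Rcpp::Named("gb") = Rcpp::NumericVector(gb.begin(), gb.end()));
}
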