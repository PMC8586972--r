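// Convolution kernels for the segmentation networks.
//
// Tensor layout everywhere: R arrays [H, W, C, N] (column-major), so for
// sample n the slice is a contiguous H*W*C block and each channel within it
// a contiguous H*W block.  Convolutions are im2col + BLAS GEMM.
//
// Weight layouts (must match the R side):
//   3x3 stride-1 pad-1 conv:      w[3, 3, Cin, Cout]
//   2x2 stride-2 conv (down):     w[2, 2, Cin, Cout]
//   2x2 stride-2 transposed conv: w[Cin, 2, 2, Cout]

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dims_of(const NumericVector& x, int need) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("array input required");
  IntegerVector dd(d);
  if (dd.size() != need) stop("expected a %d-d array", need);
  return dd;
}

// K(p, q) with p = h + H*w, q = dh + 3*dw + 9*c; zero padding of 1.
static void im2col3(const double* xn, int H, int W, int C, arma::mat& K) {
  K.zeros();
  int q = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        double* Kq = K.colptr(q++);
        int h0 = dh < 0 ? -dh : 0;
        int h1 = dh > 0 ? H - dh : H;  // exclusive
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          std::memcpy(Kq + (size_t)w * H + h0,
                      xc + (size_t)sw * H + h0 + dh,
                      sizeof(double) * (h1 - h0));
        }
      }
    }
  }
}

static void col2im3(const arma::mat& K, int H, int W, int C, double* dxn) {
  int q = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = dxn + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const double* Kq = K.colptr(q++);
        int h0 = dh < 0 ? -dh : 0;
        int h1 = dh > 0 ? H - dh : H;
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          double* dst = xc + (size_t)sw * H + dh;
          const double* src = Kq + (size_t)w * H;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x, 4), dw = dims_of(w, 4);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Cout = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C) stop("conv3: weight dims mismatch");
  NumericVector y = make4(H, W, Cout, N);
  arma::mat Wm(w.begin(), 9 * C, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat K((size_t)H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, K);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                false, true);
    Y = K * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv3_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims_of(x, 4), dw_ = dims_of(w, 4);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3], Cout = dw_[3];
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(3, 3, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), 9 * C, Cout, false);
  arma::mat dWm(dw.begin(), 9 * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat K((size_t)H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * H * W * C;
    im2col3(x.begin() + xoff, H, W, C, K);
    arma::mat dY(dy.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                 false);
    dWm += K.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dK = dY * Wm.t();
    col2im3(dK, H, W, C, dx.begin() + xoff);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 convolution: non-overlapping patches.
// K(p, q): p = ho + Ho*wo, q = dh + 2*dw + 4*c.
static void im2col2(const double* xn, int H, int W, int C, arma::mat& K) {
  int Ho = H / 2, Wo = W / 2;
  int q = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * H * W;
    for (int dw = 0; dw <= 1; ++dw) {
      for (int dh = 0; dh <= 1; ++dh) {
        double* Kq = K.colptr(q++);
        for (int wo = 0; wo < Wo; ++wo) {
          const double* src = xc + (size_t)(2 * wo + dw) * H + dh;
          double* dst = Kq + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) dst[ho] = src[2 * ho];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector down_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x, 4), dw = dims_of(w, 4);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Cout = dw[3];
  if (H % 2 || W % 2) stop("down_fwd: odd spatial side");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), 4 * C, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat K((size_t)Ho * Wo, 4 * C);
  for (int n = 0; n < N; ++n) {
    im2col2(x.begin() + (size_t)n * H * W * C, H, W, C, K);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout,
                false, true);
    Y = K * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List down_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims_of(x, 4), dw_ = dims_of(w, 4);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3], Cout = dw_[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(2, 2, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), 4 * C, Cout, false);
  arma::mat dWm(dw.begin(), 4 * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat K((size_t)Ho * Wo, 4 * C);
  for (int n = 0; n < N; ++n) {
    im2col2(x.begin() + (size_t)n * H * W * C, H, W, C, K);
    arma::mat dY(dy.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo,
                 Cout, false);
    dWm += K.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dK = dY * Wm.t();
    // scatter back (patches do not overlap)
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    int q = 0;
    for (int c = 0; c < C; ++c) {
      double* xc = dxn + (size_t)c * H * W;
      for (int dwi = 0; dwi <= 1; ++dwi) {
        for (int dh = 0; dh <= 1; ++dh) {
          const double* Kq = dK.colptr(q++);
          for (int wo = 0; wo < Wo; ++wo) {
            double* dst = xc + (size_t)(2 * wo + dwi) * H + dh;
            const double* src = Kq + (size_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) dst[2 * ho] += src[ho];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed 2x2 stride-2 convolution.  M = X * Wm with
// X (H*W x Cin), Wm (Cin x 4*Cout) where column r = dh + 2*dw + 4*co;
// y[2h+dh, 2w+dw, co] = M(h + H*w, r) + b[co].
// [[Rcpp::export]]
NumericVector up_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dims_of(x, 4), dw_ = dims_of(w, 4);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3], Cout = dw_[3];
  if (dw_[0] != C || dw_[1] != 2 || dw_[2] != 2) stop("up_fwd: weight dims mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), C, 4 * Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                (size_t)H * W, C, false);
    arma::mat M = X * Wm;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    int r = 0;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)co * Ho * Wo;
      double bco = b[co];
      for (int dwi = 0; dwi <= 1; ++dwi) {
        for (int dh = 0; dh <= 1; ++dh) {
          const double* src = M.colptr(dh + 2 * dwi + 4 * co);
          for (int w2 = 0; w2 < W; ++w2) {
            double* dst = yc + (size_t)(2 * w2 + dwi) * Ho + dh;
            const double* sc = src + (size_t)w2 * H;
            for (int h = 0; h < H; ++h) dst[2 * h] = sc[h] + bco;
          }
        }
      }
      r += 4;
    }
  }
  return y;
}

// [[Rcpp::export]]
List up_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dims_of(x, 4), dw_ = dims_of(w, 4);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3], Cout = dw_[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dw = make4(C, 2, 2, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), C, 4 * Cout, false);
  arma::mat dWm(dw.begin(), C, 4 * Cout, false, true);
  arma::mat M((size_t)H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* yc = dyn + (size_t)co * Ho * Wo;
      double s = 0;
      for (int dwi = 0; dwi <= 1; ++dwi) {
        for (int dh = 0; dh <= 1; ++dh) {
          double* dst = M.colptr(dh + 2 * dwi + 4 * co);
          for (int w2 = 0; w2 < W; ++w2) {
            const double* sc = yc + (size_t)(2 * w2 + dwi) * Ho + dh;
            double* dd = dst + (size_t)w2 * H;
            for (int h = 0; h < H; ++h) dd[h] = sc[2 * h];
          }
        }
      }
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) s += yc[p];
      db[co] += s;
    }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                (size_t)H * W, C, false);
    dWm += X.t() * M;
    arma::mat dX(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                 false, true);
    dX += M * Wm.t();
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Fused batch normalization + optional ReLU over [H, W, C, N].
// Training mode computes batch statistics over (H, W, N) per channel and
// returns updated running stats; eval mode uses the provided running stats.
// [[Rcpp::export]]
List bnrelu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool train,
                double momentum, double eps, bool relu) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  NumericVector y = make4(H, W, C, N);
  NumericVector mean(C), invstd(C);
  NumericVector rm = clone(rmean), rv = clone(rvar);
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (train) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * hw;
        for (size_t p = 0; p < hw; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
      }
      mu = s / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
      rm[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv[c] = (1 - momentum) * rv[c] + momentum * var;
    } else {
      mu = rmean[c];
      var = rvar[c];
    }
    double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu;
    invstd[c] = is;
    double a = gamma[c] * is, b0 = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      double* yc = y.begin() + ((size_t)n * C + c) * hw;
      if (relu)
        for (size_t p = 0; p < hw; ++p) {
          double v = a * xc[p] + b0;
          yc[p] = v > 0 ? v : 0;
        }
      else
        for (size_t p = 0; p < hw; ++p) yc[p] = a * xc[p] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["rmean"] = rm, _["rvar"] = rv);
}

// Backward of bnrelu_fwd (training mode).  `y` is the forward output used
// for the ReLU mask (y > 0 iff the pre-activation was positive).
// [[Rcpp::export]]
List bnrelu_bwd(NumericVector x, NumericVector mean, NumericVector invstd,
                NumericVector gamma, NumericVector y, NumericVector dy,
                bool relu) {
  IntegerVector d = dims_of(x, 4);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t hw = (size_t)H * W;
  NumericVector dx = make4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], is = invstd[c];
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * hw;
      const double* xc = x.begin() + off;
      const double* yc = y.begin() + off;
      const double* dc = dy.begin() + off;
      for (size_t p = 0; p < hw; ++p) {
        double g = dc[p];
        if (relu && yc[p] <= 0) g = 0;
        s1 += g;
        s2 += g * (xc[p] - mu) * is;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    double k = gamma[c] * is / M;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * hw;
      const double* xc = x.begin() + off;
      const double* yc = y.begin() + off;
      const double* dc = dy.begin() + off;
      double* dxc = dx.begin() + off;
      for (size_t p = 0; p < hw; ++p) {
        double g = dc[p];
        if (relu && yc[p] <= 0) g = 0;
        dxc[p] = k * (M * g - s1 - (xc[p] - mu) * is * s2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
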