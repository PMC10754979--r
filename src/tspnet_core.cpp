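// Compute kernels for the network: one-axis convolutions (im2col + GEMM),
// batch normalization, the fused parallel residual block, and the
// similarity/projection loop of the time-spatial head. Activation tensors
// are column-major arrays [C, W, H, N] (feature channels, temporal,
// spatial, batch). Heavy products go through BLAS dgemm directly so that
// kernel-size sub-blocks of the shared patch matrix can be addressed with
// a leading-dimension stride instead of copies.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static void dgemm_(bool ta, bool tb, int m, int n, int k, double alpha,
                   const double* A, int lda, const double* B, int ldb,
                   double beta, double* C, int ldc) {
  const char* tra = ta ? "T" : "N";
  const char* trb = tb ? "T" : "N";
  F77_CALL(dgemm)(tra, trb, &m, &n, &k, &alpha, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, C, &ldc FCONE FCONE);
}

// Fill the [Ci*kmax, W*H*N] patch matrix for a 1-d kernel along axis 2 (W)
// or axis 3 (H), with same-padding by zeros (only border entries are
// zeroed explicitly).
static void im2col_axis(const double* xp, arma::mat& big,
                        int C, int W, int H, int N, int k, int axis) {
  const int p = (k - 1) / 2;
  const size_t rowb = sizeof(double) * C;
  for (int j = 0; j < k; ++j) {
    const int off = j - p;
    for (long n = 0; n < N; ++n) {
      for (long h = 0; h < H; ++h) {
        const long base = (long)W * (h + (long)H * n);
        if (axis == 3) {
          const long hs = h + off;
          if (hs < 0 || hs >= H) {
            for (long wi = 0; wi < W; ++wi)
              std::memset(big.colptr(wi + base) + (long)j * C, 0, rowb);
            continue;
          }
          const double* src = xp + (long)C * (long)W * (hs + (long)H * n);
          for (long wi = 0; wi < W; ++wi)
            std::memcpy(big.colptr(wi + base) + (long)j * C,
                        src + (long)C * wi, rowb);
        } else {
          const long w0 = std::max<long>(0, -off);
          const long w1 = std::min<long>(W, W - off);
          for (long wi = 0; wi < w0; ++wi)
            std::memset(big.colptr(wi + base) + (long)j * C, 0, rowb);
          for (long wi = w0; wi < w1; ++wi)
            std::memcpy(big.colptr(wi + base) + (long)j * C,
                        xp + (long)C * (wi + off + base), rowb);
          for (long wi = w1; wi < W; ++wi)
            std::memset(big.colptr(wi + base) + (long)j * C, 0, rowb);
        }
      }
    }
  }
}

// Scatter a [Ci*kmax, cols] patch-gradient back onto the input (adds).
static void col2im_axis(const arma::mat& dbig, double* dxp,
                        int C, int W, int H, int N, int k, int axis) {
  const int p = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int off = j - p;
    for (long n = 0; n < N; ++n) {
      for (long h = 0; h < H; ++h) {
        const long base = (long)W * (h + (long)H * n);
        if (axis == 3) {
          const long hs = h + off;
          if (hs < 0 || hs >= H) continue;
          double* dst = dxp + (long)C * (long)W * (hs + (long)H * n);
          for (long wi = 0; wi < W; ++wi) {
            const double* src = dbig.colptr(wi + base) + (long)j * C;
            double* d = dst + (long)C * wi;
            for (int c = 0; c < C; ++c) d[c] += src[c];
          }
        } else {
          const long w0 = std::max<long>(0, -off);
          const long w1 = std::min<long>(W, W - off);
          for (long wi = w0; wi < w1; ++wi) {
            const double* src = dbig.colptr(wi + base) + (long)j * C;
            double* d = dxp + (long)C * (wi + off + base);
            for (int c = 0; c < C; ++c) d[c] += src[c];
          }
        }
      }
    }
  }
}

// Subsample the spatial axis with stride 2 (rows 1, 3, 5, ... one-based).
static void stride_h(const double* src, double* dst, int C, int W, int H,
                     int N, int Hs) {
  const size_t strip = sizeof(double) * (size_t)C * W;
  for (long n = 0; n < N; ++n)
    for (long h = 0; h < Hs; ++h)
      std::memcpy(dst + (long)C * W * (h + (long)Hs * n),
                  src + (long)C * W * (2 * h + (long)H * n), strip);
}

static void unstride_h(const double* src, double* dst, int C, int W, int H,
                       int N, int Hs) {
  const size_t strip = sizeof(double) * (size_t)C * W;
  for (long n = 0; n < N; ++n)
    for (long h = 0; h < Hs; ++h)
      std::memcpy(dst + (long)C * W * (2 * h + (long)H * n),
                  src + (long)C * W * (h + (long)Hs * n), strip);
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, int axis) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], W = xd[1], H = xd[2], N = xd[3];
  const int Co = wd[0], Ci = wd[1], k = wd[2];
  if (Ci != C) stop("kernel input channels do not match activation");
  const long cols = (long)W * H * N;
  arma::mat big((arma::uword)(Ci * k), (arma::uword)cols);
  im2col_axis(x.begin(), big, C, W, H, N, k, axis);
  NumericVector out(no_init(Co * cols));
  dgemm_(false, false, Co, cols, Ci * k, 1.0, w.begin(), Co,
         big.memptr(), Ci * k, 0.0, out.begin(), Co);
  out.attr("dim") = IntegerVector::create(Co, W, H, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector dy, NumericVector x, NumericVector w, int axis) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int C = xd[0], W = xd[1], H = xd[2], N = xd[3];
  const int Co = wd[0], Ci = wd[1], k = wd[2];
  const long cols = (long)W * H * N;
  arma::mat big((arma::uword)(Ci * k), (arma::uword)cols);
  im2col_axis(x.begin(), big, C, W, H, N, k, axis);
  NumericVector dw(no_init(Co * Ci * k));
  dgemm_(false, true, Co, Ci * k, cols, 1.0, dy.begin(), Co,
         big.memptr(), Ci * k, 0.0, dw.begin(), Co);
  arma::mat dbig((arma::uword)(Ci * k), (arma::uword)cols);
  dgemm_(true, false, Ci * k, cols, Co, 1.0, w.begin(), Co,
         dy.begin(), Co, 0.0, dbig.memptr(), Ci * k);
  NumericVector dx(x.size());  // zero-initialized
  col2im_axis(dbig, dx.begin(), C, W, H, N, k, axis);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Batch normalization forward over [C, M]; returns y and the statistics
// needed for the backward pass, plus updated running estimates.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, int C, NumericVector g, NumericVector b,
                NumericVector rmean, NumericVector rvar,
                bool train, double momentum, double eps) {
  const long M = x.size() / C;
  const double* xp = x.begin();
  arma::vec mu(C), var(C);
  if (train) {
    arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
    for (long m = 0; m < M; ++m) {
      const double* col = xp + (long)C * m;
      for (int c = 0; c < C; ++c) { s1[c] += col[c]; s2[c] += col[c] * col[c]; }
    }
    mu = s1 / (double)M;
    var = s2 / (double)M - mu % mu;
    var.transform([](double v) { return v < 0 ? 0.0 : v; });
  } else {
    mu = arma::vec(rmean.begin(), C);
    var = arma::vec(rvar.begin(), C);
  }
  arma::vec istd = 1.0 / arma::sqrt(var + eps);
  arma::vec scale(C), shift(C);
  for (int c = 0; c < C; ++c) {
    scale[c] = g[c] * istd[c];
    shift[c] = b[c] - mu[c] * scale[c];
  }
  NumericVector y(no_init(x.size()));
  double* yp = y.begin();
  for (long m = 0; m < M; ++m) {
    const double* col = xp + (long)C * m;
    double* ycol = yp + (long)C * m;
    for (int c = 0; c < C; ++c) ycol[c] = col[c] * scale[c] + shift[c];
  }
  y.attr("dim") = x.attr("dim");
  NumericVector nrm(C), nrv(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      nrm[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      nrv[c] = (1 - momentum) * rvar[c] + momentum * var[c];
    }
  } else { nrm = rmean; nrv = rvar; }
  return List::create(_["y"] = y,
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["istd"] = NumericVector(istd.begin(), istd.end()),
                      _["rmean"] = nrm, _["rvar"] = nrv);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector x, NumericVector mu,
                NumericVector istd, NumericVector g, bool train) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0];
  const long M = x.size() / C;
  const double* xp = x.begin();
  const double* dp = dy.begin();
  arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (long m = 0; m < M; ++m) {
    const double* xc = xp + (long)C * m;
    const double* dc = dp + (long)C * m;
    for (int c = 0; c < C; ++c) {
      const double xh = (xc[c] - mu[c]) * istd[c];
      s1[c] += dc[c];
      s2[c] += dc[c] * xh;
    }
  }
  NumericVector dx(no_init(x.size()));
  double* dxp = dx.begin();
  if (train) {
    for (long m = 0; m < M; ++m) {
      const double* xc = xp + (long)C * m;
      const double* dc = dp + (long)C * m;
      double* dxc = dxp + (long)C * m;
      for (int c = 0; c < C; ++c) {
        const double xh = (xc[c] - mu[c]) * istd[c];
        dxc[c] = g[c] * istd[c] * (dc[c] - s1[c] / M - xh * s2[c] / M);
      }
    }
  } else {
    for (long m = 0; m < M; ++m) {
      const double* dc = dp + (long)C * m;
      double* dxc = dxp + (long)C * m;
      for (int c = 0; c < C; ++c) dxc[c] = dc[c] * g[c] * istd[c];
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx,
                      _["dg"] = NumericVector(s2.begin(), s2.end()),
                      _["db"] = NumericVector(s1.begin(), s1.end()));
}

// --------------------------------------------------------------------------
// Fused parallel residual block:
//   y = sum_b relu( BN_b(conv_b(x) + skip(x)) )
// Normalization sits after the skip addition so activation scale stays
// O(1) at any depth. One shared patch matrix serves every branch (a
// k-kernel's patch rows are a centered sub-block of the widest kernel's,
// addressed via the leading dimension). The cache per branch is the
// normalized activation xhat and istd; ReLU masks are recomputed in the
// backward pass from xhat and the affine parameters.

// [[Rcpp::export]]
List cpp_block_fwd(NumericVector x, List kernels, List gammas, List betas,
                   List rmeans, List rvars, SEXP projW,
                   bool residual, bool train, bool stride2,
                   int axis, double momentum, double eps) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], W = xd[1], H = xd[2], N = xd[3];
  const int nb = kernels.size();
  int kmax = 1, Co = 0;
  for (int j = 0; j < nb; ++j) {
    IntegerVector wd = as<NumericVector>(kernels[j]).attr("dim");
    if (wd[2] > kmax) kmax = wd[2];
    Co = wd[0];
  }
  const long cols = (long)W * H * N;
  const int Hs = stride2 ? (H + 1) / 2 : H;
  const long cols_s = (long)W * Hs * N;
  arma::mat big((arma::uword)(C * kmax), (arma::uword)cols);
  im2col_axis(x.begin(), big, C, W, H, N, kmax, axis);

  // skip path (added to every branch before its normalization)
  NumericVector skipv;
  if (residual) {
    skipv = NumericVector(no_init(Co * cols_s));
    if (!Rf_isNull(projW)) {
      NumericMatrix pw(projW);
      if (stride2) {
        arma::mat tmp(Co, cols);
        dgemm_(false, false, Co, cols, C, 1.0, pw.begin(), Co,
               x.begin(), C, 0.0, tmp.memptr(), Co);
        stride_h(tmp.memptr(), skipv.begin(), Co, W, H, N, Hs);
      } else {
        dgemm_(false, false, Co, cols, C, 1.0, pw.begin(), Co,
               x.begin(), C, 0.0, skipv.begin(), Co);
      }
    } else {
      if (stride2) stride_h(x.begin(), skipv.begin(), Co, W, H, N, Hs);
      else std::memcpy(skipv.begin(), x.begin(), sizeof(double) * x.size());
    }
  }
  const double* sp = residual ? skipv.begin() : nullptr;

  NumericVector y(Co * cols_s);  // zero-initialized accumulator
  double* yp = y.begin();
  List caches(nb), new_rmeans(nb), new_rvars(nb);
  arma::mat tmp;  // full-resolution conv workspace for stride2
  if (stride2) tmp.set_size(Co, cols);
  for (int j = 0; j < nb; ++j) {
    NumericVector wj = kernels[j];
    IntegerVector wd = wj.attr("dim");
    const int k = wd[2];
    const int lead = (kmax - k) / 2;
    NumericVector xhat(no_init(Co * cols_s));
    if (stride2) {
      dgemm_(false, false, Co, cols, C * k, 1.0, wj.begin(), Co,
             big.memptr() + (long)lead * C, C * kmax, 0.0, tmp.memptr(), Co);
      stride_h(tmp.memptr(), xhat.begin(), Co, W, H, N, Hs);
    } else {
      dgemm_(false, false, Co, cols, C * k, 1.0, wj.begin(), Co,
             big.memptr() + (long)lead * C, C * kmax, 0.0, xhat.begin(), Co);
    }
    double* cp = xhat.begin();
    if (residual) {
      for (long i = 0; i < (long)Co * cols_s; ++i) cp[i] += sp[i];
    }
    // batch-norm statistics on (conv + skip), currently held in xhat
    NumericVector g = gammas[j], b = betas[j];
    NumericVector rm = rmeans[j], rv = rvars[j];
    arma::vec mu(Co), var(Co);
    if (train) {
      arma::vec s1(Co, arma::fill::zeros), s2(Co, arma::fill::zeros);
      for (long m = 0; m < cols_s; ++m) {
        const double* col = cp + (long)Co * m;
        for (int c = 0; c < Co; ++c) { s1[c] += col[c]; s2[c] += col[c] * col[c]; }
      }
      mu = s1 / (double)cols_s;
      var = s2 / (double)cols_s - mu % mu;
      var.transform([](double v) { return v < 0 ? 0.0 : v; });
    } else {
      mu = arma::vec(rm.begin(), Co);
      var = arma::vec(rv.begin(), Co);
    }
    arma::vec istd = 1.0 / arma::sqrt(var + eps);
    // in place: xhat <- standardized; z = g*xhat + b; y += relu(z)
    for (long m = 0; m < cols_s; ++m) {
      const long o = (long)Co * m;
      for (int c = 0; c < Co; ++c) {
        const double xh = (cp[o + c] - mu[c]) * istd[c];
        cp[o + c] = xh;
        const double z = g[c] * xh + b[c];
        if (z > 0) yp[o + c] += z;
      }
    }
    caches[j] = List::create(_["xhat"] = xhat,
                             _["istd"] = NumericVector(istd.begin(), istd.end()));
    NumericVector nrm(Co), nrv(Co);
    if (train) {
      for (int c = 0; c < Co; ++c) {
        nrm[c] = (1 - momentum) * rm[c] + momentum * mu[c];
        nrv[c] = (1 - momentum) * rv[c] + momentum * var[c];
      }
    } else { nrm = rm; nrv = rv; }
    new_rmeans[j] = nrm;
    new_rvars[j] = nrv;
  }
  y.attr("dim") = IntegerVector::create(Co, W, Hs, N);
  return List::create(_["y"] = y, _["caches"] = caches,
                      _["rmeans"] = new_rmeans, _["rvars"] = new_rvars);
}

// [[Rcpp::export]]
List cpp_block_bwd(NumericVector dy, NumericVector x, List kernels,
                   List gammas, List betas, List caches,
                   SEXP projW, bool residual, bool train, bool stride2,
                   int axis) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], W = xd[1], H = xd[2], N = xd[3];
  const int nb = kernels.size();
  int kmax = 1, Co = 0;
  for (int j = 0; j < nb; ++j) {
    IntegerVector wd = as<NumericVector>(kernels[j]).attr("dim");
    if (wd[2] > kmax) kmax = wd[2];
    Co = wd[0];
  }
  const long cols = (long)W * H * N;
  const int Hs = stride2 ? (H + 1) / 2 : H;
  const long cols_s = (long)W * Hs * N;
  arma::mat big((arma::uword)(C * kmax), (arma::uword)cols);
  im2col_axis(x.begin(), big, C, W, H, N, kmax, axis);
  arma::mat dbig(C * kmax, cols, arma::fill::zeros);
  const double* dp = dy.begin();

  arma::mat dz(Co, cols_s);
  arma::mat dskip;
  if (residual) dskip.zeros(Co, cols_s);
  arma::mat dcv_full;
  if (stride2) dcv_full.zeros(Co, cols);
  List dWs(nb), dgs(nb), dbs(nb);
  for (int j = 0; j < nb; ++j) {
    List cj = caches[j];
    NumericVector xhat = cj["xhat"], istdv = cj["istd"];
    NumericVector g = gammas[j], b = betas[j];
    const double* xh = xhat.begin();
    double* dzp = dz.memptr();
    arma::vec s1(Co, arma::fill::zeros), s2(Co, arma::fill::zeros);
    // recompute the ReLU mask from xhat, form dz, accumulate BN sums
    for (long m = 0; m < cols_s; ++m) {
      const long o = (long)Co * m;
      for (int c = 0; c < Co; ++c) {
        const double z = g[c] * xh[o + c] + b[c];
        const double d = z > 0 ? dp[o + c] : 0.0;
        dzp[o + c] = d;
        s1[c] += d;
        s2[c] += d * xh[o + c];
      }
    }
    // BN backward in place on dz -> gradient w.r.t. (conv + skip)
    if (train) {
      for (long m = 0; m < cols_s; ++m) {
        const long o = (long)Co * m;
        for (int c = 0; c < Co; ++c) {
          dzp[o + c] = g[c] * istdv[c] *
            (dzp[o + c] - s1[c] / cols_s - xh[o + c] * s2[c] / cols_s);
        }
      }
    } else {
      for (long m = 0; m < cols_s; ++m) {
        const long o = (long)Co * m;
        for (int c = 0; c < Co; ++c) dzp[o + c] *= g[c] * istdv[c];
      }
    }
    if (residual) dskip += dz;
    const double* dcv;
    if (stride2) {
      unstride_h(dz.memptr(), dcv_full.memptr(), Co, W, H, N, Hs);
      dcv = dcv_full.memptr();
    } else {
      dcv = dz.memptr();
    }
    // conv backward through the shared patch matrix
    NumericVector wj = kernels[j];
    IntegerVector wd = wj.attr("dim");
    const int k = wd[2];
    const int lead = (kmax - k) / 2;
    NumericVector dW(no_init(Co * C * k));
    dgemm_(false, true, Co, C * k, cols, 1.0, dcv, Co,
           big.memptr() + (long)lead * C, C * kmax, 0.0, dW.begin(), Co);
    dgemm_(true, false, C * k, cols, Co, 1.0, wj.begin(), Co,
           dcv, Co, 1.0, dbig.memptr() + (long)lead * C, C * kmax);
    dW.attr("dim") = wd;
    dWs[j] = dW;
    dgs[j] = NumericVector(s2.begin(), s2.end());
    dbs[j] = NumericVector(s1.begin(), s1.end());
  }

  NumericVector dx(x.size());  // zero-initialized
  col2im_axis(dbig, dx.begin(), C, W, H, N, kmax, axis);

  RObject dprojW = R_NilValue;
  if (residual) {
    const double* ds;
    if (stride2) {
      dcv_full.zeros();
      unstride_h(dskip.memptr(), dcv_full.memptr(), Co, W, H, N, Hs);
      ds = dcv_full.memptr();
    } else {
      ds = dskip.memptr();
    }
    if (!Rf_isNull(projW)) {
      NumericMatrix pw(projW);
      NumericMatrix dpw(Co, C);
      dgemm_(false, true, Co, C, cols, 1.0, ds, Co, x.begin(), C,
             0.0, dpw.begin(), Co);
      dgemm_(true, false, C, cols, Co, 1.0, pw.begin(), Co, ds, Co,
             1.0, dx.begin(), C);
      dprojW = dpw;
    } else {
      double* dxp = dx.begin();
      for (long i = 0; i < (long)C * cols; ++i) dxp[i] += ds[i];
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dWs"] = dWs, _["dgs"] = dgs,
                      _["dbs"] = dbs, _["dprojW"] = dprojW);
}

// --------------------------------------------------------------------------
// Time-spatial head inner loop.

static void softmax_cols_inplace(arma::mat& Q) {
  const arma::uword W = Q.n_rows;
  for (arma::uword j = 0; j < Q.n_cols; ++j) {
    double* c = Q.colptr(j);
    double mx = c[0];
    for (arma::uword i = 1; i < W; ++i) if (c[i] > mx) mx = c[i];
    double s = 0.0;
    for (arma::uword i = 0; i < W; ++i) { c[i] = std::exp(c[i] - mx); s += c[i]; }
    const double inv = 1.0 / s;
    for (arma::uword i = 0; i < W; ++i) c[i] *= inv;
  }
}

// Similarity / projection loop of the time-spatial head.
// xp: [H, W, S] channel slices (S = C*N), M: [H, H] symmetric.
// Returns Fc, Fr [H, W, S] and the normalized similarities Sc, Sr [W, W, S].
// [[Rcpp::export]]
List cpp_tspfe_fwd(NumericVector xp, NumericMatrix M) {
  IntegerVector xd = xp.attr("dim");
  const int H = xd[0], W = xd[1], S = xd[2];
  const long hw = (long)H * W;
  arma::mat Mm(const_cast<double*>(M.begin()), H, H, false, true);
  // all MX slices in one GEMM: [H, W*S]
  arma::mat MX(H, (long)W * S);
  dgemm_(false, false, H, (long)W * S, H, 1.0, M.begin(), H,
         xp.begin(), H, 0.0, MX.memptr(), H);
  NumericVector Fc(no_init(hw * S)), Fr(no_init(hw * S));
  NumericVector Sc(no_init((long)W * W * S)), Sr(no_init((long)W * W * S));
  arma::mat Q(W, W);
  for (int s = 0; s < S; ++s) {
    arma::mat X(const_cast<double*>(xp.begin()) + hw * s, H, W, false, true);
    arma::mat MXs(MX.memptr() + hw * s, H, W, false, true);
    Q = X.t() * MXs;
    arma::mat s1(Sc.begin() + (long)W * W * s, W, W, false, true);
    arma::mat s2(Sr.begin() + (long)W * W * s, W, W, false, true);
    s1 = Q;
    softmax_cols_inplace(s1);
    s2 = Q.t();
    softmax_cols_inplace(s2);
    arma::mat f1(Fc.begin() + hw * s, H, W, false, true);
    arma::mat f2(Fr.begin() + hw * s, H, W, false, true);
    f1 = X * s1;
    f2 = X * s2;
  }
  Fc.attr("dim") = IntegerVector::create(H, W, S);
  Fr.attr("dim") = IntegerVector::create(H, W, S);
  Sc.attr("dim") = IntegerVector::create(W, W, S);
  Sr.attr("dim") = IntegerVector::create(W, W, S);
  return List::create(_["Fc"] = Fc, _["Fr"] = Fr, _["Sc"] = Sc, _["Sr"] = Sr);
}

// Backward of the similarity / projection loop; returns dxp [H, W, S] and
// dM [H, H].
// [[Rcpp::export]]
List cpp_tspfe_bwd(NumericVector xp, NumericMatrix M,
                   NumericVector Sc, NumericVector Sr,
                   NumericVector dFc, NumericVector dFr) {
  IntegerVector xd = xp.attr("dim");
  const int H = xd[0], W = xd[1], S = xd[2];
  const long hw = (long)H * W;
  arma::mat Mm(const_cast<double*>(M.begin()), H, H, false, true);
  arma::mat MX(H, (long)W * S);
  dgemm_(false, false, H, (long)W * S, H, 1.0, M.begin(), H,
         xp.begin(), H, 0.0, MX.memptr(), H);
  NumericVector dxv(no_init(hw * S));
  arma::mat dM(H, H, arma::fill::zeros);
  arma::mat dS1(W, W), dS2(W, W), dQ1(W, W), dQ2t(W, W), dQ(W, W),
      dQs(W, W), XdQ(H, W);
  for (int s = 0; s < S; ++s) {
    arma::mat X(const_cast<double*>(xp.begin()) + hw * s, H, W, false, true);
    arma::mat MXs(MX.memptr() + hw * s, H, W, false, true);
    arma::mat s1(const_cast<double*>(Sc.begin()) + (long)W * W * s, W, W, false, true);
    arma::mat s2(const_cast<double*>(Sr.begin()) + (long)W * W * s, W, W, false, true);
    arma::mat dF1(const_cast<double*>(dFc.begin()) + hw * s, H, W, false, true);
    arma::mat dF2(const_cast<double*>(dFr.begin()) + hw * s, H, W, false, true);
    dS1 = X.t() * dF1;
    dS2 = X.t() * dF2;
    arma::mat dX(dxv.begin() + hw * s, H, W, false, true);
    dX = dF1 * s1.t() + dF2 * s2.t();
    for (int j = 0; j < W; ++j) {
      const double* s1c = s1.colptr(j);
      const double* d1c = dS1.colptr(j);
      const double* s2c = s2.colptr(j);
      const double* d2c = dS2.colptr(j);
      double dot1 = 0.0, dot2 = 0.0;
      for (int i = 0; i < W; ++i) { dot1 += s1c[i] * d1c[i]; dot2 += s2c[i] * d2c[i]; }
      double* q1c = dQ1.colptr(j);
      double* q2c = dQ2t.colptr(j);
      for (int i = 0; i < W; ++i) {
        q1c[i] = s1c[i] * (d1c[i] - dot1);
        q2c[i] = s2c[i] * (d2c[i] - dot2);
      }
    }
    dQ = dQ1 + dQ2t.t();
    dQs = dQ + dQ.t();
    dX += MXs * dQs;  // M symmetric
    XdQ = X * dQ;
    dM += XdQ * X.t();
  }
  dxv.attr("dim") = xd;
  NumericMatrix dMv(H, H);
  std::copy(dM.begin(), dM.end(), dMv.begin());
  return List::create(_["dxp"] = dxv, _["dM"] = dMv);
}
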