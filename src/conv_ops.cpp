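// Convolution primitives for the SGAN engine.
//
// Internal activation layout is channel-major: a batch is a C x (H*W*N)
// matrix whose column index is h + H*(w + W*n).  Kernels are stored as
// (Cin*k*k) x Cout matrices with the input channel fastest, so that
//   forward:      Y = W' * im2col(X)         (Cout x Ho*Wo*N, no reorder)
//   input grad:   dX = col2im(W * dY)
//   kernel grad:  dW = im2col(X) * dY'
// In this layout consecutive kernel rows i (at fixed tap column j) address
// consecutive image columns, so each (output pixel, j) pair transfers one
// contiguous block of C*k values.  All R matrices are borrowed, not
// copied, via Armadillo views over the R memory.  Transposed convolution
// is realised in R as the exact adjoint: its forward pass is conv_bwd_x
// and its backward uses conv_fwd / conv_bwd_w with input and output
// swapped.  The column matrix built by the forward pass can be cached
// (external pointer) and reused by the backward pass.

#include <RcppArmadillo.h>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Training allocates and frees many multi-megabyte buffers per iteration;
// with glibc's default mmap threshold each one round-trips through the
// kernel (zeroed pages).  Raising the thresholds keeps the arena warm.
// [[Rcpp::export]]
void engine_tune_malloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

static inline int out_side(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static inline arma::mat borrow(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(),
                   false, true);
}

static arma::mat* im2col(const arma::mat& x, int H, int W, int N,
                         int k, int stride, int pad, int Ho, int Wo) {
  const int C = x.n_rows;
  arma::mat* Mp = new arma::mat(C * k * k, (size_t)Ho * Wo * N,
                                arma::fill::none);
  arma::mat& M = *Mp;
  std::vector<int> i0(Ho), i1(Ho);
  for (int ho = 0; ho < Ho; ++ho) {
    i0[ho] = std::max(0, pad - ho * stride);
    i1[ho] = std::min(k - 1, H - 1 - ho * stride + pad);
  }
  const size_t nrow = (size_t)C * k * k;
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      const int j0 = std::max(0, pad - wo * stride);
      const int j1 = std::min(k - 1, W - 1 - wo * stride + pad);
      for (int ho = 0; ho < Ho; ++ho) {
        double* mcol = M.colptr((size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n));
        // zero only columns with out-of-image taps (image border)
        if (j0 > 0 || j1 < k - 1 || i0[ho] > 0 || i1[ho] < k - 1)
          std::memset(mcol, 0, nrow * sizeof(double));
        const int len = C * (i1[ho] - i0[ho] + 1);
        const int h0 = ho * stride - pad + i0[ho];
        for (int j = j0; j <= j1; ++j) {
          std::memcpy(mcol + (size_t)C * (i0[ho] + (size_t)k * j),
                      x.colptr(xoff + h0 + (size_t)H * (wo * stride - pad + j)),
                      len * sizeof(double));
        }
      }
    }
  }
  return Mp;
}

static void col2im_acc(arma::mat& dx, const arma::mat& G, int H, int W, int N,
                       int C, int k, int stride, int pad, int Ho, int Wo) {
  std::vector<int> i0(Ho), i1(Ho);
  for (int ho = 0; ho < Ho; ++ho) {
    i0[ho] = std::max(0, pad - ho * stride);
    i1[ho] = std::min(k - 1, H - 1 - ho * stride + pad);
  }
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      const int j0 = std::max(0, pad - wo * stride);
      const int j1 = std::min(k - 1, W - 1 - wo * stride + pad);
      for (int ho = 0; ho < Ho; ++ho) {
        const double* gcol =
          G.colptr((size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n));
        const int len = C * (i1[ho] - i0[ho] + 1);
        const int h0 = ho * stride - pad + i0[ho];
        for (int j = j0; j <= j1; ++j) {
          double* dst = dx.colptr(xoff + h0 + (size_t)H * (wo * stride - pad + j));
          const double* src = gcol + (size_t)C * (i0[ho] + (size_t)k * j);
          for (int t = 0; t < len; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

typedef XPtr<arma::mat> MatPtr;

// forward convolution; returns list(y, cols) where cols is an external
// pointer to the im2col matrix for reuse in conv_bwd_w (or NULL)
// [[Rcpp::export]]
List conv_fwd(const NumericMatrix& x, int H, int W, int N,
              const NumericMatrix& w, const NumericVector& b,
              int k, int stride, int pad, bool keep_cols) {
  const arma::mat X = borrow(x), Wm = borrow(w);
  if ((int)X.n_rows * k * k != (int)Wm.n_rows)
    stop("conv_fwd: channel/kernel mismatch");
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  const int Cout = Wm.n_cols;
  arma::mat* M = im2col(X, H, W, N, k, stride, pad, Ho, Wo);
  NumericMatrix y(Cout, (size_t)Ho * Wo * N);
  arma::mat Y(y.begin(), Cout, (size_t)Ho * Wo * N, false, true);
  Y = Wm.t() * (*M);
  const arma::vec bv(const_cast<double*>(b.begin()), b.size(), false, true);
  Y.each_col() += bv;
  if (keep_cols)
    return List::create(Named("y") = y, Named("cols") = MatPtr(M, true));
  delete M;
  return List::create(Named("y") = y, Named("cols") = R_NilValue);
}

// gradient w.r.t. the convolution input (also transposed-conv forward)
// [[Rcpp::export]]
NumericMatrix conv_bwd_x(const NumericMatrix& dy, int Ho, int Wo, int N,
                         const NumericMatrix& w, int k, int H, int W,
                         int stride, int pad) {
  const arma::mat Dy = borrow(dy), Wm = borrow(w);
  const int C = Wm.n_rows / (k * k);
  arma::mat G = Wm * Dy;  // (C*k*k) x (Ho*Wo*N)
  NumericMatrix dxr(C, (size_t)H * W * N);
  arma::mat dx(dxr.begin(), C, (size_t)H * W * N, false, true);
  col2im_acc(dx, G, H, W, N, C, k, stride, pad, Ho, Wo);
  return dxr;
}

// gradient w.r.t. the kernel, reusing the cached forward column matrix
// when available
// [[Rcpp::export]]
NumericMatrix conv_bwd_w(const NumericMatrix& x, int H, int W, int N,
                         const NumericMatrix& dy, int k, int stride, int pad,
                         SEXP cols) {
  const arma::mat X = borrow(x), Dy = borrow(dy);
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);
  const int nr = X.n_rows * k * k;
  NumericMatrix dwr(nr, Dy.n_rows);
  arma::mat dw(dwr.begin(), nr, Dy.n_rows, false, true);
  if (cols != R_NilValue) {
    MatPtr M(cols);
    if (M.get() != NULL && M->n_cols == Dy.n_cols) {
      dw = (*M) * Dy.t();
      return dwr;
    }
  }
  arma::mat* M = im2col(X, H, W, N, k, stride, pad, Ho, Wo);
  dw = (*M) * Dy.t();
  delete M;
  return dwr;
}

// fused LeakyReLU + inverted dropout in one pass.  The multiplier applied
// to each element is one of {0, alpha, 1, alpha/keep, 1/keep}; a byte code
// per element is kept for the backward pass.  Dropout bits come from a
// xorshift128+ stream seeded from R's RNG once per call, so runs stay
// seed-reproducible while avoiding a full RNG dispatch per element.
// [[Rcpp::export]]
List lrelu_dropout(const NumericMatrix& x, double alpha, double p,
                   bool training) {
  const R_xlen_t n = x.size();
  NumericMatrix y(x.nrow(), x.ncol());
  RawMatrix code(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* yp = y.begin();
  Rbyte* cp = code.begin();
  const bool drop = training && p > 0;
  const double ik = drop ? 1.0 / (1.0 - p) : 1.0;
  const double lut[4] = {alpha * ik, ik, 0.0, 0.0};
  if (drop) {
    uint64_t s0 = (uint64_t)(unif_rand() * 9007199254740992.0) | 1u;
    uint64_t s1 = (uint64_t)(unif_rand() * 9007199254740992.0) | 2u;
    const uint64_t thr = (uint64_t)(p * 18446744073709551616.0 /* 2^64 */);
    for (R_xlen_t i = 0; i < n; ++i) {
      uint64_t t = s0;
      const uint64_t s = s1;
      s0 = s;
      t ^= t << 23;
      t ^= t >> 18;
      t ^= s ^ (s >> 5);
      s1 = t;
      const int c = ((t + s) < thr) ? 2 : (xp[i] > 0 ? 1 : 0);
      cp[i] = (Rbyte)c;
      yp[i] = xp[i] * lut[c];
    }
  } else {
    for (R_xlen_t i = 0; i < n; ++i) {
      const int c = xp[i] > 0 ? 1 : 0;
      cp[i] = (Rbyte)c;
      yp[i] = xp[i] * lut[c];
    }
  }
  return List::create(Named("y") = y, Named("code") = code,
                      Named("mult") = NumericVector::create(lut[0], lut[1]));
}

// one Adam update for a parameter block: w_new is returned, the moment
// buffers m and v are updated in place (they are private to the layer)
// [[Rcpp::export]]
NumericVector adam_update(const NumericVector& w, const NumericVector& g,
                          NumericVector m, NumericVector v,
                          double lr, double b1, double b2, double eps,
                          double corr1, double corr2) {
  const R_xlen_t n = w.size();
  NumericVector out(n);
  const double* wp = w.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  double* op = out.begin();
  const double ic1 = 1.0 / corr1, ic2 = 1.0 / corr2;
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    op[i] = wp[i] - lr * (mp[i] * ic1) / (std::sqrt(vp[i] * ic2) + eps);
  }
  out.attr("dim") = w.attr("dim");
  return out;
}

// column-block subset: take whole images (hw consecutive columns each)
// [[Rcpp::export]]
NumericMatrix take_images(const NumericMatrix& x, const IntegerVector& idx,
                          int hw) {
  const int C = x.nrow();
  NumericMatrix out(C, (R_xlen_t)hw * idx.size());
  const size_t block = (size_t)C * hw;
  for (int j = 0; j < idx.size(); ++j)
    std::memcpy(out.begin() + block * j,
                x.begin() + block * (idx[j] - 1), block * sizeof(double));
  return out;
}

// backward pass of the fused block: dx = dy * stored multiplier
// [[Rcpp::export]]
NumericMatrix lrelu_dropout_bwd(const NumericMatrix& dy, const RawMatrix& code,
                                const NumericVector& mult) {
  const R_xlen_t n = dy.size();
  NumericMatrix dx(dy.nrow(), dy.ncol());
  const double lut[3] = {mult[0], mult[1], 0.0};
  const double* dp = dy.begin();
  const Rbyte* cp = code.begin();
  double* op = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = dp[i] * lut[cp[i]];
  return dx;
}
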