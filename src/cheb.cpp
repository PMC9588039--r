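#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Batched Chebyshev filtering kernels, channels-first layout.
//
// An activation batch is a C x (B*n) column-major matrix: column (j-1)*B + b
// holds subject b's C-vector at vertex j, so each vertex occupies one
// contiguous C*B block ("lanes"). One pass over the shared scaled
// Laplacian's CSC structure then updates every subject and channel with
// long contiguous inner loops, and no transposition is ever needed.

// yb = L xb; lanes = C*B values per vertex. L symmetric, so CSC column
// scatter equals row gather.
static void spmv_lanes(const int* p, const int* idx, const double* val,
                       int n, std::size_t lanes, const double* xb,
                       double* yb) {
  std::fill(yb, yb + lanes * n, 0.0);
  for (int j = 0; j < n; ++j) {
    const double* xc = xb + (std::size_t)j * lanes;
    for (int k = p[j]; k < p[j + 1]; ++k) {
      const double v = val[k];
      double* __restrict yc = yb + (std::size_t)idx[k] * lanes;
      for (std::size_t c = 0; c < lanes; ++c) yc[c] += v * xc[c];
    }
  }
}

// [T_0 X, T_1 X, ..., T_{K-1} X] by the three-term recurrence
// T_k = 2 L T_{k-1} - T_{k-2}; returns a list of K matrices shaped like X.
// [[Rcpp::export]]
List cheb_basis_list(IntegerVector p, IntegerVector i, NumericVector v,
                     int n, int B, NumericMatrix X, int K) {
  const std::size_t lanes = (std::size_t)X.nrow() * B;
  const std::size_t tot = lanes * n;
  List out(K);
  out[0] = X;
  if (K >= 2) {
    NumericMatrix t1(X.nrow(), X.ncol());
    spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, X.begin(),
               t1.begin());
    out[1] = t1;
    NumericMatrix tprev = X, tcur = t1;
    for (int k = 2; k < K; ++k) {
      NumericMatrix tnew(X.nrow(), X.ncol());
      spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, tcur.begin(),
                 tnew.begin());
      double* tn = tnew.begin();
      const double* tp = tprev.begin();
      for (std::size_t t = 0; t < tot; ++t) tn[t] = 2.0 * tn[t] - tp[t];
      out[k] = tnew;
      tprev = tcur;
      tcur = tnew;
    }
  }
  return out;
}

// T_k(L) Z for a single order k (k-step recurrence), same layout as above.
// [[Rcpp::export]]
NumericMatrix cheb_apply_k(IntegerVector p, IntegerVector i, NumericVector v,
                           int n, int B, NumericMatrix Z, int k) {
  const std::size_t lanes = (std::size_t)Z.nrow() * B;
  const std::size_t tot = lanes * n;
  if (k == 0) return clone(Z);
  NumericMatrix u1(Z.nrow(), Z.ncol());
  spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, Z.begin(),
             u1.begin());
  if (k == 1) return u1;
  std::vector<double> a(Z.begin(), Z.end());       // T_{j-2} Z
  std::vector<double> b(u1.begin(), u1.end());     // T_{j-1} Z
  std::vector<double> c(tot);
  for (int j = 2; j <= k; ++j) {
    spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, b.data(), c.data());
    for (std::size_t t = 0; t < tot; ++t) c[t] = 2.0 * c[t] - a[t];
    std::swap(a, b);
    std::swap(b, c);
  }
  NumericMatrix out(Z.nrow(), Z.ncol());
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// Stride-2 max pooling over sibling vertex pairs, channels-first layout.
// X is C x (B*n); siblings are vertices (2t-1, 2t). Fake (padding) vertices
// never win; pairs of two fakes yield 0. Returns the pooled C x (B*n/2)
// matrix and the winner mask (true where the even sibling won).
// [[Rcpp::export]]
List pool_fwd_cpp(NumericMatrix X, int B, LogicalVector fake) {
  const int C = X.nrow();
  const int n = fake.size();
  const int half = n / 2;
  const std::size_t lane = (std::size_t)C * B;      // one vertex block
  NumericMatrix out(C, (std::size_t)B * half);
  LogicalMatrix win(C, (std::size_t)B * half);
  for (int t = 0; t < half; ++t) {
    const bool f1 = fake[2 * t], f2 = fake[2 * t + 1];
    const double* a = X.begin() + (std::size_t)(2 * t) * lane;
    const double* b = a + lane;
    double* o = out.begin() + (std::size_t)t * lane;
    int* w = win.begin() + (std::size_t)t * lane;
    if (f1 && f2) {
      for (std::size_t c = 0; c < lane; ++c) { o[c] = 0.0; w[c] = 0; }
    } else if (f1) {
      for (std::size_t c = 0; c < lane; ++c) { o[c] = b[c]; w[c] = 1; }
    } else if (f2) {
      for (std::size_t c = 0; c < lane; ++c) { o[c] = a[c]; w[c] = 0; }
    } else {
      for (std::size_t c = 0; c < lane; ++c) {
        const bool bw = b[c] > a[c];
        o[c] = bw ? b[c] : a[c];
        w[c] = bw;
      }
    }
  }
  return List::create(_["y"] = out, _["win"] = win);
}

// Backward of the pooling above: route each gradient to the winning child.
// [[Rcpp::export]]
NumericMatrix pool_bwd_cpp(NumericMatrix dY, LogicalMatrix win, int B,
                           LogicalVector fake) {
  const int C = dY.nrow();
  const int n = fake.size();
  const int half = n / 2;
  const std::size_t lane = (std::size_t)C * B;
  NumericMatrix dX(C, (std::size_t)B * n);
  for (int t = 0; t < half; ++t) {
    const bool f1 = fake[2 * t], f2 = fake[2 * t + 1];
    if (f1 && f2) continue;
    const double* g = dY.begin() + (std::size_t)t * lane;
    const int* w = win.begin() + (std::size_t)t * lane;
    double* a = dX.begin() + (std::size_t)(2 * t) * lane;
    double* b = a + lane;
    for (std::size_t c = 0; c < lane; ++c) {
      if (w[c]) b[c] = g[c]; else a[c] = g[c];
    }
  }
  return dX;
}

// dX = sum_{k=0}^{K-1} T_k(L) Z_k by the Clenshaw recurrence
// (b_k = Z_k + 2 L b_{k+1} - b_{k+2}; S = Z_0 + L b_1 - b_2), using K-1
// sparse products. Z is the stacked (K*C) x (B*n) matrix with row block k
// holding Z_k = theta_k dY.
// [[Rcpp::export]]
NumericMatrix cheb_clenshaw_cpp(IntegerVector p, IntegerVector i,
                                NumericVector v, int n, int B,
                                NumericMatrix Z, int K, int C) {
  const int KC = Z.nrow();
  const std::size_t ncol = Z.ncol();
  const std::size_t plane = (std::size_t)C * ncol;
  const std::size_t lanes = (std::size_t)C * B;
  NumericMatrix out(C, ncol);
  // extract row block k of Z into a contiguous C x (B*n) plane
  auto extract = [&](int k, double* dst) {
    const double* src = Z.begin() + (std::size_t)k * C;
    for (std::size_t c = 0; c < ncol; ++c)
      std::copy(src + c * KC, src + c * KC + C, dst + c * C);
  };
  if (K == 1) {
    extract(0, out.begin());
    return out;
  }
  std::vector<double> bcur(plane), bnext(plane, 0.0), tmp(plane);
  extract(K - 1, bcur.data());
  for (int k = K - 2; k >= 1; --k) {
    spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, bcur.data(),
               tmp.data());
    extract(k, out.begin());   // reuse out as scratch for Z_k
    double* o = out.begin();
    for (std::size_t t = 0; t < plane; ++t)
      tmp[t] = o[t] + 2.0 * tmp[t] - bnext[t];
    std::swap(bnext, bcur);
    std::swap(bcur, tmp);
  }
  spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, bcur.data(),
             tmp.data());
  extract(0, out.begin());
  double* o = out.begin();
  for (std::size_t t = 0; t < plane; ++t) o[t] += tmp[t] - bnext[t];
  return out;
}

// Fused batch-norm + ReLU forward (single pass, channels in rows).
// Returns the post-ReLU activations, the pre-ReLU sign mask, the
// normalized values, and the statistics used.
// [[Rcpp::export]]
List bnrelu_fwd_cpp(NumericMatrix X, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar, bool training,
                    double eps) {
  const int C = X.nrow();
  const std::size_t N = X.ncol();
  NumericVector mu(C), var(C);
  if (training) {
    for (std::size_t c = 0; c < N; ++c) {
      const double* x = X.begin() + c * C;
      for (int r = 0; r < C; ++r) mu[r] += x[r];
    }
    for (int r = 0; r < C; ++r) mu[r] /= (double)N;
    for (std::size_t c = 0; c < N; ++c) {
      const double* x = X.begin() + c * C;
      for (int r = 0; r < C; ++r) {
        const double d = x[r] - mu[r];
        var[r] += d * d;
      }
    }
    for (int r = 0; r < C; ++r) var[r] /= (double)N;
  } else {
    mu = clone(rmean);
    var = clone(rvar);
  }
  std::vector<double> invstd(C);
  for (int r = 0; r < C; ++r) invstd[r] = 1.0 / std::sqrt(var[r] + eps);
  NumericMatrix Y(C, N), XH(C, N);
  LogicalMatrix mask(C, N);
  for (std::size_t c = 0; c < N; ++c) {
    const double* x = X.begin() + c * C;
    double* y = Y.begin() + c * C;
    double* xh = XH.begin() + c * C;
    int* m = mask.begin() + c * C;
    for (int r = 0; r < C; ++r) {
      const double z = (x[r] - mu[r]) * invstd[r];
      xh[r] = z;
      const double a = z * gamma[r] + beta[r];
      const bool pos = a > 0;
      m[r] = pos;
      y[r] = pos ? a : 0.0;
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = XH, _["mask"] = mask,
                      _["invstd"] = NumericVector(invstd.begin(), invstd.end()),
                      _["mu"] = mu, _["var"] = var);
}

// Fused ReLU + batch-norm backward. dY is the gradient at the post-ReLU
// output; the ReLU mask gates it before the batch-norm backward formulas.
// [[Rcpp::export]]
List bnrelu_bwd_cpp(NumericMatrix dY, LogicalMatrix mask, NumericMatrix XH,
                    NumericVector invstd, NumericVector gamma,
                    bool training) {
  const int C = dY.nrow();
  const std::size_t N = dY.ncol();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dX(C, N);
  // first pass: per-channel sums of the gated gradient
  for (std::size_t c = 0; c < N; ++c) {
    const double* g = dY.begin() + c * C;
    const int* m = mask.begin() + c * C;
    const double* xh = XH.begin() + c * C;
    for (int r = 0; r < C; ++r) {
      if (m[r]) {
        dgamma[r] += g[r] * xh[r];
        dbeta[r] += g[r];
      }
    }
  }
  if (!training) {
    for (std::size_t c = 0; c < N; ++c) {
      const double* g = dY.begin() + c * C;
      const int* m = mask.begin() + c * C;
      double* dx = dX.begin() + c * C;
      for (int r = 0; r < C; ++r)
        dx[r] = m[r] ? g[r] * gamma[r] * invstd[r] : 0.0;
    }
  } else {
    // s1 = sum(dxhat), s2 = sum(dxhat * xhat) with dxhat = gated dY * gamma
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (int r = 0; r < C; ++r) {
      s1[r] = dbeta[r] * gamma[r];
      s2[r] = dgamma[r] * gamma[r];
    }
    const double inv_n = 1.0 / (double)N;
    for (std::size_t c = 0; c < N; ++c) {
      const double* g = dY.begin() + c * C;
      const int* m = mask.begin() + c * C;
      const double* xh = XH.begin() + c * C;
      double* dx = dX.begin() + c * C;
      for (int r = 0; r < C; ++r) {
        const double dxh = m[r] ? g[r] * gamma[r] : 0.0;
        dx[r] = (dxh - s1[r] * inv_n - xh[r] * s2[r] * inv_n) * invstd[r];
      }
    }
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Full Chebyshev convolution forward: builds the basis planes and
// accumulates y = sum_k theta_k' T_k(L) X + bias with in-place BLAS calls
// (no intermediate R temporaries). theta is stacked (K*C) x Fout.
// [[Rcpp::export]]
List conv_fwd_cpp(IntegerVector p, IntegerVector i, NumericVector v,
                  int n, int B, NumericMatrix X, NumericMatrix theta,
                  NumericVector bias, int K) {
  const int C = X.nrow();
  const int Fout = theta.ncol();
  const int KC = theta.nrow();
  const int N = X.ncol();                  // B * n
  const std::size_t lanes = (std::size_t)C * B;
  List basis = cheb_basis_list(p, i, v, n, B, X, K);
  NumericMatrix Y(Fout, N);
  const double one = 1.0, zero = 0.0;
  for (int k = 0; k < K; ++k) {
    NumericMatrix Tk = basis[k];
    // Y (+)= theta_k' (Fout x C) * Tk (C x N)
    F77_CALL(dgemm)("T", "N", &Fout, &N, &C, &one,
                    theta.begin() + (std::size_t)k * C, &KC,
                    Tk.begin(), &C, (k == 0 ? &zero : &one), Y.begin(),
                    &Fout FCONE FCONE);
  }
  double* y = Y.begin();
  for (int c = 0; c < N; ++c)
    for (int r = 0; r < Fout; ++r) y[(std::size_t)c * Fout + r] += bias[r];
  return List::create(_["y"] = Y, _["basis"] = basis);
}

// acc (C x Fout, contiguous) += Tk dY' by per-column rank-1 updates; the
// accumulator stays cache-resident, which beats a BLAS call for this
// tall-inner-product shape.
static void accum_outer(const double* tk, const double* dy, int C, int Fout,
                        std::size_t N, double* acc) {
  for (std::size_t c = 0; c < N; ++c) {
    const double* t = tk + c * C;
    const double* g = dy + c * Fout;
    for (int f = 0; f < Fout; ++f) {
      const double gf = g[f];
      double* __restrict a = acc + (std::size_t)f * C;
      for (int r = 0; r < C; ++r) a[r] += gf * t[r];
    }
  }
}

// Full Chebyshev convolution backward: filter/bias gradients and the input
// gradient in one call. Returns dtheta (stacked), dbias, dx. The input
// gradient dX = sum_k T_k(L) (theta_k dY) is evaluated by the Clenshaw
// recurrence on plane buffers (Z_k produced directly by BLAS, K-1 sparse
// products).
// [[Rcpp::export]]
List conv_bwd_cpp(IntegerVector p, IntegerVector i, NumericVector v,
                  int n, int B, NumericMatrix dY, NumericMatrix theta,
                  List basis, int K, bool want_dx) {
  const int Fout = dY.nrow();
  const int N = dY.ncol();
  const int KC = theta.nrow();
  const int C = KC / K;
  const double one = 1.0, zero = 0.0;
  NumericMatrix dtheta(KC, Fout);
  NumericVector dbias(Fout);
  const double* dy = dY.begin();
  for (std::size_t c = 0; c < (std::size_t)N; ++c)
    for (int r = 0; r < Fout; ++r) dbias[r] += dy[c * Fout + r];
  {
    std::vector<double> acc((std::size_t)C * Fout);
    for (int k = 0; k < K; ++k) {
      NumericMatrix Tk = basis[k];
      std::fill(acc.begin(), acc.end(), 0.0);
      accum_outer(Tk.begin(), dy, C, Fout, N, acc.data());
      for (int f = 0; f < Fout; ++f)
        for (int r = 0; r < C; ++r)
          dtheta[(std::size_t)f * KC + (std::size_t)k * C + r] =
            acc[(std::size_t)f * C + r];
    }
  }
  if (!want_dx)
    return List::create(_["theta"] = dtheta, _["bias"] = dbias);
  // Z_k = theta_k dY computed straight into plane buffers
  const std::size_t plane = (std::size_t)C * N;
  const std::size_t lanes = (std::size_t)C * B;
  auto zk_into = [&](int k, double* dst) {
    F77_CALL(dgemm)("N", "N", &C, &N, &Fout, &one,
                    theta.begin() + (std::size_t)k * C, &KC,
                    dY.begin(), &Fout, &zero, dst, &C FCONE FCONE);
  };
  NumericMatrix dX(C, N);
  if (K == 1) {
    zk_into(0, dX.begin());
    return List::create(_["theta"] = dtheta, _["bias"] = dbias,
                        _["dx"] = dX);
  }
  std::vector<double> bcur(plane), bnext(plane, 0.0), tmp(plane), zk(plane);
  zk_into(K - 1, bcur.data());
  for (int k = K - 2; k >= 1; --k) {
    spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, bcur.data(),
               tmp.data());
    zk_into(k, zk.data());
    for (std::size_t t = 0; t < plane; ++t)
      tmp[t] = zk[t] + 2.0 * tmp[t] - bnext[t];
    std::swap(bnext, bcur);
    std::swap(bcur, tmp);
  }
  spmv_lanes(p.begin(), i.begin(), v.begin(), n, lanes, bcur.data(),
             tmp.data());
  zk_into(0, dX.begin());
  double* o = dX.begin();
  for (std::size_t t = 0; t < plane; ++t) o[t] += tmp[t] - bnext[t];
  return List::create(_["theta"] = dtheta, _["bias"] = dbias, _["dx"] = dX);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large activation buffers churn through mmap/munmap on glibc (default
// threshold 128 KB), paying page-fault costs on every training step. Keep
// big blocks on the reusable heap instead; called once at package load.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}
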