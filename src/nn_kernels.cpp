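// Compute kernels for the 1D segmentation networks.
//
// Activations are channels-first matrices (C x n) where the n columns are
// per-window time blocks of length L laid out consecutively. Convolutions
// are one BLAS dgemm per kernel tap accumulated in place, with small
// corrections at window boundaries (zero padding must not leak across
// windows).

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix nn_conv_fwd(NumericMatrix X, List W, NumericVector bias, int L,
                          bool exact_blocks) {
  const int cin = X.nrow(), n = X.ncol();
  NumericMatrix W0 = W[0];
  const int cout = W0.ncol(), k = W.size(), half = (k - 1) / 2;
  const int nb = n / L;
  NumericMatrix Y(cout, n);
  double *y = REAL(Y);
  const double *bp = REAL(bias);
  for (int c = 0; c < n; ++c) {
    double *yc = y + (size_t)c * cout;
    for (int j = 0; j < cout; ++j) yc[j] = bp[j];
  }
  const double one = 1.0;
  const char TA = 'T', TB = 'N';
  for (int t = 0; t < k; ++t) {
    const int s = t - half;
    NumericMatrix Wt = W[t];
    const double *w = REAL(Wt);
    const double *x = REAL(X);
    if (exact_blocks) {
      // one gemm per (tap, window): every window computed exactly as if it
      // were alone in the batch (evaluation path)
      const int o0 = std::max(0, -s);
      const int o1 = L - 1 - std::max(0, s);
      const int m = o1 - o0 + 1;
      if (m <= 0) continue;
      for (int blk = 0; blk < nb; ++blk) {
        const size_t base = (size_t)blk * L;
        F77_CALL(dgemm)(&TA, &TB, &cout, &m, &cin, &one, w, &cin,
                        x + (base + o0 + s) * cin, &cin, &one,
                        y + (base + o0) * cout, &cout FCONE FCONE);
      }
    } else {
      // whole-batch gemm with boundary corrections (training path; faster,
      // but column results can differ in the last bit by batch position)
      const int c0 = std::max(0, -s);
      const int c1 = n - 1 - std::max(0, s);
      const int m = c1 - c0 + 1;
      if (m <= 0) continue;
      F77_CALL(dgemm)(&TA, &TB, &cout, &m, &cin, &one, w, &cin,
                      x + (size_t)(c0 + s) * cin, &cin, &one,
                      y + (size_t)c0 * cout, &cout FCONE FCONE);
      if (s != 0) {
        for (int blk = 1; blk < nb; ++blk) {
          const int lo = (s > 0) ? blk * L - s : blk * L;
          const int hi = (s > 0) ? blk * L - 1 : blk * L - s - 1;
          for (int c = std::max(lo, c0); c <= std::min(hi, c1); ++c) {
            const double *xc = x + (size_t)(c + s) * cin;
            double *yc = y + (size_t)c * cout;
            for (int j = 0; j < cout; ++j) {
              const double *wj = w + (size_t)j * cin;
              double acc = 0;
              for (int i = 0; i < cin; ++i) acc += wj[i] * xc[i];
              yc[j] -= acc;
            }
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericMatrix X, List W, NumericMatrix dY, int L) {
  const int cin = X.nrow(), n = X.ncol();
  NumericMatrix W0 = W[0];
  const int cout = W0.ncol(), k = W.size(), half = (k - 1) / 2;
  const int nb = n / L;
  NumericMatrix dX(cin, n);
  List dW(k);
  NumericVector db(cout);
  double *dxp = REAL(dX);
  const double *dyp = REAL(dY);
  const double *xp = REAL(X);
  double *dbp = REAL(db);
  for (int c = 0; c < n; ++c) {
    const double *dyc = dyp + (size_t)c * cout;
    for (int j = 0; j < cout; ++j) dbp[j] += dyc[j];
  }
  const double one = 1.0, zero = 0.0;
  for (int t = 0; t < k; ++t) {
    const int s = t - half;
    NumericMatrix Wt = W[t];
    const double *w = REAL(Wt);
    NumericMatrix dWt(cin, cout);
    double *dw = REAL(dWt);
    const int c0 = std::max(0, -s);
    const int c1 = n - 1 - std::max(0, s);
    const int m = c1 - c0 + 1;
    if (m > 0) {
      const char NA_ = 'N', TB2 = 'T';
      // dX[:, c+s] += W_t %*% dY[:, c]
      F77_CALL(dgemm)(&NA_, &NA_, &cin, &m, &cout, &one, w, &cin,
                      dyp + (size_t)c0 * cout, &cout, &one,
                      dxp + (size_t)(c0 + s) * cin, &cin FCONE FCONE);
      // dW_t = X[:, c+s] %*% dY[:, c]^T, summed over c
      F77_CALL(dgemm)(&NA_, &TB2, &cin, &cout, &m, &one,
                      xp + (size_t)(c0 + s) * cin, &cin,
                      dyp + (size_t)c0 * cout, &cout, &zero, dw,
                      &cin FCONE FCONE);
      if (s != 0) {
        for (int blk = 1; blk < nb; ++blk) {
          const int lo = (s > 0) ? blk * L - s : blk * L;
          const int hi = (s > 0) ? blk * L - 1 : blk * L - s - 1;
          for (int c = std::max(lo, c0); c <= std::min(hi, c1); ++c) {
            const double *dyc = dyp + (size_t)c * cout;
            const double *xc = xp + (size_t)(c + s) * cin;
            double *dxc = dxp + (size_t)(c + s) * cin;
            for (int j = 0; j < cout; ++j) {
              const double *wj = w + (size_t)j * cin;
              const double g = dyc[j];
              double *dwj = dw + (size_t)j * cin;
              for (int i = 0; i < cin; ++i) {
                dxc[i] -= wj[i] * g;
                dwj[i] -= xc[i] * g;
              }
            }
          }
        }
      }
    }
    dW[t] = dWt;
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// [[Rcpp::export]]
NumericMatrix nn_lrelu_fwd(NumericMatrix X, double slope) {
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  NumericMatrix Y(X.nrow(), X.ncol());
  const double *x = REAL(X);
  double *y = REAL(Y);
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return Y;
}

// [[Rcpp::export]]
NumericMatrix nn_lrelu_bwd(NumericMatrix X, NumericMatrix dY, double slope) {
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  NumericMatrix dX(X.nrow(), X.ncol());
  const double *x = REAL(X), *dy = REAL(dY);
  double *dx = REAL(dX);
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dX;
}

// max pooling, kernel and stride 2 along time (column pairs)
// [[Rcpp::export]]
List nn_pool_fwd(NumericMatrix X) {
  const int C = X.nrow(), n = X.ncol(), m = n / 2;
  NumericMatrix Y(C, m);
  LogicalMatrix amax(C, m);
  const double *x = REAL(X);
  double *y = REAL(Y);
  int *am = LOGICAL(amax);
  for (int c = 0; c < m; ++c) {
    const double *a = x + (size_t)(2 * c) * C;
    const double *b = a + C;
    double *yc = y + (size_t)c * C;
    int *mc = am + (size_t)c * C;
    for (int i = 0; i < C; ++i) {
      const bool take_a = a[i] >= b[i];
      yc[i] = take_a ? a[i] : b[i];
      mc[i] = take_a;
    }
  }
  return List::create(Named("Y") = Y, Named("amax") = amax);
}

// [[Rcpp::export]]
NumericMatrix nn_pool_bwd(NumericMatrix dY, LogicalMatrix amax) {
  const int C = dY.nrow(), m = dY.ncol();
  NumericMatrix dX(C, 2 * m);
  const double *dy = REAL(dY);
  const int *am = LOGICAL(amax);
  double *dx = REAL(dX);
  for (int c = 0; c < m; ++c) {
    const double *dyc = dy + (size_t)c * C;
    const int *mc = am + (size_t)c * C;
    double *a = dx + (size_t)(2 * c) * C;
    double *b = a + C;
    for (int i = 0; i < C; ++i) {
      if (mc[i]) a[i] = dyc[i]; else b[i] = dyc[i];
    }
  }
  return dX;
}

// nearest-neighbour x2 upsampling along time
// [[Rcpp::export]]
NumericMatrix nn_up_fwd(NumericMatrix X) {
  const int C = X.nrow(), n = X.ncol();
  NumericMatrix Y(C, 2 * n);
  const double *x = REAL(X);
  double *y = REAL(Y);
  for (int c = 0; c < n; ++c) {
    const double *xc = x + (size_t)c * C;
    double *y1 = y + (size_t)(2 * c) * C;
    std::copy(xc, xc + C, y1);
    std::copy(xc, xc + C, y1 + C);
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix nn_up_bwd(NumericMatrix dY) {
  const int C = dY.nrow(), n2 = dY.ncol(), n = n2 / 2;
  NumericMatrix dX(C, n);
  const double *dy = REAL(dY);
  double *dx = REAL(dX);
  for (int c = 0; c < n; ++c) {
    const double *a = dy + (size_t)(2 * c) * C;
    const double *b = a + C;
    double *dxc = dx + (size_t)c * C;
    for (int i = 0; i < C; ++i) dxc[i] = a[i] + b[i];
  }
  return dX;
}

// multiply each length-L column block by a per-(window, channel) factor
// [[Rcpp::export]]
NumericMatrix nn_scale_blocks(NumericMatrix X, NumericMatrix S, int L) {
  const int C = X.nrow(), n = X.ncol();
  NumericMatrix Y(C, n);
  const double *x = REAL(X), *s = REAL(S);
  double *y = REAL(Y);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *sc = s + (size_t)blk * C;
    const double *xc = x + (size_t)c * C;
    double *yc = y + (size_t)c * C;
    for (int i = 0; i < C; ++i) yc[i] = xc[i] * sc[i];
  }
  return Y;
}

// per-(window, channel) mean over time: C x Nb
// [[Rcpp::export]]
NumericMatrix nn_block_means(NumericMatrix X, int L) {
  const int C = X.nrow(), n = X.ncol(), nb = n / L;
  NumericMatrix M(C, nb);
  const double *x = REAL(X);
  double *m = REAL(M);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *xc = x + (size_t)c * C;
    double *mc = m + (size_t)blk * C;
    for (int i = 0; i < C; ++i) mc[i] += xc[i];
  }
  for (R_xlen_t i = 0; i < (R_xlen_t)C * nb; ++i) m[i] /= L;
  return M;
}

// sum of dY * X per (window, channel): C x Nb (gradient wrt channel gates)
// [[Rcpp::export]]
NumericMatrix nn_block_dot(NumericMatrix X, NumericMatrix dY, int L) {
  const int C = X.nrow(), n = X.ncol(), nb = n / L;
  NumericMatrix M(C, nb);
  const double *x = REAL(X), *dy = REAL(dY);
  double *m = REAL(M);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *xc = x + (size_t)c * C;
    const double *dyc = dy + (size_t)c * C;
    double *mc = m + (size_t)blk * C;
    for (int i = 0; i < C; ++i) mc[i] += xc[i] * dyc[i];
  }
  return M;
}

// in-place Adam update; x, m, v are owned exclusively by the optimizer
// state and the network being trained
// [[Rcpp::export]]
void nn_adam_inplace(NumericVector x, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double t, double b1,
                     double b2, double eps) {
  const R_xlen_t n = x.size();
  double *xp = REAL(x), *mp = REAL(m), *vp = REAL(v);
  const double *gp = REAL(g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1.0 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
    xp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// add a per-(window, channel) offset to each length-L column block
// [[Rcpp::export]]
NumericMatrix nn_add_blocks(NumericMatrix X, NumericMatrix A, int L) {
  const int C = X.nrow(), n = X.ncol();
  NumericMatrix Y(C, n);
  const double *x = REAL(X), *a = REAL(A);
  double *y = REAL(Y);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *ac = a + (size_t)blk * C;
    const double *xc = x + (size_t)c * C;
    double *yc = y + (size_t)c * C;
    for (int i = 0; i < C; ++i) yc[i] = xc[i] + ac[i];
  }
  return Y;
}

// fused instance normalization: per-(window, channel) mean/variance over
// time, normalized output with per-channel affine
// [[Rcpp::export]]
List nn_inorm_fwd(NumericMatrix X, NumericVector gamma, NumericVector beta,
                  int L, double eps) {
  const int C = X.nrow(), n = X.ncol(), nb = n / L;
  NumericMatrix Y(C, n), Xhat(C, n), Inv(C, nb);
  const double *x = REAL(X), *g = REAL(gamma), *b = REAL(beta);
  double *y = REAL(Y), *xh = REAL(Xhat), *inv = REAL(Inv);
  std::vector<double> mu((size_t)C * nb, 0.0), v((size_t)C * nb, 0.0);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *xc = x + (size_t)c * C;
    double *m = mu.data() + (size_t)blk * C;
    for (int i = 0; i < C; ++i) m[i] += xc[i];
  }
  for (size_t i = 0; i < mu.size(); ++i) mu[i] /= L;
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *xc = x + (size_t)c * C;
    const double *m = mu.data() + (size_t)blk * C;
    double *vv = v.data() + (size_t)blk * C;
    for (int i = 0; i < C; ++i) {
      const double d = xc[i] - m[i];
      vv[i] += d * d;
    }
  }
  for (int blk = 0; blk < nb; ++blk)
    for (int i = 0; i < C; ++i)
      inv[(size_t)blk * C + i] =
        1.0 / std::sqrt(v[(size_t)blk * C + i] / L + eps);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *xc = x + (size_t)c * C;
    const double *m = mu.data() + (size_t)blk * C;
    const double *iv = inv + (size_t)blk * C;
    double *yc = y + (size_t)c * C;
    double *xhc = xh + (size_t)c * C;
    for (int i = 0; i < C; ++i) {
      xhc[i] = (xc[i] - m[i]) * iv[i];
      yc[i] = xhc[i] * g[i] + b[i];
    }
  }
  return List::create(Named("Y") = Y, Named("xhat") = Xhat,
                      Named("inv") = Inv);
}

// [[Rcpp::export]]
List nn_inorm_bwd(NumericMatrix dY, NumericVector gamma, NumericMatrix Xhat,
                  NumericMatrix Inv, int L) {
  const int C = dY.nrow(), n = dY.ncol(), nb = n / L;
  NumericMatrix dX(C, n);
  NumericVector dgamma(C), dbeta(C);
  const double *dy = REAL(dY), *g = REAL(gamma), *xh = REAL(Xhat),
               *inv = REAL(Inv);
  double *dx = REAL(dX), *dg = REAL(dgamma), *db = REAL(dbeta);
  std::vector<double> m1((size_t)C * nb, 0.0), m2((size_t)C * nb, 0.0);
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *dyc = dy + (size_t)c * C;
    const double *xhc = xh + (size_t)c * C;
    double *a = m1.data() + (size_t)blk * C;
    double *b2 = m2.data() + (size_t)blk * C;
    for (int i = 0; i < C; ++i) {
      const double dxh = dyc[i] * g[i];
      a[i] += dxh;
      b2[i] += dxh * xhc[i];
      dg[i] += dyc[i] * xhc[i];
      db[i] += dyc[i];
    }
  }
  for (size_t i = 0; i < m1.size(); ++i) { m1[i] /= L; m2[i] /= L; }
  for (int c = 0; c < n; ++c) {
    const int blk = c / L;
    const double *dyc = dy + (size_t)c * C;
    const double *xhc = xh + (size_t)c * C;
    const double *a = m1.data() + (size_t)blk * C;
    const double *b2 = m2.data() + (size_t)blk * C;
    const double *iv = inv + (size_t)blk * C;
    double *dxc = dx + (size_t)c * C;
    for (int i = 0; i < C; ++i)
      dxc[i] = iv[i] * (dyc[i] * g[i] - a[i] - xhc[i] * b2[i]);
  }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// channel-axis concatenation and its backward slices
// [[Rcpp::export]]
NumericMatrix nn_rbind2(NumericMatrix A, NumericMatrix B) {
  const int ca = A.nrow(), cb = B.nrow(), n = A.ncol();
  NumericMatrix Y(ca + cb, n);
  const double *a = REAL(A), *b = REAL(B);
  double *y = REAL(Y);
  for (int c = 0; c < n; ++c) {
    double *yc = y + (size_t)c * (ca + cb);
    std::copy(a + (size_t)c * ca, a + (size_t)(c + 1) * ca, yc);
    std::copy(b + (size_t)c * cb, b + (size_t)(c + 1) * cb, yc + ca);
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix nn_row_slice(NumericMatrix X, int from, int to) {
  const int C = X.nrow(), n = X.ncol(), m = to - from + 1;
  NumericMatrix Y(m, n);
  const double *x = REAL(X);
  double *y = REAL(Y);
  for (int c = 0; c < n; ++c)
    std::copy(x + (size_t)c * C + (from - 1),
              x + (size_t)c * C + to, y + (size_t)c * m);
  return Y;
}

// clamped logistic and its backward
// [[Rcpp::export]]
NumericMatrix nn_sigmoid_fwd(NumericMatrix X, double clamp) {
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  NumericMatrix Y(X.nrow(), X.ncol());
  const double *x = REAL(X);
  double *y = REAL(Y);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (v > clamp) v = clamp;
    if (v < -clamp) v = -clamp;
    y[i] = 1.0 / (1.0 + std::exp(-v));
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix nn_sigmoid_bwd(NumericMatrix Y, NumericMatrix dY) {
  const R_xlen_t n = (R_xlen_t)Y.nrow() * Y.ncol();
  NumericMatrix dX(Y.nrow(), Y.ncol());
  const double *y = REAL(Y), *dy = REAL(dY);
  double *dx = REAL(dX);
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = dy[i] * y[i] * (1.0 - y[i]);
  return dX;
}
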