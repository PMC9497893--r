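// Compute kernels for the hot paths: depthwise convolution, grouped
// pointwise convolution, batch-norm element passes and the swish family.
// Tensors are R arrays in N x H x W x C layout (column-major, N fastest):
// index n + N*(h + H*(w + W*c)).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x is an N*H*W x C column-major buffer viewed in place (m rows)
// [[Rcpp::export]]
NumericVector gconv_fwd_cpp(const NumericVector& x, int m,
                            const NumericMatrix& w,
                            const IntegerMatrix& idx, int fpg) {
  const int ch = idx.nrow(), G = idx.ncol();
  NumericVector y(static_cast<R_xlen_t>(m) * G * fpg);
  for (int g = 0; g < G; ++g)
    for (int j = 0; j < fpg; ++j) {
      double* yc = &y[static_cast<R_xlen_t>(m) * (g * fpg + j)];
      for (int c = 0; c < ch; ++c) {
        const double wv = w(g * fpg + j, c);
        const double* xc = &x[static_cast<R_xlen_t>(m) * (idx(c, g) - 1)];
        for (int n = 0; n < m; ++n) yc[n] += wv * xc[n];
      }
    }
  return y;
}

// [[Rcpp::export]]
List gconv_bwd_cpp(const NumericVector& x, int m, int C,
                   const NumericVector& dy, const NumericMatrix& w,
                   const IntegerMatrix& idx, int fpg) {
  const int ch = idx.nrow(), G = idx.ncol();
  NumericVector dx(static_cast<R_xlen_t>(m) * C);
  NumericMatrix dw(w.nrow(), w.ncol());
  for (int g = 0; g < G; ++g)
    for (int j = 0; j < fpg; ++j) {
      const double* dyc = &dy[static_cast<R_xlen_t>(m) * (g * fpg + j)];
      for (int c = 0; c < ch; ++c) {
        const double wv = w(g * fpg + j, c);
        const double* xc = &x[static_cast<R_xlen_t>(m) * (idx(c, g) - 1)];
        double* dxc = &dx[static_cast<R_xlen_t>(m) * (idx(c, g) - 1)];
        double acc = 0.0;
        for (int n = 0; n < m; ++n) {
          acc += dyc[n] * xc[n];
          dxc[n] += wv * dyc[n];
        }
        dw(g * fpg + j, c) = acc;
      }
    }
  return List::create(Named("dx") = dx, Named("dw") = dw);
}

// fused batch-norm forward: batch statistics (optional), normalise, scale
// [[Rcpp::export]]
List bn_fwd_fused_cpp(const NumericVector& x, int m,
                      const NumericVector& gamma, const NumericVector& beta,
                      const NumericVector& rmean, const NumericVector& rvar,
                      bool training, double eps) {
  const int C = gamma.size();
  NumericVector mu(C), var(C), istd(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[static_cast<R_xlen_t>(m) * c];
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < m; ++n) { s += xc[n]; s2 += xc[n] * xc[n]; }
      mu[c] = s / m;
      double v = s2 / m - mu[c] * mu[c];
      var[c] = v > 0 ? v : 0;
    }
  } else {
    mu = clone(rmean); var = clone(rvar);
  }
  NumericVector y(static_cast<R_xlen_t>(m) * C);
  NumericVector xhat(static_cast<R_xlen_t>(m) * C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(var[c] + eps);
    istd[c] = is;
    const double mc = mu[c], gc = gamma[c], bc = beta[c];
    const double* xc = &x[static_cast<R_xlen_t>(m) * c];
    double* xh = &xhat[static_cast<R_xlen_t>(m) * c];
    double* yc = &y[static_cast<R_xlen_t>(m) * c];
    for (int n = 0; n < m; ++n) {
      const double h = (xc[n] - mc) * is;
      xh[n] = h;
      yc[n] = gc * h + bc;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("istd") = istd, Named("mu") = mu,
                      Named("var") = var);
}

// [[Rcpp::export]]
NumericVector sigmoid_cpp(const NumericVector& x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = 1.0 / (1.0 + std::exp(-x[i]));
  return y;
}

// [[Rcpp::export]]
NumericVector swish_cpp(const NumericVector& x, double beta) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] / (1.0 + std::exp(-beta * x[i]));
  return y;
}

// [[Rcpp::export]]
NumericVector swish_grad_cpp(const NumericVector& x, double beta) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-beta * x[i]));
    y[i] = s * (1.0 + beta * x[i] * (1.0 - s));
  }
  return y;
}

// y = x * a[col] + b[col], columnwise on an m x C matrix
// [[Rcpp::export]]
NumericMatrix affine_cols_cpp(const NumericMatrix& xm, const NumericVector& a,
                              const NumericVector& b) {
  const int m = xm.nrow(), C = xm.ncol();
  NumericMatrix y(m, C);
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = &xm(0, c);
    double* yc = &y(0, c);
    for (int n = 0; n < m; ++n) yc[n] = xc[n] * ac + bc;
  }
  return y;
}

// batch-norm backward in one pass: given dy, xhat, per-channel gamma*istd,
// returns dx (training semantics), dgamma, dbeta
// [[Rcpp::export]]
List bn_bwd_cpp(const NumericMatrix& dym, const NumericMatrix& xhat,
                const NumericVector& gistd, bool training) {
  const int m = dym.nrow(), C = dym.ncol();
  NumericMatrix dx(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dym(0, c);
    const double* xc = &xhat(0, c);
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < m; ++n) { sg += dyc[n] * xc[n]; sb += dyc[n]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gistd[c];
    double* dxc = &dx(0, c);
    if (training) {
      const double mg = sg / m, mb = sb / m;
      for (int n = 0; n < m; ++n) dxc[n] = g * (dyc[n] - mb - xc[n] * mg);
    } else {
      for (int n = 0; n < m; ++n) dxc[n] = g * dyc[n];
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
NumericVector dw_fwd_cpp(const NumericVector& xp, const IntegerVector& xdim,
                         const NumericVector& w, int k, int stride,
                         int ho, int wo) {
  const int N = xdim[0], Hp = xdim[1], Wp = xdim[2], C = xdim[3];
  NumericVector y(static_cast<R_xlen_t>(N) * ho * wo * C);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const double wv = w[di + k * (dj + k * c)];
        for (int j = 0; j < wo; ++j) {
          const int jp = dj + stride * j;
          for (int i = 0; i < ho; ++i) {
            const int ip = di + stride * i;
            const double* xs = &xp[static_cast<R_xlen_t>(N) * (ip + static_cast<R_xlen_t>(Hp) * (jp + static_cast<R_xlen_t>(Wp) * c))];
            double* ys = &y[static_cast<R_xlen_t>(N) * (i + static_cast<R_xlen_t>(ho) * (j + static_cast<R_xlen_t>(wo) * c))];
            for (int n = 0; n < N; ++n) ys[n] += wv * xs[n];
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
List dw_bwd_cpp(const NumericVector& dy, const NumericVector& xp,
                const IntegerVector& xdim, const NumericVector& w,
                int k, int stride, int ho, int wo) {
  const int N = xdim[0], Hp = xdim[1], Wp = xdim[2], C = xdim[3];
  NumericVector dxp(static_cast<R_xlen_t>(N) * Hp * Wp * C);
  NumericVector dw(static_cast<R_xlen_t>(k) * k * C);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const double wv = w[di + k * (dj + k * c)];
        double acc = 0.0;
        for (int j = 0; j < wo; ++j) {
          const int jp = dj + stride * j;
          for (int i = 0; i < ho; ++i) {
            const int ip = di + stride * i;
            const double* xs = &xp[static_cast<R_xlen_t>(N) * (ip + static_cast<R_xlen_t>(Hp) * (jp + static_cast<R_xlen_t>(Wp) * c))];
            double* dxs = &dxp[static_cast<R_xlen_t>(N) * (ip + static_cast<R_xlen_t>(Hp) * (jp + static_cast<R_xlen_t>(Wp) * c))];
            const double* dys = &dy[static_cast<R_xlen_t>(N) * (i + static_cast<R_xlen_t>(ho) * (j + static_cast<R_xlen_t>(wo) * c))];
            for (int n = 0; n < N; ++n) {
              acc += dys[n] * xs[n];
              dxs[n] += wv * dys[n];
            }
          }
        }
        dw[di + k * (dj + k * c)] = acc;
      }
  return List::create(Named("dxp") = dxp, Named("dw") = dw);
}
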