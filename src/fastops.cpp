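// Fused elementwise kernels for the CNN engine. Feature maps are
// (C*npix x B) matrices with channel fastest; these kernels avoid the
// intermediate allocations R's vectorized arithmetic would create in the
// batch-norm and ReLU hot paths, and provide the im2col gather / col2im
// scatter-add as single passes.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix nn_relu_fwd(const NumericMatrix& X) {
  R_xlen_t n = X.size();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = x[i] > 0.0 ? x[i] : 0.0;
  return out;
}

// dY masked by the forward output (out > 0 iff the pre-activation was > 0)
// [[Rcpp::export]]
NumericMatrix nn_relu_bwd(const NumericMatrix& fwd_out, const NumericMatrix& dY) {
  R_xlen_t n = dY.size();
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* o = fwd_out.begin();
  const double* d = dY.begin();
  double* r = dX.begin();
  for (R_xlen_t i = 0; i < n; ++i) r[i] = o[i] > 0.0 ? d[i] : 0.0;
  return dX;
}

// [[Rcpp::export]]
NumericMatrix nn_add(const NumericMatrix& A, const NumericMatrix& B) {
  R_xlen_t n = A.size();
  if (B.size() != n) stop("nn_add: shape mismatch");
  NumericMatrix out(A.nrow(), A.ncol());
  const double* a = A.begin();
  const double* b = B.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = a[i] + b[i];
  return out;
}

// Training-mode batch norm: per-channel mean/var over batch + spatial, then
// one fused affine. Channel index cycles fastest through the matrix.
// [[Rcpp::export]]
List nn_bn_fwd_train(const NumericMatrix& X, int C,
                     const NumericVector& gamma, const NumericVector& beta,
                     double eps) {
  R_xlen_t n = X.size();
  R_xlen_t m = n / C;
  NumericVector mu(C), var(C), inv(C);
  const double* x = X.begin();
  double* muv = mu.begin();
  double* vv = var.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xj = x + j * C;
    for (int c = 0; c < C; ++c) {
      muv[c] += xj[c];
      vv[c] += xj[c] * xj[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    muv[c] /= m;
    vv[c] = vv[c] / m - muv[c] * muv[c];
    if (vv[c] < 0) vv[c] = 0;
    inv[c] = 1.0 / std::sqrt(vv[c] + eps);
  }
  NumericMatrix out(X.nrow(), X.ncol());
  double* o = out.begin();
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] * inv[c];
    b[c] = beta[c] - muv[c] * a[c];
  }
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xj = x + j * C;
    double* oj = o + j * C;
    for (int c = 0; c < C; ++c) oj[c] = xj[c] * a[c] + b[c];
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["var"] = var, _["inv"] = inv);
}

// [[Rcpp::export]]
NumericMatrix nn_bn_fwd_eval(const NumericMatrix& X, int C,
                             const NumericVector& gamma, const NumericVector& beta,
                             const NumericVector& mean, const NumericVector& var,
                             double eps) {
  R_xlen_t n = X.size();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* o = out.begin();
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] / std::sqrt(var[c] + eps);
    b[c] = beta[c] - mean[c] * a[c];
  }
  R_xlen_t m = n / C;
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xj = x + j * C;
    double* oj = o + j * C;
    for (int c = 0; c < C; ++c) oj[c] = xj[c] * a[c] + b[c];
  }
  return out;
}

// Batch-norm backward: two passes, no temporaries beyond the outputs.
// [[Rcpp::export]]
List nn_bn_bwd(const NumericMatrix& X, const NumericMatrix& dY, int C,
               const NumericVector& mu, const NumericVector& inv,
               const NumericVector& gamma) {
  R_xlen_t n = X.size();
  R_xlen_t m = n / C;
  NumericVector dgamma(C), dbeta(C);
  const double* x = X.begin();
  const double* d = dY.begin();
  double* dg = dgamma.begin();
  double* db = dbeta.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xj = x + j * C;
    const double* dj = d + j * C;
    for (int c = 0; c < C; ++c) {
      db[c] += dj[c];
      dg[c] += dj[c] * (xj[c] - mu[c]) * inv[c];
    }
  }
  NumericMatrix dX(dY.nrow(), dY.ncol());
  double* r = dX.begin();
  std::vector<double> a(C), mb(C), mg(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] * inv[c];
    mb[c] = db[c] / m;
    mg[c] = dg[c] / m;
  }
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* xj = x + j * C;
    const double* dj = d + j * C;
    double* rj = r + j * C;
    for (int c = 0; c < C; ++c) {
      double xhat = (xj[c] - mu[c]) * inv[c];
      rj[c] = a[c] * (dj[c] - mb[c] - xhat * mg[c]);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// im2col gather: out[i, b] = Xp[idx[i] - 1, b]
// [[Rcpp::export]]
NumericMatrix nn_gather(const NumericMatrix& Xp, const IntegerVector& idx) {
  R_xlen_t ni = idx.size();
  int B = Xp.ncol();
  R_xlen_t npr = Xp.nrow();
  NumericMatrix out(ni, B);
  const double* x = Xp.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * npr;
    double* ob = o + (R_xlen_t)b * ni;
    for (R_xlen_t i = 0; i < ni; ++i) ob[i] = xb[idx[i] - 1];
  }
  return out;
}

// col2im scatter-add: dXp[idx[i] - 1, b] += dcol[i, b]
// [[Rcpp::export]]
NumericMatrix nn_scatter_add(const NumericMatrix& dcol, const IntegerVector& idx,
                             int n_padded) {
  R_xlen_t ni = idx.size();
  int B = dcol.ncol();
  NumericMatrix out(n_padded, B);
  const double* d = dcol.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* db = d + (R_xlen_t)b * ni;
    double* ob = o + (R_xlen_t)b * n_padded;
    for (R_xlen_t i = 0; i < ni; ++i) ob[idx[i] - 1] += db[i];
  }
  return out;
}

// zero-padded copy: out[int_idx[i] - 1, b] = X[i, b]
// [[Rcpp::export]]
NumericMatrix nn_pad(const NumericMatrix& X, const IntegerVector& int_idx,
                     int n_padded) {
  R_xlen_t ni = int_idx.size();
  int B = X.ncol();
  NumericMatrix out(n_padded, B);
  const double* x = X.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * ni;
    double* ob = o + (R_xlen_t)b * n_padded;
    for (R_xlen_t i = 0; i < ni; ++i) ob[int_idx[i] - 1] = xb[i];
  }
  return out;
}

// Gaussian kernel density: f(g) = (1/(n h)) sum_j phi((g - v_j)/h)
// [[Rcpp::export]]
NumericVector kde_gauss(const NumericVector& values, const NumericVector& grid,
                        double h) {
  const double inv_h = 1.0 / h;
  const double norm = 0.3989422804014327 / (h * values.size()); // 1/sqrt(2*pi)
  R_xlen_t nv = values.size(), ng = grid.size();
  NumericVector out(ng);
  for (R_xlen_t g = 0; g < ng; ++g) {
    double acc = 0.0, gg = grid[g];
    for (R_xlen_t j = 0; j < nv; ++j) {
      double z = (gg - values[j]) * inv_h;
      acc += std::exp(-0.5 * z * z);
    }
    out[g] = acc * norm;
  }
  return out;
}
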