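#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// In-place SGD step theta -= lr * grad for a parameter matrix or vector.
// Callers must own the only reference to `theta` (train_fold deep-copies the
// model once before the update loop).
// [[Rcpp::export]]
void sgd_axpy(NumericVector theta, NumericVector grad, double lr) {
  R_xlen_t n = theta.size();
  if (grad.size() != n) stop("parameter/gradient length mismatch");
  double *t = REAL(theta);
  const double *g = REAL(grad);
  for (R_xlen_t i = 0; i < n; ++i) t[i] -= lr * g[i];
}

// Fused weight update W -= lr * t(X) %*% dZ (one dgemm, no gradient
// allocation). X is B x m, dZ is B x n, W is m x n.
// [[Rcpp::export]]
void sgd_gemm_update(NumericMatrix W, NumericMatrix X, NumericMatrix dZ,
                     double lr) {
  int B = X.nrow(), m = X.ncol(), n = dZ.ncol();
  if (dZ.nrow() != B || W.nrow() != m || W.ncol() != n)
    stop("dimension mismatch in fused weight update");
  double alpha = -lr, beta = 1.0;
  F77_CALL(dgemm)("T", "N", &m, &n, &B, &alpha, REAL(X), &B, REAL(dZ), &B,
                  &beta, REAL(W), &m FCONE FCONE);
}
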