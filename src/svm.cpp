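#include <Rcpp.h>
using namespace Rcpp;

// Linear two-class SVM trained by dual coordinate descent
// (L2-regularized, L1 hinge loss):
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
// The bias is handled as an augmented constant feature of value 1 (and is
// therefore weakly regularized), the usual linear-SVM convention. Updates
// sweep the training points in a fixed cyclic order with no randomization,
// so the fit is deterministic for a fixed input order.
//
// X: n x d training matrix, y: +1/-1 labels, C: cost, tol: stopping
// tolerance on the maximal projected gradient, max_iter: sweep cap.
// Returns a numeric vector of length d + 1: weights then bias.
// [[Rcpp::export]]
NumericVector svm_dcd(NumericMatrix X, NumericVector y, double C = 1.0,
                      double tol = 1e-4, int max_iter = 2000) {
  const int n = X.nrow();
  const int d = X.ncol();
  if (y.size() != n) stop("label length does not match training rows");

  std::vector<double> w(d + 1, 0.0);
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qdiag(n);
  for (int i = 0; i < n; ++i) {
    double q = 1.0;  // augmented bias feature
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    qdiag[i] = q;
  }

  for (int iter = 0; iter < max_iter; ++iter) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - g / qdiag[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
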