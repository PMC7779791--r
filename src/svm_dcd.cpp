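#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss linear SVM:
//   min_w 0.5*||w||^2 + sum_i C_i * max(0, 1 - y_i * w.x_i)
// Cyclic coordinate order (deterministic); bias is handled by the caller
// through an augmented constant feature. Returns the primal weight vector.
// [[Rcpp::export]]
List svm_dcd_fit(NumericMatrix X, NumericVector y, NumericVector Ci,
                 double tol, int max_passes) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> alpha(n, 0.0), w(p, 0.0), qii(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  int pass = 0;
  double max_pg = R_PosInf;
  for (pass = 0; pass < max_passes; ++pass) {
    max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double PG;
      if (alpha[i] <= 0.0)           PG = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= Ci[i])    PG = G > 0.0 ? G : 0.0;
      else                           PG = G;
      if (std::abs(PG) > max_pg) max_pg = std::abs(PG);
      if (std::abs(PG) > 1e-14 && qii[i] > 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > Ci[i]) a_new = Ci[i];
        if (a_new != a_old) {
          const double d = (a_new - a_old) * y[i];
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["passes"] = pass + 1,
                      _["max_pg"] = max_pg);
}
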