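// Dual coordinate descent for the L2-regularized L2-loss linear SVM
// (Hsieh et al., ICML 2008; the algorithm behind LIBLINEAR's default
// solver).  Deterministic: cyclic sweeps over instances, fixed tolerance.
//
// min_w  1/2 ||w||^2 + C * sum_i max(0, 1 - y_i w^T x_i)^2
//
// Dual: min_a 1/2 a^T (Q + D) a - e^T a,  a_i >= 0,  D_ii = 1/(2C).
// A bias term is handled by the caller augmenting X with a constant
// column (LIBLINEAR's -B 1 convention).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Xt: d x n (each column one training instance, bias row included)
// y: +1/-1 labels
// [[Rcpp::export]]
List svm_dcd(NumericMatrix Xt, NumericVector y, double C,
             double tol = 1e-3, int max_sweeps = 1000) {
  const int d = Xt.nrow(), n = Xt.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  const double diag = 1.0 / (2.0 * C);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* xi = &Xt(0, i);
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s + diag;
  }

  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double pg_max = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &Xt(0, i);
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      double G = y[i] * wx - 1.0 + diag * alpha[i];
      double PG = (alpha[i] == 0.0) ? std::min(G, 0.0) : G;
      if (std::fabs(PG) > pg_max) pg_max = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        alpha[i] = a_new;
        double step = (a_new - a_old) * y[i];
        if (step != 0.0)
          for (int j = 0; j < d; ++j) w[j] += step * xi[j];
      }
    }
    if (pg_max < tol) { ++sweep; break; }
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["sweeps"] = sweep);
}
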