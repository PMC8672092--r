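#include <Rcpp.h>
using namespace Rcpp;

// Per-sample SGD inner loop over pre-shuffled visit orders.
// xt: (p+1) x n matrix, each column a sample with the leading 1 for the bias.
// orders: n x epochs matrix of 1-based row visit orders (R's RNG stream).
// loss 0 = least-mean-squares on y, 1 = hinge subgradient on y in {-1, 1}.
// lambda: L2 shrinkage applied to every weight except the bias.
// [[Rcpp::export]]
List sgd_loop(NumericMatrix xt, NumericVector y, NumericVector theta0,
              IntegerMatrix orders, double alpha, double lambda, int loss,
              bool track_loss) {
  const int p1 = xt.nrow();
  const int n = xt.ncol();
  const int epochs = orders.ncol();
  NumericVector theta = clone(theta0);
  NumericVector trace(track_loss ? epochs : 0);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < n; ++r) {
      const int i = orders(r, ep) - 1;
      const double* xi = &xt(0, i);
      double h = 0.0;
      for (int j = 0; j < p1; ++j) h += theta[j] * xi[j];
      if (lambda > 0.0) {
        const double shrink = 1.0 - alpha * lambda;
        for (int j = 1; j < p1; ++j) theta[j] *= shrink;
      }
      if (loss == 0) {
        const double g = alpha * (h - y[i]);
        for (int j = 0; j < p1; ++j) theta[j] -= g * xi[j];
      } else if (y[i] * h < 1.0) {
        const double g = alpha * y[i];
        for (int j = 0; j < p1; ++j) theta[j] += g * xi[j];
      }
    }
    if (track_loss) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* xi = &xt(0, i);
        double h = 0.0;
        for (int j = 0; j < p1; ++j) h += theta[j] * xi[j];
        sse += (h - y[i]) * (h - y[i]);
      }
      trace[ep] = sse / (2.0 * n);
    }
  }
  return List::create(_["theta"] = theta, _["trace"] = trace);
}
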