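#include <Rcpp.h>
using namespace Rcpp;

// Causal cascade of biquad sections (direct form II transposed).
// sos: one row per section, columns b0 b1 b2 a0 a1 a2 with a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow();
  R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;  // zero initial state
    for (R_xlen_t i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
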