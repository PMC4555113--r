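#include <Rcpp.h>
using namespace Rcpp;

// Chi-squared cross-distance matrix between the rows of two non-negative
// matrices: out[i, k] = 0.5 * sum_j (x[i,j] - c[k,j])^2 / (x[i,j] + c[k,j]),
// with terms whose denominator is zero contributing zero (the limit as both
// entries vanish).  This is the inner loop of codebook learning and codeword
// assignment, so it lives in compiled code.
// [[Rcpp::export]]
NumericMatrix chi2_cross_cpp(NumericMatrix x, NumericMatrix c) {
  const int n = x.nrow(), k = c.nrow(), d = x.ncol();
  if (c.ncol() != d) stop("dimension mismatch: %d vs %d columns", d, c.ncol());
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int t = 0; t < d; ++t) {
        const double a = x(i, t), b = c(j, t);
        const double s = a + b;
        if (s > 0.0) {
          const double dif = a - b;
          acc += dif * dif / s;
        }
      }
      out(i, j) = 0.5 * acc;
    }
  }
  return out;
}
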