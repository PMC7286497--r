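#include <Rcpp.h>
using namespace Rcpp;

// Log-space forward recursion over a precomputed T x N log-emission matrix.
// Missing observations enter as log-emission 0 (likelihood factor 1).

// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logem, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logem.nrow(), N = logem.ncol();
  std::vector<double> alpha(N), anew(N);
  for (int j = 0; j < N; ++j) alpha[j] = logpi[j] + logem(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      double m = R_NegInf;
      for (int i = 0; i < N; ++i) {
        double v = alpha[i] + logA(i, j);
        if (v > m) m = v;
      }
      double lse;
      if (m == R_NegInf) {
        lse = R_NegInf;
      } else {
        double s = 0.0;
        for (int i = 0; i < N; ++i) s += std::exp(alpha[i] + logA(i, j) - m);
        lse = m + std::log(s);
      }
      anew[j] = lse + logem(t, j);
    }
    alpha = anew;
  }
  double m = R_NegInf;
  for (int j = 0; j < N; ++j) if (alpha[j] > m) m = alpha[j];
  if (m == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < N; ++j) s += std::exp(alpha[j] - m);
  return m + std::log(s);
}
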