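#include <Rcpp.h>
using namespace Rcpp;

// Iterate the MVAR recursion Y(t) = sum_l A_l Y(t-l) + E(t).
// coeffs: n x (n*p) matrix, [A_1 A_2 ... A_p] column-blocks.
// innovations: n x T matrix of pre-drawn noise (drawn in R so the R RNG
// governs reproducibility). Initial p columns of the state are zero.
// Returns n x T; stops with an error naming the first non-finite sample.
// [[Rcpp::export]]
NumericMatrix mvar_simulate_cpp(NumericMatrix coeffs,
                                NumericMatrix innovations, int p) {
  const int n = innovations.nrow();
  const int T = innovations.ncol();
  if (coeffs.nrow() != n || coeffs.ncol() != n * p)
    stop("coeffs must be n x (n*p)");
  NumericMatrix y(n, T);
  const double *cf = coeffs.begin();
  const double *in = innovations.begin();
  double *yp = y.begin();
  for (int t = 0; t < T; ++t) {
    double *yt = yp + (R_xlen_t)t * n;
    const double *et = in + (R_xlen_t)t * n;
    for (int i = 0; i < n; ++i) yt[i] = et[i];
    const int lmax = (p < t) ? p : t;
    for (int l = 1; l <= lmax; ++l) {
      const double *ylag = yp + (R_xlen_t)(t - l) * n;
      const double *cl = cf + (R_xlen_t)(l - 1) * n * n;
      for (int j = 0; j < n; ++j) {
        const double yj = ylag[j];
        if (yj == 0.0) continue;
        const double *cc = cl + (R_xlen_t)j * n;
        for (int i = 0; i < n; ++i) yt[i] += cc[i] * yj;
      }
    }
    for (int i = 0; i < n; ++i)
      if (!R_finite(yt[i]))
        stop("non-finite sample at channel %d, time index %d", i + 1, t + 1);
  }
  return y;
}
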