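#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// a: sub-diagonal (a[0] ignored), b: diagonal, c: super-diagonal (c[n-1]
// ignored), d: right-hand side. No pivoting: the IMEX transport matrices
// assembled in R are strictly diagonally dominant M-matrices, for which the
// unpivoted elimination is stable.
// [[Rcpp::export]]
NumericVector thomas_solve(NumericVector a, NumericVector b, NumericVector c,
                           NumericVector d) {
  int n = b.size();
  if (a.size() != n || c.size() != n || d.size() != n)
    stop("tridiagonal bands must have equal length");
  NumericVector cp(n), x(n);
  double m = b[0];
  if (m == 0.0) stop("singular tridiagonal system (zero pivot at row 1)");
  cp[0] = c[0] / m;
  x[0] = d[0] / m;
  for (int i = 1; i < n; ++i) {
    m = b[i] - a[i] * cp[i - 1];
    if (m == 0.0) stop("singular tridiagonal system (zero pivot at row " +
                       std::to_string(i + 1) + ")");
    cp[i] = c[i] / m;
    x[i] = (d[i] - a[i] * x[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
  return x;
}
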