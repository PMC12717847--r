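#include <Rcpp.h>
using namespace Rcpp;

// LDL^T factorisation of a symmetric positive-definite tridiagonal matrix
// given its diagonal d and subdiagonal e (e[i] couples rows i and i+1,
// length n-1). Returns the unit-lower subdiagonal l and the diagonal dd of D.
// [[Rcpp::export(name = ".tridiag_factor_cpp")]]
List tridiag_factor(NumericVector d, NumericVector e) {
  int n = d.size();
  NumericVector dd(n), l(n > 0 ? n - 1 : 0);
  dd[0] = d[0];
  for (int i = 1; i < n; ++i) {
    if (dd[i - 1] <= 0) stop("tridiagonal matrix is not positive definite");
    l[i - 1] = e[i - 1] / dd[i - 1];
    dd[i] = d[i] - l[i - 1] * e[i - 1];
  }
  return List::create(_["l"] = l, _["d"] = dd);
}

// Solve (L D L^T) X = B column-wise for the factor above.
// [[Rcpp::export(name = ".tridiag_solve_cpp")]]
NumericMatrix tridiag_solve(NumericVector l, NumericVector dd,
                            NumericMatrix B) {
  int n = B.nrow(), m = B.ncol();
  NumericMatrix X(n, m);
  for (int j = 0; j < m; ++j) {
    // forward: L z = b
    X(0, j) = B(0, j);
    for (int i = 1; i < n; ++i) X(i, j) = B(i, j) - l[i - 1] * X(i - 1, j);
    // diagonal
    for (int i = 0; i < n; ++i) X(i, j) /= dd[i];
    // backward: L^T x = z
    for (int i = n - 2; i >= 0; --i) X(i, j) -= l[i] * X(i + 1, j);
  }
  return X;
}
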