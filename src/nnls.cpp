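// Lawson-Hanson active-set non-negative least squares.
// Used per voxel for dictionary fitting; A is tall (volumes + ridge rows).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::vec nnls_solve(const arma::mat& A, const arma::vec& b,
                     const double tol = 1e-10, const int max_iter = 0) {
  const arma::uword n = A.n_cols;
  int maxit = max_iter > 0 ? max_iter : 3 * static_cast<int>(n);

  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec w = A.t() * (b - A * x);

  int outer = 0;
  while (outer++ < maxit) {
    // most violated KKT multiplier among the zero set
    double wmax = tol;
    arma::sword jmax = -1;
    for (arma::uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (jmax < 0) break;
    passive[jmax] = true;

    for (;;) {
      arma::uvec P(n);
      arma::uword np = 0;
      for (arma::uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      arma::vec z;
      if (!arma::solve(z, A.cols(P), b)) {
        // rank-deficient passive set: drop the entering variable
        passive[jmax] = false;
        break;
      }
      if (z.min() > 0) {
        x.zeros();
        x(P) = z;
        break;
      }
      // step toward z until the first passive variable hits zero
      double alpha = 1.0;
      for (arma::uword k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (arma::uword k = 0; k < np; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      for (arma::uword k = 0; k < np; ++k)
        if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}
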