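#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the penalised least-squares objective
//   f(b) = ||y - X b||^2 + lambda2 ||b||^2 + lambda1 ||b||_1
// worked in the Gram domain: only XtX = X'X and Xty = X'y are needed, so the
// per-sweep cost is O(p^2) regardless of n. Stationarity per coordinate gives
//   b_j = S(r_j, lambda1 / 2) / (XtX_jj + lambda2),
// with r_j the partial residual correlation and S the soft-threshold.
static void cd_solve(const double *xtx, const double *xty, int p,
                     double lambda1, double lambda2, double *beta,
                     int maxit, double tol) {
  const double thr = lambda1 / 2.0;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double r = xty[j];
      const double *col = xtx + (std::size_t)j * p; // symmetric: col = row
      for (int k = 0; k < p; ++k)
        if (k != j) r -= col[k] * beta[k];
      double denom = col[j] + lambda2;
      double bj;
      if (r > thr)
        bj = (r - thr) / denom;
      else if (r < -thr)
        bj = (r + thr) / denom;
      else
        bj = 0.0;
      double d = std::abs(bj - beta[j]);
      if (d > delta) delta = d;
      beta[j] = bj;
    }
    if (delta < tol) break;
  }
}

// [[Rcpp::export]]
NumericVector elnet_gram_cd(NumericMatrix XtX, NumericVector Xty,
                            double lambda1, double lambda2,
                            int maxit = 100000, double tol = 1e-12) {
  int p = Xty.size();
  if (XtX.nrow() != p || XtX.ncol() != p)
    stop("XtX must be %d x %d", p, p);
  NumericVector beta(p);
  cd_solve(XtX.begin(), Xty.begin(), p, lambda1, lambda2, beta.begin(),
           maxit, tol);
  return beta;
}

// Solve along a grid of (lambda1, lambda2) pairs with warm starts; pairs are
// given as parallel vectors and solved in order, each initialised at the
// previous solution. Returns a p x n_grid coefficient matrix.
// [[Rcpp::export]]
NumericMatrix elnet_gram_path(NumericMatrix XtX, NumericVector Xty,
                              NumericVector lambda1, NumericVector lambda2,
                              int maxit = 100000, double tol = 1e-12) {
  int p = Xty.size();
  int g = lambda1.size();
  if (lambda2.size() != g)
    stop("lambda1 and lambda2 must have equal length");
  if (XtX.nrow() != p || XtX.ncol() != p)
    stop("XtX must be %d x %d", p, p);
  NumericMatrix B(p, g);
  std::vector<double> beta(p, 0.0);
  for (int m = 0; m < g; ++m) {
    cd_solve(XtX.begin(), Xty.begin(), p, lambda1[m], lambda2[m],
             beta.data(), maxit, tol);
    for (int j = 0; j < p; ++j) B(j, m) = beta[j];
  }
  return B;
}
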