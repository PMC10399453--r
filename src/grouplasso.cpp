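#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Block coordinate descent for the group LASSO objective
//   (1/2n) ||y - X b||^2 + lambda * sum_g w_g ||b_g||_2
// on a design whose columns are orthonormalized within each group
// (X_g' X_g / n = I), which makes the per-group update a closed-form
// group soft-threshold.  Solutions are computed along a decreasing
// lambda path with warm starts.
// grp is 0-based, one entry per column; wg one entry per group.
// [[Rcpp::export]]
List grplasso_path_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& grp, const arma::vec& wg,
                       const arma::vec& lambdas, double tol, int maxit) {
  const int n = X.n_rows, m = X.n_cols;
  const int L = lambdas.n_elem, G = wg.n_elem;
  std::vector< std::vector<int> > gi(G);
  for (int j = 0; j < m; ++j) gi[grp[j]].push_back(j);

  arma::mat B(m, L, arma::fill::zeros);
  arma::vec beta(m, arma::fill::zeros);
  arma::vec r = y;                       // residual y - X beta
  IntegerVector iters(L);
  LogicalVector conv(L);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    double delta = R_PosInf;
    int it = 0;
    for (; it < maxit; ++it) {
      delta = 0.0;
      for (int g = 0; g < G; ++g) {
        const std::vector<int>& cols = gi[g];
        const int pg = cols.size();
        arma::vec z(pg), old(pg);
        for (int a = 0; a < pg; ++a) {
          old[a] = beta[cols[a]];
          z[a] = arma::dot(X.col(cols[a]), r) / n + old[a];
        }
        const double zn = arma::norm(z, 2);
        const double thr = lam * wg[g];
        const double shrink = (zn > thr) ? (1.0 - thr / zn) : 0.0;
        for (int a = 0; a < pg; ++a) {
          const double nb = shrink * z[a];
          const double d = old[a] - nb;
          if (d != 0.0) {
            r += X.col(cols[a]) * d;
            beta[cols[a]] = nb;
            const double ad = std::fabs(d);
            if (ad > delta) delta = ad;
          }
        }
      }
      if (delta < tol) { ++it; break; }
    }
    iters[l] = it;
    conv[l] = (delta < tol);
    B.col(l) = beta;
  }
  return List::create(_["beta"] = B, _["iters"] = iters,
                      _["converged"] = conv);
}
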