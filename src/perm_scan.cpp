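// Compiled inner loop of the adaptive permutation scan.
//
// One permutation of the sample labels is applied jointly to the
// residualized phenotype and the covariate basis (equivalent to permuting
// the genotype rows against the fixed phenotype/covariate pairing); the
// window minimum p-value is recovered from the maximum of num^2/gss across
// variants, which is monotone in t^2 at fixed residual df.
//
// Permutations are drawn from R's RNG (Fisher-Yates with unif_rand), so a
// set.seed() on the R side makes the stream reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
int perm_scan_batch(const arma::mat& M,    // n x (k+2): [y_r, Q]
                    const arma::mat& G,    // n x m window dosages
                    const arma::rowvec& G2,// colSums(G^2)
                    double yss, int df, double tol,
                    double observed_min_p, int n_perm) {
  const arma::uword n = M.n_rows;
  arma::uvec idx(n);
  int exceed = 0;
  GetRNGstate();
  for (int b = 0; b < n_perm; ++b) {
    for (arma::uword i = 0; i < n; ++i) idx[i] = i;
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = (arma::uword)(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1.0
      std::swap(idx[i], idx[j]);
    }
    arma::mat A = M.rows(idx).t() * G;            // (k+2) x m
    arma::rowvec num = A.row(0);
    arma::rowvec gss = G2;
    if (A.n_rows > 1)
      gss -= arma::sum(arma::square(A.rows(1, A.n_rows - 1)), 0);
    double mx = 0.0;
    for (arma::uword v = 0; v < gss.n_elem; ++v) {
      if (gss[v] > tol) {
        double s = num[v] * num[v] / gss[v];
        if (s > mx) mx = s;
      }
    }
    double denom = yss - mx;
    if (denom < DBL_EPSILON) denom = DBL_EPSILON;
    double t2 = mx * df / denom;
    double pmin = 2.0 * R::pt(-std::sqrt(t2), (double)df, 1, 0);
    if (pmin <= observed_min_p) ++exceed;
  }
  PutRNGstate();
  return exceed;
}
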