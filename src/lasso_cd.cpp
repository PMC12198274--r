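#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double soft_threshold(double z, double lambda) {
  if (z > lambda) return z - lambda;
  if (z < -lambda) return z + lambda;
  return 0.0;
}

// Coordinate-descent LASSO over a decreasing lambda path, Gram form.
//
// Minimizes (1/2n)||y - Xb||^2 + lambda ||b||_1 given G = X'X/n and
// xty = X'y/n. Warm starts along the path; full sweeps until the maximum
// coefficient change falls below tol.
//
// [[Rcpp::export]]
arma::mat lasso_cd_gram(const arma::mat& G,
                        const arma::vec& xty,
                        const arma::vec& lambdas,
                        double tol = 1e-8,
                        int max_iter = 100000) {
  const arma::uword p = xty.n_elem;
  const arma::uword L = lambdas.n_elem;
  arma::mat beta_path(p, L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  // residual inner products: r_j = xty_j - (G beta)_j, maintained incrementally
  arma::vec gb(p, arma::fill::zeros);

  for (arma::uword l = 0; l < L; ++l) {
    const double lambda = lambdas(l);
    for (int it = 0; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0.0) { beta(j) = 0.0; continue; }
        const double z = xty(j) - gb(j) + gjj * beta(j);
        const double bj_new = soft_threshold(z, lambda) / gjj;
        const double delta = bj_new - beta(j);
        if (delta != 0.0) {
          gb += delta * G.col(j);
          beta(j) = bj_new;
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) break;
    }
    beta_path.col(l) = beta;
  }
  return beta_path;
}
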