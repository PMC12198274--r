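#' Penalized least-squares path by coordinate descent
#'
#' Solves `min_b (1/2n)||y - X b||^2 + lambda ||b||_1` for a decreasing
#' sequence of penalties, with warm starts. The response must be centered
#' and the design columns centered and scaled (use [standardize_cols()]);
#' constant columns must have been dropped beforehand. Iteration stops when
#' the largest coefficient change in a full sweep falls below `tol`.
#'
#' @param y Centered numeric response.
#' @param X Standardized design matrix (columns mean 0, variance 1 with
#'   denominator n).
#' @param lambdas Decreasing penalty sequence; defaults to `nlambda`
#'   log-spaced values from `lambda_max = max_j |x_j' y| / n` down to
#'   `lambda_max * lambda_min_ratio`.
#' @param nlambda,lambda_min_ratio Path length and range used when
#'   `lambdas` is `NULL`.
#' @param tol Convergence tolerance on the maximum coefficient change.
#'
#' @return List with `lambdas`, `beta` (p x length(lambdas) coefficient
#'   matrix), `rss` (residual sum of squares per penalty) and `df` (number
#'   of nonzero coefficients per penalty).
#' @export
lasso_path <- function(y, X, lambdas = NULL, nlambda = 50,
                       lambda_min_ratio = 1e-4, tol = 1e-8) {
  X <- as.matrix(X)
  if (!all(is.finite(y)) || !all(is.finite(X))) abort("non-finite inputs.")
  n <- length(y)
  stopifnot(nrow(X) == n)
  G <- crossprod(X) / n
  xty <- drop(crossprod(X, y)) / n
  if (is.null(lambdas)) {
    lmax <- max(abs(xty))
    if (lmax <= 0) lmax <- 1e-3
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  }
  if (length(lambdas) > 1 && any(diff(lambdas) >= 0)) {
    abort("`lambdas` must be strictly decreasing.")
  }
  beta <- lasso_cd_gram(G, xty, lambdas, tol = tol)
  resid <- matrix(y, n, length(lambdas)) - X %*% beta
  list(
    lambdas = lambdas,
    beta = beta,
    rss = colSums(resid^2),
    df = colSums(beta != 0)
  )
}

#' Extended Bayesian information criterion
#'
#' `n * log(rss / n) + k * log(n) + 2 * gamma * k * log(P)` for a Gaussian
#' regression with `k` selected out of `P` candidate predictors. `gamma = 0`
#' recovers the ordinary BIC; `gamma = 0.5` (the package default) adds the
#' model-space penalty appropriate for high-dimensional selection.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k Number of nonzero coefficients.
#' @param P Number of candidate predictors, `P >= max(k, 1)`.
#' @param gamma Nonnegative EBIC hyperparameter.
#'
#' @return The EBIC score (smaller is better).
#' @export
#' @examples
#' ebic(rss = 50, n = 100, k = 3, P = 40, gamma = 0.5)
ebic <- function(rss, n, k, P, gamma = 0.5) {
  if (any(rss <= 0)) abort("rss must be > 0 (degenerate saturated fit).")
  stopifnot(n > 0, all(k >= 0), P >= max(k, 1), gamma >= 0)
  n * log(rss / n) + k * log(n) + 2 * gamma * k * log(P)
}

# Index of the EBIC-minimizing penalty on a lasso path; ties broken toward
# the larger penalty (sparser model). Penalties whose fit is numerically
# saturated (rss ~ 0) are excluded.
select_ebic <- function(fit, n, P, gamma) {
  ok <- fit$rss > 1e-10
  if (!any(ok)) abort("all path fits are saturated; cannot score EBIC.")
  scores <- rep(Inf, length(fit$rss))
  scores[ok] <- ebic(fit$rss[ok], n, fit$df[ok], P, gamma)
  which.min(scores)
}

#' Center and scale matrix columns
#'
#' Columns are centered and scaled to variance 1 with denominator `n` (so
#' `crossprod(x) / n` has a unit diagonal). Constant columns cannot be
#' scaled and are dropped, with their names recorded in the `"dropped"`
#' attribute.
#'
#' @param X Numeric matrix.
#' @return The standardized matrix, possibly with fewer columns.
#' @export
standardize_cols <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))
  keep <- s > 1e-12
  out <- sweep(Xc[, keep, drop = FALSE], 2, s[keep], "/")
  attr(out, "dropped") <- colnames(X)[!keep]
  out
}
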