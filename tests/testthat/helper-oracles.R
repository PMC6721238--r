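# Independent oracles and small fixtures used across the suite.

# Brute-force pairwise concentration index for UNWEIGHTED samples with
# distinct ranking values: counts, for every ordered pair, the outcome of
# the richer unit. Derived from the Gini-covariance double-sum form;
# independent of the covariance implementation.
pairwise_ci <- function(y, ranking) {
  n <- length(y)
  rk <- rank(ranking)
  p_sum <- 0
  for (i in seq_len(n)) {
    p_sum <- p_sum + y[i] * sum(rk < rk[i])
  }
  2 * p_sum / (n^2 * mean(y)) + 1 / n - 1
}

# Direct weighted-covariance CI computed from first principles (normalised
# weights, midpoint ranks supplied by the caller).
cov_formula_ci <- function(y, ranks, w) {
  wn <- w / sum(w)
  ybar <- sum(wn * y)
  2 * sum(wn * (y - ybar) * (ranks - sum(wn * ranks))) / ybar
}

# Convenient-regression point estimate: WLS slope of y on ranks mapped
# through 2 * var_w(R) / ybar.
regression_ci <- function(y, ranks, w) {
  fit <- stats::lm(y ~ ranks, weights = w)
  wn <- w / sum(w)
  rbar <- sum(wn * ranks)
  s2r <- sum(wn * (ranks - rbar)^2)
  2 * s2r * unname(stats::coef(fit)[2]) / sum(wn * y)
}

# Tiny generator configuration for fast tests.
quick_config <- function(n = 1500, seed = 1, profile = "2005-like", ...) {
  synthetic_config(n = n, year_profile = profile, seed = seed, ...)
}

# Weighted probit log-likelihood and score, for gradient/oracle checks.
probit_loglik <- function(beta, y, X, w) {
  eta <- drop(X %*% beta)
  sum(w * (y * pnorm(eta, log.p = TRUE) + (1 - y) * pnorm(-eta, log.p = TRUE)))
}

probit_score <- function(beta, y, X, w) {
  eta <- drop(X %*% beta)
  lam <- ifelse(y == 1, dnorm(eta) / pnorm(eta), -dnorm(eta) / pnorm(-eta))
  drop(crossprod(X, w * lam))
}
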