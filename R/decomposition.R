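#' Weighted probit model for binary utilization
#'
#' Fits \eqn{P(y_i = 1 \mid x_i) = \Phi(x_i'\beta)} by weighted maximum
#' likelihood (delegated to [stats::glm()] with a probit link; sampling
#' weights enter the log likelihood as case weights).
#'
#' @param data Data frame with outcome and covariates.
#' @param formula Model formula, e.g. `outpatient_use ~ lpinco + chronic`.
#' @param weights Unquoted column of positive sampling weights; omit for
#'   equal weights.
#' @return An object of class `probit_fit`: `coefficients`, `vcov`
#'   (inverse-information covariance), `log_likelihood`, `converged`, `n`,
#'   the weighted covariate means `x_means`, and the underlying `glm` fit.
#' @seealso [partial_effects_at_means()], [decompose_ci()]
#' @export
fit_probit <- function(data, formula, weights = NULL) {
  wq <- rlang::enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, nrow(data)) else dplyr::pull(data, !!wq)
  check_positive_weights(w, "fit_probit")
  df <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = df)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) {
    abort_ui("Outcome must be binary 0/1.", "utilineq_error_domain")
  }
  if (length(unique(y)) < 2L) {
    abort_ui("Outcome is constant; the probit model is degenerate.",
             "utilineq_error_degenerate_outcome")
  }
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    abort_ui("Design matrix is rank deficient.", "utilineq_error_rank_deficient")
  }
  df$.w <- w
  fit <- suppressWarnings(stats::glm(
    formula, data = df, weights = .w,
    family = stats::binomial(link = "probit"),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  # polish with Newton steps on the exact weighted likelihood so the score
  # vanishes to machine precision and the covariance is the inverse
  # observed information
  beta <- coef(fit)
  info <- NULL
  for (it in 1:8) {
    eta <- drop(X %*% beta)
    lam <- ifelse(y == 1, stats::dnorm(eta) / stats::pnorm(eta),
                  -stats::dnorm(eta) / stats::pnorm(-eta))
    score <- drop(crossprod(X, w * lam))
    info <- crossprod(X, X * (w * lam * (lam + eta)))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta <- beta + step
    if (max(abs(step)) < 1e-12 * max(1, max(abs(beta)))) break
  }
  eta <- drop(X %*% beta)
  p <- stats::pnorm(eta)
  if (any(p[y == 1] > 1 - 1e-10) && any(p[y == 0] < 1e-10) &&
      max(abs(beta)) > 50) {
    abort_ui("Perfect separation detected in the probit fit.",
             "utilineq_error_separation")
  }
  ll <- sum(w * (y * stats::pnorm(eta, log.p = TRUE) +
                   (1 - y) * stats::pnorm(-eta, log.p = TRUE)))
  structure(
    list(
      coefficients = beta,
      vcov = solve(info),
      log_likelihood = ll,
      converged = fit$converged,
      n = nrow(X),
      x_means = drop(crossprod(X, w)) / sum(w),
      formula = formula,
      glm = fit
    ),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Weighted probit fit (n = ", x$n, ", logLik = ",
      round(x$log_likelihood, 2), ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, converged = x$converged,
                 nobs = x$n)
}

#' Probit partial effects evaluated at sample means
#'
#' For each regressor the partial effect at the (weighted) sample means is
#' \eqn{\beta_k^m = \beta_k\,\phi(\bar x'\beta)}: the latent-index
#' coefficient scaled by the standard normal density at the mean linear
#' index. The derivative formula is applied uniformly to continuous and
#' indicator regressors (set `discrete = TRUE` for discrete-change effects
#' of 0/1 dummies instead).
#'
#' @param fit A `probit_fit`.
#' @param x_means Weighted covariate means (including the intercept column);
#'   defaults to the means stored in the fit.
#' @param discrete If `TRUE`, dummies (columns whose name is flagged in
#'   `dummy_cols`) get the discrete change \eqn{\Phi(\cdot|x_k=1)-\Phi(\cdot|x_k=0)}.
#' @param dummy_cols Character vector of regressor names to treat as 0/1
#'   dummies when `discrete = TRUE`.
#' @return Named numeric vector of partial effects.
#' @export
partial_effects_at_means <- function(fit, x_means = NULL, discrete = FALSE,
                                     dummy_cols = character()) {
  b <- fit$coefficients
  if (is.null(x_means)) x_means <- fit$x_means
  if (length(x_means) != length(b)) {
    abort_ui("`x_means` is not conformable with the coefficient vector.",
             "utilineq_error_dimension")
  }
  m <- sum(x_means * b)
  pe <- b * stats::dnorm(m)
  if (discrete && length(dummy_cols)) {
    for (k in intersect(dummy_cols, names(b))) {
      j <- match(k, names(b))
      m0 <- m - x_means[j] * b[j]
      pe[j] <- stats::pnorm(m0 + b[j]) - stats::pnorm(m0)
    }
  }
  pe
}

#' Concentration index of each regressor over the income ranks
#'
#' Computes the standard (uncorrected) concentration index
#' \eqn{CI_k = 2\,\mathrm{cov}_w(x_k, R)/\bar x_k} for every column of a
#' design matrix. Columns with zero weighted mean have an undefined CI and
#' are returned as `NA` with a warning.
#'
#' @param design Numeric design matrix (one column per regressor).
#' @param ranks Fractional income ranks from [weighted_fractional_rank()]
#'   on the same sample.
#' @param weights Positive weights (default equal).
#' @return Named numeric vector of per-regressor concentration indices.
#' @export
covariate_concentration <- function(design, ranks, weights = NULL) {
  design <- as.matrix(design)
  if (is.null(weights)) weights <- rep(1, nrow(design))
  check_positive_weights(weights, "covariate_concentration")
  means <- drop(crossprod(design, weights)) / sum(weights)
  covs <- apply(design, 2, function(col) wcov(col, ranks, weights))
  ci <- 2 * covs / means
  zero <- abs(means) < 1e-12
  if (any(zero)) {
    warning("CI undefined for zero-mean regressor(s): ",
            paste(colnames(design)[zero], collapse = ", "))
    ci[zero] <- NA_real_
  }
  ci
}

#' Decompose the Erreygers-corrected concentration index
#'
#' Splits income-related inequality in a binary utilization outcome into the
#' parts attributable to each model covariate plus a residual:
#' \deqn{E = 4\sum_k (\beta_k^m \bar x_k)\,CI_k + GCI_\epsilon,}
#' where \eqn{\beta_k^m} is the probit partial effect at the sample means,
#' \eqn{\bar x_k} the weighted covariate mean, \eqn{CI_k} the covariate's
#' concentration index over the income ranks, and \eqn{GCI_\epsilon} the
#' Erreygers-scaled generalized CI of the model residual. A covariate
#' contributes strongly when it both moves utilization (large elasticity
#' \eqn{\beta_k^m \bar x_k}) and is unequally distributed over income
#' (large \eqn{CI_k}).
#'
#' The residual is computed as \eqn{4\times} the generalized CI of
#' \eqn{y - \phi(\bar x'\beta)\,x'\beta}; by linearity of the weighted
#' covariance this makes the additivity identity hold to machine precision.
#' The generalized CI of the nonlinear residual
#' \eqn{y - \Phi(x'\beta)} is also reported (as `residual_gci`), for
#' comparison with the linearised term.
#'
#' @param data One survey stratum (one sex, one survey year).
#' @param formula Probit model formula; the income-rank variable (e.g.
#'   `lpinco`) should be among the regressors.
#' @param ranker Unquoted column holding the continuous ranking variable
#'   (equivalised income) used for the fractional ranks.
#' @param weights Unquoted sampling-weight column; omit for equal weights.
#' @param fit Optionally, a pre-computed `probit_fit` for `formula` on
#'   `data` (refitted when `NULL`).
#' @return An object of class `ci_decomposition`: a tibble with one row per
#'   regressor (columns `term`, `coefficient`, `std.error`, `p.value`,
#'   `stars`, `partial_effect`, `mean`, `elasticity`, `ci_k`,
#'   `contribution`) and attributes `total` (Erreygers E of the outcome),
#'   `residual` (linearised residual term), `residual_gci`, `mean_outcome`,
#'   `n`, and `fit`.
#' @examples
#' cfg <- synthetic_config(n = 800, seed = 7)
#' pop <- generate_population(cfg)
#' dec <- decompose_ci(
#'   dplyr::mutate(pop, lpinco = log(true_income_equivalised)),
#'   outpatient_use ~ lpinco + chronic_disease,
#'   ranker = true_income_equivalised, weights = weight
#' )
#' tidy(dec)
#' @export
decompose_ci <- function(data, formula, ranker, weights = NULL, fit = NULL) {
  wq <- rlang::enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, nrow(data)) else dplyr::pull(data, !!wq)
  if (is.null(fit)) fit <- fit_probit(data, formula, weights = {{ weights }})
  df <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = df)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  rk_var <- dplyr::pull(data, {{ ranker }})
  ranks <- weighted_fractional_rank(rk_var, w)

  b <- fit$coefficients
  xbar <- fit$x_means
  pe <- partial_effects_at_means(fit)
  elas <- pe * xbar
  covs <- apply(X, 2, function(col) wcov(col, ranks, w))
  ci_k <- ifelse(abs(xbar) < 1e-12, NA_real_, 2 * covs / xbar)
  # contribution via the covariance form 8 * pe_k * cov_w(x_k, R): defined
  # even for zero-mean columns and equal to 4 * elasticity * CI_k otherwise
  contrib <- 8 * pe * covs

  ybar <- wmean(y, w)
  total_e <- erreygers_correct(ci_core(y, ranks, w), ybar)
  lin_resid <- y - stats::dnorm(sum(xbar * b)) * drop(X %*% b)
  residual <- 4 * generalized_ci(lin_resid, ranks, w)
  gen_resid <- y - stats::pnorm(drop(X %*% b))
  residual_gci <- 4 * generalized_ci(gen_resid, ranks, w)

  se <- sqrt(diag(fit$vcov))
  p <- 2 * stats::pnorm(-abs(b / se))
  keep <- colnames(X) != "(Intercept)"
  rows <- tibble::tibble(
    term = colnames(X),
    coefficient = unname(b),
    std.error = unname(se),
    p.value = unname(p),
    stars = significance_stars(unname(p)),
    partial_effect = unname(pe),
    mean = unname(xbar),
    elasticity = unname(elas),
    ci_k = unname(ci_k),
    contribution = unname(contrib)
  )[keep, ]
  structure(rows,
            class = c("ci_decomposition", class(rows)),
            total = total_e,
            residual = residual,
            residual_gci = residual_gci,
            mean_outcome = ybar,
            n = length(y),
            fit = fit)
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @export
print.ci_decomposition <- function(x, ...) {
  cat("Decomposition of Erreygers-corrected concentration index",
      sprintf("(n = %d)\n", attr(x, "n")))
  cat(sprintf("  total E = %.4f, residual = %.4f\n",
              attr(x, "total"), attr(x, "residual")))
  NextMethod()
}

#' @method tidy ci_decomposition
#' @export
tidy.ci_decomposition <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ci_decomposition")
  for (a in c("total", "residual", "residual_gci", "mean_outcome", "n", "fit"))
    attr(out, a) <- NULL
  out
}

#' @method glance ci_decomposition
#' @export
glance.ci_decomposition <- function(x, ...) {
  tibble::tibble(
    total_corrected_ci = attr(x, "total"),
    residual = attr(x, "residual"),
    residual_gci = attr(x, "residual_gci"),
    explained = sum(x$contribution),
    mean_outcome = attr(x, "mean_outcome"),
    nobs = attr(x, "n")
  )
}

#' @describeIn decompose_ci Horizontal bar chart of per-covariate
#'   contributions to the corrected concentration index.
#' @param object A `ci_decomposition`.
#' @param ... Unused.
#' @method autoplot ci_decomposition
#' @export
autoplot.ci_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$term <- stats::reorder(d$term, d$contribution)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contribution, y = .data$term,
                                  fill = .data$contribution > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac")) +
    ggplot2::labs(
      x = "Contribution to corrected concentration index",
      y = NULL,
      title = "Decomposition of income-related inequality",
      subtitle = sprintf("Total E = %.4f, residual = %.4f",
                         attr(object, "total"), attr(object, "residual"))
    ) +
    ggplot2::theme_minimal()
}
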