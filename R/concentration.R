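#' Weighted fractional ranks
#'
#' Computes the fractional rank of each unit in the income (or other
#' socioeconomic) distribution: after sorting by `x`, each unit's rank is the
#' cumulative weight share of all strictly poorer units plus half its own
#' weight share, so ranks lie strictly inside (0, 1) and have weighted mean
#' exactly 0.5. Ties all receive the midpoint rank of their tied block, which
#' makes downstream indices invariant to the ordering of tied records.
#'
#' @param x Numeric ranking variable (e.g. equivalised income).
#' @param weights Positive sampling weights, recycled to `length(x)` if
#'   scalar. Defaults to equal weights.
#' @return Numeric vector of ranks in (0, 1), in the original order of `x`.
#' @examples
#' weighted_fractional_rank(c(3, 1, 2))           # 0.8333 0.1667 0.5
#' weighted_fractional_rank(1:3, c(1, 2, 1))      # 0.125 0.5 0.875
#' @export
weighted_fractional_rank <- function(x, weights = NULL) {
  if (length(x) == 0L) {
    abort_ui("Cannot rank an empty vector.", "utilineq_error_domain")
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) == 1L) weights <- rep(weights, length(x))
  if (length(weights) != length(x)) {
    abort_ui("`x` and `weights` must have equal length.", "utilineq_error_domain")
  }
  check_positive_weights(weights, "weighted_fractional_rank")
  if (any(is.na(x))) {
    abort_ui("Ranking variable contains missing values.", "utilineq_error_domain")
  }
  total <- sum(weights)
  ord <- order(x)                    # stable sort
  w_sorted <- weights[ord]
  cum_before <- cumsum(w_sorted) - w_sorted
  r_sorted <- (cum_before + w_sorted / 2) / total
  # collapse ties to the midpoint of the tied weight block
  x_sorted <- x[ord]
  grp <- cumsum(!duplicated(x_sorted))
  grp_w <- tapply(w_sorted, grp, sum)
  grp_before <- cumsum(grp_w) - grp_w
  r_sorted <- ((grp_before + grp_w / 2) / total)[grp]
  ranks <- numeric(length(x))
  ranks[ord] <- r_sorted
  ranks
}

ci_core <- function(y, ranks, weights) {
  ybar <- wmean(y, weights)
  if (ybar == 0) {
    abort_ui("Concentration index undefined: outcome mean is zero.",
             "utilineq_error_undefined_index")
  }
  2 * wcov(y, ranks, weights) / ybar
}

#' Concentration index of an outcome over the income distribution
#'
#' The concentration index is twice the weighted covariance between the
#' outcome \eqn{y_i} and the fractional income rank \eqn{R_i}, divided by the
#' weighted outcome mean \eqn{\bar y}:
#' \deqn{CI = \frac{2}{\bar y}\,\mathrm{cov}_w(y_i, R_i).}
#' A positive value indicates concentration of the outcome among the rich
#' (pro-rich), negative among the poor. For bounded outcomes Erreygers'
#' correction \eqn{E = 4\bar y\,CI/(y^{max}-y^{min})} rescales the index so
#' that perfect concentration of a binary outcome attains \eqn{\pm 1}; for a
#' binary outcome the bounds are fixed at (0, 1) so that \eqn{E = 4\bar y\,CI}.
#'
#' Standard errors come from the "convenient regression" formulation: the
#' weighted least-squares slope of \eqn{y} on \eqn{R} equals
#' \eqn{\mathrm{cov}_w(y,R)/\mathrm{var}_w(R)}, so
#' \eqn{CI = 2\sigma^2_R b/\bar y} and the index SE is the
#' heteroskedasticity-robust (HC1) SE of \eqn{b} mapped through the same
#' scaling (and through the Erreygers factor for the corrected index).
#'
#' @param data A data frame of survey records.
#' @param outcome Unquoted column with the outcome \eqn{y_i} (binary
#'   utilization indicator, or any bounded/unbounded numeric outcome).
#' @param ranker Unquoted column with the continuous socioeconomic ranking
#'   variable (equivalised income).
#' @param weights Unquoted column of positive sampling weights; omit for
#'   equal weights.
#' @param bounds Length-2 numeric outcome bounds used by the Erreygers
#'   correction. The default `c(0, 1)` is the convention for binary
#'   utilization variables regardless of observed values; pass observed
#'   bounds explicitly for other bounded outcomes.
#' @return A one-row tibble: `n`, `mean` (\eqn{\bar y}), `index` (CI),
#'   `se_index`, `corrected` (Erreygers E), `se_corrected`, `bound_lower`,
#'   `bound_upper`.
#' @seealso [weighted_fractional_rank()], [compare_indices()],
#'   [erreygers_correct()]
#' @examples
#' d <- tibble::tibble(use = c(0, 1), inc = c(1000, 2000))
#' concentration_index(d, use, inc)   # CI = 0.5, E = 1
#' @export
concentration_index <- function(data, outcome, ranker, weights = NULL,
                                bounds = c(0, 1)) {
  y <- dplyr::pull(data, {{ outcome }})
  x <- dplyr::pull(data, {{ ranker }})
  wq <- rlang::enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, length(y)) else dplyr::pull(data, !!wq)
  if (anyNA(y) || anyNA(x) || anyNA(w)) {
    abort_ui("Missing values in outcome, ranker or weights; filter first.",
             "utilineq_error_domain")
  }
  if (length(bounds) != 2L || bounds[2] <= bounds[1]) {
    abort_ui("`bounds` must be an increasing length-2 numeric.",
             "utilineq_error_degenerate_bounds")
  }
  ranks <- weighted_fractional_rank(x, w)
  ybar <- wmean(y, w)
  ci <- ci_core(y, ranks, w)
  se <- if (length(y) >= 3L) {
    ci_standard_error(y, ranks, w, corrected = FALSE, bounds = bounds)
  } else {
    NA_real_
  }
  scale_e <- 4 * ybar / (bounds[2] - bounds[1])
  tibble::tibble(
    n = length(y),
    mean = ybar,
    index = ci,
    se_index = se,
    corrected = scale_e * ci,
    se_corrected = abs(scale_e) * se,
    bound_lower = bounds[1],
    bound_upper = bounds[2]
  )
}

#' Erreygers correction for bounded outcomes
#'
#' Rescales a concentration index by \eqn{4\bar y/(y^{max}-y^{min})} so the
#' index of a bounded outcome attains \eqn{\pm 1} under perfect concentration
#' and treats health and ill-health symmetrically.
#'
#' @param index Concentration index value(s).
#' @param mean_outcome Weighted outcome mean(s) \eqn{\bar y}.
#' @param outcome_min,outcome_max Outcome bounds; `(0, 1)` for binary
#'   utilization indicators.
#' @return Corrected index value(s).
#' @examples
#' erreygers_correct(0.5, mean_outcome = 0.5)   # 1
#' @export
erreygers_correct <- function(index, mean_outcome, outcome_min = 0,
                              outcome_max = 1) {
  if (any(outcome_max <= outcome_min)) {
    abort_ui("Degenerate outcome bounds: `outcome_max` must exceed `outcome_min`.",
             "utilineq_error_degenerate_bounds")
  }
  4 * mean_outcome * index / (outcome_max - outcome_min)
}

#' Generalized concentration index
#'
#' Twice the weighted covariance of a variable with the fractional rank,
#' without normalisation by the mean. Used for the residual term of the
#' inequality decomposition (where the variable is a model residual whose
#' mean may be zero).
#'
#' @param values Numeric vector.
#' @param ranks Fractional ranks from [weighted_fractional_rank()].
#' @param weights Positive weights (default equal).
#' @return Scalar generalized CI.
#' @export
generalized_ci <- function(values, ranks, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  check_positive_weights(weights, "generalized_ci")
  2 * wcov(values, ranks, weights)
}

#' Convenient-regression standard error of a concentration index
#'
#' Regresses the outcome on the fractional rank by weighted least squares and
#' maps the heteroskedasticity-robust (HC1) standard error of the rank slope
#' through the identity \eqn{CI = 2\sigma^2_R b/\bar y} (and through the
#' Erreygers factor \eqn{4\bar y/(y^{max}-y^{min})} when `corrected = TRUE`).
#' \eqn{\bar y} and \eqn{\sigma^2_R} are treated as fixed, the standard
#' convenient-regression approximation.
#'
#' @param y Outcome vector.
#' @param ranks Fractional ranks on the same sample.
#' @param weights Positive weights (default equal).
#' @param corrected If `TRUE`, return the SE of the Erreygers-corrected index.
#' @param bounds Outcome bounds used when `corrected = TRUE`.
#' @return Non-negative scalar standard error.
#' @export
ci_standard_error <- function(y, ranks, weights = NULL, corrected = FALSE,
                              bounds = c(0, 1)) {
  if (length(y) < 3L) {
    abort_ui("At least 3 observations are required for a CI standard error.",
             "utilineq_error_insufficient_data")
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  check_positive_weights(weights, "ci_standard_error")
  if (stats::var(y) == 0) return(0)
  fit <- stats::lm(y ~ ranks, weights = weights)
  se_b <- sqrt(sandwich::vcovHC(fit, type = "HC1")[2, 2])
  ybar <- wmean(y, weights)
  s2r <- wvar(ranks, weights)
  se_ci <- 2 * s2r * se_b / abs(ybar)
  if (corrected) 4 * abs(ybar) * se_ci / (bounds[2] - bounds[1]) else se_ci
}

#' Compare concentration indices from two independent samples
#'
#' Tests the difference of two indices estimated on independent
#' cross-sectional samples (e.g. two survey years). The difference SE
#' combines the two SEs in quadrature, \eqn{\sqrt{se_a^2 + se_b^2}}, and the
#' p value is the two-sided normal tail probability of the z statistic.
#'
#' @param a,b One-row data frames with columns named by `value_col` and
#'   `se_col` — typically rows returned by [concentration_index()] — with `a`
#'   the baseline (e.g. earlier survey).
#' @param value_col,se_col Column names holding the index and its SE.
#' @return A one-row tibble: `index_a`, `index_b`, `difference`
#'   (`b - a`), `difference_se`, `z_statistic`, `p_value`.
#' @examples
#' a <- tibble::tibble(corrected = 0.0256, se_corrected = 0.0334)
#' b <- tibble::tibble(corrected = -0.0098, se_corrected = 0.0304)
#' compare_indices(a, b)   # difference -0.0354, se 0.0452
#' @export
compare_indices <- function(a, b, value_col = "corrected",
                            se_col = "se_corrected") {
  va <- a[[value_col]][1]; sa <- a[[se_col]][1]
  vb <- b[[value_col]][1]; sb <- b[[se_col]][1]
  if (is.null(va) || is.null(vb) || is.na(va) || is.na(vb)) {
    abort_ui("Inputs must carry the index value and SE columns.",
             "utilineq_error_domain")
  }
  diff <- vb - va
  se <- sqrt(sa^2 + sb^2)
  if (se == 0) {
    if (diff == 0) {
      return(tibble::tibble(index_a = va, index_b = vb, difference = 0,
                            difference_se = 0, z_statistic = 0, p_value = 1))
    }
    abort_ui("Both standard errors are zero; the comparison is undefined.",
             "utilineq_error_undefined_test")
  }
  z <- diff / se
  tibble::tibble(
    index_a = va, index_b = vb,
    difference = diff, difference_se = se,
    z_statistic = z, p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Concentration curve coordinates and plot
#'
#' `concentration_curve()` returns the cumulative population share (by
#' income rank) against the cumulative outcome share; `plot_concentration_curve()`
#' draws it against the line of equality. A curve below the diagonal indicates
#' pro-rich concentration.
#'
#' @inheritParams concentration_index
#' @return A tibble with `pop_share` and `outcome_share` columns.
#' @export
concentration_curve <- function(data, outcome, ranker, weights = NULL) {
  y <- dplyr::pull(data, {{ outcome }})
  x <- dplyr::pull(data, {{ ranker }})
  wq <- rlang::enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, length(y)) else dplyr::pull(data, !!wq)
  ord <- order(x)
  tibble::tibble(
    pop_share = c(0, cumsum(w[ord]) / sum(w)),
    outcome_share = c(0, cumsum(w[ord] * y[ord]) / sum(w * y))
  )
}

#' @rdname concentration_curve
#' @export
plot_concentration_curve <- function(data, outcome, ranker, weights = NULL) {
  cc <- concentration_curve(data, {{ outcome }}, {{ ranker }}, {{ weights }})
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$pop_share, y = .data$outcome_share)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Cumulative population share (poorest first)",
      y = "Cumulative outcome share",
      title = "Concentration curve"
    ) +
    ggplot2::theme_minimal()
}
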