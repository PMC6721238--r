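test_that("fractional ranks hit the hand-computed midpoints", {
  expect_equal(weighted_fractional_rank(5), 0.5)
  expect_equal(weighted_fractional_rank(c(10, 20, 30, 40)),
               c(0.125, 0.375, 0.625, 0.875))
  expect_equal(weighted_fractional_rank(1:3, c(1, 2, 1)),
               c(0.125, 0.5, 0.875))
  # returned in original record order
  expect_equal(weighted_fractional_rank(c(30, 10, 20)),
               c(5 / 6, 1 / 6, 0.5))
})

test_that("tied ranking values share their block midpoint rank", {
  r <- weighted_fractional_rank(c(1, 2, 2, 3))
  expect_equal(r, c(0.125, 0.5, 0.5, 0.875))
  # invariant under permutation within the tie
  r2 <- weighted_fractional_rank(c(1, 2, 2, 3), c(1, 3, 1, 1))
  expect_equal(r2[2], r2[3])
})

test_that("ranks stay in (0,1), average 0.5, and follow the income order", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    x <- rnorm(n)
    w <- rgamma(n, 2, 2)
    r <- weighted_fractional_rank(x, w)
    expect_true(all(r > 0 & r < 1))
    expect_lt(abs(sum(w * r) / sum(w) - 0.5), 1e-10)
    expect_true(all(diff(r[order(x)]) >= 0))
  }
})

test_that("rank input validation rejects empty and non-positive-weight input", {
  expect_error(weighted_fractional_rank(numeric(0)), class = "utilineq_error")
  expect_error(weighted_fractional_rank(1:3, c(1, 0, 1)),
               class = "utilineq_error")
  expect_error(weighted_fractional_rank(c(1, NA)), class = "utilineq_error")
})

test_that("two-unit perfect concentration gives CI 0.5 and Erreygers E 1", {
  d <- tibble::tibble(use = c(0, 1), inc = c(100, 200))
  res <- concentration_index(d, use, inc)
  expect_identical(res$index, 0.5)
  expect_identical(res$corrected, 1)
  expect_equal(res$mean, 0.5)
})

test_that("constant outcomes have zero index and zero standard error", {
  d <- tibble::tibble(use = rep(1, 10), inc = rnorm(10), w = rgamma(10, 2, 2))
  res <- concentration_index(d, use, inc, w)
  expect_equal(res$index, 0)
  expect_equal(res$se_index, 0)
  expect_error(
    concentration_index(tibble::tibble(use = rep(0, 5), inc = 1:5), use, inc),
    class = "utilineq_error_undefined_index")
})

test_that("covariance CI equals the pairwise oracle and regression form", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    x <- sample(seq_len(n))        # distinct ranking values
    w <- rep(1, n)
    r <- weighted_fractional_rank(x, w)
    ci <- concentration_index(tibble::tibble(y = y, x = x), y, x)$index
    expect_equal(ci, pairwise_ci(y, x), tolerance = 1e-10)
    expect_equal(ci, regression_ci(y, r, w), tolerance = 1e-10)
  }
})

test_that("indices are invariant to weight scaling and monotone rank transforms", {
  set.seed(11)
  n <- 80
  d <- tibble::tibble(y = rbinom(n, 1, 0.4), x = rlnorm(n),
                      w = rgamma(n, 3, 3))
  base <- concentration_index(d, y, x, w)
  scaled <- concentration_index(dplyr::mutate(d, w = w * 37.5), y, x, w)
  expect_equal(scaled$index, base$index, tolerance = 1e-12)
  expect_equal(scaled$se_index, base$se_index, tolerance = 1e-12)
  mono <- concentration_index(dplyr::mutate(d, x = log(x) * 3 + 2), y, x, w)
  expect_equal(mono$index, base$index, tolerance = 1e-12)
})

test_that("reversing the income order negates CI and E", {
  set.seed(12)
  d <- tibble::tibble(y = rbinom(50, 1, 0.5), x = runif(50),
                      w = rgamma(50, 2, 2))
  a <- concentration_index(d, y, x, w)
  b <- concentration_index(dplyr::mutate(d, x = -x), y, x, w)
  expect_equal(b$index, -a$index, tolerance = 1e-12)
  expect_equal(b$corrected, -a$corrected, tolerance = 1e-12)
})

test_that("binary outcomes satisfy E = 4 * mean * CI", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    d <- tibble::tibble(y = rbinom(n, 1, runif(1, 0.2, 0.8)),
                        x = rnorm(n), w = rgamma(n, 2, 2))
    if (mean(d$y) %in% c(0, 1)) next
    res <- concentration_index(d, y, x, w)
    expect_equal(res$corrected, 4 * res$mean * res$index, tolerance = 1e-12)
  }
})

test_that("erreygers_correct applies the bounded-outcome rescaling", {
  expect_equal(erreygers_correct(0, 0.7), 0)
  expect_equal(erreygers_correct(0.5, 0.5), 1)
  expect_equal(erreygers_correct(0.123, 0.25), 0.123)  # 4*0.25 = 1
  expect_equal(erreygers_correct(0.2, 5, 0, 10), 0.4)
  expect_error(erreygers_correct(0.1, 0.5, 1, 1),
               class = "utilineq_error_degenerate_bounds")
})

test_that("generalized CI matches closed forms and flips under reversal", {
  r <- weighted_fractional_rank(seq_len(2000))
  expect_equal(generalized_ci(r, r), (1 / 6) * (1 - 1 / 2000^2),
               tolerance = 1e-12)
  expect_equal(generalized_ci(rep(2, 10), weighted_fractional_rank(1:10)), 0)
  set.seed(14)
  v <- rnorm(30); x <- runif(30)
  expect_equal(generalized_ci(v, weighted_fractional_rank(-x)),
               -generalized_ci(v, weighted_fractional_rank(x)),
               tolerance = 1e-12)
})

test_that("convenient-regression SE scales like independent replication", {
  set.seed(15)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  x <- runif(n)
  r <- weighted_fractional_rank(x)
  se1 <- ci_standard_error(y, r)
  # doubling the sample as independent copies should shrink SE by ~ 1/sqrt(2)
  y2 <- rep(y, 2); x2 <- rep(x, 2)
  se2 <- ci_standard_error(y2, weighted_fractional_rank(x2))
  expect_equal(se2 / se1, 1 / sqrt(2), tolerance = 0.02)
  # splitting each record in two half-weight copies leaves the estimate alone
  ci1 <- cov_formula_ci(y, r, rep(1, n))
  ci2 <- cov_formula_ci(y2, weighted_fractional_rank(x2, rep(0.5, 2 * n)),
                        rep(0.5, 2 * n))
  expect_equal(ci1, ci2, tolerance = 1e-12)
  expect_error(ci_standard_error(c(0, 1), c(0.25, 0.75)),
               class = "utilineq_error_insufficient_data")
})

test_that("compare_indices reproduces the quadrature rule and null identity", {
  a <- tibble::tibble(corrected = 0.0256, se_corrected = 0.0334)
  b <- tibble::tibble(corrected = -0.0098, se_corrected = 0.0304)
  cmp <- compare_indices(a, b)
  expect_equal(cmp$difference, -0.0354)
  expect_equal(cmp$difference_se, sqrt(0.0334^2 + 0.0304^2))
  expect_equal(cmp$p_value, 2 * pnorm(-abs(cmp$z_statistic)), tolerance = 1e-12)
  same <- compare_indices(a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  z <- tibble::tibble(corrected = 0.1, se_corrected = 0)
  z2 <- tibble::tibble(corrected = 0.2, se_corrected = 0)
  expect_error(compare_indices(z, z2), class = "utilineq_error_undefined_test")
})

test_that("concentration curve is monotone from (0,0) to (1,1)", {
  set.seed(16)
  d <- tibble::tibble(y = rbinom(40, 1, 0.5), x = rnorm(40),
                      w = rgamma(40, 2, 2))
  cc <- concentration_curve(d, y, x, w)
  expect_equal(cc$pop_share[1], 0)
  expect_equal(cc$outcome_share[nrow(cc)], 1)
  expect_true(all(diff(cc$outcome_share) >= 0))
  p <- plot_concentration_curve(d, y, x, w)
  expect_s3_class(p, "ggplot")
})
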