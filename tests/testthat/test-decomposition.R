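test_that("intercept-only probit inverts the weighted outcome mean", {
  set.seed(21)
  d <- tibble::tibble(y = rbinom(500, 1, 0.37), w = rgamma(500, 4, 4))
  fit <- fit_probit(d, y ~ 1, weights = w)
  expect_equal(unname(fit$coefficients),
               qnorm(weighted.mean(d$y, d$w)), tolerance = 1e-7)
})

test_that("probit fit is invariant to splitting records into half-weight copies", {
  set.seed(22)
  d <- tibble::tibble(y = rbinom(300, 1, 0.5), x = rnorm(300),
                      w = rgamma(300, 2, 2))
  d2 <- dplyr::bind_rows(d, d) |> dplyr::mutate(w = w / 2)
  f1 <- fit_probit(d, y ~ x, weights = w)
  f2 <- fit_probit(d2, y ~ x, weights = w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("probit score vanishes at the reported solution", {
  set.seed(23)
  n <- 1000
  d <- tibble::tibble(x = rnorm(n), w = rgamma(n, 3, 3))
  d$y <- rbinom(n, 1, pnorm(-0.3 + 0.8 * d$x))
  fit <- fit_probit(d, y ~ x, weights = w)
  X <- cbind(1, d$x)
  g <- probit_score(fit$coefficients, d$y, X, d$w)
  expect_lt(max(abs(g)), 1e-6 * sum(d$w))
  expect_true(fit$converged)
})

test_that("probit recovers generating coefficients within 3 SEs", {
  set.seed(24)
  n <- 5000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  beta <- c(-0.4, 0.6, 0.5)
  y <- rbinom(n, 1, pnorm(beta[1] + beta[2] * x1 + beta[3] * x2))
  fit <- fit_probit(tibble::tibble(y = y, x1 = x1, x2 = x2), y ~ x1 + x2)
  td <- tidy(fit)
  expect_true(all(abs(td$estimate - beta) < 3 * td$std.error))
})

test_that("probit coefficients agree with a brute-force likelihood grid", {
  set.seed(25)
  n <- 50
  x <- rnorm(n)
  y <- rbinom(n, 1, pnorm(0.2 + 0.7 * x))
  d <- tibble::tibble(y = y, x = x)
  fit <- fit_probit(d, y ~ x)
  X <- cbind(1, x)
  # iterated grid refinement around a wide initial box
  centre <- c(0, 0); width <- 3
  for (round in 1:6) {
    g0 <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    g1 <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    ll <- outer(g0, g1, Vectorize(function(a, b)
      probit_loglik(c(a, b), y, X, rep(1, n))))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    centre <- c(g0[best[1]], g1[best[2]])
    width <- width / 10
  }
  expect_equal(unname(fit$coefficients), centre, tolerance = 1e-4)
})

test_that("degenerate outcomes and designs are rejected", {
  d <- tibble::tibble(y = rep(1, 20), x = rnorm(20))
  expect_error(fit_probit(d, y ~ x), class = "utilineq_error_degenerate_outcome")
  d2 <- tibble::tibble(y = rbinom(20, 1, 0.5), x = rnorm(20))
  d2$x2 <- -d2$x
  expect_error(fit_probit(d2, y ~ x + x2), class = "utilineq_error_rank_deficient")
  d3 <- tibble::tibble(y = c(2, 0, 1), x = 1:3)
  expect_error(fit_probit(d3, y ~ x), class = "utilineq_error_domain")
})

test_that("partial effects at means follow the density formula", {
  fake <- structure(list(coefficients = c(`(Intercept)` = 0, a = 0.5, b = 0),
                         x_means = c(1, 0, 0.3)), class = "probit_fit")
  pe <- partial_effects_at_means(fake)
  expect_equal(unname(pe["b"]), 0)
  expect_equal(unname(pe["a"]), 0.5 * dnorm(0))      # index is 0 at means
  expect_equal(round(unname(pe["a"]), 4), round(0.5 * 0.3989423, 4))
  expect_error(partial_effects_at_means(fake, x_means = c(1, 0)),
               class = "utilineq_error_dimension")
  # discrete-change option for a dummy
  fake2 <- structure(list(coefficients = c(`(Intercept)` = -0.2, d = 0.8),
                          x_means = c(1, 0.4)), class = "probit_fit")
  pe2 <- partial_effects_at_means(fake2, discrete = TRUE, dummy_cols = "d")
  m0 <- -0.2
  expect_equal(unname(pe2["d"]), pnorm(m0 + 0.8) - pnorm(m0))
})

test_that("elasticity is invariant to covariate rescaling", {
  set.seed(26)
  n <- 2000
  d <- tibble::tibble(x = rlnorm(n), w = rgamma(n, 2, 2))
  d$y <- rbinom(n, 1, pnorm(-1 + 0.2 * d$x))
  f1 <- fit_probit(d, y ~ x, weights = w)
  f2 <- fit_probit(dplyr::mutate(d, x = x / 100), y ~ x, weights = w)
  e1 <- partial_effects_at_means(f1) * f1$x_means
  e2 <- partial_effects_at_means(f2) * f2$x_means
  expect_equal(unname(e1["x"]), unname(e2["x"]), tolerance = 1e-6)
})

test_that("covariate concentration indices match the pairwise oracle", {
  r <- weighted_fractional_rank(1:10)
  X <- cbind(intercept = rep(1, 10),
             rich_half = rep(c(0, 1), each = 5),
             income = 1:10)
  ci <- covariate_concentration(X, r)
  expect_equal(unname(ci["intercept"]), 0, tolerance = 1e-14)
  expect_equal(unname(ci["rich_half"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(ci["rich_half"]), pairwise_ci(X[, 2], 1:10),
               tolerance = 1e-12)
  expect_gt(unname(ci["income"]), 0)
  Xz <- cbind(z = c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1))
  expect_warning(out <- covariate_concentration(Xz, r), "zero-mean")
  expect_true(is.na(out["z"]))
})

test_that("decomposition rows satisfy the exact per-row identities", {
  cfg <- quick_config(n = 1200, seed = 27)
  pop <- generate_population(cfg)
  pop$lpinco <- log(pop$true_income_equivalised)
  dec <- decompose_ci(pop, outpatient_use ~ lpinco + chronic_disease +
                        mobility_difficulty + education,
                      ranker = true_income_equivalised, weights = weight)
  expect_equal(dec$contribution, 4 * dec$elasticity * dec$ci_k,
               tolerance = 1e-12)
  expect_equal(dec$elasticity, dec$partial_effect * dec$mean,
               tolerance = 1e-12)
})

test_that("contributions plus residual reproduce total E to 1e-10", {
  for (seed in c(28, 29, 30)) {
    cfg <- quick_config(n = 900, seed = seed)
    pop <- generate_population(cfg)
    pop$lpinco <- log(pop$true_income_equivalised)
    dec <- decompose_ci(pop, outpatient_use ~ lpinco + age_group +
                          chronic_disease + self_rated_health,
                        ranker = true_income_equivalised, weights = weight)
    expect_lt(abs(attr(dec, "total") - sum(dec$contribution) -
                    attr(dec, "residual")), 1e-10)
  }
})

test_that("a covariate orthogonal to income contributes nothing on average", {
  set.seed(31)
  reps <- purrr::map_dbl(1:40, function(i) {
    n <- 1500
    inc <- rlnorm(n)
    x <- rbinom(n, 1, 0.5)      # independent of income
    y <- rbinom(n, 1, pnorm(-0.3 + 0.6 * x))
    dec <- decompose_ci(tibble::tibble(y = y, x = x, inc = inc),
                        y ~ x, ranker = inc)
    dec$contribution[dec$term == "x"]
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps)), 3 * se + 1e-4)
})

test_that("rescaling a continuous covariate leaves its contribution unchanged", {
  cfg <- quick_config(n = 1500, seed = 32)
  pop <- generate_population(cfg)
  pop$lpinco <- log(pop$true_income_equivalised)
  d1 <- decompose_ci(pop, outpatient_use ~ lpinco + chronic_disease,
                     ranker = true_income_equivalised, weights = weight)
  pop2 <- dplyr::mutate(pop, lpinco = lpinco * 100)
  d2 <- decompose_ci(pop2, outpatient_use ~ lpinco + chronic_disease,
                     ranker = true_income_equivalised, weights = weight)
  expect_equal(d1$contribution[d1$term == "lpinco"],
               d2$contribution[d2$term == "lpinco"], tolerance = 1e-6)
})

test_that("tidy, glance and autoplot expose the decomposition results", {
  cfg <- quick_config(n = 700, seed = 33)
  pop <- generate_population(cfg)
  pop$lpinco <- log(pop$true_income_equivalised)
  dec <- decompose_ci(pop, outpatient_use ~ lpinco + chronic_disease,
                      ranker = true_income_equivalised, weights = weight)
  td <- tidy(dec)
  expect_true(all(c("term", "coefficient", "elasticity", "ci_k",
                    "contribution", "stars") %in% names(td)))
  gl <- glance(dec)
  expect_equal(gl$total_corrected_ci,
               gl$explained + gl$residual, tolerance = 1e-10)
  expect_s3_class(autoplot(dec), "ggplot")
})
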