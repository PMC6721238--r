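---
title: "Measuring and decomposing income-related inequality in health-care utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing income-related inequality in health-care utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utilineq)
library(dplyr)
```

## The model

The package quantifies income-related inequality in a binary
health-care utilization indicator from cross-sectional survey
micro-data. The core statistic is the concentration index

$$\mathrm{CI} = \frac{2}{\bar y}\,\mathrm{cov}_w(y_i, R_i),$$

where $y_i \in \{0,1\}$ records use, $R_i \in (0,1)$ is the weighted
fractional rank of individual $i$ in the equivalised-income
distribution, and all moments are weighted by the survey sampling
weights (normalised to sum one, with no small-sample correction). The
index is twice the weighted covariance scaled by the mean: positive
when use is concentrated among the rich, zero under proportionality,
and invariant to positive rescaling of the weights and to monotone
transformations of the ranking variable.

For a bounded outcome the attainable range of CI shrinks with
$\bar y$, so indices of groups with different prevalences are not
comparable. Erreygers' correction

$$E = \frac{4\bar y}{y^{\max} - y^{\min}}\,\mathrm{CI}$$

restores $\pm 1$ under perfect concentration and treats $y$ and $1-y$
symmetrically. For the binary utilization variable the bounds are fixed
at $(0, 1)$ — so $E = 4\bar y\,\mathrm{CI}$ — rather than taken from
the observed minimum and maximum, which would collapse the correction
whenever a sample happens to contain only users or only non-users of
some subgroup.

### Fractional ranks and ties

Ranks are midpoint cumulative weight shares: after sorting by income,
$R_i = (\sum_{j \prec i} w_j + w_i/2)/\sum_j w_j$. Tied incomes all
receive the midpoint rank of their tied block. This convention keeps the
weighted mean rank at exactly $1/2$ (the telescoping sum
$\sum_g W_g W_{<g} + W_g^2/2 = W^2/2$ holds for any tie structure) and
makes every downstream index invariant to permutation of tied records.
Ties matter here: imputed incomes from a categorical covariate model can
coincide exactly.

### Standard errors and cross-wave comparison

The index is algebraically identical to a scaled slope of the
"convenient regression" of $y$ on $R$:
$\mathrm{CI} = 2\sigma^2_R\,b/\bar y$ with $b$ the weighted
least-squares slope. We report the heteroskedasticity-robust (HC1)
standard error of $b$ mapped through that scaling, treating $\bar y$
and $\sigma^2_R$ as fixed — the standard convenient-regression
approximation, and the estimator whose nominal 95% intervals the test
suite checks by simulation (coverage between 93% and 97% under the
null at $n = 500$). Cross-wave differences assume independent samples:
$\mathrm{se}_{\Delta} = \sqrt{\mathrm{se}_a^2 + \mathrm{se}_b^2}$ with a
two-sided normal test. Survey design features beyond the weights
(strata, clustering) are not modelled; SEs are correct under
independent weighted sampling and only approximate under multistage
designs.

## Income imputation

Many surveys record monthly income only as one of ten bands. The
imputation chain is:

1. **Interval regression** on the log scale: latent
   $\log(\text{income}) = x'\gamma + \sigma\varepsilon$, each band
   contributing the interval-censored Gaussian likelihood
   $\Phi((\log u - x'\gamma)/\sigma) - \Phi((\log l - x'\gamma)/\sigma)$,
   weighted by the sampling weights. The bottom band's lower bound is
   mapped to one currency unit ($\log 1 = 0$) and the top band is
   right-censored. The log scale is the coherent choice given the
   1-currency-unit floor and the later log transform of equivalised
   income; it also keeps the generator's log-normal incomes exactly
   within the fitted family, so parameter-recovery tests are clean.
   Estimation is delegated to `survival::survreg()`, the canonical
   interval-censored Gaussian MLE.
2. **Prediction**: the pipeline default is the *band-conditional* mean,
   $\exp(E[\log \text{income} \mid x,\ l < \text{income} \le u])$, the
   truncated-normal conditional mean on the log scale. The plain linear
   prediction $\exp(x'\gamma)$ (available as
   `predict_income(type = "linear")`) takes only as many distinct
   values as the categorical design has cells, so ranks degenerate into
   a few massive ties; conditioning on the reported band retains the
   ordering information the respondent actually supplied. Predictions
   are floored at 1 currency unit.
3. **Equivalisation** by the modified OECD divisor
   $1 + 0.5(\text{adults} - 1) + 0.3\,\text{children}$, and
4. **CPI rescaling** to a base year by the price-index ratio.

With the default synthetic settings (10 geometric bands, log-income SD
0.9) the imputed equivalised income has Spearman correlation above 0.95
with the latent truth; the test suite asserts > 0.8 at $n = 5{,}000$.

## Decomposition

Within one sex-year stratum a weighted probit
$P(y = 1 \mid x) = \Phi(x'\beta)$ is fitted (via `stats::glm`, followed
by Newton steps on the exact weighted likelihood so the score vanishes
to machine precision; the covariance is the inverse observed
information). Using partial effects at the weighted sample means
$\beta_k^m = \beta_k\,\phi(\bar x'\beta)$ — applied uniformly to
continuous and indicator regressors, with discrete-change effects for
dummies available as an option — the corrected index decomposes as

$$E = 4\sum_k \left(\beta_k^m \bar x_k\right) \mathrm{CI}_k +
  \mathrm{GCI}_\varepsilon,$$

where $\mathrm{CI}_k$ is the *standard* (uncorrected) concentration
index of regressor $k$ over the income ranks — the factor 4 already
carries the Erreygers scaling, and this convention reproduces the
printed contribution = 4 × elasticity × CI arithmetic of published
decomposition tables — and the residual is the Erreygers-scaled
generalized CI (twice the weighted covariance with the rank, no mean
normalisation) of the model error.

Two residual variants are reported. The primary residual uses the
linearisation error $y - \phi(\bar x'\beta)\,x'\beta$: because the
weighted covariance is linear, $E$ then equals
$\sum_k \text{contribution}_k + \text{residual}$ to machine precision
by construction, not by enforced subtraction. The generalized CI of the
nonlinear residual $y - \Phi(x'\beta)$ is also attached
(`residual_gci`) for diagnostic comparison. A regressor with exactly
zero weighted mean has an undefined $\mathrm{CI}_k$ (flagged `NA`); its
contribution is still computed from the covariance form
$8\,\beta_k^m\,\mathrm{cov}_w(x_k, R)$, which needs no division by the
mean.

Estimation is stratified by sex and survey year (four separate models),
with reference categories: aged 75+, never married, informal/illiterate
education, fair self-rated health, no chronic disease, no mobility
difficulty, CES-D below 10, no recent exercise, central region, middle
physician-density band.

## The synthetic survey generator

Real national health-interview extracts are restricted, so the
generator emulates their structure with known ground truth:

- **Covariates** are drawn independently from configurable category
  probabilities; the two wave profiles default to margins matching the
  published descriptives of a survey of adults aged 65+ (e.g. 64%
  poor self-rated health, 48%/56% chronic disease by wave).
  Cross-covariate dependence beyond what income loadings induce is not
  modelled.
- **Income** is log-normal with covariate shifts of the mean (education,
  age group, marital status, region), baseline $\log$-mean 8.85 and SD
  0.9 — chosen once so the log equivalised income mean (≈ 8.9–9.0)
  and spread match the published wave descriptives — banded into 10
  geometric intervals with interior bounds $3000 \cdot 2^{0..8}$
  currency units. Published sources do not reveal the true bounds;
  these are explicit configuration, not constants.
- **Utilization** follows the probit latent model with the log of true
  equivalised income as the income regressor. The non-intercept
  coefficients are patterned on the published stratified fits; each
  profile's intercept was calibrated once by root-finding at $n = 2
  \times 10^6$ so the weighted utilization rate matches the published
  overall rate (53.8% earlier wave, 46.5% later wave), and frozen.
- **Weights** are gamma with mean 1 and variance 0.2 (strictly
  positive, simple dispersion control), independent of covariates —
  unlike real post-stratification weights, which correlate with
  demographics.
- **CES-D counts** are a truncated negative-binomial mixture around the
  clinical cutoff of 10, with the ≥ 10 prevalence matching the wave
  margin; only the dichotomy enters the utilization model.

Because covariates are independent and weights uninformative, passing
recovery tests on these data demonstrates correctness of the
estimators, not robustness to the dependence structures, design
effects, or item nonresponse of real surveys.

`true_decomposition()` runs the *same* estimation pipeline on a very
large sample ($n \ge 10^5$), so small-sample runs are compared against
an oracle that shares any attenuation induced by banding and imputation
— the recovery tests measure estimator consistency, not the
identifiability of the generating coefficients from banded data.

## Numerical choices

- Probit: `glm` IRLS to deviance tolerance $10^{-12}$, then Newton
  polish until the step is below $10^{-12}$; perfect separation and
  rank-deficient designs raise classed errors.
- Interval regression: `survreg` with up to 200 iterations; a fit with
  all mass in one band raises a non-identifiable-scale error.
- Band-conditional prediction falls back to the nearer band bound when
  a band has essentially zero probability under the fitted model
  (interval probability below $10^{-12}$).
- Chi-square tests in descriptive tables are Pearson without continuity
  correction on unweighted counts — the variant that reproduces
  published descriptive-table statistics exactly — with the statistic
  flagged undefined when a margin is empty.
- The index-undefined case $\bar y = 0$, empty strata, non-positive
  weights, illegal categories and unmapped columns raise classed,
  field-naming validation errors.

## Problem sizes used in the test suite

Worked-example identities run on printed summary cells (instant).
Property suites use 1,000 random samples of $n \le 50$ for the
three-way estimator-equivalence check, 1,000 null simulations at
$n = 500$ for coverage, 200 replicates at $n = 5{,}000$ (female
stratum) against an oracle at $n = 5 \times 10^5$ for full-pipeline
recovery, and an end-to-end run at $n = 10{,}000$ per wave in the
acceptance script. Monte-Carlo tolerances are 3 combined standard
errors (replicate mean plus oracle noise in quadrature); joint
comparisons over many terms use 3-sigma per-term bands as a
multiplicity allowance.

## Known limitations

- Only sampling weights are honoured; multistage stratum/PSU variance
  is out of scope, so standard errors understate design effects in
  clustered surveys.
- Income is imputed as a point prediction; no multiple imputation, so
  downstream SEs ignore imputation uncertainty.
- The exact SE estimator behind published index tables is typically
  unstated; the HC1 convenient-regression choice here matches the
  published difference-SE combination rule but need not match every
  published per-wave SE to the last digit.
- No need-standardisation (horizontal inequity) and no concentration-
  curve dominance testing.
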