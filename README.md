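# utilineq

Income-related inequality in health-care utilization: concentration
indices, Erreygers correction, and regression-based decomposition for
survey micro-data.

## The problem

National health-insurance systems aim to make care accessible regardless
of income. Whether they succeed is an empirical question: is a binary
utilization outcome (e.g. *"used outpatient services in the last month"*)
concentrated among richer or poorer respondents, how does that change
between survey waves, and which covariates drive it?

`utilineq` implements the standard tool chain for answering this from
cross-sectional survey extracts in which income is only reported in
bands:

1. **Income imputation** — weighted interval regression of latent log
   income on demographics (`fit_interval_regression()`), band-conditional
   point prediction floored at 1 currency unit, modified-OECD
   equivalisation (divisor `1 + 0.5(adults − 1) + 0.3·children`) and CPI
   rescaling to a base year (`impute_income()`).
2. **Concentration index** — with weighted fractional income ranks
   `R_i` (cumulative weight share to the midpoint of each unit's weight),

   ```
   CI = (2 / ȳ) · cov_w(y_i, R_i)
   ```

   positive = pro-rich. For a binary outcome the Erreygers-corrected
   index `E = 4ȳ·CI` restores the ±1 bounds under perfect concentration
   (`concentration_index()`). Standard errors come from the convenient
   regression of `y` on `R` with heteroskedasticity-robust (HC1)
   variance; two independent waves are compared with
   `difference_se = √(se_a² + se_b²)` (`compare_indices()`).
3. **Decomposition** — a weighted probit `P(y=1|x) = Φ(x'β)` per
   sex-year stratum; with partial effects at sample means
   `β_k^m = β_k·φ(x̄'β)`, covariate means `x̄_k`, and each regressor's
   concentration index `CI_k` over the income ranks,

   ```
   E = 4 Σ_k (β_k^m · x̄_k) · CI_k + GCI_ε
   ```

   splits total inequality into per-covariate contributions plus a
   residual (`decompose_ci()`, `analyse_stratum()`,
   `run_full_analysis()`).
4. **Synthetic surveys** — `generate_population()` draws respondent
   records (binary utilization from a probit latent model, 10-band
   log-normal income with covariate shifts, gamma sampling weights,
   CES-D counts, household composition) with known ground truth, so the
   whole pipeline is testable without restricted survey files;
   `true_decomposition()` provides the large-sample oracle.

## Worked example

```r
library(utilineq)
library(dplyr)

cfg <- synthetic_config(n = 4000, year_profile = "2009-like", seed = 42)
pop <- generate_population(cfg)
women <- filter(pop, sex == "female")

dec <- analyse_stratum(women, cfg$income_band_bounds)
attr(dec, "concentration")
#> # A tibble: 1 × 8
#>       n  mean  index se_index corrected se_corrected bound_lower bound_upper
#>   <int> <dbl>  <dbl>    <dbl>     <dbl>        <dbl>       <dbl>       <dbl>
#> 1  2242 0.476 0.0844   0.0137     0.161       0.0260           0           1

head(select(tidy(dec), term, coefficient, stars, elasticity, ci_k, contribution), 5)
#> # A tibble: 5 × 6
#>   term                      coefficient stars elasticity     ci_k contribution
#>   <chr>                           <dbl> <chr>      <dbl>    <dbl>        <dbl>
#> 1 lpinco                         0.255  "***"    0.906    0.0596      0.216
#> 2 age_group65-74                -0.127  "*"     -0.0299   0.0266     -0.00318
#> 3 married_ever                   0.0365 ""       0.00930  0.00291     0.000108
#> 4 educationelementary           -0.333  "***"   -0.0636  -0.00602     0.00153
#> 5 educationjunior_high_plus     -0.419  "***"   -0.0363   0.230      -0.0334
```

Reading: 47.6% of the 2,242 women used outpatient care; the corrected
concentration index E = 0.161 (SE 0.026) is significantly pro-rich. The
decomposition attributes most of it to log equivalised income itself
(contribution 0.216 of E = 0.161, partly offset by negative terms):
income both raises utilization (positive elasticity) and is, by
construction, concentrated among the rich. Post-secondary education is
strongly pro-rich distributed (`ci_k = 0.23`) but lowers utilization in
this profile, contributing −0.033. `autoplot(dec)` draws the
contribution bars and `plot_concentration_curve()` the concentration
curve.

`glance(dec)` reports the additivity identity: `explained + residual`
equals `total_corrected_ci` to machine precision.

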