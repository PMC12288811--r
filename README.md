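# fgmi — multiple imputation of missing covariates for Fine–Gray models

Competing-risks analyses often model the cumulative incidence of one event of
interest with the Fine–Gray subdistribution hazard model

λ₁(t | X, Z) = λ₀₁(t) exp(β₁X + β₂Z),   F₁(t | X, Z) = 1 − {1 − F₀₁(t)}^exp(β₁X+β₂Z),

where F₀₁ is the baseline cumulative incidence and D ∈ {0, 1, 2} records
censoring, the event of interest, or the competing event. When baseline
covariates are partly missing, chained-equations imputation is routine for
single-event Cox models but not obviously correct here: the Fine–Gray
likelihood involves the *subdistribution time* V = I(D=1)·T + I(D≠1)·C, and
for subjects failing from the competing event the potential censoring time C
is unobserved under random censoring.

`fgmi` implements a two-stage solution for epidemiologists and
biostatisticians fitting Fine–Gray prognostic models with missing covariates:

1. **Censoring-time imputation.** Potential censoring times for
   competing-event failures are multiply imputed from the Kaplan–Meier
   estimate Ĝ of the censoring distribution, drawing from the conditional law
   1 − Ĝ(t−)/Ĝ(Tᵢ−) given C > Tᵢ (marginal, stratified, or Cox-model based
   when censoring depends on fully observed covariates). Each draw produces a
   *censoring-complete* dataset in which the Fine–Gray model is an ordinary
   Cox model on (V, I(D = 1)).
2. **Covariate imputation.** In each censoring-complete dataset, missing
   covariates are imputed either *substantive-model-compatibly* — sampling
   from a density proportional to
   f(V, D | X, Z; β̂*) · f(Xⱼ | X₋ⱼ, Z; φ*) with
   f(V, D | X, Z) = λ₁(V|X,Z)^{I(D=1)} exp{−Λ₁(V|X,Z)} — or *approximately
   compatibly* (MICE-style logistic/linear models with I(D=1) and the
   marginal cumulative subdistribution hazard Λ̂₁(V) as predictors). Both
   flavors are also available for cause-specific Cox substantive models
   (densities built from two cause-specific hazards, predictors D, Ĥ₁(T),
   Ĥ₂(T)).

Estimates from the completed datasets are pooled with Rubin's rules
(Barnard–Rubin degrees of freedom), and cumulative incidence curves are
pooled predict-then-pool on the complementary log-log scale with
delta-method variances.

The package also ships the synthetic data-generating mechanisms used to
validate the methods (a correctly specified proportional-subdistribution-
hazards generator, a matched Weibull cause-specific generator with
"least-false" target coefficients, exponential/administrative censoring, and
calibrated MAR missingness) plus a simulation harness with Monte-Carlo
performance summaries.

## Worked example

```r
library(fgmi)
library(dplyr)
set.seed(2026)

dat <- gen_fg_correct(2000, fg_correct_params(p = 0.15)) |>   # beta1 = 0.75, beta2 = 0.5
  apply_censoring(censoring_spec("random")) |>                 # ~30% censored
  induce_missingness(missingness_spec("mar_z"))                # ~40% of X missing given Z

stacks <- dat |>
  attach_cause_specific_hazards() |>
  impute_censoring_times(m = 10, seed = 11)                    # 10 censoring-complete datasets

completed <- lapply(stacks$datasets, function(d)
  run_smcfcs(d, "fine_gray", c("X", "Z"),
             list(cov_model("X", "logistic", "Z")),
             m = 1, iterations = 20)$datasets[[1]])

pooled <- pool_fg(completed, c("X", "Z"))
tidy(pooled) |> select(term, estimate, std.error, df, conf.low, conf.high)
#> # A tibble: 2 × 6
#>   term  estimate std.error    df conf.low conf.high
#>   <chr>    <dbl>     <dbl> <dbl>    <dbl>     <dbl>
#> 1 X        0.794    0.191   32.8    0.405     1.18
#> 2 Z        0.383    0.0662 366.     0.252     0.513

tidy(pooled_cif_at(pooled, c(X = 0, Z = 0), times = c(1, 2, 5)))
#> # A tibble: 3 × 4
#>    time estimate conf.low conf.high
#>   <dbl>    <dbl>    <dbl>     <dbl>
#> 1     1    0.100   0.0761     0.131
#> 2     2    0.121   0.0929     0.157
#> 3     5    0.153   0.118      0.197
```

The pooled log subdistribution hazard ratio for the 40%-missing binary
covariate X is 0.79 (95% CI 0.41–1.18) against a generating value of 0.75,
and the pooled baseline cumulative incidence tracks the closed-form truth
(0.095, 0.122, 0.145 at t = 1, 2, 5). `autoplot()` methods display pooled
coefficient and incidence curves, and `run_simulation()` /
`summarize_performance()` reproduce bias / coverage benchmarking across
scenarios.

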