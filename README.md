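# cbwmsm: calibrated covariate-balancing weights for marginal structural models

`cbwmsm` estimates the causal effect of a time-varying treatment sequence on a
longitudinal outcome from observational cohort data, in the presence of
**time-varying confounding** (treatment chosen in the light of evolving
covariates that also predict the outcome) and **dependent censoring**
(covariate-driven monotone dropout). It is aimed at biostatisticians and
epidemiologists fitting marginal structural models (MSMs) to person-period
("long") data such as treatment cohorts with scheduled visits.

## The estimator

The MSM specifies the marginal mean of the potential outcome under a
treatment sequence `ā_j`:

    E(Y_ij^{ā_j}) = g{h(ā_j), γ},   h(ā_j = 0) = 0.

γ is estimated by weighted estimating equations over the uncensored
person-periods, with weights `SW^A_ij · W^C_ij`, where

    SW^A_ij = ∏_{k≤j} pr(A_ik | Ā_{i,k-1}) / pr(A_ik | X̄_{i,k-1})     (treatment)
    W^C_ij  = ∏_{k≤j} 1 / pr(R_ik = 1 | H̄_{i,k-1}, R_{i,k-1} = 1)     (censoring)

Instead of plugging in raw maximum-likelihood weights — which can be unstable
and leave finite-sample covariate imbalance — `cbwmsm` **calibrates** them:
moment conditions, linear in the weights (`K'W* = l`), force the weighted
sample to show *no* covariate-treatment association at any visit (cumulative
treatment-model score conditions) and to be an exact stand-in for the
dropout-free target population (censoring balance conditions, implying among
other things `Σ R_ij W*_ij = nT`). Two solvers are provided:

* **exponential tilting** (default): `W* = W ∘ exp(Kλ)`, the unique solution
  of a convex program, found by damped Newton in a few iterations;
* **estimating equations**: re-solves the weight-model parameters so the
  standard-form weights satisfy the conditions; honestly reports
  non-convergence and multiple solutions, both of which genuinely occur.

Binary, ordinal (two nested logistic stages) and continuous (heteroscedastic
normal) treatments are supported, along with a pooled logistic dropout model,
patient-resampling bootstrap standard errors, balance diagnostics, and a
simulator with known causal truth.

## Worked example

Simulate a cohort of 500 patients over 3 visits with a 3-level ordinal
treatment, confounding by a time-varying covariate `x`, and covariate-driven
dropout; then estimate the MSM `y ~ dose_cum + dose` with tilted weights:

```r
library(cbwmsm)

scn <- generate_scenario(sim_config(n = 500, T = 3), seed = 2026)
scn$table
#> person_period_table: 500 patients, T = 3 follow-up visits, ordinal treatment
#>   2000 rows, 1183 uncensored person-periods (retention 78.9%)
scn$truth$gamma
#> (Intercept)    dose_cum        dose
#>         0.0         1.0         0.4

fit <- cbwmsm(scn$table,
              denominator = list(~ x_lag1 + v + a0_lag1,   # stage 1: any treatment
                                 ~ x_lag1 + v + a1_lag1),  # stage 2: high level
              numerator   = list(~ a0_lag1, ~ a1_lag1),    # stabilization
              censoring   = ~ x_lag1 + dose_lag1,          # dropout model
              balance     = ~ v + x,                       # censoring balance
              msm         = y ~ dose_cum + dose,
              method      = "type1", boot = 200, seed = 1)
fit
#> Marginal structural model with calibrated weights (exponential tilting)
#> msm_fit: 500 patients, 1183 person-periods
#>             estimate boot_se
#> (Intercept)   0.0590  0.0534
#> dose_cum      0.9960  0.0334
#> dose          0.3712  0.0619
#>   (200 bootstrap replicates, 0 failed)

sum(weights(fit))          # dropout-free population size n*T
#> [1] 1500
fit$calibration
#> calibration_result (type1): converged after 5 iterations
#>   max |K'W* - l| = 2.27e-13; weights in [0.204, 7.42]
```

The cumulative-dose and current-dose estimates (0.996, 0.371) recover the
known truth (1, 0.4) within one bootstrap standard error; every moment
condition is satisfied to machine precision, and the calibrated weights sum
exactly to the person-periods the full cohort would have contributed without
dropout. `summary(fit)` adds per-visit weight summaries, effective sample
sizes and a pre/post balance table; `run_pipeline()` drives the same workflow
from a YAML configuration and writes weights, coefficients, balance report
and a reproducible run log.

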