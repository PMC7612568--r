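---
title: "Jointly calibrated balancing weights for marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jointly calibrated balancing weights for marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cbwmsm)
```

## The problem

In longitudinal cohorts, treatment at each visit is chosen in the light of
evolving covariates that also predict the outcome (time-varying confounding),
and patients drop out for reasons related to those same covariates (dependent
censoring). A marginal structural model (MSM) specifies the mean of the
*potential* outcome under a treatment sequence $\bar a_j$,

$$E(Y_{ij}^{\bar a_j}) = g\{h(\bar a_j), \gamma\}, \qquad h(\bar a_j = 0) = 0,$$

and $\gamma$ is estimated from the observed data by weighting each uncensored
person-period with the product of a stabilized inverse-probability-of-
treatment weight
$SW^A_{ij} = \prod_{k\le j} \Pr(A_{ik}\mid \bar A_{i,k-1}) / \Pr(A_{ik}\mid
\bar X_{i,k-1})$
and an inverse-probability-of-censoring weight
$W^C_{ij} = \prod_{k\le j} 1/\Pr(R_{ik}=1 \mid \bar H_{i,k-1}, R_{i,k-1}=1)$,
then solving weighted least-squares-type estimating equations. Plugging in
maximum-likelihood estimates of the weight models is the standard recipe, but
the resulting estimators can be unstable — a few person-periods receive
enormous weights — and finite-sample covariate imbalance survives the
weighting, especially when a weight model is misspecified.

This package implements a *joint calibration* of those weights: moment
conditions are derived that force the weighted sample to show (I) no
association between treatment assignment and covariate history at any visit,
and (II) a weighted uncensored sample that is an exact stand-in for the
dropout-free target population. Both sets of conditions are linear in the
calibrated weights, so they assemble into one system $K^\top W^\star = l$
with one row of $K$ per uncensored person-period and one column per moment
condition.

## The moment conditions

**Treatment.** For a treatment model with parameters split into a
treatment-history part and a covariate-dependence part, the weighted score
equations of the model are required to be solved exactly at the point "no
covariate dependence", with the treatment-history part fixed at its
(unweighted) maximum-likelihood value. For the two-stage ordinal model
(logistic for any treatment, logistic for the highest level given any), row
$(i,j)$ of the block carries the cumulative residual scores
$\sum_{k \le j}(A^0_{ik}-\hat e^0_{ik})\,\tilde X^0_{i,k-1}$ and
$\sum_{k \le j}A^0_{ik}(A^1_{ik}-\hat e^1_{ik})\,\tilde X^1_{i,k-1}$, where
$\hat e$ are predictions from the treatment-history-only fit; all targets are
zero. Binary treatment is the one-stage special case; a continuous treatment
uses the analogous precision-weighted and squared-residual scores of a
heteroscedastic normal model.

**Censoring.** For a pooled logistic dropout model with functionals
$\tilde H$ of the observed history, the condition for row $(i,j)$ and
functional $h$ is
$(T-j+1)\,h_{i,j} - (T-j)\,h_{i,j+1}$ with target $T \sum_i h_{i,1}$, where
$h_{i,t}$ evaluates the functional for the visit-$t$ transition. With the
constant functional this forces the weighted number of uncensored
person-periods to equal $nT$ — the size of the dropout-free population; with
a baseline covariate it matches the weighted covariate average to the sample
average; with per-visit indicators (`visitf`) it enforces both per visit.

**Normalization.** When only treatment weights are calibrated by tilting,
per-visit mean-weight-one conditions replace the censoring block (they are
implied by it, and the two are rejected together); they also rule out the
degenerate all-zero solution of the treatment-score conditions.

## Two solvers

*Exponential tilting* (`solve_type1`, the default) keeps the initial
maximum-likelihood weights and multiplies them by $\exp(K\lambda)$. Solving
$K^\top W^\star(\lambda) = l$ is then exactly the stationarity condition of
the convex function $1^\top\{W \circ \exp(K\lambda)\} - l^\top \lambda$, so
the solution is unique and found by damped Newton iteration in a handful of
steps. The gradient of that objective *is* the moment-condition residual,
which makes the convergence check interpretable: calibration succeeded when
the worst residual is below tolerance.

*Estimating equations* (`solve_type2`) keeps the weights in standard
inverse-probability form and re-estimates the denominator and censoring model
parameters so the moment conditions hold, with the stabilization fits held at
their MLE values. This needs exactly as many free parameters as conditions,
is not convex, and is allowed to fail: non-convergence is reported with the
best residual found, and converged multi-starts whose weight sets differ by
more than a constant of proportionality set a `multiple_solutions` flag.
Both behaviors occur in practice for joint treatment-and-censoring
calibration, which is why the tilting solver is the default.

### Numerical choices

- Convergence: residual max-norm below `1e-8 * max(1, sqrt(m))` by default
  (`m` = number of weights); Newton steps are Armijo-backtracked, the Hessian
  carries a `1e-12`-scale ridge, and columns of `K` are rescaled to unit
  max-absolute-value internally (the solution in $W^\star$ is invariant).
- Exponents are clipped at $\pm 40$ *inside line-search evaluations only*;
  a solution is declared converged only if its exponents are interior.
- Infeasible targets (no positive-weight solution) manifest as an unbounded
  descent direction and raise an error that prints the direction.
- Fitted probabilities are clipped to $[10^{-8}, 1-10^{-8}]$ before
  inversion, with the number of clipped values recorded.
- Iteration caps: 200 (both solvers); Type-2 Jacobians use forward
  differences with step `1e-6 * (1 + |par|)` and fall back to a Gauss-Newton
  step when the Jacobian is singular.

## What the simulator emulates

`sim_config()` / `generate_scenario()` generate the study conditions used
throughout the tests: `n` patients over `T` follow-up visits; a standard-
normal baseline covariate `v` and an autoregressive time-varying confounder
`x`; within visit $j$ the order is dropout → treatment → confounder →
outcome. Treatment is ordinal by default (two nested logistic stages, the
same 0.5/0.4/0.6 slopes on the lagged confounder, baseline covariate and own
history in both stages; binary and heteroscedastic-normal continuous
variants share the coefficients); the confounder responds to the current
dose ($\kappa = 0.8$, no autoregression by default so the causal truth is
closed-form); the outcome adds a unit effect of cumulative dose and 0.5
times the current confounder; retention follows a logistic law with
intercept 2, confounder slope −0.4 and dose slope 0.3, i.e. roughly 8% of
at-risk patients drop out per visit (≈77% retention at `T = 3`). Those
values were chosen once to give moderate, realistic confounding and dropout;
with them the true coefficients of the canonical MSM
`y ~ dose_cum + dose` are $(0, 1, 0.4)$.

Misspecification (`misspec = "transform"`) exports
$x \mapsto \exp(x/2)$ and $v \mapsto v/(1+e^{v})$ while the data are still
generated from the untransformed covariates, so every analysis model —
treatment, censoring, and balance functionals — sees distorted regressors.

The generator does **not** emulate several features of real cohorts:
intermittent (non-monotone) missingness, measurement error, informative
visit timing, non-normal covariates, or unmeasured confounding. Passing
tests therefore demonstrate correctness of the estimator under its stated
assumptions, not robustness to their violation.

Randomness is laid out in per-patient blocks of one stream, so increasing
`n` at a fixed seed extends the sample without reshuffling earlier patients.

## What the package's checks compute

The test suite validates, among other things: exact satisfaction of all
moment conditions after tilting (residual below $10^{-6}$ on the default
n = 500, T = 3 ordinal-with-dropout scenario); agreement of the tilt with a
generic dense root-finder on small systems and with three hand-solved
systems; the $nT$ identity; uniqueness from random starts; shrinking of the
calibration function at the $n^{-1/2}$ rate under correct specification
(100 replicates at n = 500/2000/8000) and its separation from zero under
misspecification; negligible bias of the treatment-effect components for
maximum-likelihood, calibrated and oracle weights (200 replicates, n = 1000);
and a smaller mean squared error for the calibrated estimator than for the
maximum-likelihood estimator under covariate-transform misspecification
(200 replicates, n = 500). Problem sizes were fixed at those values as a
balance between Monte-Carlo resolution and the few minutes a routine check
should take.

## Design choices that were genuinely open

- **Ordinal model**: the continuation-ratio factorization (two nested
  logistics) rather than proportional odds — it factorizes the likelihood so
  each stage is an ordinary pooled logistic fit and the calibration
  restrictions take the same cumulative-score form per stage.
- **Pooling over visits**: treatment and censoring models are pooled by
  default, with visit indicators available as ordinary terms; fully
  visit-specific models are expressed through `visitf` interactions rather
  than a separate code path.
- **Working variance**: the MSM estimating equations use unit working
  variance and independence working correlation, making the estimator an
  exact weighted least squares; other links are left as an extension point.
- **Numerators**: stabilization models are always fitted unweighted by
  maximum likelihood first and held fixed through calibration.
- **Type-2 multi-start protocol**: the MLE start plus Gaussian perturbations
  (scale `0.25 * (|par| + 0.1)`); solutions are compared modulo
  proportionality after normalizing to mean weight 1.
- **Degenerate inputs**: constant treatments, all-in/all-out dropout,
  perfect separation and rank-deficient designs are rejected with named
  errors; a panel with *no* dropout events yields censoring weights ≈ 1 plus
  a warning rather than an error.

## Limitations

- Only unstabilized censoring weights are calibrated; stabilized-censoring
  and outcome-augmented variants are out of scope.
- The identity link is the only implemented MSM link.
- Exact balance limits how many functionals can be balanced at once;
  approximate (inequality) balance is not implemented.
- Bootstrap standard errors treat patients as resampling units and re-run
  the full pipeline; analytic (sandwich) variances are not provided.
- Consistency still requires a correctly specified set of balance
  functionals capturing the confounding; calibration repairs finite-sample
  imbalance and weight instability, not omitted confounders.
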