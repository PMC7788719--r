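---
title: "Ordinal versus dichotomized outcomes in hospital profiling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal versus dichotomized outcomes in hospital profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordprof)
```

## The problem

Hospital comparisons on clinical outcomes are chronically underpowered:
observed differences between centers are mostly noise, especially when the
outcome is a rare binary event such as mortality. Yet many conditions are
scored on ordinal disability scales — the Glasgow Outcome Scale (GOS) for
traumatic brain injury, the modified Rankin Scale (mRS) for stroke — which
are routinely dichotomized before profiling. Dichotomization discards
information; analysing the full ordinal scale with proportional-odds
regression retains it.

`ordprof` quantifies what that information is worth for *provider
profiling*: how many more true outlier hospitals an ordinal analysis
detects at fixed sample size, and conversely how many fewer patients per
hospital it needs at fixed detection power.

## Simulation design

Each Monte-Carlo replicate simulates a complete registry and profiles it
three ways:

1. **Cohort generation.** `H` fictitious hospitals receive `n` patients
   each. Baseline covariates are drawn from a study template; ordinal
   outcomes are drawn from an outcome generator (below).
2. **Center effects.** In scenario A each hospital `h` gets a true effect
   `beta_h ~ N(0, sd)` with `sd = 0.35` by default, applied as an additive
   shift on every cumulative logit: `logit P(Y >= k) + beta_h` for all
   `k`. Positive effects mean uniformly better outcomes, and the injection
   is proportional-odds-consistent, so the ordinal analysis model is
   correctly specified. In scenario B all effects are zero (the null used
   for specificity).
3. **Analysis.** The same simulated patients are analysed on (i) the full
   ordinal scale with proportional-odds regression, (ii) the
   favorable/unfavorable dichotomy, and (iii) the mortality-style
   dichotomy, each with binary logistic regression, always adjusting for
   the baseline covariates and including hospital as a categorical
   variable. Sharing one outcome draw across the three codings removes
   between-analysis Monte-Carlo noise.
4. **Outlier detection.** Hospitals whose estimated center effect deviates
   from the overall mean beyond a 95% confidence bound are flagged; the
   fraction flagged, averaged over replicates, is the detection rate
   (sensitivity in scenario A, type-I error in scenario B).

The full-scale defaults (`experiment_grid()`) are 250 hospitals, 25–200
patients per hospital in steps of 25, and 500 replicates per cell.
`desk_grid()` is the scaled-down preset used by this package's own test
suite and acceptance script: 50 hospitals, 100 replicates, grid
{25, 50, 100, 150, 200}. At that scale one template's scenario-A pass
takes a few minutes on one core.

## Outcome scales and cut points

Both built-in scales collapse the two worst states for ethical reasons
before any analysis: death + vegetative state for the 5-point GOS (leaving
4 categories) and death + mRS 5 for the 7-point mRS (leaving 6). Categories
are stored worst-to-best with 1-based indices, so "higher is better"
throughout and a positive center effect means better outcomes.

Two dichotomies are derived from the collapsed scale:

* *favorable*: good recovery / moderate disability (GOS), mRS 0–2;
* *"mortality"*: the bottom collapsed category versus the rest. Despite the
  conventional label this event includes the merged worst disability
  state — it is defined by the collapse, matching the 32% (TBI) and 21%
  (stroke) event fractions rather than pure death rates.

## Outcome generators

The configured-marginals generator represents the outcome distribution as
cumulative-logit intercepts `theta_k = logit P(Y >= k)` (strictly
decreasing in `k`). The study templates pin the marginals to the published
figures:

* **TBI template** (`impact_generator()`): 4-point GOS with
  (0.32, 0.16, 0.22, 0.30) from worst to best — 32% in the bottom
  category, 52% favorable. The published figures fix the bottom and
  favorable fractions and hence severe disability (16%); the
  moderate/good split (22/30) is fixed once at values typical of
  multi-study TBI cohorts.
* **Stroke template** (`practise_generator()`): 6-point mRS with
  (0.21, 0.11, 0.12, 0.17, 0.22, 0.17) — 21% in the bottom category, 56%
  favorable (mRS 0–2). Only the bottom (21%) and favorable (56%)
  fractions are published; the within-band splits are fixed once at
  values typical of thrombolysis-era stroke trials.

Covariates (age, sex, pupillary reactivity and motor score for TBI; age,
sex, atrial fibrillation, diabetes, prior stroke and NIHSS for stroke)
reproduce the published baseline tables: log-normal age calibrated to the
printed median/IQR, an integer-rounded gamma for NIHSS (mean 8; the source
prints no spread, SD 6 is the package default and configurable). By
default the configured generator gives covariates *no* effect on outcome
(`coefs = NULL`): the published marginals constrain only the outcome
distribution, and detection power is driven by it. The covariates still
enter every analysis model, so the estimators pay the same case-mix
adjustment cost as on real data. Coefficients can be supplied when
covariate-outcome dependence is wanted, and `fit_generator()` estimates a
multinomial generalized-logit generator from any user-supplied
patient-level table (every category must be observed; apparent separation
aborts the fit).

## Model fitting

Both analysis models are fitted by maximum likelihood with hospital as a
categorical variable in reference coding (full-rank, numerically simple),
then transformed to deviations from the mean center effect with
delta-method standard errors from the full coefficient covariance — the
deviations sum to zero over the estimable hospitals by construction.

The proportional-odds fitter is a Newton algorithm on the observed
information in the cumulative-intercept parametrization, with analytic
gradient and Hessian assembled per outcome category. Safeguards: step
halving whenever a step would decrease the likelihood or disorder the
intercepts; convergence at max absolute gradient `1e-8`; at most 100
iterations. On desk-scale problems (10,000 patients, ~60 parameters) a fit
takes well under a second, which is what makes the Monte-Carlo experiments
cheap. With two categories the fit reduces exactly to binary logistic
regression; the binary model itself is fitted by iteratively reweighted
least squares (`stats::glm.fit`) with Fisher-information standard errors.

**Degenerate hospitals.** A hospital whose patients all share one outcome
value is separated — its fixed-effect estimate is infinite. Such hospitals
are excluded from the fit, excluded from the mean, reported as
`non_estimable`, and never flagged as outliers. At the default marginals
this is rare (it needs e.g. 25 consecutive non-events at probability
0.68), but the accounting keeps small-`n` cells honest.

## Outlier rules

Three rules are implemented in `flag_outliers()`; all compare the
deviation `d_h` with `z = qnorm(1 - alpha/2)`:

* `ci_screen` (default): flag when
  `|d_h| > z * sqrt(se_h^2 + mean(se^2))`. This is the behaviour of the
  common applied practice of screening each hospital's 95% CI — built from
  the model's hospital-coefficient standard errors, which carry the
  reference contrast's uncertainty (about `sqrt(2)` times the exact
  deviation SE) — against the overall mean. It is deliberately
  conservative: under the null its empirical flag rate is a few tenths of
  a percent, which reproduces the reported "type-I error below 1% in all
  cases" behaviour of this style of profiling.
* `wald_vs_mean`: the exact per-hospital Wald test `|d_h|/se_h > z` with
  delta-method deviation SEs. Correctly sized (about 5% per hospital at
  `alpha = 0.05`), hence *not* what applied CI-screening does; it is kept
  for sensitivity analyses.
* `mean_ci`: the literal "estimate outside the CI of the overall mean"
  reading, `|d_h| > z * se(mean)`.

The default was chosen because it is the only rule whose null behaviour
matches the published specificity; the choice barely affects the
*relative* efficiency of the three analyses (all rules scale with each
analysis's information), which is the quantity of interest. No
multiple-testing correction is applied: raw flagged fractions are the
estimand.

## From detection curves to sample-size reductions

For each analysis, scenario-A detection rates versus patients-per-hospital
form a power curve. Raw Monte-Carlo curves can dip non-monotonically at
modest replicate counts, so `required_n()` first applies isotonic
regression, then monotone piecewise-linear interpolation; it returns the
smallest `n` achieving a target rate, `NA` when the target exceeds the
curve's maximum, and the smallest evaluated `n` when the target sits below
the curve's first point (a conservative clamp).

`summarize_efficiency()` evaluates, for every target power achieved by the
dichotomized reference curve at its grid points, the equal-power
requirement on both curves and reports `1 - n_ordinal / n_reference`. The
headline "up to X%" figure is the maximum over targets — mirroring how
such figures are read off a detection-rate plot. Note that a maximum over
noisy interpolated ratios carries upward Monte-Carlo bias at desk scale;
the replicate counts here trade that against runtime.

## Numerical and design notes

* All randomness flows from one master seed; per-replicate sub-seeds are
  pre-derived, so serial and parallel execution agree bit for bit and any
  replicate is reproducible in isolation.
* `sd = 0` in scenario A draws no random numbers and is therefore
  bit-identical to scenario B under a shared seed.
* Equal patients per hospital, as in the emulated experiments; mixed
  hospital sizes are a known departure of real registries.
* Category probabilities from cumulative-logit shifts are positive by
  construction; fitted-mode cumulative probabilities are clamped away from
  0/1 before the shift.
* Threshold monotonicity is enforced by rejecting disordering Newton
  steps rather than reparametrizing; accepted optima always satisfy it.

## What the simulations do and do not show

The generator emulates *marginal* structure: outcome marginals, covariate
marginals, equal hospital sizes, proportional-odds center effects. It does
not emulate covariate-outcome dependence (unless configured),
between-covariate correlation, unequal hospital volumes, inter-rater
misclassification of scale scores, or departures from proportional odds.
Detection rates and efficiency gains transfer to real registries only to
the extent that these features matter; published analyses based on
real-data-fitted generators report somewhat different headline
percentages, with the same qualitative ordering (ordinal > favorable >
mortality, and gains growing as the event gets rarer). The
ordinal-vs-mortality comparison is the most sensitive to
covariate-outcome dependence, because case-mix effects concentrate
per-profile event probabilities and penalize a rare-event dichotomy most;
with the marginals-only generator its measured gain is therefore expected
on the low side.

## Reproducing the numbers

`scripts/acceptance.R` in the source repository reruns the desk-scale
experiments end to end (scenario B specificity, outcome marginals at
100,000 patients, and both templates' scenario-A efficiency summaries)
from a single seed and writes the resulting quantities to JSON; the test
suite asserts the same properties with fixed seeds.
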