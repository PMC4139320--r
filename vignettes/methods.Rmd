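---
title: "Methods: hierarchical Bayesian smoothing of sparse stratified mortality rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian smoothing of sparse stratified mortality rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented by `hbmort`
and the reasoning behind the main design choices. The workflow targets a
common epidemiological setting: mortality comparisons between small
population groups from a linked census–mortality cohort, where many
strata carry a handful of deaths (or none), death records must be
weighted for incomplete linkage, and published counts are subject to
statistical disclosure control.

## Data layout

The unit of analysis is a *stratum*: one cell of the cross-classification
ethnicity × cause of death × sex × five-year age group (25–29 … 70–74) ×
comparison group, carrying person-years of follow-up and death counts.
Two comparison designs are supported:

* **nativity** — New Zealand-born (`NZB`, reference) vs overseas-born
  (`OSB`);
* **dor** — duration of residence `0-9`, `10-24`, `25+` years
  (reference `25+`).

`cohort_table()` validates grid completeness and internal consistency
(`linked ≤ eligible`, zero deaths wherever exposure is zero) and
round-trips losslessly through CSV.

## Linkage weighting

Census–mortality linkage misses some eligible death records. Analysing
only linked deaths would understate rates, so each linked death in a
stratum is up-weighted by

\[ w = \frac{\text{eligible deaths}}{\text{linked deaths}}, \]

making the weighted death count equal in expectation to the eligible
count (`linkage_weight()`, `weighted_deaths()`). In sparse synthetic (and
real) tables some strata have eligible deaths but no linked deaths, where
the per-stratum weight is undefined. `apply_linkage_weights()` then pools
the weight over a cascade of progressively coarser cells: ethnicity ×
group × sex × broad age band (25–44 / 45–64 / 65–74), then ethnicity ×
group, then the whole table. Pooling is a bias–variance trade-off: a
pooled weight is biased for the stratum if linkage propensity varies
within the pool, but a per-stratum weight from one or two deaths is far
noisier. The default (`pooling = "stratum"`) refuses to weight an
unweightable stratum so the user must opt into pooling explicitly.

## The hierarchical model

For stratum \(s\) with exposure \(E_s\) person-years and weighted death
count \(y_s\):

\[
y_s \sim \text{Poisson}(E_s \lambda_s), \qquad
\log \lambda_s = x_s^\top \beta + \varepsilon_s, \qquad
\varepsilon_s \sim \mathcal N(0, \sigma^2),
\]

with \(x_s\) containing an intercept, a female indicator, a linear age
spline, and comparison-group indicators against the reference group. Age
enters as a scaled score \(a\) (0 at 45–49, one unit per five years) with
hinge terms \((a+2)_+\) and \((a-2)_+\), i.e. knots at 35–39 and 55–59 —
three coefficients that let the log-rate slope differ below, between and
above the knots, which is flexible enough for adult mortality while
remaining identifiable from 10 age bands.

Priors are weakly informative: \(\mathcal N(0, 10^2)\) on regression
coefficients and Half-Normal(1) on \(\sigma\). The stratum effect
\(\varepsilon_s\) gives partial pooling: strata with many deaths keep
their crude rates, sparse strata are shrunk toward the value implied by
the covariate structure. The strength of shrinkage is learned from the
data through \(\sigma\).

Weighted death counts are non-integer, so the Poisson likelihood is
implemented in JAGS with the standard "zeros trick": an observed zero
with a Poisson mean equal to the negative weighted log-likelihood plus a
constant, which reproduces
\(y \log \mu - \mu\) exactly for real-valued \(y\).

### Orthogonalised sampling

The raw design matrix is highly correlated (intercept vs age columns),
which made Gibbs sampling mix poorly. `fit_hb()` therefore samples in an
orthonormalised basis: with \(X = Q R\) (thin QR, scaled so
\(Q^\top Q = n I\)), the sampler draws \(\theta\) for the columns of
\(Q\) and the original coefficients are recovered as
\(\beta = R^{-1}\theta\). The \(\mathcal N(0, 10^2)\) prior is placed on
\(\theta\), i.e. on the orthonormal scale; this is a deliberate, recorded
deviation — it is the same class of weakly informative prior, and with
prior scale 10 on standardised columns it is if anything flatter over the
plausible coefficient region, while improving minimum effective sample
size by roughly an order of magnitude at fixed cost. Stratum effects are
sampled non-centred (\(\varepsilon_s = \sigma z_s\)).

### Convergence contract

Each fit computes split-\(\widehat R\) over halved chains and effective
sample sizes, and warns unless \(\widehat R < 1.05\) and ESS \(> 400\)
for every monitored rate. Chains are seeded per chain
(`mcmc$seed + chain`), so fits are reproducible draw for draw.

## Direct standardisation, draw-wise

Group comparisons use direct standardisation: a fixed set of sex × age
weights (exposure shares of the combined analysis population, summing
to 1) applied to each group's cell rates. Crucially this is done *per
posterior draw* (`standardised_rate_draws()`), so the standardised rate
is itself a posterior sample and credible intervals need no delta-method
approximations. Rate ratios are likewise formed draw by draw — never as
a ratio of summary medians — paired by draw index within one fitted
model (the joint posterior) and by a seeded permutation across
independently fitted models.

Summaries are sample medians with 2.5th/97.5th percentile intervals,
computed by linear interpolation between order statistics (type-7
quantiles). A ratio is flagged *significant* when fewer than 10% of its
draws fall on one side of 1; draws exactly equal to 1 count as
not-greater, and the threshold comparison is strict.

## The synthetic cohort generator

Real linked-cohort unit data are confidential, so the package ships a
generator (`generate_cohort()`) that emulates the *structure* of such
data with known truth: log-linear structural rates (ethnicity baseline,
sex effect, age spline, multiplicative group effect), log-normal
exposure around a group-specific profile (overseas-born exposure an
order of magnitude larger than native-born, and decreasing with duration
of residence), Normal stratum noise \(\sigma_\text{strata}\), Poisson
eligible deaths, and Binomial linkage. Because the truth is analytic
(`truth_standardised_rates()`), estimator calibration can be tested:
credible-interval coverage and recovery of a known group effect.

What the generator does **not** emulate: cohort attrition and censoring
within the follow-up window, misclassification of ethnicity between
census and death records, correlation of linkage propensity with cause
of death, and overdispersion beyond the log-normal stratum noise. It is
a test-bed for the estimation machinery, not a population model.

Default problem sizes (three ethnicities × 2 sexes × 10 age bands × 2–3
groups, a few hundred to a couple of thousand deaths per cause) are the
package's own choice, picked so a full three-cause analysis runs in
about a minute on one CPU while still exercising the sparse-stratum
regime the model exists for.

## Disclosure control

Raw integer counts destined for release pass through `rr3()` — random
rounding to base 3 (nearest multiple with probability 2/3, second
nearest with 1/3, unbiased, never moving a count by more than 2) — and
`suppress_small()`, which suppresses nonzero rounded counts below 6.
Disclosure control applies to released *counts* only, never to model
inputs or posterior summaries.

## Limitations

* Inference is conditional on the fitted log-linear structure; strong
  interactions (e.g. group-specific age slopes) are not modelled.
* The linkage-weight cascade assumes linkage propensity is roughly
  constant within a pooling cell.
* Cross-model rate ratios treat the two posteriors as independent, which
  ignores any shared-standard dependence (the standard weights are fixed
  constants, so this is exact unless the weights are themselves
  estimated).
* With 40–60 strata per fit, \(\sigma\) is only moderately informed;
  its Half-Normal(1) prior matters in very sparse designs.
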