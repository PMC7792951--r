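---
title: "Measuring inequality and inequity in long-term care use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inequality and inequity in long-term care use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcineq)
```

## The problem

As populations age, more people need long-term care (LTC): either *formal*
care — professional help at home or institutionalization — or *informal*
care from family or acquaintances. Because formal care is expensive, its use
may depend not only on health needs but on household resources. This package
measures two distinct things in respondent-level survey microdata of older
adults:

* **Inequality**: is care use concentrated among richer or poorer
  households, full stop?
* **Horizontal inequity**: do people with the *same level of need* use care
  differently depending on their socioeconomic status (SES)?

Both questions are answered with concentration indices computed against a
household income ranking and, for robustness, a household wealth ranking.

## The measurement chain

### Fractional ranks

Respondents are ranked by the SES variable. With survey weights $w_i$
(unit weights by default), the fractional rank of respondent $i$ is the
midpoint of their cumulative weight block after sorting ascending:

$$ r_i = \frac{\sum_{j < i} w_j + w_i/2}{\sum_j w_j}. $$

Ties share the midpoint of their whole block, which is the average of the
ranks the tied members would receive under any tie-breaking order. This
choice removes input-order dependence and keeps the weighted mean of the
ranks at exactly $1/2$, an invariant the test suite enforces on random
inputs. Ranks are always computed *within the analysis sample actually used
by an estimator* (after listwise deletion), not on the full file, and
household-level SES repeated across household members is ranked as given.

### Concentration index and the binary-outcome correction

For outcome $h_i$ with mean $\mu$,

$$ CI = \frac{2}{\mu}\,\mathrm{cov}(h_i, r_i), $$

positive when use is concentrated among the rich. For a binary outcome the
attainable range of $CI$ shrinks as $\mu$ grows, so the corrected index

$$ CCI = 4\,\mu\,CI = 8\,\mathrm{cov}(h_i, r_i) $$

is reported alongside. We use the *population*-weighted covariance (divide
by total weight, not total minus one). That convention is what makes the two
printed forms of $CCI$ identical to machine precision, and makes the
geometric route — one minus twice the area under the concentration curve,
computed by the trapezoid rule over rank-sorted data — agree with the
covariance form up to discreteness ($O(1/n)$). Both routes are implemented;
their agreement on random data is one of the package's standing oracle
checks. Both CI and CCI are always reported, with explicit labels, since
published tables do not always say which of the two they print.

### Utilization models

Care use is modelled by logistic regression of each binary outcome on need
determinants (age group, gender, self-assessed good health, ADL limitations,
chronic conditions) and non-need determinants (marital status, education,
children, household size, urbanicity, region where applicable). Age enters
as two dummies (66–80, 80+) against 50–65; education against primary.
Estimation is maximum likelihood via IRLS (`stats::glm`); the default
covariance is the robust sandwich estimator, the companion of the
log-pseudolikelihood that such studies print. Coefficients are reported as
odds ratios $e^\beta$ with delta-method standard errors
$\mathrm{SE}(OR) = OR \cdot \mathrm{SE}(\beta)$. Convergence is declared at
a relative deviance change below $10^{-10}$ within 100 iterations;
perfect separation (fitted probabilities at machine 0/1) and rank-deficient
designs raise errors naming the offending terms, while covariates that are
constant in the estimation sample are dropped with a message — a small
country sample can easily have, say, no co-resident children. Survey
weights, when supplied, enter as frequency-style weights in the score and in
the sandwich; the default is unweighted.

### Indirect need-standardization and horizontal inequity

The fitted model is split into need ($N$) and non-need ($Z$) parts.
Need-expected use $\hat h_i$ is the model prediction with need variables at
their observed values and every non-need *design column* fixed at its sample
mean — for categorical variables the dummy proportions, which preserves the
sample-mean prediction property. Standardized use is

$$ h'_i = h_i - \hat h_i + \overline{\hat h}, $$

recentred by the mean of the predictions so that
$\mathrm{mean}(h') = \bar h$ holds exactly under both prediction engines;
when predictions average to $\bar h$ (always true for the linear-probability
engine) this is the textbook $h_i - \hat h_i + \bar h$. The horizontal
inequity index HI is the concentration index of $h'$. An alternative
construction, $CI(h) - CI(\hat h)$, is also reported: under the LPM engine
the two coincide to machine precision (an algebraic identity given the
covariance convention), under the logit engine they differ by the
linearization error of the prediction, typically in the third decimal.
Which functional form to predict from is genuinely open — the
standardization equation is linear while the utilization model is logistic —
so both engines are provided (`engine = "logit"` is the default, being
consistent with the utilization model; `"lpm"` gives the exact
decomposition identity). Per-country tables standardize within country by
default, with a pooled option, since the pooling level is itself a modelling
choice.

### Standard errors

Published LTC concentration tables print standard errors without stating the
estimator, so the package offers two and labels them:

* `"convenient"` (default): the slope SE from the convenient regression
  $2\sigma_r^2 (h_i/\mu) = a + b\,r_i$ with HC1 robust variance — the slope
  estimates the index. For HI, the regression is run on the standardized
  outcome with the need-prediction treated as fixed. Fast; its 2-SE coverage
  of a true zero index is verified by simulation (about 95% nominal) in the
  test suite.
* `"bootstrap"`: respondents resampled i.i.d. with replacement, the full
  estimator — including re-ranking, and for HI re-fitting the
  standardization model — recomputed per replicate; 500 replicates by
  default, deterministic given a seed. Slower but reflects rank and model
  estimation noise.

## The synthetic generator

Restricted-access survey microdata cannot ship with a package, so every
stage is validated against a generator whose data-generating process is
known. Each country block draws, from its own RNG stream (derived
deterministically from the master seed and the country code, so adding a
country never perturbs another):

* household income and wealth from correlated log-normals (Gaussian copula
  on the logs, correlation 0.6 by default) — right-skewed, as in real data;
* age from a truncated normal, cut into the three analysis groups; gender,
  marital status, urbanicity and co-resident children as Bernoulli draws;
  education as a three-level categorical; children and household size as
  (shifted) Poisson counts;
* ADL limitations and chronic-disease counts from negative binomials —
  real ADL counts are strongly over-dispersed (SD several times the mean),
  and the default dispersion sizes (0.12 and 4.9) reproduce that;
* self-assessed good health as Bernoulli with log-odds declining in the ADL
  count (slope 0.8), levelled to the country's marginal good-health share;
* outcomes as Bernoulli with logit equal to the configured coefficient
  vector over need and non-need terms **plus a direct SES effect
  $\delta_{ses} \cdot r_i$ on the within-country fractional income rank**.
  Putting the SES effect on the rank itself, rather than raw income, makes
  the induced inequity exactly the quantity the concentration machinery
  measures, so recovery tests are sharp. $\delta_{ses} = 0$ gives
  conditional independence of use and SES — the null for HI tests.

Default parameters are calibrated once to published per-country summary
statistics for the European 50+ survey population this emulates: per-country
prevalences (informal care ranging about 0.20–0.45, formal 0.05–0.19,
pooled formal near 0.09), covariate means, and education shares. The default
outcome coefficients are published utilization-model estimates for the same
population, and the default SES effects are $\delta = +0.5$ for formal and
$-1.0$ for informal care, chosen once so the generator reproduces the
well-documented qualitative pattern — formal care pro-rich, informal care
pro-poor — at roughly the published index magnitudes (raw CI about $+0.06$
and $-0.12$ respectively). Country intercepts are not free parameters: they
are solved by root-finding on the realized linear predictor so the expected
prevalence equals the country target (the solved values are attached to the
generated table, so recovery tests can check them too). The generating model
carries no region dummies — per-country intercepts already absorb regional
level differences, and including both would double-count.

What the generator does **not** emulate: correlation between need and SES
(poorer respondents are sicker in real data), non-need covariates correlated
with income, household clustering, item non-response patterns, and
cross-country differences in LTC supply. Consequently a passing null-HI
test shows the estimator chain is unbiased under conditional independence,
not that real-data HI estimates are free of the usual observational-data
caveats; and the generator's raw informal-care CI and its informal HI share
a sign, whereas in real data need gradients can make informal care look
pro-poor in the raw CI while need-standardization reveals pro-rich inequity.

## Numerical and design choices

* Sample SD ($n-1$) in descriptives, matching survey reporting; population
  weighting inside all covariances (see above). Proportions are reported on
  $[0,1]$; the CLI may format as percentages.
* Missing data: listwise deletion per estimator by default (each model on
  its own complete cases, with the count recorded); a drop-at-read policy
  is available. No imputation. This is why the two utilization models can
  legitimately have different estimation sizes.
* Degenerate cells (a country with no users of an outcome) are flagged and
  skipped in the per-country tables; an all-users cell triggers a warning
  that the corrected-index bound is degenerate.
* Significance stars at 1/5/10% from two-sided normal tests on
  estimate/SE ratios.
* Reproducibility: bootstraps restore the caller's RNG state; `run_study()`
  writes a manifest (seed, package version, configuration hash) and a
  per-respondent rank file from which every index in the inequality table
  can be recomputed exactly.

## Problem sizes used in validation

The package's own simulation checks run at sizes chosen to balance
resolution against runtime: identity and oracle checks on 1,000 random
samples; SE coverage at $n = 2{,}000$ over 500 replicates; null-HI coverage
at $n = 50{,}000$ over 200 replicates; sign recovery at $n = 10{,}000$ over
200 replicates; coefficient recovery at $n = 50{,}000$. Module-level
variants of the same properties run at smaller sizes.

## A worked run

```{r example, eval = FALSE}
cfg <- default_share_like_config(n_per_country = 2000, seed = 1)
tab <- generate_microdata(cfg)

# inequality: who uses care?
it <- inequality_table(tab, outcomes = "formal", ranks = "income")

# inequity: who uses care, at equal need?
ht <- horizontal_inequity_table(tab, outcomes = "formal", ranks = "income")

# or the whole study at once
res <- run_study(study_config(synthetic = cfg, output_dir = tempdir()))
```

## Known limitations

HI inference treats the need-prediction as fixed under the convenient SE
(use the bootstrap when model noise matters); the logit-engine HI identity
is approximate by construction; the generator's independence assumptions
are stated above; and no decomposition of CI/HI into covariate
contributions, dominance tests between concentration curves, or
longitudinal standardization is provided.
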