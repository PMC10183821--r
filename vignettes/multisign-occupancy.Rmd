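---
title: "Multi-sign dynamic occupancy models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sign dynamic occupancy models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pikasign)
```

This vignette documents the statistical model implemented in `pikasign`,
the assumptions behind it, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical results; all numbers quoted in the README
are printed by the code there, and the test suite computes every
quantitative claim it asserts.

## The state process

Occupancy is a latent binary state `z[i, t]` per site and calendar year.
Initial occupancy is logit-linear in substrate complexity with a park
random intercept and a park random slope on complexity (complexity is a
known driver of pika site use, and its effect plausibly differs among
parks). Subsequent years follow the usual dynamic-occupancy kernel: an
occupied site persists with probability `1 − ε[i, t]`, an empty one is
colonized with probability `γ[i, t]`. Both are logit-linear in site
covariates (defaults: forb and shrub cover for colonization, forb cover
for extinction) plus a park-by-year random intercept per process.

Two structural decisions deserve comment:

* **The modeled year grid is every consecutive calendar year** spanned by
  the data, even years with no surveys anywhere. The transition kernel is
  defined per annual step; skipping unsurveyed years would conflate
  multi-year transitions with annual rates. Unsurveyed site-years simply
  contribute emission likelihood 1.
* **Random effects are park-by-year intercepts** (each park has its own
  annual deviation, with one scale parameter per process). This is the
  richest structure that still supports between-park correlation of
  annual process variation, which `process_correlations()` computes from
  the posterior means of those deviations. A crossed park + year
  structure would force every park to share annual shocks and make that
  correlation degenerate.

## The observation process

Each sign type (FS, FH, PC, PS) is an independent Bernoulli detection
process given the latent state: probability `p_s` (logit-linear in survey
covariates) at occupied sites, `p^ξ_s` at unoccupied ones. Ambiguity is
the identifiability anchor: an unambiguous observation has `p^ξ = 0`, so
any site-year carrying one is known occupied, and the contrast between
ambiguous and unambiguous detections lets the data separate false
positives from true ones. Without any unambiguous observations the
false-positive rates are only weakly identified, and `fit_occupancy()`
warns accordingly.

Ambiguity rules, in order: sightings are unambiguous whenever detected
(observers only record high-confidence sightings); haypiles and calls are
never unambiguous (browse can be another herbivore's; a call can come
from outside the plot); fresh scat is unambiguous when its notes contain
a mucous-bound morphology keyword (*stuck, pyramid, tower, perched,
stacked, teepee, cluster* — matched case-insensitively on word stems,
since note-takers inflect freely) or when a fresh haypile co-occurs in
the same survey. Records without notes are classified ambiguous except
through the sighting and co-occurrence rules, which need none; this is
the right behaviour for datasets whose early years lack consistent
note-taking. The co-occurrence rule enters only through this
deterministic upgrade — sign types remain conditionally independent given
`z`; no joint emission term is modeled.

Default observation designs (configurable via `default_obs_designs()`):
scat detectability varies by survey period (single- vs multi-observer
eras); haypile detectability by complexity and forb cover; calls and
sightings by season and complexity. False-positive designs mirror the
processes plausibly driving misidentification: period for scat, forb for
haypiles, season and complexity for calls. Sightings have no
false-positive design at all.

## Covariates

Percent covers and climate covariates are standardized (mean 0, sd 1 —
covers over sites, climate over all modeled site-years) so coefficients
are comparable across covariates; complexity is centered to
`{−1, 0, +1}`. Missing complexity is imputed at the neutral centered
value 0 with a retained missingness flag — dropping those sites would
discard an entire park in the motivating dataset. Standardization
constants are stored for inverse transforms, and pairwise absolute
correlations among quantitative covariates above 0.75 trigger a warning
(strongly collinear covariates should not share a linear predictor).

## Priors

Defaults (`prior_spec()`): normal(0, sd 3.16) on all logit-scale
coefficients — vague, but avoiding the sd ≥ 10 priors that pile mass at
probabilities 0 and 1; gamma(1, 1) on each random-effect precision;
probability-scale intercepts are initialized from uniform(0, 1) draws
mapped through the logit. Results may be mildly sensitive to these
hyperparameters for weakly identified blocks (notably the random-effect
scales with few parks); they are all arguments.

## Inference

The sampler works on the *marginalized* likelihood: a two-state forward
recursion integrates the latent path out of every site's likelihood, so
the chain never conditions on imputed states and mixes far better than
data-augmented samplers at the same iteration count. Updates are
scalar adaptive random-walk Metropolis (Robbins–Monro adaptation of step
sizes toward 0.44 acceptance, during burn-in only, so the post-burn-in
kernel is fixed and valid); random-effect scales are drawn exactly from
their conjugate gamma conditionals; latent states are recovered at
retained iterations by forward-filtering backward-sampling, which is what
`occupancy_rates()`, `turnover_rates()` and `detection_rate_table()`
consume.

Numerical choices:

* The forward filter runs on the probability scale with per-step
  normalization (mathematically equivalent to log-space recursion); the
  per-site log-likelihood accumulates the log of the running product of
  normalizers, flushed whenever it drops below 1e−250 so it cannot
  underflow.
* Linear predictors are clamped to ±30 before the inverse logit, keeping
  probabilities in (1e−13, 1 − 1e−13); the only exact zeros are the
  structural ones (unambiguous observations, sightings, the
  no-false-positive variants), and an impossible configuration returns a
  log-likelihood sentinel of −1e300 so Metropolis rejects it cleanly.
* Update blocks recompute only what a parameter touches: a detection
  coefficient refreshes its sign's survey probabilities and all site
  forwards; a park-year random effect refreshes one park's transition
  probabilities in one year and that park's forwards.

Convergence is monitored with split-chain Gelman–Rubin statistics
(constant chains are defined to have R-hat 1), and a fit whose structural
parameters exceed the threshold (default 1.1) is automatically rerun once
with doubled iterations, with a persistent warning — never silently
looped. The default `sampler_config()` is desk-scale (3 chains × 10,000
iterations, half burn-in); `paper_sampler_config()` provides the
heavyweight production configuration (3 × 100,000 thinned by 10, 50,000
burn-in). Latent-state draws are stored for a thinned subset of retained
iterations (default ~150 per chain) to bound memory; all derived
summaries are Monte-Carlo averages over that subset, paired with the
matching parameter draws.

The posterior predictive check follows the binary sum-of-squared-error
discrepancy: per retained draw, `T = Σ_j (y_j − pd_j)²` over surveys for
the observed data and for a replicate simulated from the same draw, with
`pd_j` the detection probability given the drawn state of survey *j*'s
site-year. The p-value is the fraction of draws with `T_rep ≥ T_obs`. An
alternative would aggregate counts per site-year before squaring; the
per-survey binary version is used because it is defined identically for
all sign types and variants.

## Observation-model variants

`apply_variant()` defines the reduction rules: `nofp` removes all
false-positive blocks (`p^ξ ≡ 0`); `standard` collapses detections to a
single any-sign binary with one coefficient vector (default design:
intercept, season, survey period); `perfect` removes the observation
layer — a surveyed site-year is pinned to its any-sign indicator, with
replicate surveys OR-ed together (under perfect detection a detection in
any replicate implies occupancy, and a blank replicate alongside a
detection carries no extra information), and unsurveyed site-years remain
latent. The reductions are exact limits: the test suite verifies that the
full likelihood with false-positive coefficients pushed to −∞ equals the
`nofp` likelihood, and that a single-sign `nofp` model equals `standard`
on the collapsed data.

## Derived summaries

* **Occupancy series**: per draw, the fraction of *monitored* sites
  (≥ 1 survey that park-year) with `z = 1`; the monitored-sites
  denominator is used because unsurveyed park-years are exactly the ones
  a monitoring report would flag as missing. 90% equal-tailed intervals
  for occupancy rates, 95% for coefficients.
* **Trends**: weighted least squares of posterior-mean occupancy on year,
  weights = inverse posterior variance, significance at α = 0.1.
* **Detection-rate table**: raw detection frequencies classified by the
  drawn state of each survey's site-year, each survey weighted equally
  (so site-years with resurveys contribute proportionally to their survey
  count), averaged over draws, per park and pooled.
* **Turnover**: two rates are reported. `compare_variants()` gives the
  posterior mean of site-year-averaged transition *probabilities*, and
  `turnover_rates()` the posterior *realized* transition frequencies of
  the latent states. With a strong covariate effect (the default
  extinction–forb coefficient is −2.7) these differ materially: averaging
  a convex-then-concave inverse logit over standardized forb inflates the
  unconditional mean probability, while realized extinction is computed
  over the occupied (exposure-weighted, higher-forb) site-years. Single
  headline "rates" should be read as the realized ones.

## The synthetic-data generator

`sim_scenario()` defaults emulate the motivating monitoring program: 5
parks × 100 sites, modeled years 2010–2021 with 2015–2016 unsurveyed, a
10% chance a park skips a surveyed year, 30% resurveys drawn within the
closure period (no state change between replicates), seasons split
roughly evenly, and the survey-period covariate switching in 2017.
Generating parameters default to the fitted full model's posterior
operating point (scat detection ≈ 0.8, haypiles ≈ 0.29, calls ≈ 0.41,
sightings ≈ 0.13; false-positive rates of 2–4%; colonization and
extinction intercepts near 6%; the reported covariate coefficients),
because parameter-recovery experiments are most informative near the
regime the model is actually used in. The probability that a true scat
detection presents unambiguous features defaults to 0.3 — the empirical
fraction is not reported anywhere, so this is a free knob that mainly
controls identifiability strength. Covariates come from bounded beta
distributions (covers), a uniform three-level complexity, and climate
with park means plus annual and site deviations.

The generator deliberately does **not** emulate: spatial autocorrelation
or distance-dependent colonization (the model has none), observer
experience effects, free-text notes (ambiguity is drawn directly),
within-season state change, sign counts beyond the binary summary, or
old-sign misclassification dynamics. Passing recovery tests on these data
therefore show that the estimator is correct *for the model's own
assumptions*, not that real surveys satisfy those assumptions.

## Problem sizes used by the checks

The test suite runs recovery, directional-bias and calibration
experiments on 20 replicate datasets at a reduced scale chosen to keep
the default suite quick: 3 parks × 40 sites over 2014–2021 with the
2015–2016 gap, fitted with 3 chains × 5,000 iterations (half burn-in).
The acceptance script runs the full-scale default scenario once per
variant with the same sampler length. The enumeration oracle checks the
forward recursion against all `2^T` latent sequences for histories up to
T = 6 at tolerance 1e−10.

## Known limitations

* Sign types are conditionally independent given occupancy; correlated
  misidentification (e.g. one surveyor misreading both scat and haypiles
  at the same visit) is not modeled.
* Two latent states only — no "old sign / formerly occupied" state, and
  no count-valued emissions.
* False-positive identifiability rests entirely on the unambiguous
  observations; programs without them should use the `nofp` variant or
  expect prior-driven false-positive estimates.
* With few parks the random-effect scales are weakly identified and
  their posteriors lean on the gamma(1, 1) prior.
* The stepwise-AIC screening stage assumes perfect detection by
  construction; it is advisory input to the Bayesian fit, not inference.
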