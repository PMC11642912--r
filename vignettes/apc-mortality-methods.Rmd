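---
title: "Correcting death records and fitting age-period-cohort models on a Lexis grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting death records and fitting age-period-cohort models on a Lexis grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexisapc)
```

## The problem

Suicide mortality recorded in vital-registration systems is distorted in
two well-known ways. First, a substantial share of true suicides is
certified under *garbage codes* — events of undetermined intent (ICD-10
Y10–Y24 family, ICD-9 E980–E985), or sequelae of self-inflicted injury —
or mis-certified as accidents or assaults of the same mechanism. Second,
registration itself is incomplete, with coverage varying by region and
improving over decades. Any trend analysis that skips these corrections
confounds real epidemiology with changes in certification and coverage.

This package implements the full pipeline for method-specific suicide
rates among women aged 10+ on a 5-year Lexis grid: record correction,
descriptive rates, and Poisson age–period–cohort (APC) modelling
identified through estimable functions. A synthetic-data generator with a
known APC surface closes the loop, letting every stage be validated
against ground truth.

## Cause mapping

`causeMap()` ships a versioned table of inclusive ICD-9 (E-code) and
ICD-10 ranges classifying codes into mechanism (hanging/strangulation/
suffocation HSS, autointoxication AUT, firearm FA) × intent (suicide,
accident, assault, undetermined, sequelae). Two editorial decisions are
baked into the packaged table and flagged in its `source` column:

* suicide ranges are published per mechanism only for firearm
  (E955 / X72–X74); the HSS (E953 / X70) and AUT (E950–E952 / X60–X69)
  suicide rows are the standard ICD blocks for those mechanisms and are
  flagged `inferred`;
* the undetermined-poisoning ICD-10 range is stored as Y10–Y19 (the
  canonical undetermined self-poisoning block);
* sequelae of self-inflicted injury (E959 / Y87) identify no mechanism;
  the row carries `mechanism = NA` and is handled specially below.

## Record correction

**Garbage redistribution.** Within each stratum — by default
region × 5-year period × age group × mechanism —
`redistributeGarbage()` reallocates undetermined-intent and sequelae
deaths across the stratum's determined intents (suicide, accident,
assault) proportionally to their observed distribution. Totals are
conserved exactly and suicide counts never decrease. The choice of
strata, the garbage intents, and optional fractions of accident/assault
deaths to feed into the pool are all configuration, because the
literature on suicide under-certification is not unanimous on which
intents to reclaim; the default reclaims only undetermined + sequelae,
which is the conservative reading.

Degenerate strata (garbage present, no determined deaths) are resolved by
progressively coarsening the stratum — dropping age group, then period —
and, if nothing determined exists even at (region, mechanism) level,
leaving the garbage in place unless `allowAllToSuicide = TRUE`. Every
fallback is recorded in an audit table attached to the result (and
written to `correction_audit.csv` by the pipeline). Sequelae, having no
mechanism, redistribute across *all* mechanisms' determined deaths within
(region, period, age group).

Redistribution produces fractional deaths; these are carried as reals
end-to-end and rounded only for display, to avoid compounding bias.

**Coverage.** `applyCoverage()` divides counts by the registration
coverage of the record's (region, decade), supplied as a factor table in
(0, 1]. Coverage factors are *inputs* here — estimating them (e.g. by
death-distribution methods) is a separate exercise. Correction order is
misclassification first, then coverage; since coverage is constant within
a stratum-decade the two stages commute up to that resolution.

## Rates

`ageSpecificRate()` is deaths/person-years × 100,000.
`directStandardize()` uses the WHO world standard population, packaged as
5-year weights with 80+ collapsed and renormalized to ages 10+ by
default, because the study population excludes children under 10 (a
`minAge = 0` option keeps the full standard). `movingAverage()` smooths
annual series with centered triennial windows; the endpoint rule is not
standardized anywhere, so we use symmetric partial windows (the mean of
the two available values) to preserve series length for plotting, with a
`"trim"` option that returns NA at the ends instead.

`buildLexis()` aggregates corrected suicide-intent deaths of one
mechanism and the person-years onto the I × J grid. The cohort index is
k = j − i + I, constant along diagonals; for the default grid the labels
run 1900–1904 … 2005–2009. Each synthetic 5-year cohort actually spans
ten birth years (a 5-year age group crossed with a 5-year period); we
follow the conventional 5-year labelling and note the overlap here rather
than pretending otherwise.

## The APC model and its identification

Counts are Poisson, log-linear in age, period and cohort with log
person-years offset. The design is categorical — one free parameter per
5-year category, which matches how the effects are reported (per-category
rate ratios); smooth-function effects would be a natural extension but
are not the default. Fitting is plain IRLS via `stats::glm`; no
overdispersion adjustment is applied (the model is specified as plain
Poisson), but the deviance/df dispersion diagnostic is carried in the
fit's options so a user can see when it matters. Zero-count cells are
retained; cells with zero person-years are excluded with a warning.

Because cohort = period − age, the full model is rank-deficient by
exactly one linear dependence, and only estimable functions are reported:

* **drift**: the sum of the period and cohort slopes under a chosen inner
  product, divided by 5 to give a per-year log rate ratio. Slopes are
  weighted least-squares slopes against the category index; the weights
  are `"uniform"` by default with a `"personYears"` option, since the
  drift/curvature split (not the fitted model) depends on this choice and
  the convention is genuinely open in the literature.
* **curvatures**: period and cohort effects projected onto the orthogonal
  complement of {constant, linear} under the same weights, re-anchored so
  the reference category (period 2000–2004, cohort 1950–1954 by default)
  is exactly 1 with a degenerate [1, 1] interval.
* **drift allocation**: the drift has to live somewhere; by default it is
  folded into the cohort curve (`driftTo = "cohort"`), so period RRs are
  slope-free and cohort RRs carry the long-run gradient. The opposite
  convention is one argument away, and the fitted rates are provably
  identical either way — the invariance is asserted to 1e-8 in the test
  suite.
* **age curve**: the remainder, a function of age alone, reported as
  fitted rates per 100,000. It carries the longitudinal age trend (age
  slope plus period slope), i.e. the age-specific rates adjusted for
  period and cohort curvature.

Confidence intervals are Wald intervals on the log scale from the GLM
covariance, propagated through the (linear) estimable-function map by the
delta method. Aliased coefficients are fixed at zero — a valid
representative of the equivalence class, since every reported quantity is
invariant to the unidentified transformation.

The six-model deviance ladder (age; age-drift; age-cohort; APC;
age-period; age-drift) is reported with residual deviance, residual df, a
deviance-based AIC (residual deviance + 2 × parameters, which ranks
models identically to the likelihood AIC and — unlike the likelihood —
stays defined for fractional corrected counts), and likelihood-ratio
p-values between successive pairs, which are nested in one direction or
the other along the ladder. The two age-drift rows are the same model
space indexed by period or cohort, and their deviances agree to numerical
precision — a built-in consistency check. The table reports both AIC and
LRT without an automatic verdict; when they disagree, the choice of
"best" model is the analyst's.

The drift is estimated from the full model by default; the age-drift
model's estimate is also carried in the fit for comparison, as the two
differ in finite samples. Trend classification follows the CI-versus-1
rule: Upward if the lower bound exceeds 1, Downward if the upper bound is
below 1, Stationary otherwise.

## The synthetic generator

`syntheticScenario()` defines the generating truth: log baseline rates
per age group, an annual drift, zero-slope period and cohort curvature
vectors (any supplied shape is detrended on construction, so drift is
identified against them *exactly*), person-years per (year, age group)
cell, misclassification fractions, and coverage by decade. Defaults
emulate the study conditions the package targets: the 15 × 8 grid over
1980–2019; an age curve rising from ~0.4 per 100,000 in adolescence to a
mid-life plateau around 1.4 per 100,000 (the magnitude of female
method-specific suicide rates); annual drift RR 1.02 (the order of the
published HSS drifts); mild sinusoidal curvatures; one million female
person-years per (year, age-group) cell, giving roughly 6,000 deaths per
40-year series — a mid-sized region; 15% of suicides mis-certified as
undetermined, 5% as accident, 2% as assault (together ~22%, consistent
with correction factors of ~1.3 reported for poorly-certified settings);
and coverage rising 0.80 → 0.95 across the four decades, the range
reported for the weaker regional registries.

`simulateScenario()` draws Poisson counts per single calendar year with
the Lexis cell's rate applied uniformly within the cell (the model is
defined on the 5-year grid; no within-cell gradient is invented), then
emits annual records carrying the mechanism's true suicide code — ICD-9
before 1996, ICD-10 after, mirroring the registry transition — so the
downstream binning and revision handling is genuinely exercised.
`degradeRecords()` is the exact inverse of the correction: a multinomial
re-certification per record row followed by binomial thinning at the
(region, decade) coverage. Both are deterministic given the scenario
seed. One scenario is one region; multi-region studies are a list of
scenarios fitted independently.

What the generator does *not* emulate: real secular changes in
certification practice (fractions are constant over time), within-cell
age/period gradients, migration between regions, and record-level
covariates. Passing tests therefore demonstrate that the pipeline's
*logic* is correct and that parameters are recovered under the stated
degradation model — not that any particular real registry satisfies that
model.

## Numerical choices

* Detrending uses exact weighted projections; scenario curvatures satisfy
  the zero-slope invariant to 1e-10 by construction.
* The IRLS fit runs to `glm`'s default convergence with a 100-iteration
  cap and errors if unconverged; an independent BFGS maximization of the
  Poisson log-likelihood on a toy grid agrees with IRLS to better than
  1e-6 in deviance (asserted in tests).
* Reference-category RRs are set to exactly 1 (their computed value is 0
  on the log scale by construction; the assignment removes floating-point
  dust from the anchoring subtraction).
* Proportional redistribution is exact conservation arithmetic; no
  rounding happens inside the pipeline.
* Deviance uses 2Σ[D log(D/D̂) − (D − D̂)] with 0·log 0 = 0.

## Problem sizes in the validation suite

The simulation-backed checks use the default scenario (~6,000 deaths per
replicate): 100 replicates for drift-recovery coverage, 50 grids for the
deviance-nesting sweep, 25 replicates per arm for the drift-LRT
level/power check, and a high-rate scenario (~1.2 × 10^5 deaths) for the
correction round-trip, which is verified to undo known degradation within
2% on pooled totals. These sizes give Monte-Carlo error comfortably below
the margins asserted while keeping the suite quick to run.

## Known limitations

* The redistribution scheme is proportional within strata; if
  certification bias is correlated with covariates not in the strata
  (e.g. race, urbanicity), the correction inherits that blind spot.
* Coverage is applied uniformly within a decade; sub-decade coverage
  changes alias into period effects.
* Wald intervals on the log scale can be optimistic for cells with very
  few deaths; the dispersion diagnostic should be consulted.
* The drift/curvature split depends on the detrending weights; both
  conventions are exposed, and only fitted rates and deviances are
  convention-free.
* No Bayesian, intrinsic-estimator or partial-least-squares
  identification schemes, and no projections.
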