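# lexisapc

Age–period–cohort (APC) analysis of method-specific suicide mortality from
vital-registration death-record tables, with the two corrections such data
need before any trend can be trusted: redistribution of garbage-coded
deaths (undetermined intent, sequelae) back to determined intents, and
inflation for incomplete death registration.

The package is aimed at epidemiologists working with cause-of-death
tabulations from registries of uneven quality — the motivating setting is
female suicide by hanging/strangulation/suffocation (HSS), autointoxication
(AUT) and firearm (FA) on a 15 × 8 Lexis grid (5-year age groups 10–14 …
80+, quinquennia 1980–1984 … 2015–2019, hence K = I + J − 1 = 22 birth
cohorts) — but the machinery is generic in the grid.

## The model

Deaths D<sub>ij</sub> in age group *i* and period *j* are Poisson with

log E[D<sub>ij</sub>] = log N<sub>ij</sub> + μ + α<sub>i</sub> + β<sub>j</sub> + γ<sub>k</sub>,  k = j − i + I,

where N<sub>ij</sub> are person-years. Because cohort = period − age, the
three time effects are linearly dependent and only *estimable functions*
are identified: curvatures (detrended effects), the **drift**
β<sub>L</sub> + γ<sub>L</sub> (total linear time trend, reported as annual
rate ratio), the longitudinal age trend α<sub>L</sub> + β<sub>L</sub>, and
the fitted rates. `estimableDecomposition()` fits the full model by IRLS
and reports exactly these: a six-model nested deviance ladder
(age / age-drift / age-cohort / APC / age-period / age-drift), the drift
with a delta-method 95% CI and an Upward/Downward/Stationary
classification, and period and cohort rate ratios anchored at reference
categories (period 2000–2004, cohort 1950–1954 by default; the reference
rows are exactly 1 with degenerate CIs).

A synthetic-data module generates registry-shaped annual records from a
known APC surface, mis-certifies a fraction of suicides as
undetermined/accident/assault of the same mechanism, and thins them by
registration coverage — so the whole correct → rates → fit pipeline can be
scored against ground truth.

## Worked example

```r
library(lexisapc)

sc <- syntheticScenario(seed = 42L)    # 1.02 annual drift RR, 15 x 8 grid
res <- runPipeline(sc, outDir = "apc-out")
res$fit
```

```
APCFit (Poisson age-period-cohort, estimable functions)
  drift: annual RR 1.016 (1.014-1.019) — Upward
  references: period 2000 to 2004 | cohort 1950 to 1954 
  drift carried by: cohort | detrending weights: uniform 
  dispersion (dev/df): 1.309 
  deviance table:
             model resDev resDf   AIC      pLRT
               Age  396.4   105 426.4        NA
         Age-drift  161.9   104 193.9 6.410e-53
        Age-Cohort  110.7    84 182.7 1.460e-04
 Age-Period-Cohort  102.1    78 186.1 1.977e-01
        Age-Period  153.2    98 197.2 1.552e-04
         Age-drift  161.9   104 193.9 1.863e-01
```

Reading this: the fitted annual rate ratio is 1.016 (95% CI 1.014–1.019),
an Upward trend — rates grow ~1.6% per calendar year for this draw of the
1.02-drift scenario. The deviance ladder shows drift is overwhelmingly
needed (p ≈ 1e−53), cohort curvature improves on drift (p ≈ 1e−4), and
the full APC model's p against age-cohort reflects the simulated period
curvature. `periodRR(res$fit)`, `cohortRR(res$fit)` and
`ageCurve(res$fit)` return the RR curves and the longitudinal age-rate
curve per 100,000; `runPipeline()` also writes them as CSV alongside a
correction audit and a JSON manifest.

Smaller pieces are exposed individually: `mapCause()` (ICD-9/ICD-10 →
mechanism × intent), `redistributeGarbage()` / `applyCoverage()` (the two
correction stages), `ageSpecificRate()`, `directStandardize()` (WHO world
standard, renormalized to ages 10+), `movingAverage()` (triennial
smoothing), `buildLexis()`, `nestedDevianceTable()`, `classifyTrend()`,
and `proportionalMortalityChange()`.

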