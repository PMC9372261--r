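# modmod

Moderated moderation analysis for questionnaire cohorts: scale scoring
and reliability, depression screening, three-way interaction OLS with
simple-slope probing and slope-difference tests, Monte-Carlo power, and
a synthetic item-level cohort generator.

## What it is for

A recurring design in mental-health epidemiology asks whether a buffer
weakens a risk relationship, and whether a second resource modifies the
buffering itself. The motivating application: interpersonal sensitivity
(X, SCL-90 subscale) predicting depressive symptoms (Y, PHQ-9) among
college freshmen, with psychological capital (M, PCQ-24) as internal
buffer and perceived family support (W, 20 binary items) as the external
resource acting on the buffer. On standardized variables the package
fits

```
model 1:  Y = b0 + b1 X + b2 M + b3 XM + e
model 3:  Y = b0 + b1 X + b2 M + b3 XM + b4 W + b5 XW + b6 MW + b7 XMW + e
```

from first principles (QR solve, t inference on n−k−1 df), probes the
three-way interaction via the four simple slopes at ±1 SD of both
moderators,

```
slope(m, w) = b1 + b3 m + b5 w + b7 m w ,   (m, w) ∈ {±1}²
```

tests all six pairwise slope differences as linear contrasts of
(b3, b5, b7) with covariance-based z tests (the Dawson–Richter
procedure), and estimates power for the XM and XMW terms by Monte-Carlo
simulation under `Y = D b + Normal(0, 0.8)` noise. A configurable
generator produces item-level cohorts (PHQ-9, IS, PCQ-24, FS items)
with a chosen correlation and regression structure plus exact counts of
contaminated records, so the whole chain — scoring, reliability
(Cronbach's α, KR-21), exclusion rules, PHQ-9 ≥ 5 screening, Harman's
single-factor test, model fitting, probing, power — runs and is tested
without any raw survey data.

## Worked example

```r
library(modmod)

cfg <- generator_config(n_respondents = 694, seed = 2024,
                        contamination = c(incomplete = 0.02))
cohort <- generate_cohort(cfg)
screening_report(cohort)
#> Screening report (PHQ-9 >= 5)
#>   raw records:      694
#>   excluded:         14 (2.02%)  [incomplete=14, straight_line=0, patterned=0]
#>   retained:         680
#>   screen positive:  583 (prevalence 85.74%)
```

Exactly `round(0.02 * 694) = 14` records were planted with missing items
and exactly those 14 are excluded; prevalence is high because the
generator's defaults emulate the *screened* analysis sample, whose mean
PHQ-9 is already above threshold.

```r
scores <- score_cohort(apply_exclusions(cohort)$retained)
fit <- fit_model(scores, model = 3)
fit
#> Interaction model 3 (n = 680)
#>      term estimate    se      t     p   llci   ulci
#>  constant   -0.046 0.038 -1.193 0.233 -0.121  0.029
#>         X    0.304 0.039  7.715 0.000  0.227  0.381
#>        XM   -0.138 0.037 -3.768 0.000 -0.210 -0.066
#>       ...
#> R-squared 0.148, F(7, 672) = 16.682
```

Interpersonal sensitivity predicts depression (b1 = 0.304) and PsyCap
weakens that link (b3 = −0.138 < 0), recovering the structure the
generator was configured with. Probing a *published* coefficient table
needs no raw data at all:

```r
fit_pub <- model_fit_from_coefficients(study_coefficients(), n = 694)
slope_difference_tests(fit_pub)[, c("pair", "difference")]
#>          pair difference
#> 1 (1) and (2)      0.088
#> 2 (1) and (3)     -0.060
#> 3 (1) and (4)     -0.276
#> 4 (2) and (3)     -0.148
#> 5 (2) and (4)     -0.364
#> 6 (3) and (4)     -0.216
```

Slope 1 is "high PsyCap, high FS", slope 4 "low PsyCap, low FS"; e.g.
the (2, 4) contrast 2(b3 − b7) = −0.364 says the X→Y slope is much
shallower for high- than low-PsyCap respondents when family support is
low. Power at the fitted two-way effect, on a fixed design calibrated to
the published standard errors:

```r
sc <- power_scenario("A", predictor_mode = "calibrated", reps = 1000, seed = 1)
power_at(sc, -0.106)
#>   effect power       mc_se reps
#> 1 -0.106 0.921 0.008529889 1000
```

`run_pipeline(pipeline_config(...))` chains
simulate → score → screen → fit → slopes → power and writes one CSV/JSON
artifact per stage; `inst/cli/modmod.R` is a thin command-line wrapper
over the same functions.

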