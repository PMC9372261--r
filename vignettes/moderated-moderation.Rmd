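---
title: "Moderated moderation: models, probing, power and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated moderation: models, probing, power and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmod)
```

## The problem

Interpersonal sensitivity — discomfort, feelings of inferiority and
rejection-sensitivity in social interaction — is a robust predictor of
depressive symptoms, particularly in college freshmen. Two buffering
resources are of interest: psychological capital (PsyCap, an internal
composite of self-efficacy, optimism, hope and resilience) and perceived
family support (FS, an external resource). The scientific question is a
*moderated moderation*: does PsyCap weaken the interpersonal
sensitivity → depression link, and does family support in turn modify
that buffering effect?

`modmod` implements the full analysis chain for this design —
questionnaire scoring and reliability, data-quality screening, the
interaction models with their probing machinery, and Monte-Carlo power —
plus a synthetic item-level cohort generator so that every stage can be
exercised and tested without access to raw survey data.

## Instruments and scoring

Four instruments are scored by simple item sums (`score_scale()`,
`score_cohort()`):

| scale   | instrument            | items | item range | total range |
|---------|-----------------------|-------|------------|-------------|
| dep     | PHQ-9                 | 9     | 0–3        | 0–27        |
| is      | SCL-90 IS subscale    | 9     | 0–4        | 0–36        |
| psycap  | PCQ-24                | 24    | 1–6        | 24–144      |
| fs      | family support        | 20    | 0/1        | 0–20        |

Any missing item voids that respondent's scale total — no prorating,
consistent with the screening stage's outright exclusion of incomplete
questionnaires. PHQ-9 totals are banded at the conventional thresholds
5/10/15/20 (`severity_band()`): none / mild / moderate / moderately
severe / severe.

Reliability is reported as Cronbach's α (`cronbach_alpha()`) and, for the
binary family-support items, KR-21 (`kr21()`). Both use population
(divide-by-n) variances; at realistic sample sizes the choice moves the
third decimal only, but it is fixed and documented so the worked examples
are exactly reproducible.

## Screening

`apply_exclusions()` implements three concrete data-quality rules:

* **incomplete** — at least one missing item anywhere;
* **straight_line** — identical answers on every item of at least two of
  the three *polytomous* instruments (PHQ-9, IS, PCQ-24). The binary FS
  scale is deliberately excluded from this rule: a constant binary
  response (e.g. "yes" to all 20 family-support items) is a legitimate
  and common answer pattern, not evidence of careless responding;
* **patterned** — a strict two-value alternating cycle across all items
  of any instrument.

The published criteria behind these rules are qualitative ("answers were
too short", "choices had a clear pattern"); the rules above are the
concrete, testable proxies this package commits to. Exclusion runs
*before* scoring; the PHQ-9 ≥ 5 screen (`screen_positive()`) runs after.
`screening_report()` assembles counts, exclusion percentage, severity
bands and the screening prevalence; `pearson_matrix()`,
`gender_t_test()` (pooled Student's t by default, Welch behind a flag,
all tests two-sided) and `harman_single_factor()` cover the preliminary
analyses. Harman's test uses the first unrotated principal component of
the pooled item correlation matrix — the extraction convention is not
universal, but PCA is the dominant choice and is deterministic; both an
item-level (62 items, the default) and a scale-level entry point are
provided.

## The interaction models

With Y = depression, X = interpersonal sensitivity, M = PsyCap and
W = family support, `fit_model()` fits, on standardized variables:

* **model 1** `Y = b0 + b1 X + b2 M + b3 XM + e`
* **model 3** `Y = b0 + b1 X + b2 M + b3 XM + b4 W + b5 XW + b6 MW + b7 XMW + e`

Two numerical conventions matter and are fixed:

* **Standardize, then multiply.** Components are z-scored (sample SD,
  n−1) before product terms are formed. This is what makes ±1 SD probing
  algebra exact: a "high PsyCap" slope is literally the contrast at
  m = +1. Standardizing the products themselves would destroy that
  correspondence.
* **t-based inference with n − k − 1 df.** `sigma2 = RSS/(n-k-1)`,
  covariance `sigma2 (D'D)^{-1}` from a QR solve, two-sided t p-values
  and t confidence intervals. At n = 694 the t critical value is 1.9635
  vs the normal 1.96 — below reporting precision, but the convention is
  fixed.

Rank-deficient designs raise a collinearity error naming the offending
columns; zero-variance variables raise a degenerate-variable error before
any algebra runs.

## Probing: simple slopes and slope differences

`simple_slopes()` evaluates the conditional effect of X,
`b1 + b3 m + b5 w + b7 m w`, at the four (±1 SD, ±1 SD) moderator
corners, numbered by the reporting convention (1 = high M high W,
2 = high M low W, 3 = low M high W, 4 = low M low W).
`slope_difference_tests()` forms all six pairwise contrasts; each
difference is a linear contrast of (b3, b5, b7) — for example
pair (1,2) = 2(b5 + b7) and pair (2,4) = 2(b3 − b7) — with standard error
`sqrt(c' V c)` from the coefficient covariance, a normal z statistic and
a 1.96-multiplier confidence interval. The z convention (rather than
t(686)) follows the slope-difference testing tradition and reproduces
published intervals; the numerical difference is below reporting
precision. `model_fit_from_coefficients()` lets all of this machinery run
directly off a published coefficient table — point estimates are then
exact and standard errors are `NA` unless a covariance is supplied.

```{r slopes}
fit <- model_fit_from_coefficients(study_coefficients(), n = 694)
simple_slopes(fit)[, c("slope", "label", "estimate")]
slope_difference_tests(fit)[, c("pair", "difference")]
```

`interaction_plot_data()` returns the eight predicted points behind the
classic three-way interaction plot; its line slopes equal the simple
slopes exactly.

## Monte-Carlo power

`power_scenario()` / `run_power()` estimate power for the XM (scenario A)
and XMW (scenario B) coefficients: per replicate, draw predictors, form
`Y = D b + e` with `e ~ Normal(0, 0.8)`, refit model 3, and record
whether the tested coefficient's two-sided p-value falls below alpha.
Defaults are the study conditions: n = 694, 1,000 replicates,
alpha = 0.05, baseline coefficients from the fitted model, grids
b3 = −0.03…−0.12 and b7 = 0.01…0.10.

Three predictor modes are provided because the predictor source is the
one genuinely underdetermined part of the published experiment:

* `simulate_mvn` (default) — fresh standardized trivariate-normal
  predictors each replicate, with the published correlations
  (−0.361, −0.286, 0.229). The natural choice for *prospective* power
  questions.
* `fixed_design` — one design drawn (or supplied) once; only the noise is
  redrawn. The classic conditional-power experiment.
* `calibrated` — a fixed surrogate design whose Gram-inverse diagonal is
  rescaled to match a *published* standard-error column exactly
  (`calibrated_design()`). Under a fixed design, power for a single
  coefficient depends on the design only through
  `sigma^2 [(D'D)^{-1}]_jj`, and that quantity is recoverable from the
  published SEs via `sigma_hat = sqrt((n-1)(1-R^2)/(n-k-1))`. Column
  rescaling breaks the literal product structure between columns — which
  is irrelevant for a linear-model simulation — so the matrix is a
  *surrogate* for the unavailable observed design, and is documented as
  such.

The calibrated mode exists because the two published power values
(90.8% for b3 = −0.106, 87.7% for b7 = 0.076) are mutually consistent
only with a fixed observed design: under fresh multivariate-normal
predictors the XMW column is substantially better conditioned than in
the real (bounded, screened) survey data, and scenario-B power comes out
near 77% — far from the published value — while the calibrated fixed
design reproduces both published numbers within Monte-Carlo noise. The
published description ("the noise term was drawn from a normal
distribution...") is itself consistent with redrawing only the noise.

Sub-seeding is per (grid point, replicate), so power curves are
reproducible point-wise and a single-point grid equals `power_at()`
under the same seed.

## The synthetic cohort generator

`generate_cohort()` emulates the *analysed* cohort (the screened sample
whose summary statistics are published):

1. **Latents.** (X, M, W) from a zero-mean unit-variance trivariate
   normal with the configured correlations; Y from the configured
   8-coefficient equation plus Normal(0, 0.8) noise
   (`generate_latents()`).
2. **Totals.** Latents are rescaled to the configured raw means/SDs
   (Y standardized by its sample moments first, because the generating
   equation's variance is not 1), rounded, and clipped to each
   instrument's feasible range.
3. **Items.** Each total is distributed over bounded items by uniform
   capacity-slot allocation (`discretize_to_items()`), which preserves
   totals exactly — totals being all the downstream analysis uses.
   Copulas and IRT-style item models are deliberately out of scope; a
   side-effect is that *item-level* internal consistency of generated
   cohorts (e.g. a PHQ-9 α near 0.5) is lower than real instruments
   achieve, because items share no factor structure beyond their common
   total.
4. **Contamination.** `round(rate * n)` records per class are corrupted
   to violate *exactly one* exclusion rule each. Clean records are
   "de-triggered" by minimal total-preserving adjustments so they can
   never trip a rule by accident — this is what makes contamination
   counts exact rather than approximate.
5. **Gender** is assigned independently of all scores (the study found
   no gender differences), at the published 59.65% female fraction.

One root seed; every stage derives its own sub-stream, so adding
contamination does not perturb the clean records.

Known, documented distortions of the emulation:

* **Family-support ceiling.** The configured FS mean and SD place the
  20-point cap at +1.26 SD, so ~10% of clean records are censored at the
  ceiling; the realized FS mean and SD are those of a censored normal
  (≈ 13.66 and 4.41), and FS correlations attenuate by ~2%. The
  parameters are kept as published — they are study conditions, not
  tuning knobs — and the tests check FS against the censored-normal
  oracle.
* **Model-implied vs printed correlations.** The generating equation
  with the published coefficients implies r(IS, Dep) ≈ 0.426, slightly
  above the printed 0.399 (the published equation and the published
  correlation matrix are not exactly mutually consistent). The
  round-trip tests therefore use a ±0.05 band.
* **Coefficient recovery scale.** Because the equation's Y-variance is
  ≈ 0.83, refitting on a *re-standardized* outcome recovers b/sd(Y);
  parameter-recovery tests are run on the generating (latent) scale.
* The generator produces exchangeable, unordered respondents; real
  survey data have clustering (classes, dorms), item-level missingness
  patterns and response styles none of which are emulated. Passing tests
  demonstrate the *analysis machinery* is correct under the stated
  generative model, not that the model captures every feature of real
  data.

`study_fixture_cohort()` is a separate, deterministic-count fixture for
the screening arithmetic: 2,359 records with depression totals assigned
band-by-band at the published counts and exactly 112 contaminated
records (47/47/18). It emulates screening *counts*, not the correlation
structure of the post-screening sample.

## Problem sizes used by the test suite

The packaged tests run the generator at n = 5,000 for moment and
correlation recovery, n = 50,000 (latents only) for coefficient
recovery, 1,000 replicates per power point at the study conditions and
2,000 replicates for the type-I calibration check, with a fixed seed per
test; smaller sizes are used for pure plumbing checks. These sizes keep
each Monte-Carlo assertion at 3 simulation standard errors or better.

## Limitations

* Only OLS with homoskedastic errors; no robust (HC) standard errors,
  bootstrap intervals, Johnson–Neyman regions, or mediation paths —
  probing is ±1 SD pick-a-point by design.
* The Harman test is a heuristic screen for common-method bias, not a
  substitute for a measurement model.
* The calibrated power mode reconstructs only the diagonal of the design
  geometry; published z/p values for slope differences that depend on
  the full unpublished coefficient covariance cannot be reproduced
  exactly, only their point estimates.
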