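---
title: "Age-specific LACE thresholds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-specific LACE thresholds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laceroc)
library(dplyr)
```

## The problem

The LACE index is an additive 0–19 risk score assigned at hospital
discharge, built from four components: **L**ength of stay (0–7 points),
**A**cuity of the admission (0 or 3), **C**harlson comorbidity (0–5) and
prior **E**mergency-department visits (0–4). A single cutoff — usually
"LACE ≥ 10" — is commonly used to label a patient high-risk for death or
readmission after discharge. Because age dominates post-discharge
mortality, a one-size cutoff misclassifies systematically at the extremes
of age: a threshold calibrated on a mixed-age population is far too high
for young adults (missing most of their deaths) and slightly too low for
the very old (flooding services with false positives). `laceroc`
implements the full analysis chain needed to evaluate this and to derive
age-band-specific thresholds: Charlson coding from ICD-10, LACE scoring,
ROC/AUC estimation, likelihood ratios, two-graph ROC threshold derivation,
and an age-stratified study pipeline — plus a calibrated synthetic cohort
generator so the whole chain is testable without access to hospital
records.

## Scoring: Charlson and LACE

Charlson comorbidity is computed from ICD-10 diagnosis codes with the Quan
et al. (2005) coding algorithm and the original condition weights
(1/2/3/6). Matching is by normalized prefix — codes are uppercased and
dots stripped, then compared against 3- and 4-character stems — which is
the standard way the Quan tables are applied to routine hospital coding.
Three severity hierarchies are enforced (diabetes with complications over
diabetes; moderate/severe over mild liver disease; metastatic solid tumour
over any malignancy), so adding a milder code to a set never changes an
index already dominated by the severe member. Whether a given study used
original or updated Charlson weights is often unstated in the literature;
this package uses the original weights and documents that choice here. The
mapping ships as a plain CSV (`charlson_map()`) and is user-replaceable.

The LACE C component bins the Charlson index as 0, 1, 2, 3, and 5 for any
index of 4 or more. The L component uses the published day-count bins
(`lace_los_bins()`). For the E component two dialects exist in the wild:
the source algorithm scores the visit count capped at 4 (`count_capped`,
the default here), while some descriptions read it as a binary 0-or-4
component (`binary`). Both are provided and both respect the 0–19 total;
the dialect is an argument throughout (`lace_score()`, `add_lace()`,
`cohort_config()`).

## ROC estimation

For integer scores the ROC is described threshold-wise over the full
integer grid from the minimum score to one above the maximum, under the
positivity rule *score ≥ t ⇒ test positive*:

- sensitivity(t) = P(score ≥ t | event), non-increasing in t,
- specificity(t) = P(score < t | non-event), non-decreasing in t.

The AUC is not read off this grid but computed as the Mann–Whitney
concordance from midranks — the probability that a random event outscores
a random non-event, ties counted ½ — which equals the trapezoidal area
under the step polygon (the package cross-checks the two to 10⁻¹² in its
tests, and checks exact agreement with a brute-force all-pairs oracle on
small instances). The default AUC standard error is the Hanley–McNeil
nonparametric formula (the default of the common commercial ROC
implementations), with the DeLong placement-variance estimator available
via `ci_method = "delong"`; the reported p-value is a two-sided z-test of
AUC = 50%. Hanley–McNeil is slightly conservative under strong ties; the
test suite verifies ≥ 90% coverage of the true AUC over 1,000 simulated
binormal cohorts of n = 500.

## Two-graph threshold derivation

`two_graph()` treats sensitivity and specificity as piecewise-linear
functions of the threshold between grid points and derives:

- **θ₀**, the equal-error threshold where the interpolated curves cross
  (sensitivity = specificity, i.e. maximum balanced accuracy). Since
  sensitivity starts at 1 and falls while specificity starts at 0 and
  rises, the crossing of a genuine ROC is unique. Linear interpolation is
  a documented choice, not an attempt to reproduce any particular vendor's
  interpolation; if the curves coincide over a flat segment, the segment
  midpoint is returned (tie-break, also used for the IR limits).
- the **intermediate range** at an accuracy level (default 95%): from the
  threshold where sensitivity falls to the level (lower limit) to the
  threshold where specificity rises to it (upper limit). Scores inside the
  range are "borderline"; lowering the level (e.g. `level = 0.90`)
  narrows it. A limit that cannot be attained inside the score range is
  clipped to the range end and flagged rather than extrapolated.

Likelihood ratios LR+ = se/(1−sp) and LR− = (1−se)/sp are evaluated at any
real threshold using the same interpolation; a specificity of exactly 1
yields an infinite LR+ flagged in the output, not an error. On integer
scores a half-point threshold such as 11.5 flags exactly the episodes
scoring ≥ 12; the equivalence is unit-tested.

## The study pipeline

`run_study()` orchestrates the whole analysis: schema validation, LACE
scoring (deriving Charlson from ICD-10 if needed), outcome definition
(death within 6 months, death within 30 days, and *frequent readmission* =
two or more readmissions within 28 days of the index discharge), age-band
assignment (18–49.9, 50–59.9, 60–69.9, 70–79.9, ≥ 80; lower-inclusive),
and per-cell ROC, two-graph, likelihood-ratio and threshold-impact
analyses for every outcome in every stratum (all patients + each band).
Likelihood ratios are evaluated at each stratum's own θ₀ — the reading of
"age-specific thresholds" adopted here; the threshold is configurable.
`threshold_impact()` compares two cutoffs by events captured, percentage
captured (1 decimal), false-positive rate and relative change; the oldest
band also compares the conventional cutoff 10 against 11.5 by default. A
stratum with no events (or no non-events) for an outcome is reported as
undefined with a warning and the run continues. Reports label rows as
episodes: no within-patient deduplication is attempted, and the 28-day
readmission window is taken to start at the index discharge date.

Report rounding follows the field's conventions (`report_study()`): AUC
and its CI as percentages to 1 decimal, p-values as "<0.001" below that
level, LRs to 2 decimals, θ₀ and IR limits to 1 decimal.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a two-financial-year NHS
cohort of consecutive alive-discharge unplanned-admission episodes:
32,270 episodes by default, split over the five age bands as
8,403 / 4,304 / 4,739 / 6,068 / 8,756, with band-wise outcome rates of
0.5/2.0/4.8/7.7/15.6% (death within 6 months), 0.2/0.7/1.8/2.9/6.0%
(death within 30 days) and 1.0/1.5/2.4/3.3/6.7% (frequent readmission).
Ages are uniform within each band (the top band truncated at 107, the
oldest age the cohort is meant to contain).

The component distributions are not dictated by any published source, so
they were fixed once at values a hospital-informatics analyst would call
realistic and are not tuned thereafter: length of stay geometric with mean
4 days; acuity emergent with probability 1 (the cohort is unplanned
admissions by construction); ED visits Poisson with mean 1 truncated at
10; and the Charlson index drawn directly from a decreasing categorical
distribution on 0–10 (≈ 55% of episodes carry at least one coded
condition). With `emit_icd10 = TRUE` each episode instead carries a
hierarchy-consistent ICD-10 code set that scores back to its Charlson
index, so the coding path is exercised end to end.

Outcomes follow a logistic model on the LACE score,
*logit P = a₍band₎ + slope · (lace − mean band lace)*, with the intercept
found by monotone root-finding (`calibrate_intercept()`; closed form
`qlogis(rate)` when the slope is 0) so each band's marginal rate hits its
target to 10⁻⁶. The slope (log-odds per LACE point; scalar or per-band)
is the discrimination dial: 0 gives AUC ≈ 0.5 and the AUC rises
monotonically with it. The default of 0.4 per LACE point produces
moderate-to-good discrimination (AUC around 0.75–0.80 at the default
score spread), in the range reported for LACE against mortality in the
literature. Death within 30 days is a Bernoulli thinning of death within
6 months with conditional probability equal to the band's rate ratio,
which guarantees the 30-day deaths are a subset of the 6-month deaths.
Readmission counts are drawn from a band-calibrated Poisson (mean chosen
so P(count ≥ 2) equals the band's frequent-readmission rate) conditioned
on the logistic frequent-readmission flag — ≥ 2 when flagged, ≤ 1
otherwise — so the count column, the modelled flag and the band rate stay
mutually consistent while the slope still controls the flag's
discrimination.

What the generator deliberately does **not** model: within-patient
correlation across episodes (episodes are independent records, matching
how the analysis treats them), seasonality, hospital sites, discharge
destinations, cancer/obstetrics exclusions (treated as upstream data
curation), or survival time beyond the two binary horizons. Passing tests
on synthetic cohorts therefore demonstrate that the *analysis machinery*
is correct and calibrated — not that real hospital data satisfy the
logistic model, and real-data AUCs or thresholds cannot be reproduced
from it.

## Numerical choices and degenerate inputs

- Intercept calibration: `uniroot` on a strictly increasing mean-probability
  function, interval extended upward as needed, tolerance 10⁻¹² on the
  intercept; target rates of exactly 0 or 1 have no finite intercept and
  are handled by constant outcomes.
- AUC is undefined without both an event and a non-event; this is an error
  at the `roc_curve()` level and a warned-and-skipped cell at the
  `run_study()` level.
- Curves that never cross (possible for hand-built or truncated curves,
  not for genuine ROC step curves) raise a typed no-crossing error.
- Confidence intervals are clamped to [0, 1]; with a degenerate (zero)
  standard error the AUC-vs-50% p-value degenerates to 0 or 1.
- Validation errors name the offending field; table validation reports
  row numbers.

## Problem sizes in the test suite

The suite exercises small exact oracles (all-pairs AUC up to n = 200,
exhaustive LACE grids of ~7,500 component combinations), mid-size
structural runs of the full pipeline (5 × 600 to 5 × 2,000 episodes),
and a few large stochastic checks chosen as the smallest sizes at which
the targeted tolerances are comfortably identifiable: θ₀ recovery within
0.25 points at n = 50,000, rate calibration at 20,000 episodes per band
over 10 seeds, AUC–slope monotonicity at n = 20,000, and CI coverage over
1,000 cohorts of n = 500. The full suite runs in well under a minute on
one core.

## Known limitations

- Prefix matching of ICD-10 codes cannot distinguish sub-codes a more
  granular dialect would separate; the mapping file is replaceable for
  such cases.
- θ₀ from piecewise-linear interpolation can differ by a fraction of a
  point from implementations that interpolate differently or smooth the
  curves; it is reported to 1 decimal for that reason.
- The Hanley–McNeil interval is symmetric on the AUC scale and can clip at
  1 for near-perfect classifiers; DeLong is available where that matters.
- Episodes, not patients, are the unit of analysis throughout.
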