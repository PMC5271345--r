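---
title: "Methods: score calculation, synthetic cohorts and validation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score calculation, synthetic cohorts and validation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meldkit)
```

## What meldkit models

Patients on a liver-transplant waiting list are prioritised by laboratory-based
prognostic scores. The reference score is MELD (Model for End-Stage Liver
Disease), a log-linear combination of serum creatinine, total bilirubin and the
INR; a family of variants adds serum sodium (MELD-Na, UKELD, refitMELD-Na),
recipient age (iMELD), re-estimated coefficients (refitMELD, upMELD) or a
sodium ratio (MESO index), and the pediatric PELD score replaces creatinine
with albumin plus age-under-one-year and growth-failure indicators. meldkit
implements all nine calculators and the machinery used to validate them
against the standard endpoint, death on the waiting list within 90 days of
listing: ROC/AUROC discrimination analysis with confidence intervals,
univariable screening with judgment-based collinearity resolution followed by
forward likelihood-ratio logistic regression, and a 20-point quality-appraisal
instrument for the score-development studies themselves.

## Score calculators and their handling rules

Each published score prescribes not just coefficients but *variable handling*:
floors, caps, a creatinine substitution under hemodialysis, and rounding.
These rules change results materially near the bounds, so they are implemented
exactly as published and audited per patient (`score_cohort()` appends an
`applied_rules` column naming every rule that changed an input).

Key choices, where the published descriptions leave room:

* **Rounding.** "Rounded to the nearest integer" is implemented as round-half-
  up on the positive axis (`floor(x + 0.5)`), the behaviour of clinical
  calculators, and applied only to MELD and MELD-Na — the only scores whose
  descriptions state rounding. MELD is computed, rounded, then capped at 40
  (equivalent to cap-then-round for this formula).
* **MESO and iMELD use the rounded integer MELD** ("MELD as above" includes
  its rounding) and apply no sodium clamp, because none is stated for them.
* **upMELD ignores dialysis.** Its published rule caps creatinine at 4.0
  mg/dl "with or without renal replacement therapy"; the dialysis
  substitution used by MELD (4.0) and refitMELD (3.0) does not apply.
* **refitMELD-Na enters BiliCC untransformed** in the sodium interaction term
  (bilirubin floored at 1, capped at 20 mg/dl, no logarithm), exactly as the
  validated formulation prints it.
* **PELD's under-1-year indicator** is computed from age at listing only. The
  published refinement (children listed before their first birthday keep the
  indicator until 24 months) needs listing *and* assessment dates, which the
  cohort schema does not carry; this is a documented simplification. Growth
  failure is forced to 0 above 219 months. PELD is unrounded, may be
  negative, and is computed for all ages by default, with
  `score_cohort(..., peld_max_age = 12)` available to mirror OPTN practice.
* **Units.** Formulas mix conventional and SI units, so the lab panel carries
  creatinine/bilirubin in both, converted with the standard factors 88.42
  (creatinine) and 17.104 (bilirubin) and albumin ×10; the cohort schema
  demands explicit unit tags rather than guessing (an albumin median of 31 is
  physiologically possible only in g/l, not g/dl — exactly the ambiguity unit
  tags prevent).
* **Missing data.** A score whose input is missing returns `NA` for that
  patient (complete case); nothing is imputed.
* **Dialysis.** A patient counts as on hemodialysis when
  `dialysis_per_week >= 1`; an explicit `on_dialysis` column overrides this.

Every calculator is cross-checked in the test suite against an independent
literal transcription of its formula (no shared code), against clamp-
equivalence and monotonicity properties, and against analytic extrema: the
MELD floor of 6 points and cap of 40, the upMELD floor
$(1.266+0.939+1.658)\ln 2 = 2.68$ and the refitMELD floor
$8.485\ln 0.8 + 7.432 = 5.5$ (at printed rounding).

## The synthetic cohort generator

Primary waiting-list registries are not public, so validation machinery is
exercised on synthetic cohorts. `generate_cohort()` emulates a single-centre
waiting list of n = 818 with 28.4% pediatric patients (age < 16), 7.3% on
hemodialysis, 18.5% growth failure among children, an indication mix over the
ten ELTR diagnosis groups (published group counts normalised to a proper
probability vector, since categories overlap in the source), and laboratory
marginals that are independent truncated log-normals matched to SI-unit
medians — creatinine 70 umol/l, bilirubin 66 umol/l, INR 1.4, albumin 31 g/l,
PTT 41 s — except sodium, which is truncated normal (138 ± 4.5 mmol/l). The
log-normal spreads (sdlog 0.8, 1.3, 0.35, 0.25, 0.35 respectively) were
chosen once as clinically plausible dispersions consistent with the published
ranges; they are not fitted quantities.

Sub-models the source data do not constrain were chosen for simplicity and
documented here: child ages mix infants (log-uniform 0.02–2 y, 40%) with
older children (uniform 2–16 y); adult ages are truncated normal (50 ± 11 y
on 16–73.6); heights use a crude log height-for-age curve for children and a
normal adult distribution; weight derives from a BMI marginal. Waiting time
is exponential with median 91.5 days truncated at 2323, resampled below 90
days for patients who die within 90 days.

**Mortality mechanism.** The 90-day death indicator is Bernoulli with
probability $\operatorname{logit}^{-1}(\alpha + \beta \cdot \text{iMELD})$.
The intercept $\alpha$ is calibrated by bisection at generation time so the
mean event probability equals the 9% target (74/818);
`calibrate_intercept()` exposes the same calibration against a large
fixed-seed cohort and reduces to the closed-form logit when $\beta = 0$. The
slope default $\beta = 0.13$ per iMELD point was calibrated once so the
driver's whole-cohort AUROC is ≈ 0.80 at the 9% event rate, the regime the
validation study operates in; because the generator's lab marginals are
independent, the iMELD spread is narrower than in real cohorts and the slope
implied by the published univariable odds ratio (≈ 1.09/point) would give
only chance-plus discrimination. This is a mechanism choice, not a
biological claim.

What the generator deliberately does **not** reproduce: lab–lab correlations
(a Gaussian-copula hook is a natural extension but is not a default),
competing risks (transplantation as informative censoring), longitudinal lab
trajectories, and per-subgroup lab distributions — so subgroup AUROC
patterns are not simulation targets, and passing tests say nothing about
real-data subgroup behaviour.

## ROC analysis

`auroc()` is the tie-aware Mann–Whitney statistic computed via midranks
(O(n log n)), oriented as higher score ⇒ death; ties use midranks throughout,
never jittering. `roc_curve()` emits one operating point per distinct
threshold, and its trapezoidal area equals the pairwise statistic exactly.
Confidence intervals default to the DeLong structural-components variance
with a normal interval truncated to [0, 1]; a seeded stratified bootstrap is
available for sensitivity (the published analysis ran in SPSS, whose exact CI
option is unreported — both are therefore configurable). A degenerate
(zero-variance) interval collapses to a point with a warning.

`auroc_matrix()` reproduces the standard validation layout: every score
crossed with all cases, children/adults, first-listing vs re-transplant, and
each major indication group plus its complement, complete-case per score
within subgroup. A score is flagged *acceptable* only when its AUROC strictly
exceeds 0.700 (a value of exactly 0.699–0.700 fails, matching the convention
that 0.699 "just fails"). The pediatric cut-off defaults to age < 16, with
< 12 available, since both definitions circulate. Subgroups with fewer than
two events or two non-events are flagged not estimable rather than erroring.

## Regression modelling

`fit_logistic()` is maximum-likelihood logistic regression via IRLS
(deviance tolerance 1e-12, 100 iterations) with Wald standard errors, 95%
Wald odds-ratio intervals and two-sided Wald p-values; perfect separation is
detected and reported with the offending covariate. `univariable_screen()`
runs one single-covariate fit per candidate at α = 0.05.
`resolve_collinearity()` implements judgment-based collinearity exclusion
through *declared* groups — anthropometry {weight, height, BMI} and age
{age, pediatric < 16, pediatric < 12} — keeping the most significant member
(first-declared on ties), with an override for a deliberate choice such as
retaining BMI; `vif_report()` is emitted for transparency but makes no
decisions. Score components and scores are never co-entered: the pipeline
runs two model sets (set 1: clinical/laboratory covariates; set 2: the
clinical covariates retained by set 1 plus the nine scores).

`forward_lr_select()` starts from intercept-only, enters the candidate with
the smallest likelihood-ratio p-value below 0.05, and after each entry
removes any term whose LR removal p-value exceeds 0.10 — the removal
threshold adopted from the standard forward-LR default, since the source
convention states only the 0.05 significance level. The full entry/removal
trace is recorded. All LR tests are computed on the common complete-case set
across candidates so nested likelihoods are comparable.

## Quality appraisal

The 20-point instrument scores a score-development study on 18 binary
subheadings in five categories (internal validity 4, external validity 2,
statistical validity 4, model evaluation 4, practicality 4); the two
external-validity items are doubled so each category has a weighted maximum
of 4. Marks from several evaluators are averaged per item *before*
weighting (averaging and linear weighting commute; with three evaluators,
item means land on the 1/3 grid). `radar_export()` normalises category
subtotals by 4 for pentagon (spider-web) plots.

The packaged fixture `table3_means()` ships the published evaluator-averaged
marks for the nine score studies, external cells stored as printed
(already ×2). Several printed column totals disagree with their own printed
cells (e.g. one column's cells sum to 12.01 against a printed total of 11);
both values are retained — `printed_total` verbatim, and the recomputed sum
— and only the two internally consistent columns (UKELD 16, MELD-Na 14.35)
are exact-sum test targets. The published cohort summary (mean 14.45 points,
72.25% of 20; weakest per-item categories statistical validity 0.49 and
model evaluation 0.67) is reproduced from the printed totals and cells at
printed precision.

## Problem sizes and numerical choices

The test suite exercises: oracle equality on 1,000 random lab draws per
score and 500 random small ROC instances (n ≤ 50); DeLong coverage over 500
binormal replicates at n = 2,000 and true AUC 0.75 (accepted band 93–97%);
slope recovery and driver-vs-noise forward selection over 100 seeded cohorts
of n = 818 each (≥ 90% success required). These sizes make the binomial
noise on each proportion small relative to its acceptance band while keeping
the full suite under a minute on one core. Bisection for the mortality
intercept runs 200 halvings on [-60, 60] (precision far below the 0.1
percentage-point contract); clamp bounds are closed intervals; all
randomness flows from explicit seeds and the generator restores the
caller's RNG state.

## Known limitations

Synthetic cohorts cannot certify real-data performance: independent lab
marginals understate score correlations, there is no center effect, no
measurement error model, and mortality follows the generating score by
construction — so the discrimination ordering among *non-driver* scores is
an artifact of their correlation with the driver, not evidence. PELD's
under-24-months rule is simplified as noted. The regression stage assumes a
binary endpoint; competing-risk and survival formulations are out of scope.
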