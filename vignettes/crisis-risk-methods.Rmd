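---
title: "Methods: continuous 28-day crisis-risk prediction from EHR event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous 28-day crisis-risk prediction from EHR event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling decisions behind `crisisforecast`: the
prediction target and its parameterization, the leakage discipline of the
feature engineering, the model suite and its search, the evaluation battery,
the synthetic cohort that stands in for real mental-health EHR data, and the
limits of what the shipped tests demonstrate.

## 1. The prediction problem

The pipeline operates on a weekly grid of fixed Monday-start calendar weeks.
Calendar alignment (rather than per-patient alignment) makes the week-of-year
seasonality feature well defined and lets rows from different patients share
one temporal split. Every week, for every eligible patient, the model outputs
the probability that a *crisis episode* begins within the next 28 days, using
only records dated strictly before that week's Monday.

**Episodes.** Crisis events cluster while a patient is acutely unwell, so
single events are not useful targets. A crisis episode is a maximal run of
crisis weeks in which consecutive crisis weeks are separated by fewer than
`s` stable weeks; a new episode opens at any crisis week preceded by at
least `s` crisis-free weeks. The episode's first week is its **onset** — the
event worth predicting, because everything after the onset already happens
under close clinical attention.

**Labels.** Week `t` is positive iff the patient has no crisis event in week
`t` itself and some onset falls in `(t + g, t + g + w]`. The main target is
`(s, w, g) = (1, 4, 0)`; `enumerate_label_variants()` provides the full
sensitivity grid `s` ∈ 1..4, `w` ∈ 1..4, `g` ∈ 0..2 (48 definitions). Two
boundary decisions needed fixing where the target definition is silent:

* *Gap semantics.* `g` shifts the prediction window only; the "no crisis in
  the current week" check stays at week `t`. The gap models operational
  latency between scoring and clinical action, which does not move the
  query week.
* *Weeks inside an ongoing episode* are labelled negative, per the rule
  above, but flagged `in_crisis`; `make_split(..., drop_in_crisis = TRUE)`
  excludes them for users who consider them clinically unqueryable. The
  default keeps them.
* *Right-censoring.* Weeks whose window overruns the end of observation get
  `censored = TRUE` and are excluded from training and evaluation — a
  negative label there would often be a false negative.

**Eligibility.** The pipeline targets patients with a relapse history: a
patient-week is eligible once at least two episode onsets lie strictly
before it and the first record is at least 13 weeks (three months, at weekly
resolution) old. Patients who never reach two episodes are excluded
outright; first-crisis prediction is a different problem with different
ground truth and is deliberately out of scope.

## 2. Leakage-safe feature engineering

All features at week `t` are computed from records dated strictly before
`t`'s Monday; an event in the current week informs the *next* week's
features. Consequently `weeks_since_last()` of an event in the immediately
preceding week equals 1, never 0. The test suite enforces this with an
injection probe: adding any future-dated record (in every table, including a
status spell starting in the future) must leave all earlier rows
bit-identical.

Six procedures generate the default registry (~170 columns):

1. **Statics** — age (updated each calendar year), gender and ethnicity
   one-hots, weeks since first record, weeks since any record. Time-varying
   statics such as marital status are excluded from the schema entirely to
   avoid retrospective leakage.
2. **Diagnosis** — the latest chapter-F diagnosis mapped to its first-level
   ICD-10 category (F0 organic … F6 personality, Other, Not Diagnosed),
   frozen at the last training week so later diagnoses cannot leak across
   the temporal split. Any F-coded record counts as valid; no
   clinician-status filtering is applied, since record-level validity flags
   are site-specific.
3. **Weekly aggregations** — per event stream (16 streams over the six
   event tables), the previous week's count, trailing-window sums over 2,
   4, 8, 12, 26 and 52 weeks, and a cumulative total. Absence is a genuine
   0.
4. **Time-elapsed** — weeks since the last occurrence per stream; `NA`
   means *never happened to date* and is passed to the trees untouched.
5. **Last-episode descriptors** — length, event count and hospitalization
   count of the episode containing the latest crisis week before `t`,
   computed *causally* (an ongoing episode is summarized as observed so
   far) and carried forward until the next crisis.
6. **Status** — value of start–end records overlapping the last completed
   week (later start wins on overlap), plus carried-forward latest
   assessment values.

plus the cyclic seasonal pair sin(2πweek/52), cos(2πweek/52) (week-of-year
capped at 52 so the encoding has a fixed period). No imputation or scaling
is applied anywhere. The registry is data (`default_feature_registry()`
returns a table), so a site with a different EHR taxonomy supplies its own
mapping without code changes.

## 3. Model suite

**General model.** Gradient-boosted trees (xgboost, `tree_method = "hist"`,
single-threaded for reproducibility) with missing markers handled natively.
The boosting-round count comes from early stopping on validation AUROC;
predictions and attributions are sliced at the selected iteration.
Hyperparameters (`eta` 0.03–0.2 log-uniform, depth 2–6, `min_child_weight`
2–100 log-uniform, subsample/colsample, `reg_lambda`) and one binary
inclusion flag per feature *group* are selected by `tpe_search()`, a small
sequential Parzen-estimator-style sampler: random warm-up, then candidates
drawn around the best quartile of past trials and ranked by the ratio of
good-trial to bad-trial kernel density. Group-level (rather than
column-level) selection keeps the search space tractable and mirrors how
collinear EHR features travel in blocks.

**Clinical-practice baseline.** One depth-tuned decision tree on the
indicators a duty clinician reviews: latest suicide and substance-misuse
risk assessments, diagnostic group, crisis recency, age. The tree is fit
with `rpart` as an *anova* (probability-scoring) tree: with ~4% positives a
misclassification-loss tree never splits (no split reduces the error of
"predict negative"), whereas leaf-mean scoring recovers the intended
risk-ranking behaviour while remaining a single shallow tree.

**Diagnosis baseline.** Logistic regression on the diagnostic-group one-hots
(reference level dropped) plus weeks-since-last-crisis. Logistic models
cannot ingest missing markers, so never-had-a-crisis rows get an indicator
plus a sentinel recency of 999 weeks.

**Calibration.** Isotonic regression fit on validation scores — a weighted
pool-adjacent-violators fit over unique raw scores with linear interpolation
between knots — applied to the test scores. The map is monotone, so ranks
(and therefore AUROC and operating points) are preserved up to ties;
degenerate constant scores map to the validation positive rate. Operating
points are reported on the calibrated PRS.

**Reduced model.** The same training protocol restricted to eight
crisis/contact/hospitalization features (episode counts and descriptors,
crisis and contact recencies, unplanned-contact window counts, cumulative
hospitalizations) — the portability variant for sites that only register
crises, visits and hospitalizations. At the shipped cohort scale its AUROC
is statistically indistinguishable from the general model's (see §6).

## 4. Evaluation battery

Evaluation is weekly: each test week contributes one AUROC and one average
precision, pooled as a mean with a **t-interval** over the weekly values —
t rather than normal because the number of weekly splits is small (the
10% test share of a five-year span is ~26 weeks). Weeks with a single
outcome class carry no ranking information; they are skipped and recorded,
never silently dropped. Subgroup tables reuse the same machinery per
diagnostic group, decade age bin (with dedicated <18 and 65–74 bins),
recency-of-last-record bin and history-length bin.

Model comparisons use the paired DeLong z-test (midrank placements, the
generalized U-statistic variance accounting for the correlation of two
score vectors on the same rows), implemented vectorized so a
1000-replicate null simulation verifying its empirical size runs in
seconds; `pROC::roc.test` serves as an independent cross-check in the test
suite. Multiplicity is handled by the two-stage step-up FDR procedure:
stage one runs Benjamini–Hochberg at `q/(1+q)`, the non-rejection count
estimates the number of true nulls `m0`, and stage two reruns the step-up
rule with `m0` in the denominator. The returned adjusted values are
stage-two step-up values to be compared against `q/(1+q)`; the rejection
set is the procedure's primary contract and is tested against a literal
step-by-step re-implementation.

Probability quality is summarized by the Brier score, a 25-equal-width-bin
calibration curve (empty bins reported empty), decision curves
(net benefit `TP/n − (FP/n)·t/(1−t)` against treat-all and treat-none), and
sensitivity at a specificity grid, where the operating point is the
smallest threshold whose specificity meets the target — i.e. maximal
sensitivity subject to the constraint.

## 5. The synthetic cohort

Real mental-health EHRs cannot be distributed, so validation runs on a
generator whose statistical structure matches what the pipeline assumes,
with latent ground truth retained for testing. Per patient `p` and week
`t`, the weekly crisis hazard is

```
h(p,t) = plogis( b_p + k_g * [ Σ_effects f(Δ) + β_ep·log1p(#episodes) + β_sev·log1p(hosp in last episode) ] + A·sin(2π·woy(t)/52) )
```

where each history effect is `β·exp(−Δ/τ)` in the weeks `Δ` since the last
event of that type (zero if it never occurred), sign-reversing effects
subtract the value at their zero-crossing, and `b_p` is the patient
baseline: a calibrated intercept plus a diagnosis-group offset, an age term
(0.6 per 20 years), and a small residual (SD 0.3). Crisis weeks are
Bernoulli draws from `h`; auxiliary streams (contacts, referrals,
assessments, care-program spells) are Poisson/Bernoulli draws whose rates
increase with the current hazard, and hospitalization marks within episodes
are exogenous severity draws that feed back into the hazard.

Default effect shapes (weeks):

| channel | β | decay τ | zero-crossing |
|---|---|---|---|
| crisis recency | 4.5 | 12 | 29 |
| unplanned contact | 0.5 | 1 | — |
| missed appointment | 0.4 | 6 | — |
| carer contact | 0.3 | 4 | — |
| referral | 0.35 | 10 | 25 |
| positive suicide-risk assessment | 0.5 | 30 | — |

The design is *relapse-dominant*: a deep low baseline with a large,
observable crisis-recency effect concentrates onset risk in the months
after an episode. That choice is what makes the planted signal recoverable
from the engineered features — the dominant drivers (recency, episode
count, severity, age, diagnosis, season) are all columns of the feature
matrix — while keeping the qualitative effect shapes (a contact effect
gone within weeks, sustained missed-appointment and carer effects,
sign-reversing crisis and referral effects, a long suicide-assessment
effect) intact for the attribution-shape checks.

**Prevalence calibration.** The main-label prevalence among eligible,
uncensored patient-weeks is calibrated to 4% by moving the baseline
intercept. Prevalence is a noisy, non-monotone function of the intercept:
at very low intercepts the few eligible patients are all dense relapse
chains (high per-week prevalence, negligible mass), and at high intercepts
in-crisis negative weeks dominate. Calibration therefore (i) requires a
minimum eligible mass of 1% of patient-weeks, and (ii) fits an isotonic
smooth of probe simulations over an intercept grid, refined on a finer grid
with two probe seeds, interpolating the target crossing. The realized
prevalence lands within a few tenths of a percentage point of target; the
acceptance band is ±1 point.

**Two latent references.** `oracle_risk_28d()` evaluates
`1 − Π(1 − h(t+k))` over the *realized* future hazards. In a
history-dependent hazard this functional is clairvoyant: once an onset
lands inside the window, the following weeks' hazards spike (the crisis
feeds back into its own recency term), so the realized-hazard score
partially encodes the label itself. Measured across many generator
settings, its AUROC exceeds the best predictor restricted to
information available at the query week by 0.06–0.11 — no trainable model
can approach it, regardless of sample size. `oracle_bayes_28d()` is the
attainable yardstick: it freezes the history at the query week, advances
each recency deterministically (`Δ + k`), applies the same hazard model,
and compounds over the horizon. Signal-recovery checks compare the trained
model against the frozen-history reference; both AUROCs are reported by
the acceptance script.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: free-text notes; demographic realism of any
particular catchment; coding errors, duplicate records and measurement
noise; care-pathway feedback beyond severity-coupled event rates (e.g.
clinicians intervening on rising risk, which would attenuate real-world
effects); non-stationarity of clinical practice across years; and
correlated missingness. Performance figures on the synthetic cohort
validate the machinery, not the clinical effect sizes.

## 6. Numerical choices, scale, and known limitations

* **Problem sizes.** Acceptance runs use the full default cohort
  (2000 patients × 261 weeks, ≈6.5k eligible patient-weeks at 4%
  prevalence, ≈350 training positives); module tests run a 500 × 150
  fixture with a fixed intercept. The stability experiment ships with
  100 replicates by default and is exercised at 10 in tests; a pilot run
  at the fixture scale put the median top-20 cosine similarity near 0.7 —
  the top-20 mass sits on collinear recency/window columns that replicates
  reshuffle, so the test asserts a 0.55 floor rather than a cosmetic 0.8.
* **Replicate regularization.** Stability replicates retrain on 40% of the
  patients; `min_child_weight` is scaled by the subsample fraction so the
  effective leaf-size constraint is unchanged (otherwise a threshold tuned
  on the full cohort can forbid *any* split on the subsample, silently
  producing constant replicate models).
* **Desk-scale Monte-Carlo noise.** With ~90 test positives, AUROC noise is
  ±0.02–0.03. Two consequences are documented rather than tuned away:
  the reduced 8-feature model is *not* reliably below the general model
  (its clean low-dimensional search wins at this sample size; at the
  acceptance seed, 0.922 vs 0.907), so tests assert the two agree within
  0.05; and the margin of the general model over the diagnosis baseline,
  while strictly positive at the acceptance conditions, is smaller than
  one would expect at production scale, because a recency-dominant hazard
  is partially captured by any monotone function of recency.
* **Floating point.** TreeSHAP runs in single precision; per-row additivity
  residuals sit at the 1e-7 scale for the acceptance model and the
  acceptance bound is 1e-6. Isotonic calibration uses a weighted PAVA with
  `approxfun(..., rule = 2)` clamping out-of-range test scores.
* **Tie-breaks.** Top-k risk lists order by descending PRS with a
  deterministic patient-id tie-break; top-feature rankings tie-break by
  feature name; the operating point takes the smallest qualifying
  threshold.
* **Seeds.** Every stochastic step (generator, search, xgboost, subsample
  replicates) flows from one master seed; xgboost runs single-threaded so
  the full train→calibrate→predict path is bit-reproducible.
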