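# crisisforecast

Continuous prediction of mental-health crises from electronic health records
(EHRs), for biostatisticians and clinical data scientists working with
secondary-care mental-health data.

Community mental-health services face a caseload-management problem: most
crises (emergency assessments, urgent hospitalizations) strike patients who
are already known to the service, but reviewing every record every week is
impossible. `crisisforecast` implements a rolling-window risk pipeline for
this setting: every calendar week, for every eligible patient, it estimates
the probability that a **crisis episode begins within the next 28 days**,
using only EHR events dated strictly before that week.

## The model

A *crisis episode* is a run of crisis events preceded by at least one full
stable (crisis-free) week; the prediction target is the episode **onset**.
Week *t* for patient *p* receives label

> y(p, t) = 1 iff p has no crisis event in week t and some episode onset
> falls in weeks (t + g, t + g + w],

with the main configuration s = 1 stable week, window w = 4 weeks, gap
g = 0 — and a 48-configuration sensitivity grid over s ∈ 1..4, w ∈ 1..4,
g ∈ 0..2. Patient-weeks are eligible once the patient has two prior episode
onsets and at least 13 weeks of history.

Each eligible patient-week becomes a feature vector (~170 columns by
default) built by six procedures: static demographics, ICD-10 chapter-F
diagnostic grouping frozen at the end of training, weekly event-count
aggregations over trailing windows, time-elapsed ("weeks since last X")
features with `NA` meaning *never happened*, last-episode length/severity
descriptors, and start–end status features, plus the cyclic pair
sin(2πweek/52), cos(2πweek/52). No imputation is performed.

The general model is a gradient-boosted tree ensemble (xgboost) whose
hyperparameters and feature *groups* are selected by a sequential
Parzen-estimator-style search maximizing validation AUROC on a strictly
temporal 80/10/10 split. It is benchmarked against a clinical-practice
baseline (one shallow decision tree on the indicators a duty clinician
checks) and a diagnosis baseline (logistic regression on diagnostic group
and crisis recency). Raw scores are calibrated by isotonic regression fit on
the validation period, yielding the predicted risk score (PRS) in [0, 1].

Evaluation follows the temporal design: per-week AUROC / average precision
pooled with t-intervals, subgroup AUROC tables (diagnosis, age,
data-recency, history-length), paired DeLong tests for correlated ROC
curves with two-stage (Benjamini–Krieger–Yekutieli) FDR correction, Brier
score, a 25-bin calibration curve, decision-curve analysis, and
sensitivity-at-specificity operating points. Interpretation uses exact
TreeSHAP attributions on the log-odds scale, top-20 rankings, per-value
dependence summaries, and a patient-subsample stability experiment.

Because real mental-health EHRs cannot be shared, the package ships a
synthetic cohort generator (`generate_cohort()`) with known latent risk: a
history-dependent weekly hazard with episodic crisis clustering, seasonal
modulation, severity-coupled auxiliary event streams, and an onset-label
prevalence calibrated to 4%. Ground-truth references
(`oracle_risk_28d()`, `oracle_bayes_28d()`) make signal recovery testable.

## Worked example

```r
library(crisisforecast)

cohort <- generate_cohort(generator_config(n_patients = 800, n_weeks = 200, seed = 42))
labels <- build_label_table(cohort$store, label_config())
plan   <- proportional_split_plan(labels$labels$week)
fm     <- build_matrix(cohort$store, labels$labels, diagnosis_cutoff_week = plan$train[2])
split  <- make_split(fm, plan)

model    <- train_general(fm, split, budget = 8, seed = 42)
raw_val  <- predict_risk(model, fm, split$validation)
raw_test <- predict_risk(model, fm, split$test)
cal      <- calibrate(raw_val, fm$meta$label[split$validation], raw_test)

report <- eval_report(cal$prs, fm$meta$label[split$test], fm$meta$week[split$test])
report
#> <eval_report> n=368, prevalence 0.062, 14 weekly splits
#>   AUROC 0.752 (95% CI 0.634-0.869)
#>   AP    0.323 (95% CI 0.188-0.459)
#>   Brier 0.0630
#>   sensitivity 65.2% at specificity 85.5%

att <- attribute(model, fm, split$test)
top_features(att, 5)
#>                      feature mean_abs_shap
#> 1:           crisis_wkssince     0.5813268
#> 2:    referral_acute_sum_26w     0.4108065
#> 3:     contact_carer_sum_26w     0.3808786
#> 4:    contact_carer_wkssince     0.3145479
#> 5: contact_unplanned_sum_26w     0.2986660
```

The report says: over the 14 test weeks the model separates onset from
non-onset weeks with mean AUROC 0.752; the calibrated PRS has Brier score
0.063 at 6.2% prevalence; and at a decision threshold holding specificity
near 85%, 65% of upcoming onsets are flagged. The attribution table shows
crisis recency and recent unplanned/carer contacts and acute referrals
driving the score — the structure the generator planted.

The same flow runs from the shell:

```sh
Rscript inst/cli/crisisforecast.R all --config cfg.yaml --out rundir --seed 42
```

producing CSV tables, labels, the feature matrix registry, a model bundle,
an evaluation report, attributions and weekly (or biweekly) top-25 risk
lists under `rundir/`.

## Package tour

| Area | Functions |
|---|---|
| EHR store | `ehr_store()`, `read_tables()`, `write_tables()`, `map_icd10_group()`, `latest_valid_diagnosis()` |
| Labels | `segment_episodes()`, `build_labels()`, `build_label_table()`, `enumerate_label_variants()`, `eligibility_mask()` |
| Features | `default_feature_registry()`, `build_matrix()`, `weekly_counts()`, `weeks_since_last()`, `last_episode_descriptors()`, `status_at_week()`, `seasonal_encoding()` |
| Models | `train_general()`, `train_baseline_clinical()`, `train_baseline_diagnosis()`, `reduced_model()`, `calibrate()`, `predict_risk()`, `rank_top_k()`, `tpe_search()` |
| Evaluation | `eval_report()`, `weekly_metrics()`, `subgroup_auroc()`, `compare_roc()`, `bky_adjust()`, `brier()`, `calibration_curve()`, `net_benefit()`, `operating_point()` |
| Interpretation | `attribute()`, `top_features()`, `dependence_summary()`, `stability_experiment()` |
| Synthetic cohort | `generator_config()`, `generate_cohort()`, `oracle_risk_28d()`, `oracle_bayes_28d()`, `write_latent()` |
| Orchestration | `run_config()`, `run_pipeline()`, `inst/cli/crisisforecast.R` |

The methods vignette (`vignettes/crisis-risk-methods.Rmd`) documents the
modelling choices, the generator's assumptions, and known limitations.
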