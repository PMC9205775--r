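Package: crisisforecast
Title: Continuous Prediction of Mental Health Crises from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rolling-window pipeline for predicting the onset of mental health
    crisis episodes within the next 28 days from longitudinal electronic health
    record (EHR) event streams. Provides typed in-memory EHR tables with CSV
    readers and ICD-10 chapter-F diagnostic grouping, crisis-episode
    segmentation and onset labelling over a configurable stable-week / window /
    gap grid, leakage-safe weekly feature engineering (weekly aggregations,
    time-elapsed features, last-episode descriptors, status features,
    seasonality encoding), gradient-boosted-tree risk models with
    clinical-practice and diagnosis-based baselines, isotonic calibration,
    temporal and subgroup evaluation (weekly confidence intervals, correlated
    ROC comparison, two-stage FDR correction, calibration and decision curves),
    Shapley-value model interpretation with a subsample stability experiment,
    and a synthetic EHR cohort generator with known latent risk for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    xgboost,
    rpart,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
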