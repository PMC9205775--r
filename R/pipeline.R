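# ---------------------------------------------------------------------------
# Pipeline orchestration: stage-wise runs with a serializable config, atomic
# artifacts in a run directory, and a structured line-delimited log.
# ---------------------------------------------------------------------------

#' Default pipeline run configuration
#'
#' Everything a run needs, fully serializable to YAML: generator settings,
#' label definition, split fractions, search budget and the reduced feature
#' list. The master `seed` drives the generator, the hyperparameter search
#' and xgboost.
#'
#' @param seed master seed.
#' @param n_patients,n_weeks cohort size handed to [generator_config()].
#' @param label `c(stable_weeks, window_weeks, gap_weeks)`.
#' @param split_fractions train/validation/test proportions by week.
#' @param budget hyperparameter-search trials.
#' @param nrounds_max,early_stopping boosting-round controls.
#' @param rank_k length of the per-week top-risk list.
#' @param rank_biweekly if TRUE the rank stage exports lists every second
#'   week (the cadence used when lists are delivered to clinical teams)
#'   rather than weekly.
#' @return a nested list (class `run_config`).
#' @export
run_config <- function(seed = 1L, n_patients = 500L, n_weeks = 261L,
                       label = c(1L, 4L, 0L),
                       split_fractions = c(0.8, 0.1, 0.1),
                       budget = 8L, nrounds_max = 300L, early_stopping = 25L,
                       rank_k = 25L, rank_biweekly = FALSE) {
  cfg <- list(seed = as.integer(seed),
              generator = list(n_patients = as.integer(n_patients),
                               n_weeks = as.integer(n_weeks)),
              label = as.integer(label),
              split_fractions = split_fractions,
              train = list(budget = as.integer(budget),
                           nrounds_max = as.integer(nrounds_max),
                           early_stopping = as.integer(early_stopping)),
              rank = list(k = as.integer(rank_k),
                          biweekly = isTRUE(rank_biweekly)))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      utils::modifyList(cfg[[nm]], raw[[nm]])
    } else raw[[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$label <- as.integer(unlist(cfg$label))
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(run_dir, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(run_dir, "log.jsonl"), append = TRUE)
}

artifact <- function(run_dir, name) file.path(run_dir, paste0(name, ".rds"))

need_artifact <- function(run_dir, name, producer) {
  p <- artifact(run_dir, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "': run the '", producer, "' stage first")
  }
  readRDS(p)
}

#' Run the crisis-prediction pipeline
#'
#' Executes one stage (or `"all"`) against a run directory. Stages:
#' `simulate` (synthetic cohort + CSV tables), `label` (episodes + onset
#' labels), `featurize` (the patient-week matrix), `train` (general model,
#' both baselines, reduced model, isotonic calibration), `evaluate` (the
#' full evaluation battery plus correlated-ROC comparisons with two-stage FDR
#' correction), `explain` (attributions, top-20, dependence), `rank` (top-k
#' risk lists over the test weeks). Each stage writes its artifacts into
#' `run_dir` and appends to `log.jsonl`; reruns with the same config and seed
#' reproduce the same artifacts.
#'
#' @param stage one of simulate, label, featurize, train, evaluate, explain,
#'   rank, all.
#' @param config a [run_config()] (or path to a YAML file).
#' @param run_dir output directory.
#' @return invisibly, `run_dir`.
#' @export
run_pipeline <- function(stage = "all", config = run_config(), run_dir) {
  stages <- c("simulate", "label", "featurize", "train", "evaluate",
              "explain", "rank")
  stage <- match.arg(stage, c(stages, "all"))
  if (is.character(config)) config <- read_run_config(config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(run_dir, "config_resolved.yaml"))
  todo <- if (stage == "all") stages else stage
  for (s in todo) {
    t0 <- Sys.time()
    switch(s,
      simulate = {
        gcfg <- do.call(generator_config,
                        c(config$generator, list(seed = config$seed)))
        cohort <- generate_cohort(gcfg)
        saveRDS(cohort, artifact(run_dir, "cohort"))
        write_tables(cohort$store, file.path(run_dir, "tables"))
      },
      label = {
        cohort <- need_artifact(run_dir, "cohort", "simulate")
        lcfg <- label_config(config$label[1], config$label[2], config$label[3])
        lt <- build_label_table(cohort$store, lcfg)
        saveRDS(lt, artifact(run_dir, "labels"))
        write_labels(lt$labels, file.path(run_dir, "labels.csv"))
      },
      featurize = {
        cohort <- need_artifact(run_dir, "cohort", "simulate")
        lt <- need_artifact(run_dir, "labels", "label")
        plan <- proportional_split_plan(lt$labels$week, config$split_fractions)
        fm <- build_matrix(cohort$store, lt$labels,
                           diagnosis_cutoff_week = plan$train[2],
                           stable_gap = config$label[1])
        saveRDS(list(fm = fm, plan = plan), artifact(run_dir, "matrix"))
        fwrite(fm$registry, file.path(run_dir, "feature_registry.csv"))
      },
      train = {
        mx <- need_artifact(run_dir, "matrix", "featurize")
        fm <- mx$fm
        split <- make_split(fm, mx$plan)
        general <- train_general(fm, split, budget = config$train$budget,
                                 seed = config$seed,
                                 nrounds_max = config$train$nrounds_max,
                                 early_stopping = config$train$early_stopping)
        clinical <- train_baseline_clinical(fm, split, seed = config$seed)
        diagnosis <- train_baseline_diagnosis(fm, split)
        reduced <- reduced_model(fm, split, budget = max(2L, config$train$budget %/% 2L),
                                 seed = config$seed,
                                 nrounds_max = config$train$nrounds_max,
                                 early_stopping = config$train$early_stopping)
        raw_val <- predict_risk(general, fm, split$validation)
        raw_test <- predict_risk(general, fm, split$test)
        cal <- calibrate(raw_val, fm$meta$label[split$validation], raw_test)
        bundle <- list(general = general, clinical = clinical,
                       diagnosis = diagnosis, reduced = reduced,
                       calibration_knots = cal$knots, split = split,
                       seed = config$seed,
                       registry_hash = paste(fm$registry$name, collapse = "|"))
        saveRDS(bundle, artifact(run_dir, "model_bundle"))
        preds <- data.table(patient_id = fm$meta$patient_id[split$test],
                            week_start_date = week_start(fm$meta$week[split$test]),
                            raw = raw_test, prs = cal$prs)
        fwrite(preds, file.path(run_dir, "predictions.csv"), dateTimeAs = "ISO")
        saveRDS(list(raw_val = raw_val, raw_test = raw_test, prs = cal$prs),
                artifact(run_dir, "predictions"))
      },
      evaluate = {
        mx <- need_artifact(run_dir, "matrix", "featurize")
        bundle <- need_artifact(run_dir, "model_bundle", "train")
        pr <- need_artifact(run_dir, "predictions", "train")
        fm <- mx$fm; split <- bundle$split
        y <- fm$meta$label[split$test]; wk <- fm$meta$week[split$test]
        groupings <- list(
          diagnosis = diagnosis_group_of(fm, split$test),
          age = age_bins(fm$X[split$test, "age"]),
          last_record = recency_bins(fm$X[split$test, "weeks_since_any_record"]),
          history = history_bins(fm$X[split$test, "weeks_since_first_record"])
        )
        report <- eval_report(pr$prs, y, wk, groupings)
        raw_clin <- predict_risk(bundle$clinical, fm, split$test)
        raw_diag <- predict_risk(bundle$diagnosis, fm, split$test)
        raw_red <- predict_risk(bundle$reduced, fm, split$test)
        cmp <- list(
          vs_clinical = compare_roc(pr$raw_test, raw_clin, y),
          vs_diagnosis = compare_roc(pr$raw_test, raw_diag, y),
          vs_reduced = compare_roc(pr$raw_test, raw_red, y)
        )
        fdr <- bky_adjust(vapply(cmp, `[[`, 1, "p_value"))
        ev <- list(report = report, comparisons = cmp, fdr = fdr,
                   auroc = list(
                     general = auroc(pr$raw_test, y),
                     clinical = auroc(raw_clin, y),
                     diagnosis = auroc(raw_diag, y),
                     reduced = auroc(raw_red, y)))
        saveRDS(ev, artifact(run_dir, "evaluation"))
        write_eval_report(report, file.path(run_dir, "eval_report"))
      },
      explain = {
        mx <- need_artifact(run_dir, "matrix", "featurize")
        bundle <- need_artifact(run_dir, "model_bundle", "train")
        fm <- mx$fm
        att <- attribute(bundle$general, fm, bundle$split$test)
        tf <- top_features(att, 20L)
        saveRDS(list(top = tf, residual = att$additivity_residual),
                artifact(run_dir, "attribution_summary"))
        fwrite(tf, file.path(run_dir, "top_features.csv"))
        write_attributions(att, file.path(run_dir, "attributions.csv"))
      },
      rank = {
        mx <- need_artifact(run_dir, "matrix", "featurize")
        bundle <- need_artifact(run_dir, "model_bundle", "train")
        pr <- need_artifact(run_dir, "predictions", "train")
        fm <- mx$fm; split <- bundle$split
        wk <- fm$meta$week[split$test]
        dt <- data.table(patient_id = fm$meta$patient_id[split$test],
                         week = wk, prs = pr$prs)
        weeks <- sort(unique(wk))
        if (config$rank$biweekly) weeks <- weeks[seq(1L, length(weeks), by = 2L)]
        lists <- rbindlist(lapply(weeks, function(w) {
          one <- dt[week == w][, .(prs = max(prs)), by = patient_id]
          cbind(week_start_date = week_start(w),
                rank_top_k(one, k = min(config$rank$k, nrow(one))))
        }))
        fwrite(lists, file.path(run_dir, "top_risk_lists.csv"), dateTimeAs = "ISO")
        saveRDS(lists, artifact(run_dir, "rank"))
      }
    )
    log_line(run_dir, s, seed = config$seed,
             elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  }
  invisible(run_dir)
}

# diagnostic group per row, reconstructed from the one-hot columns
diagnosis_group_of <- function(fm, rows) {
  onehot <- paste0("dx_", gsub("[^A-Za-z0-9]+", "_", DIAGNOSIS_GROUPS))
  present <- onehot %in% colnames(fm$X)
  sub <- fm$X[rows, onehot[present], drop = FALSE]
  idx <- max.col(cbind(sub, 0.5)) # fallback column if no one-hot is set
  c(DIAGNOSIS_GROUPS[present], NA)[idx]
}
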