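# ---------------------------------------------------------------------------
# Model suite: temporal splitting, the gradient-boosted general model with
# TPE-style hyperparameter / feature-group search, the two baselines,
# isotonic calibration, the reduced-feature variant and top-k ranking.
# ---------------------------------------------------------------------------

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed via the rank-sum identity AUROC = (R1 - n1(n1+1)/2) / (n1 n0),
#' with midranks, so it equals the Mann-Whitney U statistic normalized to
#' \[0, 1\].
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @return AUROC in \[0, 1\]; `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Threshold-stepped AP: the sum over descending unique score thresholds of
#' the recall increment times the precision at that threshold.
#'
#' @inheritParams auroc
#' @return AP in \[0, 1\]; `NA` if no positives.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- c(s[-1] != s[-length(s)], TRUE) # last index of each threshold block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Temporal split plan
#'
#' Rows are assigned to train/validation/test strictly by calendar week. The
#' default plan reproduces the study timeline: training from the first week
#' of September 2012 through the last week of December 2017, validation from
#' the first week of January 2018 through the last week of June 2018, test
#' from the first week of July 2018 through the third week of November 2018.
#' For synthetic cohorts spanning other dates use
#' [proportional_split_plan()].
#'
#' @param train_start,train_end,validation_end,test_end `Date`s (any day of
#'   the intended week).
#' @return a `split_plan` (absolute week indices, inclusive ranges).
#' @export
split_plan <- function(train_start = as.Date("2012-09-03"),
                       train_end = as.Date("2017-12-25"),
                       validation_end = as.Date("2018-06-25"),
                       test_end = as.Date("2018-11-19")) {
  w <- date_to_week(c(train_start, train_end, validation_end, test_end))
  stopifnot(w[1] <= w[2], w[2] < w[3], w[3] < w[4])
  structure(list(train = c(w[1], w[2]),
                 validation = c(w[2] + 1L, w[3]),
                 test = c(w[3] + 1L, w[4])),
            class = "split_plan")
}

#' @rdname split_plan
#' @param weeks integer vector of the weeks to be partitioned (e.g.
#'   `fm$meta$week`).
#' @param fractions length-3 proportions for train/validation/test.
#' @export
proportional_split_plan <- function(weeks, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  lo <- min(weeks); hi <- max(weeks); span <- hi - lo + 1L
  t_end <- lo + as.integer(ceiling(span * fractions[1])) - 1L
  v_end <- lo + as.integer(ceiling(span * (fractions[1] + fractions[2]))) - 1L
  structure(list(train = c(lo, t_end),
                 validation = c(t_end + 1L, v_end),
                 test = c(v_end + 1L, hi)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  for (p in c("train", "validation", "test")) {
    cat(sprintf("  %-10s %s .. %s\n", p,
                week_start(x[[p]][1]), week_start(x[[p]][2])))
  }
  invisible(x)
}

#' Partition a feature matrix by the split plan
#'
#' @param fm a `feature_matrix`.
#' @param plan a [split_plan()].
#' @param drop_censored exclude right-censored rows (default TRUE).
#' @param drop_in_crisis also exclude weeks with a crisis in progress
#'   (default FALSE: such weeks are labelled negative per the target
#'   definition and kept).
#' @return list with integer row indices `train`, `validation`, `test`, plus
#'   the `plan`.
#' @export
make_split <- function(fm, plan, drop_censored = TRUE, drop_in_crisis = FALSE) {
  wk <- fm$meta$week
  keep <- rep(TRUE, length(wk))
  if (drop_censored) keep <- keep & !fm$meta$censored
  if (drop_in_crisis) keep <- keep & !fm$meta$in_crisis
  out <- list(
    train = which(keep & wk >= plan$train[1] & wk <= plan$train[2]),
    validation = which(keep & wk >= plan$validation[1] & wk <= plan$validation[2]),
    test = which(keep & wk >= plan$test[1] & wk <= plan$test[2])
  )
  empty <- names(out)[vapply(out, length, 1L) == 0L]
  if (length(empty)) stop("empty partition(s): ", paste(empty, collapse = ", "))
  out$plan <- plan
  out
}

# ---------------------------------------------------------------------------
# TPE-style sequential search: random warm-up, then candidates sampled from a
# kernel density over the best quartile of trials and ranked by the ratio of
# good-trial to bad-trial density (the Parzen-estimator heuristic).
# ---------------------------------------------------------------------------

sample_param <- function(sp) {
  switch(sp$type,
    uniform = runif(1, sp$lo, sp$hi),
    loguniform = exp(runif(1, log(sp$lo), log(sp$hi))),
    int = sample(seq.int(sp$lo, sp$hi), 1L),
    choice = sp$values[[sample.int(length(sp$values), 1L)]],
    stop("unknown parameter type: ", sp$type)
  )
}

param_log_density <- function(x, obs, sp) {
  if (sp$type == "choice") {
    vals <- vapply(sp$values, identity, obs[[1]])
    counts <- vapply(sp$values, function(v) sum(unlist(obs) == v), 1) + 1
    return(log(counts[match(x, vals)] / sum(counts)))
  }
  o <- unlist(obs)
  if (sp$type == "loguniform") { o <- log(o); x <- log(x) }
  bw <- max(1.06 * sd(o) * length(o)^(-0.2), (max(o) - min(o)) / 20, 1e-3)
  log(mean(stats::dnorm(x, mean = o, sd = bw)) + 1e-12)
}

mutate_param <- function(v, sp) {
  if (sp$type == "choice") return(sample_param(sp))
  if (sp$type == "int") {
    return(min(max(v + sample(-2:2, 1L), sp$lo), sp$hi))
  }
  lo <- sp$lo; hi <- sp$hi
  if (sp$type == "loguniform") {
    exp(min(max(log(v) + rnorm(1, 0, (log(hi) - log(lo)) / 8), log(lo)), log(hi)))
  } else {
    min(max(v + rnorm(1, 0, (hi - lo) / 8), lo), hi)
  }
}

#' Sequential model-based hyperparameter search
#'
#' Maximizes `objective(params)` over a mixed space of numeric and choice
#' parameters with a Tree-structured-Parzen-Estimator-style strategy: after a
#' random warm-up, candidate configurations are drawn around the best
#' quartile of past trials and ranked by the ratio of good-trial to bad-trial
#' kernel density before the top candidate is evaluated.
#'
#' @param objective function(named list of parameter values) -> numeric score
#'   (larger is better; non-finite scores are treated as failures).
#' @param space named list; each element is `list(type, lo, hi)` with type
#'   `"uniform"`, `"loguniform"` or `"int"`, or `list(type = "choice",
#'   values = list(...))`.
#' @param budget total number of trials (>= 1).
#' @param n_candidates candidate draws per sequential step.
#' @return list: `best` (parameter list), `best_score`, `history`
#'   (`data.table` of trial scores).
#' @export
tpe_search <- function(objective, space, budget = 100L, n_candidates = 24L) {
  stopifnot(budget >= 1L)
  n_startup <- min(budget, max(5L, budget %/% 5L))
  trials <- list(); scores <- numeric(0)
  for (i in seq_len(budget)) {
    if (i <= n_startup || sum(is.finite(scores)) < 4L) {
      cand <- lapply(space, sample_param)
    } else {
      ok <- which(is.finite(scores))
      n_good <- max(2L, ceiling(length(ok) / 4))
      good <- ok[order(scores[ok], decreasing = TRUE)][seq_len(n_good)]
      bad <- setdiff(ok, good)
      cands <- lapply(seq_len(n_candidates), function(k) {
        base <- trials[[sample(good, 1L)]]
        lapply(names(space), function(p) mutate_param(base[[p]], space[[p]])) |>
          setNames(names(space))
      })
      ei <- vapply(cands, function(cd) {
        sum(vapply(names(space), function(p) {
          lg <- param_log_density(cd[[p]], lapply(trials[good], `[[`, p), space[[p]])
          lb <- if (length(bad) >= 2L) {
            param_log_density(cd[[p]], lapply(trials[bad], `[[`, p), space[[p]])
          } else 0
          lg - lb
        }, 1))
      }, 1)
      cand <- cands[[which.max(ei)]]
    }
    trials[[i]] <- cand
    scores[i] <- tryCatch(objective(cand), error = function(e) -Inf)
  }
  best <- which.max(ifelse(is.finite(scores), scores, -Inf))
  list(best = trials[[best]], best_score = scores[best],
       history = data.table(trial = seq_len(budget), score = scores))
}

#' Default search space for the boosted-tree model
#'
#' Numeric hyperparameters on published sensible ranges plus one binary
#' inclusion flag per feature group, mirroring group-level feature selection
#' inside the hyperparameter search.
#'
#' @param groups character vector of feature group ids (from the registry).
#' @return named list usable with [tpe_search()].
#' @export
default_xgb_space <- function(groups) {
  space <- list(
    eta = list(type = "loguniform", lo = 0.03, hi = 0.2),
    max_depth = list(type = "int", lo = 2L, hi = 6L),
    min_child_weight = list(type = "loguniform", lo = 2, hi = 100),
    subsample = list(type = "uniform", lo = 0.6, hi = 1),
    colsample_bytree = list(type = "uniform", lo = 0.4, hi = 1),
    reg_lambda = list(type = "loguniform", lo = 0.5, hi = 10)
  )
  for (g in groups) {
    space[[paste0("use_", g)]] <- list(type = "choice", values = list(TRUE, FALSE))
  }
  space
}

selected_features <- function(registry, params) {
  flags <- params[startsWith(names(params), "use_")]
  if (!length(flags)) return(registry$name)
  off <- sub("^use_", "", names(flags)[!unlist(flags)])
  feats <- registry[!(group_id %in% off), name]
  if (!length(feats)) registry[group_id == "crisis_history", name] else feats
}

fit_xgb <- function(X, y, Xval, yval, params, seed, nrounds_max, early_stopping) {
  hp <- list(
    objective = "binary:logistic", eval_metric = "auc",
    eta = params$eta, max_depth = params$max_depth,
    min_child_weight = params$min_child_weight,
    subsample = params$subsample, colsample_bytree = params$colsample_bytree,
    reg_lambda = params$reg_lambda,
    tree_method = "hist", nthread = 1L, seed = seed
  )
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  dval <- xgboost::xgb.DMatrix(Xval, label = yval)
  booster <- xgboost::xgb.train(
    params = hp, data = dtrain, nrounds = nrounds_max,
    evals = list(val = dval), early_stopping_rounds = early_stopping,
    verbose = 0
  )
  att <- xgboost::xgb.attributes(booster)
  list(booster = booster,
       best_iteration = as.integer(att$best_iteration),
       val_auc = as.numeric(att$best_score))
}

new_crisis_model <- function(kind, fit, features, params = NULL,
                             val_auroc = NA_real_, extra = list()) {
  structure(c(list(kind = kind, fit = fit, features = features,
                   params = params, val_auroc = val_auroc), extra),
            class = "crisis_model")
}

#' @export
print.crisis_model <- function(x, ...) {
  cat(sprintf("<crisis_model:%s> %d features, validation AUROC %.3f\n",
              x$kind, length(x$features), x$val_auroc))
  invisible(x)
}

#' Train the general boosted-tree crisis model
#'
#' Gradient-boosted decision trees (xgboost) on the full feature matrix, with
#' hyperparameters and group-level feature selection chosen by [tpe_search()]
#' to maximize validation AUROC. Missing markers are passed to the trees
#' untouched; no imputation or scaling is applied. The number of boosting
#' rounds is set by early stopping on the validation AUROC.
#'
#' @param fm a `feature_matrix`.
#' @param split output of [make_split()].
#' @param space search space (default [default_xgb_space()] over the
#'   registry's feature groups).
#' @param budget number of search trials (default 100; small budgets are fine
#'   for smoke runs).
#' @param seed integer seed controlling both the search and xgboost.
#' @param nrounds_max,early_stopping boosting-round cap and early-stopping
#'   patience.
#' @return a `crisis_model` (kind `"xgboost"`).
#' @export
train_general <- function(fm, split, space = NULL, budget = 20L, seed = 1L,
                          nrounds_max = 300L, early_stopping = 25L) {
  y_tr <- fm$meta$label[split$train]
  y_va <- fm$meta$label[split$validation]
  if (length(unique(y_tr)) < 2L) stop("training labels are single-class")
  if (length(unique(y_va)) < 2L) stop("validation labels are single-class")
  if (is.null(space)) space <- default_xgb_space(unique(fm$registry$group_id))
  set.seed(seed)
  trial_seed <- sample.int(1e6, 1L)

  evaluate <- function(params) {
    feats <- selected_features(fm$registry, params)
    r <- fit_xgb(fm$X[split$train, feats, drop = FALSE], y_tr,
                 fm$X[split$validation, feats, drop = FALSE], y_va,
                 params, trial_seed, nrounds_max, early_stopping)
    r$val_auc
  }
  search <- tpe_search(evaluate, space, budget = budget)

  feats <- selected_features(fm$registry, search$best)
  set.seed(seed)
  final <- fit_xgb(fm$X[split$train, feats, drop = FALSE], y_tr,
                   fm$X[split$validation, feats, drop = FALSE], y_va,
                   search$best, trial_seed, nrounds_max, early_stopping)
  new_crisis_model("xgboost", final$booster, feats, search$best,
                   final$val_auc,
                   extra = list(best_iteration = final$best_iteration,
                                search_history = search$history, seed = seed,
                                fit_seed = trial_seed,
                                nrounds_max = nrounds_max,
                                early_stopping = early_stopping))
}

#' Clinical-practice baseline: a single decision tree
#'
#' Emulates a clinician's rule-of-thumb risk review: one decision tree on a
#' small set of patient status indicators (latest risk assessments,
#' diagnostic group, crisis recency, age by default), with depth tuned on the
#' validation set.
#'
#' @param fm a `feature_matrix`.
#' @param split output of [make_split()].
#' @param features character vector of indicator columns (default described
#'   above).
#' @param max_depths candidate tree depths tried on the validation set.
#' @param seed integer seed.
#' @return a `crisis_model` (kind `"rpart"`).
#' @export
train_baseline_clinical <- function(fm, split, features = NULL,
                                    max_depths = 1:6, seed = 1L) {
  if (is.null(features)) {
    features <- intersect(
      c("suicide_risk_latest", "substance_risk_latest",
        fm$registry[procedure == "diagnosis", name], "crisis_wkssince", "age"),
      colnames(fm$X))
  }
  missing_feats <- setdiff(features, colnames(fm$X))
  if (length(missing_feats)) stop("unknown feature(s): ",
                                  paste(missing_feats, collapse = ", "))
  y_tr <- fm$meta$label[split$train]
  if (length(unique(y_tr)) < 2L) stop("training labels are single-class")
  # anova (probability-scoring) tree: with a ~4% positive rate a
  # misclassification-loss tree never splits, so score the leaf means instead
  df_tr <- as.data.frame(fm$X[split$train, features, drop = FALSE])
  df_tr$.y <- y_tr
  df_va <- as.data.frame(fm$X[split$validation, features, drop = FALSE])
  y_va <- fm$meta$label[split$validation]

  best <- NULL; best_auc <- -Inf; best_depth <- NA_integer_
  for (d in max_depths) {
    set.seed(seed)
    fit <- rpart::rpart(.y ~ ., data = df_tr, method = "anova",
                        control = rpart::rpart.control(
                          maxdepth = d, cp = 1e-5, xval = 0, minbucket = 50))
    a <- auroc(predict(fit, df_va), y_va)
    if (!is.na(a) && a > best_auc) { best <- fit; best_auc <- a; best_depth <- d }
  }
  new_crisis_model("rpart", best, features, list(maxdepth = best_depth),
                   best_auc, extra = list(seed = seed))
}

#' Diagnosis-based baseline: logistic regression
#'
#' A threshold-style rule system relying solely on the diagnostic group and
#' the time elapsed since the last crisis. Logistic models cannot ingest
#' missing markers, so a never-had-a-crisis indicator plus a large sentinel
#' recency (999 weeks) stand in for `NA`.
#'
#' @param fm a `feature_matrix`.
#' @param split output of [make_split()].
#' @param sentinel recency value substituted for `NA`.
#' @return a `crisis_model` (kind `"glm"`).
#' @export
train_baseline_diagnosis <- function(fm, split, sentinel = 999) {
  dxcols <- fm$registry[procedure == "diagnosis", name]
  needed <- c(dxcols, "crisis_wkssince")
  missing_feats <- setdiff(needed, colnames(fm$X))
  if (length(missing_feats)) stop("missing feature(s): ",
                                  paste(missing_feats, collapse = ", "))
  make_df <- function(rows) {
    d <- as.data.frame(fm$X[rows, dxcols, drop = FALSE])
    rec <- fm$X[rows, "crisis_wkssince"]
    d$crisis_never <- as.numeric(is.na(rec))
    d$crisis_wkssince <- ifelse(is.na(rec), sentinel, rec)
    d
  }
  df_tr <- make_df(split$train)
  y_tr <- fm$meta$label[split$train]
  if (length(unique(y_tr)) < 2L) stop("training labels are single-class")
  # drop the reference diagnosis column (all-zero columns too)
  keep_dx <- dxcols[colSums(df_tr[dxcols]) > 0]
  if (length(keep_dx)) keep_dx <- keep_dx[-1L]
  df_tr <- df_tr[c(keep_dx, "crisis_wkssince", "crisis_never")]
  df_tr$.y <- y_tr
  fit <- glm(.y ~ ., data = df_tr, family = binomial())
  new_crisis_model("glm", fit, c(dxcols, "crisis_wkssince"),
                   list(sentinel = sentinel, terms = names(df_tr)),
                   extra = list(make_df_cols = c(keep_dx, "crisis_wkssince",
                                                 "crisis_never")))
}

#' Predict raw risk scores
#'
#' @param model a `crisis_model`.
#' @param fm the `feature_matrix` to score.
#' @param rows integer row indices (default: all rows).
#' @return numeric scores in \[0, 1\].
#' @export
predict_risk <- function(model, fm, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$X))
  switch(model$kind,
    xgboost = {
      d <- xgboost::xgb.DMatrix(fm$X[rows, model$features, drop = FALSE])
      as.numeric(predict(model$fit, d, iterationrange = xgb_iteration_range(model)))
    },
    rpart = {
      df <- as.data.frame(fm$X[rows, model$features, drop = FALSE])
      pmin(pmax(as.numeric(predict(model$fit, df)), 0), 1)
    },
    glm = {
      dxcols <- model$features[model$features != "crisis_wkssince"]
      df <- as.data.frame(fm$X[rows, dxcols, drop = FALSE])
      rec <- fm$X[rows, "crisis_wkssince"]
      df$crisis_never <- as.numeric(is.na(rec))
      df$crisis_wkssince <- ifelse(is.na(rec), model$params$sentinel, rec)
      as.numeric(predict(model$fit, df, type = "response"))
    },
    stop("unknown model kind: ", model$kind)
  )
}

# Early stopping keeps the overshoot trees in the booster; predictions must be
# sliced at the selected iteration (upper bound is exclusive in iterationrange).
xgb_iteration_range <- function(model) {
  b <- model$best_iteration
  if (is.null(b) || is.na(b)) NULL else c(1L, as.integer(b) + 1L)
}

# weighted pool-adjacent-violators: isotonic fit of y on sorted x with weights
pava <- function(y, w) {
  n <- length(y)
  vals <- y; wts <- w; idx_end <- seq_len(n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]; wts[m] <- w[i]; idx_end[m] <- i
    while (m > 1L && vals[m - 1L] > vals[m]) {
      tot <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- (wts[m - 1L] * vals[m - 1L] + wts[m] * vals[m]) / tot
      wts[m - 1L] <- tot
      idx_end[m - 1L] <- idx_end[m]
      m <- m - 1L
    }
  }
  out <- numeric(n); start <- 1L
  for (b in seq_len(m)) {
    out[start:idx_end[b]] <- vals[b]
    start <- idx_end[b] + 1L
  }
  out
}

#' Isotonic calibration of risk scores
#'
#' Fits a monotone (isotonic) map from raw validation scores to outcome
#' frequencies and applies it to the test scores, yielding the calibrated
#' predicted risk score (PRS). The map is the weighted
#' pool-adjacent-violators fit over unique validation scores with linear
#' interpolation between them, so it preserves the raw-score ordering; test
#' scores outside the validation range are clamped. With degenerate
#' (constant) validation scores every prediction maps to the validation
#' positive rate.
#'
#' @param val_scores,val_labels raw scores and 0/1 outcomes on the validation
#'   set.
#' @param test_scores raw scores to transform.
#' @return list: `prs` (calibrated test scores), `map` (function), `knots`
#'   (`data.table` of the fitted map).
#' @export
calibrate <- function(val_scores, val_labels, test_scores) {
  stopifnot(length(val_scores) == length(val_labels))
  agg <- data.table(x = val_scores, y = as.numeric(val_labels))[
    , .(y = mean(y), w = .N), keyby = x]
  if (nrow(agg) == 1L) {
    p <- agg$y
    map <- function(s) rep(p, length(s))
    return(list(prs = map(test_scores), map = map,
                knots = data.table(x = agg$x, yhat = p)))
  }
  yhat <- pava(agg$y, agg$w)
  map <- stats::approxfun(agg$x, yhat, method = "linear", rule = 2, ties = "ordered")
  list(prs = map(test_scores), map = map,
       knots = data.table(x = agg$x, yhat = yhat))
}

#' Reduced-feature model
#'
#' The portability variant: the same boosted-tree training protocol
#' restricted to a small configured feature list (by default eight
#' crisis/contact/hospitalization features drawn from the top predictors).
#'
#' @param fm a `feature_matrix`.
#' @param split output of [make_split()].
#' @param features character vector naming the restricted feature set.
#' @param budget,seed,nrounds_max,early_stopping as in [train_general()].
#' @return a `crisis_model`.
#' @export
reduced_model <- function(fm, split,
                          features = c(
                            "n_prior_episodes", "crisis_wkssince",
                            "last_episode_length", "last_episode_n_hosp",
                            "contact_unplanned_wkssince", "contact_missed_wkssince",
                            "contact_unplanned_sum_4w", "hosp_total"),
                          budget = 10L, seed = 1L, nrounds_max = 300L,
                          early_stopping = 25L) {
  missing_feats <- setdiff(features, colnames(fm$X))
  if (length(missing_feats)) {
    stop("reduced feature(s) absent from the registry: ",
         paste(missing_feats, collapse = ", "))
  }
  sub <- fm
  sub$X <- fm$X[, features, drop = FALSE]
  sub$registry <- fm$registry[name %in% features]
  space <- default_xgb_space(character(0)) # no group flags: the set is fixed
  train_general(sub, split, space = space, budget = budget, seed = seed,
                nrounds_max = nrounds_max, early_stopping = early_stopping)
}

#' Rank the top-k patients by predicted risk score
#'
#' Descending PRS with a deterministic tie-break on patient id; optionally
#' restricted to a caseload. Asking for more patients than exist returns all
#' of them with a warning.
#'
#' @param predictions `data.table`/data.frame with columns `patient_id` and
#'   `prs` (one row per patient for the queried week).
#' @param k list length (default 25).
#' @param caseload optional character vector restricting the ranking.
#' @return `data.table` `patient_id`, `prs`, `rank`.
#' @export
rank_top_k <- function(predictions, k = 25L, caseload = NULL) {
  dt <- as.data.table(predictions)
  stopifnot(all(c("patient_id", "prs") %in% names(dt)))
  if (!is.null(caseload)) dt <- dt[patient_id %in% caseload]
  if (anyDuplicated(dt$patient_id)) stop("one prediction per patient required")
  if (k > nrow(dt)) {
    warning("k exceeds caseload size; returning all ", nrow(dt), " patients")
    k <- nrow(dt)
  }
  setorder(dt, -prs, patient_id)
  out <- dt[seq_len(k), .(patient_id, prs)]
  out[, rank := .I][]
}
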