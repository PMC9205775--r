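# ---------------------------------------------------------------------------
# Model interpretation: exact tree-path Shapley attributions, top-feature
# ranking, dependence summaries, and the patient-subsample stability
# experiment.
# ---------------------------------------------------------------------------

#' Shapley-value attributions for a boosted-tree model
#'
#' Exact tree-path SHAP values on the margin (log-odds) scale, computed by
#' xgboost's TreeSHAP implementation, which honours missing markers the same
#' way prediction does. Per row, the base value plus the attributions equals
#' the model margin (local accuracy / additivity).
#'
#' @param model a `crisis_model` of kind `"xgboost"` (tree ensembles only;
#'   the interface is reserved for other kinds).
#' @param fm the `feature_matrix` to attribute (typically the test rows).
#' @param rows integer row indices (default: all rows).
#' @return an `attribution_matrix`: list with `phi` (rows x features), `base`
#'   (per-row base value), `values` (the feature values, for dependence
#'   summaries), `meta` (the matching meta rows), `additivity_residual`
#'   (max abs deviation of base + sum(phi) from the predicted margin).
#' @export
attribute <- function(model, fm, rows = NULL) {
  stopifnot(inherits(model, "crisis_model"))
  if (model$kind != "xgboost") {
    stop("attributions are implemented for tree-ensemble (xgboost) models only")
  }
  if (is.null(rows)) rows <- seq_len(nrow(fm$X))
  V <- fm$X[rows, model$features, drop = FALSE]
  d <- xgboost::xgb.DMatrix(V)
  ir <- xgb_iteration_range(model)
  contrib <- predict(model$fit, d, predcontrib = TRUE, iterationrange = ir)
  margin <- predict(model$fit, d, outputmargin = TRUE, iterationrange = ir)
  p <- length(model$features)
  phi <- contrib[, seq_len(p), drop = FALSE]
  base <- contrib[, p + 1L]
  resid <- max(abs(base + rowSums(phi) - margin))
  out <- list(phi = phi, base = base, values = V,
              meta = fm$meta[rows],
              additivity_residual = resid)
  class(out) <- "attribution_matrix"
  out
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d rows x %d features (additivity residual %.2e)\n",
              nrow(x$phi), ncol(x$phi), x$additivity_residual))
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' @param attr an `attribution_matrix`.
#' @param k number of features to return (default 20; larger than the feature
#'   count returns all).
#' @return `data.table`: feature, mean_abs_shap, descending with a
#'   deterministic name tie-break.
#' @export
top_features <- function(attr, k = 20L) {
  m <- colMeans(abs(attr$phi))
  dt <- data.table(feature = names(m), mean_abs_shap = as.numeric(m))
  setorder(dt, -mean_abs_shap, feature)
  dt[seq_len(min(k, nrow(dt)))]
}

#' Dependence summary for one feature
#'
#' Groups the attributions by the feature's value and reports the mean effect
#' and its standard deviation per value (the spread at a fixed value reflects
#' interactions with the other features). Missing-marker rows — the absence
#' of the event type in the patient's history — form their own group.
#'
#' @param attr an `attribution_matrix`.
#' @param feature feature name.
#' @param max_groups continuous features are binned to at most this many
#'   distinct values (quantile bins) before grouping.
#' @return `data.table`: value (NA row = missing marker), n, mean_effect,
#'   sd_effect.
#' @export
dependence_summary <- function(attr, feature, max_groups = 50L) {
  if (!feature %in% colnames(attr$phi)) stop("unknown feature: ", feature)
  v <- attr$values[, feature]
  eff <- attr$phi[, feature]
  grp <- v
  ux <- unique(v[!is.na(v)])
  if (length(ux) > max_groups) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = max_groups + 1L),
                          na.rm = TRUE))
    mid <- (head(br, -1) + tail(br, -1)) / 2
    grp[!is.na(v)] <- mid[pmin(findInterval(v[!is.na(v)], br,
                                            rightmost.closed = TRUE),
                               length(mid))]
  }
  dt <- data.table(value = grp, eff = eff)
  out <- dt[, .(n = .N, mean_effect = mean(eff),
                sd_effect = if (.N > 1L) sd(eff) else 0), keyby = value]
  out[]
}

#' Attribution stability under patient subsampling
#'
#' Retrains the model on random patient subsamples (default 40% of the
#' training patients), recomputes attributions on the full test set, and
#' measures the cosine similarity between each replicate's mean-absolute-SHAP
#' vector over the final model's top-k features and the final model's own
#' vector. High similarity means the headline feature ranking is not an
#' artifact of the particular cohort draw.
#'
#' @param fm a `feature_matrix`.
#' @param split output of [make_split()].
#' @param model the final `crisis_model` (kind `"xgboost"`); replicates reuse
#'   its selected features and hyperparameters so the experiment isolates the
#'   effect of the cohort composition.
#' @param n_reps number of replicates (default 100).
#' @param frac fraction of patients per subsample (default 0.4).
#' @param k size of the compared top-feature vector (default 20).
#' @param seed master seed; replicate seeds derive from it.
#' @return a `stability_result`: list with `similarity` (`data.table` rep,
#'   cosine, n_patients), `top_features` (the final model's top-k), `failed`
#'   (replicates whose training failed).
#' @export
stability_experiment <- function(fm, split, model, n_reps = 100L, frac = 0.4,
                                 k = 20L, seed = 1L) {
  stopifnot(model$kind == "xgboost", frac > 0, frac <= 1)
  test_rows <- split$test
  final_attr <- attribute(model, fm, test_rows)
  tf <- top_features(final_attr, k)
  ref_vec <- tf$mean_abs_shap
  feats <- tf$feature

  train_patients <- unique(fm$meta$patient_id[c(split$train, split$validation)])
  y <- fm$meta$label
  # keep the effective leaf-size regularization constant on the subsample
  rep_params <- model$params
  if (!is.null(rep_params$min_child_weight)) {
    rep_params$min_child_weight <- rep_params$min_child_weight * frac
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  sims <- vector("list", n_reps); failed <- integer(0)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    keep <- sample(train_patients, max(2L, round(frac * length(train_patients))))
    tr <- split$train[fm$meta$patient_id[split$train] %in% keep]
    va <- split$validation[fm$meta$patient_id[split$validation] %in% keep]
    res <- tryCatch({
      fit <- fit_xgb(fm$X[tr, model$features, drop = FALSE], y[tr],
                     fm$X[va, model$features, drop = FALSE], y[va],
                     rep_params, seed = model$fit_seed,
                     nrounds_max = model$nrounds_max,
                     early_stopping = model$early_stopping)
      rep_model <- new_crisis_model("xgboost", fit$booster, model$features,
                                    rep_params, fit$val_auc,
                                    extra = list(best_iteration = fit$best_iteration))
      a <- attribute(rep_model, fm, test_rows)
      v <- colMeans(abs(a$phi))[feats]
      sum(v * ref_vec) / sqrt(sum(v^2) * sum(ref_vec^2))
    }, error = function(e) NA_real_)
    if (is.na(res)) failed <- c(failed, r)
    sims[[r]] <- data.table(rep = r, cosine = res, n_patients = length(keep))
  }
  out <- list(similarity = rbindlist(sims)[!is.na(cosine)],
              top_features = tf, failed = failed)
  class(out) <- "stability_result"
  out
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d replicates, median cosine %.3f (IQR %.3f-%.3f)\n",
              nrow(x$similarity), median(x$similarity$cosine),
              quantile(x$similarity$cosine, 0.25),
              quantile(x$similarity$cosine, 0.75)))
  if (length(x$failed)) cat("  failed replicates:", length(x$failed), "\n")
  invisible(x)
}

#' Write an attribution matrix to CSV
#' @param attr an `attribution_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_attributions <- function(attr, path) {
  out <- cbind(
    data.table(patient_id = attr$meta$patient_id,
               week_start_date = week_start(attr$meta$week),
               base = attr$base),
    as.data.table(attr$phi)
  )
  fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}
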