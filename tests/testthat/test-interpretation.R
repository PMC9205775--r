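# deterministic toy training data for single-tree attribution checks
toy_xgb_matrix <- function(n = 400L, p = 3L, seed = 61L) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * X[, 1] - X[, 2] + 0.5 * X[, 1] * X[, 2]))
  list(X = X, y = y)
}

single_tree_model <- function(X, y, max_depth = 2L) {
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 1, min_child_weight = 1, nthread = 1L, seed = 1L,
                  base_score = 0.5), # logit 0: margins are pure tree values
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 1L, verbose = 0
  )
  structure(list(kind = "xgboost", fit = booster, features = colnames(X),
                 params = list(), val_auroc = NA_real_),
            class = "crisis_model")
}

test_that("attributions satisfy per-row additivity on a trained model", {
  tp <- tiny_pipeline()
  m <- tiny_model()
  att <- attribute(m, tp$fm, tp$split$test[1:200])
  # single-precision TreeSHAP: residuals sit at float32 rounding scale
  expect_lt(att$additivity_residual, 1e-5)
  expect_equal(dim(att$phi), c(200L, length(m$features)))
  expect_error(attribute(list(kind = "glm"), tp$fm), "tree-ensemble|crisis_model")
})

test_that("a one-feature stump attributes the full margin shift to its feature", {
  d <- toy_xgb_matrix(p = 2L)
  X1 <- d$X[, 1L, drop = FALSE]
  m <- single_tree_model(X1, d$y, max_depth = 1L)
  fm <- list(X = X1, meta = data.table::data.table(
    patient_id = "x", week = seq_len(nrow(X1)), label = d$y,
    censored = FALSE, in_crisis = FALSE))
  att <- attribute(m, fm)
  margin <- predict(m$fit, xgboost::xgb.DMatrix(X1), outputmargin = TRUE)
  expect_equal(att$phi[, 1], margin - att$base, tolerance = 1e-6)
})

test_that("single-tree attributions equal the exhaustive-coalition Shapley oracle", {
  d <- toy_xgb_matrix(p = 3L)
  for (depth in 2:3) {
    m <- single_tree_model(d$X, d$y, max_depth = depth)
    fm <- list(X = d$X, meta = data.table::data.table(
      patient_id = "x", week = seq_len(nrow(d$X)), label = d$y,
      censored = FALSE, in_crisis = FALSE))
    att <- attribute(m, fm, rows = 1:20)
    tree <- xgboost::xgb.model.dt.tree(model = m$fit)
    for (i in 1:20) {
      orc <- shapley_tree_oracle(tree, d$X[i, ])
      expect_equal(unname(att$phi[i, ]), orc$phi, tolerance = 1e-5,
                   label = sprintf("depth %d row %d", depth, i))
      expect_equal(unname(att$base[i]), orc$base, tolerance = 1e-5)
    }
  }
})

test_that("top-feature ranking is deterministic and ignores dead features", {
  tp <- tiny_pipeline()
  m <- tiny_model()
  att <- attribute(m, tp$fm, tp$split$test)
  tf <- top_features(att, k = 1000L) # larger than feature count: return all
  expect_equal(nrow(tf), length(m$features))
  expect_true(all(diff(tf$mean_abs_shap) <= 0))
  # a constant column can carry no attribution and ranks at the bottom
  const_cols <- tf[mean_abs_shap == 0, feature]
  dead <- names(which(apply(tp$fm$X[tp$split$train, ], 2, function(z) {
    !anyNA(z) && length(unique(z)) == 1L
  })))
  expect_true(all(dead %in% c(const_cols, setdiff(colnames(tp$fm$X), m$features))))
  # ranking is invariant to row order
  att2 <- attribute(m, tp$fm, rev(tp$split$test))
  expect_equal(top_features(att2, 10)$feature, tf$feature[1:10])
})

test_that("the planted relapse driver dominates the synthetic ranking", {
  tp <- tiny_pipeline()
  m <- tiny_model_all_features()
  att <- attribute(m, tp$fm, tp$split$test)
  top5 <- top_features(att, 5)$feature
  crisis_like <- tp$fm$registry[group_id == "crisis_history", name]
  expect_true(any(top5 %in% crisis_like))
})

test_that("dependence summaries group by value with missing rows separate", {
  tp <- tiny_pipeline()
  # a model with every feature available, so contact effects are attributable
  m_all <- tiny_model_all_features()
  att <- attribute(m_all, tp$fm, tp$split$test)
  ds <- dependence_summary(att, "crisis_wkssince", max_groups = 30L)
  expect_equal(sum(ds$n), length(tp$split$test))
  expect_error(dependence_summary(att, "ghost"), "unknown feature")
  # recent-crisis weeks must push risk up relative to distant ones
  recent <- ds[!is.na(value) & value <= 4]
  distant <- ds[!is.na(value) & value >= 30]
  if (nrow(recent) && nrow(distant)) {
    expect_gt(weighted.mean(recent$mean_effect, recent$n),
              weighted.mean(distant$mean_effect, distant$n))
  }
  # single-valued feature collapses to one observed group
  ds2 <- dependence_summary(att, "gender_male")
  expect_lte(nrow(ds2), 2L)
})

test_that("attribution stability is perfect at full resampling and reproducible", {
  tp <- tiny_pipeline()
  m <- tiny_model()
  full <- stability_experiment(tp$fm, tp$split, m, n_reps = 2L, frac = 1,
                               k = 10L, seed = 13L)
  expect_equal(full$similarity$cosine, c(1, 1), tolerance = 1e-12)
  again <- stability_experiment(tp$fm, tp$split, m, n_reps = 3L, frac = 0.5,
                                k = 10L, seed = 13L)
  again2 <- stability_experiment(tp$fm, tp$split, m, n_reps = 3L, frac = 0.5,
                                 k = 10L, seed = 13L)
  expect_equal(again$similarity, again2$similarity)
  expect_true(all(again$similarity$cosine >= -1 & again$similarity$cosine <= 1))
})

test_that("attribution CSV export carries one row per test row", {
  tp <- tiny_pipeline()
  m <- tiny_model()
  att <- attribute(m, tp$fm, tp$split$test[1:50])
  p <- withr::local_tempfile(fileext = ".csv")
  write_attributions(att, p)
  back <- data.table::fread(p)
  expect_equal(nrow(back), 50L)
  expect_equal(ncol(back), length(m$features) + 3L)
})
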