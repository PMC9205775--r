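test_that("ranking metrics agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(2024)
  for (rep in 1:10) {
    n <- 150L
    y <- rbinom(n, 1, 0.3)
    s <- rnorm(n) + y
    s[sample(n, 10)] <- s[sample(n, 10)] # induce ties occasionally
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
  # average precision closed cases
  expect_equal(average_precision(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(average_precision(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_true(is.na(average_precision(rnorm(5), rep(0, 5))))
})

test_that("the default split plan reproduces the study timeline", {
  plan <- split_plan()
  stamp <- function(d) date_to_week(as.Date(d))
  in_range <- function(w, r) w >= r[1] & w <= r[2]
  expect_true(in_range(stamp("2018-03-15"), plan$validation))
  expect_true(in_range(stamp("2018-08-10"), plan$test))
  expect_true(in_range(stamp("2015-06-01"), plan$train))
  expect_true(in_range(stamp("2012-09-05"), plan$train))
  expect_false(in_range(stamp("2018-12-01"), plan$test))
})

test_that("splits partition the eligible rows by week", {
  tp <- tiny_pipeline()
  s <- tp$split
  idx <- c(s$train, s$validation, s$test)
  expect_equal(anyDuplicated(idx), 0L)
  keep <- !tp$fm$meta$censored
  expect_setequal(idx, which(keep))
  expect_true(max(tp$fm$meta$week[s$train]) < min(tp$fm$meta$week[s$validation]))
  expect_true(max(tp$fm$meta$week[s$validation]) < min(tp$fm$meta$week[s$test]))
  bad_plan <- proportional_split_plan(tp$fm$meta$week)
  bad_plan$test <- c(max(tp$fm$meta$week) + 10L, max(tp$fm$meta$week) + 20L)
  expect_error(make_split(tp$fm, bad_plan), "empty partition")
})

test_that("the TPE search improves over its own first trial and handles failures", {
  space <- list(
    x = list(type = "uniform", lo = -3, hi = 3),
    k = list(type = "choice", values = list("a", "b"))
  )
  obj <- function(p) -(p$x - 1)^2 + (p$k == "a")
  set.seed(1)
  res1 <- tpe_search(obj, space, budget = 1L)
  set.seed(1)
  res40 <- tpe_search(obj, space, budget = 40L)
  expect_gte(res40$best_score, res1$best_score)
  expect_gt(res40$best_score, -0.3) # near the optimum at x = 1, k = "a"
  # a sometimes-failing objective is tolerated
  obj_bad <- function(p) if (p$x < 0) stop("boom") else p$x
  set.seed(2)
  res <- tpe_search(obj_bad, space, budget = 15L)
  expect_true(is.finite(res$best_score))
  expect_equal(nrow(res$history), 15L)
})

test_that("the general model trains reproducibly and beats chance", {
  tp <- tiny_pipeline()
  m <- tiny_model()
  raw <- predict_risk(m, tp$fm, tp$split$test)
  y <- tp$fm$meta$label[tp$split$test]
  expect_gt(auroc(raw, y), 0.6)
  expect_true(all(raw >= 0 & raw <= 1))
  m2 <- train_general(tp$fm, tp$split, budget = 3L, seed = 7L,
                      nrounds_max = 150L, early_stopping = 20L)
  expect_identical(predict_risk(m2, tp$fm, tp$split$test), raw)
  # single-class labels are rejected
  fm0 <- tp$fm
  fm0$meta <- data.table::copy(fm0$meta)[, label := 0L]
  expect_error(train_general(fm0, tp$split, budget = 1L), "single-class")
})

test_that("the clinical baseline is a shallow tree between chance and the model", {
  tp <- tiny_pipeline()
  bc <- train_baseline_clinical(tp$fm, tp$split, seed = 7L)
  y <- tp$fm$meta$label[tp$split$test]
  a <- auroc(predict_risk(bc, tp$fm, tp$split$test), y)
  expect_gt(a, 0.5)
  expect_s3_class(bc$fit, "rpart")
  # same seed twice -> identical tree and predictions
  bc2 <- train_baseline_clinical(tp$fm, tp$split, seed = 7L)
  expect_identical(predict_risk(bc2, tp$fm, tp$split$test),
                   predict_risk(bc, tp$fm, tp$split$test))
  # an uninformative indicator set scores at chance
  fmc <- tp$fm
  fmc$X <- cbind(tp$fm$X, junk = rep(1, nrow(tp$fm$X)))
  b0 <- train_baseline_clinical(fmc, tp$split, features = "junk", seed = 7L)
  expect_equal(auroc(predict_risk(b0, fmc, tp$split$test), y), 0.5)
  expect_error(train_baseline_clinical(tp$fm, tp$split, features = "nope"),
               "unknown feature")
})

test_that("the diagnosis baseline has the documented coefficient structure", {
  tp <- tiny_pipeline()
  bd <- train_baseline_diagnosis(tp$fm, tp$split)
  y <- tp$fm$meta$label[tp$split$test]
  expect_gt(auroc(predict_risk(bd, tp$fm, tp$split$test), y), 0.5)
  # coefficients: (groups present - 1) one-hots + recency + missing flag + intercept
  dxcols <- tp$fm$registry[procedure == "diagnosis", name]
  present <- sum(colSums(tp$fm$X[tp$split$train, dxcols]) > 0)
  expect_equal(length(coef(bd$fit)), (present - 1) + 2 + 1)
  expect_true(all(c("crisis_wkssince", "crisis_never") %in% names(coef(bd$fit))))
  # recency carries signal: dropping it hurts validation AUROC
  yv <- tp$fm$meta$label[tp$split$validation]
  dx_only <- glm(y ~ ., family = binomial(),
                 data = data.frame(y = tp$fm$meta$label[tp$split$train],
                                   tp$fm$X[tp$split$train, dxcols[-1]]))
  p_dx <- predict(dx_only, data.frame(tp$fm$X[tp$split$validation, dxcols[-1]]),
                  type = "response")
  expect_gt(auroc(predict_risk(bd, tp$fm, tp$split$validation), yv),
            auroc(as.numeric(p_dx), yv))
})

test_that("isotonic calibration preserves order and improves validation Brier", {
  set.seed(88)
  n <- 4000L
  raw <- runif(n)
  y <- rbinom(n, 1, plogis(4 * raw - 3)) # miscalibrated but monotone signal
  test_raw <- runif(1000L)
  cal <- calibrate(raw, y, test_raw)
  expect_true(all(cal$prs >= 0 & cal$prs <= 1))
  o <- order(test_raw)
  expect_true(all(diff(cal$prs[o]) >= -1e-12)) # no rank inversions
  # Spearman rank preservation on strictly increasing sections
  expect_gte(cor(test_raw, cal$prs, method = "spearman"), 0.99)
  # on the data the map was fit to, squared error cannot get worse
  self <- calibrate(raw, y, raw)
  expect_lte(brier(self$prs, y), brier(raw, y))
  # degenerate constant scores map to the validation positive rate
  flat <- calibrate(rep(0.7, 100), rbinom(100, 1, 0.2), c(0.1, 0.7, 0.9))
  expect_equal(unique(flat$prs), mean(flat$knots$yhat))
})

test_that("the reduced model is confined to its feature list", {
  tp <- tiny_pipeline()
  expect_error(reduced_model(tp$fm, tp$split, features = c("crisis_wkssince", "ghost")),
               "absent from the registry")
  red <- reduced_model(tp$fm, tp$split, budget = 2L, seed = 7L,
                       nrounds_max = 100L, early_stopping = 15L)
  y <- tp$fm$meta$label[tp$split$test]
  p0 <- predict_risk(red, tp$fm, tp$split$test)
  expect_gt(auroc(p0, y), 0.55)
  # perturbing an excluded column cannot change its predictions
  fm2 <- tp$fm
  fm2$X <- data.table::copy(tp$fm$X)
  excluded <- setdiff(colnames(fm2$X), red$features)[1]
  fm2$X[, excluded] <- rnorm(nrow(fm2$X))
  expect_identical(predict_risk(red, fm2, tp$split$test), p0)
})

test_that("top-k ranking is deterministic and order-invariant", {
  set.seed(5)
  preds <- data.table::data.table(
    patient_id = sprintf("P%02d", 1:30),
    prs = round(runif(30), 2)
  )
  top <- rank_top_k(preds, k = 25L)
  expect_equal(nrow(top), 25L)
  expect_true(all(diff(top$prs) <= 0))
  expect_equal(top$rank, 1:25)
  shuffled <- rank_top_k(preds[sample(30)], k = 25L)
  expect_identical(shuffled, top)
  # equal scores break ties by patient id
  tie <- data.table::data.table(patient_id = c("P2", "P1"), prs = c(0.5, 0.5))
  expect_equal(rank_top_k(tie, k = 2L)$patient_id, c("P1", "P2"))
  expect_warning(all30 <- rank_top_k(preds, k = 40L), "exceeds")
  expect_equal(nrow(all30), 30L)
  expect_error(rank_top_k(rbind(preds, preds[1]), k = 5L), "one prediction per patient")
  # caseload filter restricts before ranking
  sub <- rank_top_k(preds, k = 5L, caseload = preds$patient_id[1:10])
  expect_true(all(sub$patient_id %in% preds$patient_id[1:10]))
})
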