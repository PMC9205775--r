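test_that("weekly metrics pool per-week values with a t interval", {
  # perfect predictions: AUROC 1 every week, zero-width interval
  y <- rep(c(0, 1), 50)
  wk <- rep(1:5, each = 20)
  wm <- weekly_metrics(y + 0, y, wk)
  expect_equal(wm$per_week$auroc, rep(1, 5))
  a <- wm$pooled[metric == "auroc"]
  expect_equal(c(a$mean, a$lo, a$hi), c(1, 1, 1))
  expect_equal(a$n_weeks, 5L)
  # constant scores in a week: AP equals that week's prevalence
  lab2 <- rep(c(1, 0, 0, 0), 5) # 3 positives in week 1, 2 in week 2
  wm2 <- weekly_metrics(rep(0.4, 20), lab2, rep(1:2, each = 10))
  expect_equal(wm2$per_week$ap, c(0.3, 0.2))
  # single-class weeks are skipped, not dropped silently
  y3 <- c(rep(0, 10), rep(c(0, 1), 5))
  wm3 <- weekly_metrics(rnorm(20), y3, rep(1:2, each = 10))
  expect_equal(wm3$skipped_weeks, 1L)
  expect_equal(wm3$pooled[metric == "auroc", n_weeks], 1L)
  expect_error(weekly_metrics(rnorm(10), rep(0, 10), rep(1:2, 5)), "both outcome")
})

test_that("uniform predictions pool to an interval covering one half", {
  set.seed(11)
  n <- 5000L * 4L
  y <- rbinom(n, 1, 0.1)
  wm <- weekly_metrics(runif(n), y, rep(1:4, each = 5000L))
  a <- wm$pooled[metric == "auroc"]
  expect_true(a$lo <= 0.5 && 0.5 <= a$hi)
})

test_that("subgroup AUROC reduces to overall metrics and reports undefined groups", {
  set.seed(3)
  n <- 600L
  y <- rbinom(n, 1, 0.2)
  s <- rnorm(n) + y
  wk <- rep(1:3, each = 200L)
  whole <- subgroup_auroc(s, y, wk, rep("all", n))
  wm <- weekly_metrics(s, y, wk)
  expect_equal(whole$auroc, wm$pooled[metric == "auroc", mean])
  g <- rep(c("a", "b"), n / 2)
  tab <- subgroup_auroc(s, y, wk, g)
  expect_equal(sum(tab$n), n)
  # a group with only negatives is reported as NA, not dropped
  y2 <- y; y2[g == "b"] <- 0
  tab2 <- subgroup_auroc(s, y2, wk, g)
  expect_true(is.na(tab2[group == "b", auroc]))
  expect_equal(nrow(tab2), 2L)
  # informative group discriminates, pure-noise group does not
  s3 <- ifelse(g == "a", y + rnorm(n, 0, 0.5), rnorm(n))
  tab3 <- subgroup_auroc(s3, y, wk, g)
  expect_gt(tab3[group == "a", auroc], 0.8)
  expect_lt(abs(tab3[group == "b", auroc] - 0.5), 0.1)
})

test_that("standard groupings bin ages and data availability", {
  expect_equal(as.character(age_bins(c(17, 70, 90))), c("<18", "65-74", "75+"))
  expect_equal(as.character(recency_bins(c(2, 60))), c("<=1 month", ">=1 year"))
  expect_equal(as.character(history_bins(c(10, 300))), c("<=6 months", ">=5 years"))
})

test_that("the correlated-ROC test matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:12) {
    n <- 180L
    y <- rbinom(n, 1, 0.35)
    z <- rnorm(n)
    a <- 0.8 * y + z + rnorm(n, 0, 0.6)
    b <- 0.3 * y + z + rnorm(n, 0, 0.6)
    ours <- compare_roc(a, b, y)
    ref <- pROC::roc.test(
      pROC::roc(y, a, direction = "<", quiet = TRUE),
      pROC::roc(y, b, direction = "<", quiet = TRUE),
      method = "delong", paired = TRUE
    )
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-8)
  }
  y <- rbinom(100, 1, 0.3); s <- rnorm(100)
  same <- compare_roc(s, s, y)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the correlated-ROC test has power against a real difference", {
  set.seed(9)
  n <- 2000L
  y <- rbinom(n, 1, 0.3)
  informative <- y + rnorm(n, 0, 0.4)
  noise <- rnorm(n)
  expect_lt(compare_roc(informative, noise, y)$p_value, 0.001)
})

test_that("two-stage FDR correction matches the literal step-by-step oracle", {
  expect_equal(bky_adjust(rep(1, 6))$rejected, rep(FALSE, 6))
  expect_equal(bky_adjust(rep(0, 6))$rejected, rep(TRUE, 6))
  expect_error(bky_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(14)
  for (rep in 1:400) {
    m <- sample(1:10, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- sample(c(0.05, 0.1, 0.2), 1)
    expect_equal(bky_adjust(p, q)$rejected, bky_oracle(p, q),
                 label = paste(c(q, p), collapse = ","))
  }
})

test_that("Brier score closed forms hold", {
  y <- rbinom(200, 1, 0.3)
  expect_equal(brier(y, y), 0)
  expect_equal(brier(rep(0.5, 200), y), 0.25)
  pi0 <- mean(y)
  expect_equal(brier(rep(pi0, 200), y), pi0 * (1 - pi0), tolerance = 1e-12)
  expect_error(brier(c(0.5, 1.2), c(0, 1)), ">= 0")
})

test_that("the calibration curve uses 25 even bins and reports empty ones", {
  set.seed(30)
  n <- 50000L
  p <- runif(n)
  y <- rbinom(n, 1, p)
  cc <- calibration_curve(p, y)
  expect_equal(nrow(cc), 25L)
  expect_equal(sum(cc$n), n)
  occupied <- cc[n >= 100]
  expect_lt(max(abs(occupied$obs_rate - occupied$mean_pred)), 0.05)
  # all mass in one bin: observed rate is the sample prevalence
  y400 <- rbinom(400, 1, 0.3)
  one <- calibration_curve(rep(0.3, 400), y400)
  expect_equal(one[n > 0, bin], 8L)
  expect_equal(one[n > 0, obs_rate], mean(y400))
  expect_equal(sum(one$n > 0), 1L)
})

test_that("net benefit reproduces its closed forms and the worked contingency", {
  y <- rbinom(300, 1, 0.25)
  nb <- net_benefit(as.numeric(y), y, thresholds = c(0.1, 0.3, 0.5))
  expect_equal(nb$net_benefit, rep(mean(y), 3)) # perfect predictor
  expect_equal(nb$treat_none, rep(0, 3))
  expect_equal(nb$treat_all,
               mean(y) - (1 - mean(y)) * c(0.1, 0.3, 0.5) / (1 - c(0.1, 0.3, 0.5)))
  # TP=8, FP=10, n=100 at t=0.2: NB = 0.08 - 0.10 * 0.25 = 0.055
  pred <- c(rep(0.6, 18), rep(0.1, 82))
  lab <- c(rep(1, 8), rep(0, 10), rep(0, 82))
  got <- net_benefit(pred, lab, thresholds = 0.2)
  expect_equal(got$net_benefit, 0.055)
  # boundary thresholds are excluded
  expect_equal(nrow(net_benefit(pred, lab, thresholds = c(0, 0.2, 1))), 1L)
})

test_that("operating points meet the specificity target with maximal sensitivity", {
  # perfect separation: sensitivity 1 at any specificity
  y <- c(rep(0, 60), rep(1, 40))
  s <- c(runif(60, 0, 0.4), runif(40, 0.6, 1))
  for (sp in c(0.5, 0.85, 0.99)) {
    op <- operating_point(s, y, sp)
    expect_equal(op$sensitivity, 1)
    expect_gte(op$specificity, sp)
  }
  # random scores: sensitivity ~ 1 - specificity
  set.seed(44)
  y2 <- rbinom(20000, 1, 0.3)
  s2 <- runif(20000)
  op2 <- operating_point(s2, y2, 0.85)
  expect_lt(abs(op2$sensitivity - 0.15), 0.03)
  expect_gte(op2$specificity, 0.85)
  expect_error(operating_point(s2, rep(0, 20000), 0.85), "both outcome")
  expect_error(operating_point(s2, y2, 1.2), "unreachable")
})

test_that("the evaluation report bundles the battery coherently", {
  set.seed(50)
  n <- 3000L
  y <- rbinom(n, 1, 0.1)
  prs <- plogis(qlogis(0.1) + 2 * y + rnorm(n, 0, 0.8))
  wk <- rep(1:6, each = 500L)
  grp <- sample(c("x", "y"), n, TRUE)
  rep_ <- eval_report(prs, y, wk, groupings = list(g = grp))
  expect_s3_class(rep_, "eval_report")
  expect_equal(nrow(rep_$per_week), 6L)
  expect_equal(nrow(rep_$calibration), 25L)
  expect_equal(nrow(rep_$subgroups$g), 2L)
  expect_equal(rep_$prevalence, mean(y))
  op85 <- rep_$operating_points[target_specificity == 0.85]
  expect_gte(op85$specificity, 0.85)
  dir <- withr::local_tempdir()
  write_eval_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "per_week.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "subgroup_g.csv")))
})
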