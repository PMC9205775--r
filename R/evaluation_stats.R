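# ---------------------------------------------------------------------------
# Evaluation battery: weekly-split CIs, subgroup AUROC, correlated-ROC
# comparison, two-stage FDR correction, Brier score, calibration curve,
# decision-curve analysis and operating points.
# ---------------------------------------------------------------------------

#' Per-week metrics with pooled confidence intervals
#'
#' The test range is evaluated one calendar week at a time; each week
#' contributes one AUROC and one average-precision value, and the pooled
#' estimate is the mean across weeks with a t-interval over the weekly values
#' (t rather than normal because the number of weekly splits is small).
#' Weeks with a single outcome class carry no ranking information and are
#' skipped (recorded in the output, never silently dropped).
#'
#' @param scores,labels predictions and 0/1 outcomes.
#' @param weeks integer week index per row.
#' @param conf confidence level (default 0.95).
#' @return list: `per_week` (`data.table` week, n, n_pos, auroc, ap),
#'   `pooled` (`data.table` metric, mean, lo, hi, n_weeks),
#'   `skipped_weeks` (integer vector).
#' @export
weekly_metrics <- function(scores, labels, weeks, conf = 0.95) {
  dt <- data.table(s = scores, y = as.integer(labels), w = as.integer(weeks))
  per_week <- dt[, .(n = .N, n_pos = sum(y),
                     auroc = auroc(s, y), ap = average_precision(s, y)),
                 keyby = w]
  setnames(per_week, "w", "week")
  valid <- per_week[!is.na(auroc)]
  if (!nrow(valid)) stop("no evaluable week has both outcome classes")
  tci <- function(x) {
    m <- mean(x); k <- length(x)
    half <- if (k > 1L) qt(1 - (1 - conf) / 2, k - 1L) * sd(x) / sqrt(k) else 0
    c(mean = m, lo = m - half, hi = m + half)
  }
  pooled <- rbind(
    data.table(metric = "auroc", t(tci(valid$auroc))),
    data.table(metric = "ap", t(tci(valid$ap)))
  )
  pooled[, n_weeks := nrow(valid)]
  list(per_week = per_week, pooled = pooled,
       skipped_weeks = per_week[is.na(auroc), week])
}

#' Subgroup AUROC table
#'
#' [weekly_metrics()] restricted to each level of a grouping (diagnosis, age
#' bin, data-recency bin, ...). Groups whose rows never contain both classes
#' are reported with `NA` metrics rather than dropped.
#'
#' @param scores,labels,weeks as in [weekly_metrics()].
#' @param group vector assigning each row to at most one group (`NA` rows are
#'   ignored).
#' @return `data.table`: group, n, n_pos, auroc mean/lo/hi, ap mean, n_weeks.
#' @export
subgroup_auroc <- function(scores, labels, weeks, group) {
  dt <- data.table(s = scores, y = as.integer(labels),
                   w = as.integer(weeks), g = group)[!is.na(g)]
  res <- lapply(split(dt, by = "g", sorted = TRUE), function(d) {
    wm <- tryCatch(weekly_metrics(d$s, d$y, d$w), error = function(e) NULL)
    if (is.null(wm)) {
      data.table(group = d$g[1], n = nrow(d), n_pos = sum(d$y),
                 auroc = NA_real_, auroc_lo = NA_real_, auroc_hi = NA_real_,
                 ap = NA_real_, n_weeks = 0L)
    } else {
      a <- wm$pooled[metric == "auroc"]
      data.table(group = d$g[1], n = nrow(d), n_pos = sum(d$y),
                 auroc = a$mean, auroc_lo = a$lo, auroc_hi = a$hi,
                 ap = wm$pooled[metric == "ap", mean], n_weeks = a$n_weeks)
    }
  })
  rbindlist(res)
}

#' Age and data-availability groupings
#'
#' Standard subgroup definitions: decade age bins with dedicated "<18" and
#' "65-74" bins, recency-of-last-record bins, and history-length bins.
#'
#' @param x numeric vector (age in years, or weeks for the recency/history
#'   variants).
#' @return factor of bins.
#' @export
age_bins <- function(x) {
  cut(x, breaks = c(-Inf, 17, 24, 34, 44, 54, 64, 74, Inf),
      labels = c("<18", "18-24", "25-34", "35-44", "45-54", "55-64",
                 "65-74", "75+"))
}

#' @rdname age_bins
#' @export
recency_bins <- function(x) {
  cut(x, breaks = c(-Inf, 4, 13, 26, 52, Inf),
      labels = c("<=1 month", "1-3 months", "3-6 months", "6-12 months",
                 ">=1 year"))
}

#' @rdname age_bins
#' @export
history_bins <- function(x) {
  cut(x, breaks = c(-Inf, 26, 52, 104, 260, Inf),
      labels = c("<=6 months", "6-12 months", "1-2 years", "2-5 years",
                 ">=5 years"))
}

#' Compare two correlated ROC curves
#'
#' Paired z-test for the difference of two AUROCs computed on the same rows,
#' using the generalized U-statistic (DeLong) variance that accounts for the
#' correlation between the two score vectors. Two-sided p-value.
#'
#' @param scores_a,scores_b the two prediction vectors (same rows).
#' @param labels 0/1 outcomes.
#' @return list: `auc_a`, `auc_b`, `statistic` (z), `p_value`.
#' @export
compare_roc <- function(scores_a, scores_b, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  pos <- y == 1L; neg <- !pos
  m <- sum(pos); n <- sum(neg)
  if (m == 0L || n == 0L) stop("both outcome classes required")

  placements <- function(s) {
    # V10[i] = P(s_pos_i > s_neg) + .5 P(=), via midranks (Sun & Xu 2014)
    sp <- s[pos]; sn <- s[neg]
    r_all <- rank(c(sp, sn))
    v10 <- (r_all[seq_len(m)] - rank(sp)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(sn)) / m
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  d10 <- pa$v10 - pb$v10; d01 <- pa$v01 - pb$v01
  v <- (if (m > 1L) stats::var(d10) / m else 0) +
       (if (n > 1L) stats::var(d01) / n else 0)
  diff <- pa$auc - pb$auc
  if (v <= 0) {
    z <- 0; p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, statistic = z, p_value = p)
}

#' Two-stage step-up FDR correction (Benjamini-Krieger-Yekutieli)
#'
#' Stage one runs Benjamini-Hochberg at level `q/(1+q)`; the number of
#' non-rejections estimates the number of true nulls `m0`; stage two reruns
#' the step-up procedure with `m0` in place of `m`. If the first stage
#' rejects nothing (or everything) the procedure stops there.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q target false-discovery rate (default 0.05).
#' @return list: `rejected` (logical), `adjusted` (stage-two step-up adjusted
#'   p-values, to be compared against `q/(1+q)`), `m0` (estimated true
#'   nulls).
#' @export
bky_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  q1 <- q / (1 + q)
  bh_reject <- function(p, level, m_eff) {
    o <- order(p)
    ok <- p[o] <= seq_len(m) * level / m_eff
    k <- if (any(ok)) max(which(ok)) else 0L
    rej <- logical(m)
    if (k > 0L) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  r1 <- bh_reject(p, q1, m)
  n1 <- sum(r1)
  if (n1 == 0L) {
    return(list(rejected = logical(m), adjusted = rep(1, m), m0 = m))
  }
  if (n1 == m) {
    return(list(rejected = rep(TRUE, m), adjusted = p * 0, m0 = 0L))
  }
  m0 <- m - n1
  rejected <- bh_reject(p, q1, m0)
  # step-up adjusted values with m0 in place of m (compare against q/(1+q))
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m0 / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[o] <- pmin(adj_sorted, 1)
  list(rejected = rejected, adjusted = adjusted, m0 = m0)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes.
#' @param predictions probabilities in \[0, 1\].
#' @param labels 0/1 outcomes.
#' @return the score.
#' @export
brier <- function(predictions, labels) {
  stopifnot(all(predictions >= 0 & predictions <= 1))
  mean((predictions - as.numeric(labels))^2)
}

#' Calibration curve over evenly spaced bins
#'
#' Bins the PRS into `n_bins` equal-width bins on \[0, 1\] and reports, per
#' bin, the mean prediction, the observed outcome rate and the count. Empty
#' bins are reported empty rather than dropped.
#'
#' @param predictions probabilities in \[0, 1\].
#' @param labels 0/1 outcomes.
#' @param n_bins number of bins (default 25).
#' @return `data.table`: bin, lo, hi, n, mean_pred, obs_rate.
#' @export
calibration_curve <- function(predictions, labels, n_bins = 25L) {
  stopifnot(n_bins >= 2L, all(predictions >= 0 & predictions <= 1))
  bin <- pmin(floor(predictions * n_bins) + 1L, n_bins)
  dt <- data.table(bin = bin, p = predictions, y = as.numeric(labels))
  agg <- dt[, .(n = .N, mean_pred = mean(p), obs_rate = mean(y)), keyby = bin]
  out <- data.table(bin = seq_len(n_bins))
  out[, `:=`(lo = (bin - 1) / n_bins, hi = bin / n_bins)]
  out <- merge(out, agg, by = "bin", all.x = TRUE)
  out[is.na(n), n := 0L][]
}

#' Decision-curve analysis (net benefit)
#'
#' Net benefit at decision threshold t: `TP/n - (FP/n) * t/(1-t)`, classifying
#' positive when the prediction is at least t. Includes the treat-all
#' (`pi - (1-pi) t/(1-t)`) and treat-none (0) reference strategies.
#' Thresholds of exactly 0 or 1 are excluded.
#'
#' @param predictions probabilities in \[0, 1\].
#' @param labels 0/1 outcomes.
#' @param thresholds numeric vector in (0, 1).
#' @return `data.table`: threshold, net_benefit, treat_all, treat_none.
#' @export
net_benefit <- function(predictions, labels, thresholds = seq(0.01, 0.5, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  y <- as.integer(labels); n <- length(y); prev <- mean(y)
  res <- vapply(thresholds, function(t) {
    cls <- predictions >= t
    tp <- sum(cls & y == 1L); fp <- sum(cls & y == 0L)
    tp / n - (fp / n) * t / (1 - t)
  }, 1)
  data.table(threshold = thresholds, net_benefit = res,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Sensitivity at a target specificity
#'
#' Scans the ROC curve for the smallest threshold whose specificity meets the
#' target — i.e. the operating point with maximal sensitivity subject to the
#' specificity constraint (classification positive at scores >= threshold).
#'
#' @param predictions scores.
#' @param labels 0/1 outcomes.
#' @param target_specificity value in \[0, 1\].
#' @return list: `sensitivity`, `specificity` (achieved), `threshold`.
#' @export
operating_point <- function(predictions, labels, target_specificity = 0.85) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both outcome classes required")
  if (target_specificity > 1) stop("unreachable specificity target")
  sn <- predictions[y == 0L]
  n0 <- length(sn)
  # thresholds: unique scores ascending, plus one above the maximum
  thr <- c(sort(unique(predictions)), max(predictions) + 1)
  spec <- vapply(thr, function(t) mean(sn < t), 1)
  ok <- which(spec >= target_specificity)
  t_star <- thr[ok[1L]]
  sp <- predictions[y == 1L]
  list(sensitivity = mean(sp >= t_star),
       specificity = spec[ok[1L]],
       threshold = t_star)
}

#' Full evaluation report
#'
#' Bundles the evaluation battery for one prediction vector: weekly AUROC/AP
#' with pooled CIs, Brier score, 25-bin calibration curve, decision curve,
#' the sensitivity-at-85%-specificity operating point (plus a specificity
#' grid) and any requested subgroup AUROC tables.
#'
#' @param prs calibrated predicted risk scores.
#' @param labels 0/1 outcomes.
#' @param weeks integer week per row.
#' @param groupings named list of per-row grouping vectors (optional).
#' @param specificity_grid specificities at which operating points are
#'   reported.
#' @return an `eval_report` list.
#' @export
eval_report <- function(prs, labels, weeks, groupings = list(),
                        specificity_grid = c(0.75, 0.80, 0.85, 0.90, 0.95)) {
  wm <- weekly_metrics(prs, labels, weeks)
  ops <- rbindlist(lapply(specificity_grid, function(sp) {
    op <- operating_point(prs, labels, sp)
    data.table(target_specificity = sp, sensitivity = op$sensitivity,
               specificity = op$specificity, threshold = op$threshold)
  }))
  out <- list(
    per_week = wm$per_week, pooled = wm$pooled,
    skipped_weeks = wm$skipped_weeks,
    brier = brier(prs, labels),
    calibration = calibration_curve(prs, labels),
    decision_curve = net_benefit(prs, labels),
    operating_points = ops,
    subgroups = lapply(groupings, function(g) subgroup_auroc(prs, labels, weeks, g)),
    n = length(prs), prevalence = mean(as.numeric(labels))
  )
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$pooled[metric == "auroc"]; p <- x$pooled[metric == "ap"]
  cat(sprintf("<eval_report> n=%d, prevalence %.3f, %d weekly splits\n",
              x$n, x$prevalence, a$n_weeks))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f)\n", a$mean, a$lo, a$hi))
  cat(sprintf("  AP    %.3f (95%% CI %.3f-%.3f)\n", p$mean, p$lo, p$hi))
  cat(sprintf("  Brier %.4f\n", x$brier))
  op <- x$operating_points[abs(target_specificity - 0.85) < 1e-9]
  if (nrow(op)) {
    cat(sprintf("  sensitivity %.1f%% at specificity %.1f%%\n",
                100 * op$sensitivity, 100 * op$specificity))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report's tables as CSVs plus a JSON summary into a directory.
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(report$per_week, file.path(dir, "per_week.csv"))
  fwrite(report$pooled, file.path(dir, "pooled.csv"))
  fwrite(report$calibration, file.path(dir, "calibration.csv"))
  fwrite(report$decision_curve, file.path(dir, "decision_curve.csv"))
  fwrite(report$operating_points, file.path(dir, "operating_points.csv"))
  for (g in names(report$subgroups)) {
    fwrite(report$subgroups[[g]], file.path(dir, paste0("subgroup_", g, ".csv")))
  }
  summary <- list(n = report$n, prevalence = report$prevalence,
                  brier = report$brier,
                  auroc = as.list(report$pooled[metric == "auroc"]),
                  ap = as.list(report$pooled[metric == "ap"]))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
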