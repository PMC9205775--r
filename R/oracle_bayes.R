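# Frozen-history Bayes reference for the 28-day target. oracle_risk_28d()
# scores each week with the *realized* future hazards; in a history-dependent
# hazard those hazards react to post-query events (most notably the predicted
# onset itself), so that functional is clairvoyant — no predictor restricted
# to information available at the query week can match its discrimination.
# This reference instead evolves the recency state deterministically over the
# horizon (as if no further events occurred) and applies the generator's own
# hazard model, yielding the attainable yardstick for signal recovery.

#' Frozen-history 28-day risk from the generator's latent model
#'
#' The 28-day crisis risk implied by the generator's hazard model when the
#' patient's history is frozen at the query week: each recency advances
#' deterministically (`delta + k`), the episode count stays fixed, and the
#' seasonal term follows the calendar. Unlike [oracle_risk_28d()], which
#' scores with the realized future hazards (and therefore conditions on
#' events after the query week), this reference uses only information
#' available when the model itself is queried, so it is the appropriate
#' ceiling for the trained model's discrimination.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param patient_id character vector of patients.
#' @param week integer vector of absolute week indices (parallel).
#' @param horizon number of future weeks (default 4).
#' @return numeric vector of probabilities.
#' @export
oracle_bayes_28d <- function(cohort, patient_id, week, horizon = 4L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config; store <- cohort$store; latent <- cohort$latent

  q <- data.table(patient_id = patient_id, week = as.integer(week),
                  row = seq_along(week))
  stream_weeks <- list(
    crisis = store$crisis[, .(patient_id, week = date_to_week(date))],
    unplanned = store$contact[category == "unplanned",
                              .(patient_id, week = date_to_week(date))],
    missed = store$contact[category == "missed",
                           .(patient_id, week = date_to_week(date))],
    carer = store$contact[category == "carer",
                          .(patient_id, week = date_to_week(date))],
    referral = store$referral[category %in% c("gp", "community", "acute"),
                              .(patient_id, week = date_to_week(date))],
    suicide_pos = store$risk_assessment[category == "suicide" & value == 1,
                                        .(patient_id, week = date_to_week(date))]
  )

  delta <- matrix(Inf, nrow(q), length(stream_weeks),
                  dimnames = list(NULL, names(stream_weeks)))
  for (s in names(stream_weeks)) {
    ev <- stream_weeks[[s]]
    setkey(ev, patient_id)
    for (p in unique(q$patient_id)) {
      rows <- q[patient_id == p, row]
      d <- weeks_since_last(ev[.(p), week, nomatch = NULL], q$week[rows])
      delta[rows, s] <- ifelse(is.na(d), Inf, d)
    }
  }
  # episode onsets (stable gap 1) strictly before the query week, plus the
  # latest episode's hospitalization severity mark
  n_eps <- numeric(nrow(q))
  ep_hosp <- numeric(nrow(q))
  cw <- store$crisis[, .(n_events = .N),
                     by = .(patient_id, week = date_to_week(date))]
  hw <- store$hospitalization[, .(n_hosp = .N),
                              by = .(patient_id, week = date_to_week(date))]
  cw <- merge(cw, hw, by = c("patient_id", "week"), all.x = TRUE)
  cw[is.na(n_hosp), n_hosp := 0]
  setkey(cw, patient_id, week)
  for (p in unique(q$patient_id)) {
    pw <- cw[.(p), nomatch = NULL]
    rows <- q[patient_id == p, row]
    if (nrow(pw)) {
      onsets <- pw$week[c(TRUE, diff(pw$week) >= 2L)]
      n_eps[rows] <- findInterval(q$week[rows] - 1L, onsets)
      d <- last_episode_descriptors(pw$week, q$week[rows], 1L,
                                    pw$n_events, pw$n_hosp)
      ep_hosp[rows] <- ifelse(is.na(d$n_hosp), 0, d$n_hosp)
    }
  }

  b <- latent$baseline_logit[q$patient_id]
  ksig <- cfg$group_signal_scale[latent$group[q$patient_id]]
  surv <- rep(1, nrow(q))
  for (k in seq_len(horizon)) {
    hist_sum <- rep(0, nrow(q))
    for (s in names(cfg$effects)) {
      if (s %in% colnames(delta)) {
        hist_sum <- hist_sum + history_effect(delta[, s] + k, cfg$effects[[s]])
      }
    }
    lp <- b + ksig * (hist_sum + cfg$beta_n_episodes * log1p(n_eps) +
                        cfg$beta_last_ep_hosp * log1p(ep_hosp)) +
      cfg$seasonal_amp * sin(2 * pi * week_of_year(q$week + k) / 52)
    surv <- surv * (1 - plogis(lp))
  }
  out <- numeric(nrow(q))
  out[q$row] <- 1 - surv
  out
}
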