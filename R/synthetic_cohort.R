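#' Configuration for the synthetic EHR cohort generator
#'
#' The generator emulates the statistical structure the crisis-prediction
#' pipeline assumes in real mental-health EHR data: patient-level
#' heterogeneity (a Gaussian random intercept on the logit of weekly crisis
#' hazard plus diagnosis-group offsets), episodic clustering of crisis events
#' driven by history-dependent hazard terms, auxiliary event streams
#' (contacts, referrals, hospitalizations, assessments) whose rates increase
#' with the latent severity, week-of-year seasonality, and staggered patient
#' entry. Each history effect has the qualitative temporal shape reported for
#' the corresponding predictor: a short-lived unplanned-contact effect
#' (roughly gone by 2 weeks), sustained carer-contact (~10 weeks) and
#' missed-appointment (~16 weeks) effects, and sign-reversing crisis-recency
#' and referral effects crossing zero near 29 and 25 weeks, plus a
#' long-lasting positive-suicide-risk-assessment effect. The hazard is
#' relapse-dominant: a deep low baseline with a large crisis-recency effect,
#' so onset risk concentrates in the months after an episode — which is what
#' makes the planted signal recoverable from the engineered recency features.
#' The baseline intercept is calibrated on an intercept grid (isotonic smooth
#' of probe simulations) so the main onset label has the target prevalence
#' (default 4.0%) among eligible patient-weeks.
#'
#' @param n_patients number of patients (default 2000).
#' @param n_weeks study span in weeks (default 261, about five years).
#' @param start_date `Date`, Monday opening the study (default 2012-09-03).
#' @param seed integer master seed.
#' @param baseline_logit_mean starting value of the population intercept on
#'   the weekly hazard logit (replaced by the calibrated value when
#'   `calibrate = TRUE`).
#' @param baseline_logit_sd SD of the patient random intercept.
#' @param target_prevalence target onset-label prevalence among eligible,
#'   uncensored patient-weeks, in (0,1).
#' @param calibrate logical: bisect the intercept to hit `target_prevalence`.
#' @param effects named list of history-effect parameters; each element is
#'   `list(beta=, scale=)` with an optional `cross=` (weeks at which a
#'   sign-reversing effect crosses zero). See Details.
#' @param beta_n_episodes coefficient on log1p(#prior crisis episodes).
#' @param beta_age coefficient on standardized age `(age - 50)/20` in the
#'   baseline logit; together with the diagnosis-group offsets it makes most
#'   of the between-patient risk spread observable to the model.
#' @param beta_last_ep_hosp coefficient on log1p(hospitalizations in the
#'   latest crisis episode) — an exogenous severity mark: a severe last
#'   episode raises relapse hazard.
#' @param seasonal_amp amplitude of the sine seasonal term on the logit.
#' @param group_intercepts named numeric, additive logit offset per diagnostic
#'   group (drives the between-diagnosis prevalence spread).
#' @param group_signal_scale named numeric, multiplier on the history effects
#'   per diagnostic group (1 = full signal; 0 plants an uninformative group).
#' @param entry_frac patients enter uniformly over the first `entry_frac` of
#'   the span.
#' @return a `generator_config` list.
#' @details The weekly hazard for patient p at week t is
#'   `plogis(b_p + group_offset + k_g * (sum of history effects) + seasonal)`
#'   where each history effect is `beta * exp(-delta/scale)` (or
#'   `beta * (exp(-delta/scale) - exp(-cross/scale))` for sign-reversing ones)
#'   in the weeks `delta` since the last event of that type, and 0 if the event
#'   never occurred.
#' @export
generator_config <- function(n_patients = 2000L,
                             n_weeks = 261L,
                             start_date = as.Date("2012-09-03"),
                             seed = 20120903L,
                             baseline_logit_mean = -4.5,
                             baseline_logit_sd = 0.3,
                             target_prevalence = 0.04,
                             calibrate = TRUE,
                             effects = list(
                               unplanned   = list(beta = 0.5,  scale = 1),
                               missed      = list(beta = 0.4,  scale = 6),
                               carer       = list(beta = 0.3,  scale = 4),
                               crisis      = list(beta = 4.5,  scale = 12, cross = 29),
                               referral    = list(beta = 0.35, scale = 10, cross = 25),
                               suicide_pos = list(beta = 0.5,  scale = 30)
                             ),
                             beta_n_episodes = 0.3,
                             beta_age = 0.6,
                             beta_last_ep_hosp = 0.5,
                             seasonal_amp = 0.6,
                             group_intercepts = c(
                               "F0 Organic" = -0.8, "F1 Substance Misuse" = 0.1,
                               "F2 Schizophrenia and Psychotic" = 0,
                               "F3 Mood" = -0.1, "F4 Neurotic Stress and Anxiety" = -0.2,
                               "F6 Personality and Behavior" = 0.6,
                               "Other Diagnosis" = -0.3, "Not Diagnosed" = -0.4
                             ),
                             group_signal_scale = setNames(rep(1, 8), DIAGNOSIS_GROUPS),
                             entry_frac = 0.4) {
  stopifnot(n_patients >= 1, n_weeks >= 20,
            target_prevalence > 0, target_prevalence < 1,
            baseline_logit_sd >= 0, entry_frac >= 0, entry_frac < 1)
  for (e in effects) stopifnot(is.numeric(e$beta), e$scale > 0)
  cfg <- list(
    n_patients = as.integer(n_patients), n_weeks = as.integer(n_weeks),
    start_date = start_date, seed = as.integer(seed),
    baseline_logit_mean = baseline_logit_mean,
    baseline_logit_sd = baseline_logit_sd,
    target_prevalence = target_prevalence, calibrate = calibrate,
    effects = effects, beta_n_episodes = beta_n_episodes,
    beta_age = beta_age, beta_last_ep_hosp = beta_last_ep_hosp,
    seasonal_amp = seasonal_amp,
    group_intercepts = group_intercepts,
    group_signal_scale = group_signal_scale,
    entry_frac = entry_frac
  )
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d patients x %d weeks, seed %d, target prevalence %.1f%%\n",
              x$n_patients, x$n_weeks, x$seed, 100 * x$target_prevalence))
  invisible(x)
}

# effect of an event `delta` weeks ago; delta = Inf encodes "never occurred".
# Optional `offset` anchors the decay at delta = offset (so the effect equals
# beta exactly `offset` weeks after the event); optional `cross` makes the
# effect sign-reversing with a zero crossing at delta = cross.
history_effect <- function(delta, par) {
  off <- if (is.null(par$offset)) 0 else par$offset
  eff <- par$beta * if (is.null(par$cross)) {
    exp(-(delta - off) / par$scale)
  } else {
    exp(-(delta - off) / par$scale) - exp(-(par$cross - off) / par$scale)
  }
  eff[is.infinite(delta)] <- 0
  eff
}

# One pass of the weekly simulation. Returns per-(patient,week) count matrices,
# the hazard matrix, and per-patient metadata. All randomness flows through the
# R RNG; callers set the seed.
simulate_cohort_arrays <- function(cfg, mu) {
  P <- cfg$n_patients; T <- cfg$n_weeks
  grp <- sample(DIAGNOSIS_GROUPS, P, replace = TRUE,
                prob = c(0.05, 0.10, 0.15, 0.25, 0.15, 0.10, 0.08, 0.12))
  age_at_end <- pmin(16 + round(rbeta(P, 2, 3) * 86), 102)
  b <- rnorm(P, mu, cfg$baseline_logit_sd) + cfg$group_intercepts[grp] +
    cfg$beta_age * (age_at_end - 50) / 20
  ksig <- cfg$group_signal_scale[grp]
  entry <- if (cfg$entry_frac > 0) {
    sample.int(max(1L, floor(T * cfg$entry_frac)), P, replace = TRUE) - 1L
  } else rep(0L, P)

  week0 <- date_to_week(cfg$start_date)
  woy <- week_of_year(week0 + seq_len(T) - 1L)
  seas <- cfg$seasonal_amp * sin(2 * pi * woy / 52)

  cats <- c("crisis", "hosp", "planned", "unplanned", "missed", "phone",
            "in_person", "carer", "ref_gp", "ref_community", "ref_acute",
            "sui_pos", "sui_neg", "sub_pos", "sub_neg", "wellbeing")
  M <- lapply(cats, function(z) matrix(0L, P, T))
  names(M) <- M_names <- cats
  wb_val <- matrix(NA_real_, P, T)
  H <- matrix(0, P, T)

  inf <- rep(Inf, P)
  last <- list(crisis = inf, unplanned = inf, missed = inf, carer = inf,
               referral = inf, suicide_pos = inf)
  n_episodes <- rep(0L, P)
  ep_hosp <- rep(0L, P) # hospitalization count of the latest episode so far
  status_rows <- list()

  for (t in seq_len(T)) {
    active <- entry < t # patient has entered the system
    lp <- b +
      ksig * (history_effect(last$crisis, cfg$effects$crisis) +
              (if (is.null(cfg$effects$persist)) 0 else
                 history_effect(last$crisis, cfg$effects$persist)) +
              history_effect(last$unplanned, cfg$effects$unplanned) +
              history_effect(last$missed, cfg$effects$missed) +
              history_effect(last$carer, cfg$effects$carer) +
              history_effect(last$referral, cfg$effects$referral) +
              history_effect(last$suicide_pos, cfg$effects$suicide_pos) +
              cfg$beta_n_episodes * log1p(n_episodes) +
              cfg$beta_last_ep_hosp * log1p(ep_hosp)) +
      seas[t]
    h <- plogis(lp)
    h[!active] <- 0
    H[, t] <- h

    cr <- rbinom(P, 1L, h) == 1L
    # crisis weeks carry 1+Pois(1.2) crisis events, Pois(0.8) hospitalizations
    M$crisis[cr, t] <- 1L + rpois(sum(cr), 1.2)
    M$hosp[cr, t] <- rpois(sum(cr), 0.8)

    sev <- h # latent severity driving auxiliary event rates
    draw <- function(base, slope) {
      n <- rpois(P, base + slope * sev)
      n[!active] <- 0L
      n
    }
    M$planned[, t]   <- draw(0.25, 0.5)
    M$unplanned[, t] <- draw(0.06, 2.0)
    M$missed[, t]    <- draw(0.04, 1.0)
    M$phone[, t]     <- draw(0.15, 0.8)
    M$in_person[, t] <- draw(0.12, 0.6)
    M$carer[, t]     <- draw(0.03, 0.8)
    M$ref_gp[, t]        <- draw(0.015, 0.15)
    M$ref_community[, t] <- draw(0.015, 0.25)
    M$ref_acute[, t]     <- draw(0.005, 0.40)

    sui_assessed <- runif(P) < (0.03 + 0.4 * sev) & active
    sui_pos <- sui_assessed & runif(P) < pmin(0.15 + 2.5 * sev, 0.95)
    M$sui_pos[sui_pos, t] <- 1L
    M$sui_neg[sui_assessed & !sui_pos, t] <- 1L
    sub_assessed <- runif(P) < (0.02 + 0.2 * sev) & active
    sub_pos <- sub_assessed & runif(P) < pmin(0.25 + 1.5 * sev, 0.95)
    M$sub_pos[sub_pos, t] <- 1L
    M$sub_neg[sub_assessed & !sub_pos, t] <- 1L

    wb <- runif(P) < (0.05 + 0.2 * sev) & active
    M$wellbeing[wb, t] <- 1L
    wb_val[wb, t] <- pmin(pmax(round(rnorm(sum(wb), 7 - 6 * sev[wb], 1.5)), 0), 10)

    # occasional care-program spells (status records with start/end)
    sp <- runif(P) < (0.002 + 0.02 * sev) & active
    if (any(sp)) {
      status_rows[[length(status_rows) + 1L]] <- data.table(
        p = which(sp), start_t = t,
        dur = pmin(4L + rpois(sum(sp), 10), T - t + 1L),
        level = sample(1:3, sum(sp), replace = TRUE)
      )
    }

    # episode bookkeeping (stable gap of 1 week): a crisis with no crisis in
    # the immediately preceding week opens a new episode. The episode's
    # hospitalization count is an exogenous severity mark feeding the hazard.
    new_onset <- cr & last$crisis >= 2
    n_episodes[new_onset] <- n_episodes[new_onset] + 1L
    hosp_t <- integer(P); hosp_t[cr] <- M$hosp[cr, t]
    ep_hosp[new_onset] <- hosp_t[new_onset]
    continuing <- cr & !new_onset
    ep_hosp[continuing] <- ep_hosp[continuing] + hosp_t[continuing]

    # recency state updates happen after the draws: week-t events affect t+1+
    bump <- function(old, happened) ifelse(happened, 1, old + 1)
    last$crisis      <- bump(last$crisis, cr)
    last$unplanned   <- bump(last$unplanned, M$unplanned[, t] > 0L)
    last$missed      <- bump(last$missed, M$missed[, t] > 0L)
    last$carer       <- bump(last$carer, M$carer[, t] > 0L)
    last$referral    <- bump(last$referral,
                             (M$ref_gp[, t] + M$ref_community[, t] + M$ref_acute[, t]) > 0L)
    last$suicide_pos <- bump(last$suicide_pos, sui_pos)
  }

  list(M = M, wb_val = wb_val, H = H, grp = grp, entry = entry, b = b,
       age_at_end = age_at_end, status = rbindlist(status_rows), week0 = week0)
}

# Onset-label prevalence (main config s=1,w=4,g=0) straight from the crisis
# count matrix -- the generator's internal criterion for intercept calibration.
prevalence_from_arrays <- function(crisis_mat, entry, horizon = 4L, min_history = 13L) {
  P <- nrow(crisis_mat); T <- ncol(crisis_mat)
  C <- crisis_mat > 0L
  prevC <- cbind(FALSE, C[, -T, drop = FALSE])
  onset <- C & !prevC
  cum_on <- t(apply(onset, 1L, cumsum))
  # onsets in (t, t+horizon]
  future <- matrix(0L, P, T)
  for (t in seq_len(T - horizon)) {
    future[, t] <- cum_on[, t + horizon] - cum_on[, t]
  }
  label <- !C & future > 0L
  weekmat <- matrix(seq_len(T), P, T, byrow = TRUE)
  prior_onsets <- cbind(0L, cum_on[, -T, drop = FALSE])
  eligible <- prior_onsets >= 2L &
    (weekmat - 1L - matrix(entry, P, T)) >= min_history
  eligible[, (T - horizon + 1L):T] <- FALSE # right-censored
  n <- sum(eligible)
  c(prevalence = if (n) mean(label[eligible]) else NA_real_, n_eligible = n)
}

#' Generate a synthetic EHR cohort with known latent risk
#'
#' Runs the weekly hazard simulation described in [generator_config()],
#' calibrates the baseline intercept to the target onset prevalence, and
#' materializes the result as an [ehr_store()] (the same CSV-ready tables the
#' pipeline reads) plus the latent ground truth needed for validation. The
#' latent state is returned separately and is never written by
#' [write_tables()], so the modelling pipeline cannot read it by accident.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_cohort` with elements `store` (an
#'   `ehr_store`), `latent` (list: `hazard` patients x weeks matrix, `week0`
#'   absolute index of the first study week, `patient_id`, `entry_week`
#'   absolute entry weeks, `group` true diagnostic group), and
#'   `baseline_logit_mean` (the calibrated intercept).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(generator_config(n_patients = 200, n_weeks = 120))
#' cohort$store
#' }
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config

  mu <- cfg$baseline_logit_mean
  if (cfg$calibrate) {
    # Each probe simulates a fresh cohort, so the observed prevalence is a
    # noisy, locally non-monotone function of the intercept (tiny eligible
    # sets at low intercepts produce wild estimates). Prevalence also rises
    # with the intercept only while crises are sparse, falling again once
    # episodes merge and in-crisis (negative) weeks dominate. Calibrate on
    # the rising branch with an isotonic (PAVA) smooth of probe estimates
    # over an intercept grid, interpolating the target crossing; refine on a
    # finer grid averaged over two probe seeds.
    # At very low intercepts the few eligible patients are all dense relapse
    # chains, so their week-level prevalence can exceed the target even
    # though the cohort is nearly crisis-free; such degenerate regimes are
    # excluded by requiring a minimum eligible mass (1% of patient-weeks).
    n_floor <- 0.01 * cfg$n_patients * cfg$n_weeks
    prev_at <- function(m, probe = 0L) {
      set.seed((cfg$seed + 7777L * probe) %% 2147483647L)
      sim <- simulate_cohort_arrays(cfg, m)
      pr <- prevalence_from_arrays(sim$M$crisis, sim$entry)
      if (is.na(pr["prevalence"]) || pr["n_eligible"] < n_floor) 0
      else unname(pr["prevalence"])
    }
    cross_of <- function(grid, p_grid) {
      ph <- pava(p_grid, rep(1, length(p_grid)))
      i <- which(ph >= cfg$target_prevalence)[1L]
      if (is.na(i) || i == 1L) return(NULL)
      if (ph[i] <= ph[i - 1L]) return(grid[i])
      grid[i - 1L] + (cfg$target_prevalence - ph[i - 1L]) /
        (ph[i] - ph[i - 1L]) * (grid[i] - grid[i - 1L])
    }
    g1 <- seq(-9, -2, by = 0.5)
    mu1 <- cross_of(g1, vapply(g1, prev_at, 1))
    if (is.null(mu1)) {
      stop("prevalence calibration failed: target ", cfg$target_prevalence,
           " not reachable on the rising branch")
    }
    g2 <- seq(mu1 - 0.4, mu1 + 0.4, by = 0.1)
    p2 <- vapply(g2, function(m) (prev_at(m, 1L) + prev_at(m, 2L)) / 2, 1)
    mu2 <- cross_of(g2, p2)
    mu <- if (is.null(mu2)) mu1 else mu2
  }

  set.seed(cfg$seed %% 2147483647L)
  sim <- simulate_cohort_arrays(cfg, mu)
  P <- cfg$n_patients; T <- cfg$n_weeks; week0 <- sim$week0
  pid <- sprintf("P%05d", seq_len(P))

  # ---- static + diagnosis tables ----------------------------------------
  age_at_end <- sim$age_at_end
  end_year <- as.POSIXlt(week_start(week0 + T - 1L))$year + 1900L
  first_record_date <- week_start(week0 + sim$entry)
  static <- data.table(
    patient_id = pid,
    birth_year = end_year - age_at_end,
    gender = sample(c("male", "female"), P, replace = TRUE, prob = c(0.515, 0.485)),
    ethnicity = sample(c("White", "Asian", "Black", "Mixed", "Other"), P,
                       replace = TRUE, prob = c(0.66, 0.15, 0.09, 0.07, 0.03)),
    first_record_date = first_record_date
  )

  grp_digit <- c(
    "F0 Organic" = "0", "F1 Substance Misuse" = "1",
    "F2 Schizophrenia and Psychotic" = "2", "F3 Mood" = "3",
    "F4 Neurotic Stress and Anxiety" = "4", "F6 Personality and Behavior" = "6"
  )
  diagnosed <- sim$grp != "Not Diagnosed"
  dx_digit <- ifelse(sim$grp %in% names(grp_digit), grp_digit[sim$grp],
                     sample(c("5", "7", "8", "9"), P, replace = TRUE))
  dx_code <- paste0("F", dx_digit, sample(0:9, P, TRUE), sample(0:9, P, TRUE))
  dx_week <- sim$entry + pmin(sample.int(26L, P, replace = TRUE), T - 1L)
  diagnosis <- data.table(
    patient_id = pid[diagnosed],
    icd10_code = dx_code[diagnosed],
    date = week_start(week0 + pmin(dx_week[diagnosed], T - 1L))
  )

  # ---- long event tables from the count matrices ------------------------
  melt_counts <- function(mat, category, values = NULL) {
    idx <- which(mat > 0L, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    n <- mat[idx]
    dt <- data.table(
      patient_id = rep(pid[idx[, 1L]], n),
      date = rep(week_start(week0 + idx[, 2L] - 1L), n) +
        sample(0:6, sum(n), replace = TRUE),
      category = category,
      value = if (is.null(values)) NA_real_ else rep(values[idx], n),
      start = as.Date(NA), end = as.Date(NA)
    )
    dt
  }
  M <- sim$M
  crisis <- melt_counts(M$crisis, "crisis_event")
  hospitalization <- melt_counts(M$hosp, "admission")
  contact <- rbindlist(list(
    melt_counts(M$planned, "planned"), melt_counts(M$unplanned, "unplanned"),
    melt_counts(M$missed, "missed"), melt_counts(M$phone, "phone"),
    melt_counts(M$in_person, "in_person"), melt_counts(M$carer, "carer")
  ))
  referral <- rbindlist(list(
    melt_counts(M$ref_gp, "gp"), melt_counts(M$ref_community, "community"),
    melt_counts(M$ref_acute, "acute")
  ))
  if (nrow(sim$status)) {
    spells <- data.table(
      patient_id = pid[sim$status$p],
      date = week_start(week0 + sim$status$start_t - 1L),
      category = "care_program",
      value = as.numeric(sim$status$level),
      start = week_start(week0 + sim$status$start_t - 1L),
      end = week_start(week0 + sim$status$start_t - 1L + sim$status$dur - 1L) + 6L
    )
    referral <- rbind(referral, spells)
  }
  risk_assessment <- rbindlist(list(
    melt_counts(M$sui_pos, "suicide", values = matrix(1, P, T)),
    melt_counts(M$sui_neg, "suicide", values = matrix(0, P, T)),
    melt_counts(M$sub_pos, "substance", values = matrix(1, P, T)),
    melt_counts(M$sub_neg, "substance", values = matrix(0, P, T))
  ))
  wellbeing_assessment <- melt_counts(M$wellbeing, "wellbeing", values = sim$wb_val)

  store <- ehr_store(
    static = static, diagnosis = diagnosis,
    crisis = crisis, hospitalization = hospitalization, contact = contact,
    referral = referral, risk_assessment = risk_assessment,
    wellbeing_assessment = wellbeing_assessment
  )

  dimnames(sim$H) <- list(pid, week0 + seq_len(T) - 1L)
  out <- list(
    store = store,
    latent = list(hazard = sim$H, week0 = week0, patient_id = pid,
                  entry_week = week0 + sim$entry,
                  group = setNames(sim$grp, pid),
                  baseline_logit = setNames(sim$b, pid)),
    baseline_logit_mean = mu,
    config = cfg
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d weeks (calibrated intercept %.3f)\n",
              nrow(x$latent$hazard), ncol(x$latent$hazard), x$baseline_logit_mean))
  print(x$store)
  invisible(x)
}

#' Bayes-optimal 28-day crisis risk from the latent hazards
#'
#' The reference probability that at least one crisis week occurs among the
#' four weeks following `week`: `1 - prod(1 - h)` over weeks `week+1 ..
#' week+4`. This is the quantity an ideal model would predict; the trained
#' model's AUROC is benchmarked against it.
#'
#' @param latent the `latent` element of a [generate_cohort()] result.
#' @param patient_id character vector of patients.
#' @param week integer vector (absolute week indices) parallel to
#'   `patient_id`.
#' @param horizon number of future weeks (default 4).
#' @return numeric vector of probabilities.
#' @export
oracle_risk_28d <- function(latent, patient_id, week, horizon = 4L) {
  H <- latent$hazard
  wk_cols <- as.integer(colnames(H))
  t_idx <- match(week, wk_cols)
  p_idx <- match(patient_id, rownames(H))
  if (anyNA(p_idx)) stop("unknown patient id")
  if (anyNA(t_idx) || any(t_idx + horizon > ncol(H))) {
    stop("prediction horizon exceeds the simulated span")
  }
  out <- numeric(length(week))
  surv <- rep(1, length(week))
  for (k in seq_len(horizon)) {
    surv <- surv * (1 - H[cbind(p_idx, t_idx + k)])
  }
  1 - surv
}

#' Write the latent ground truth to CSV
#'
#' Kept deliberately separate from [write_tables()]: the latent hazards are
#' validation-only ground truth and must never enter the modelling pipeline.
#'
#' @param latent the `latent` element of a [generate_cohort()] result.
#' @param path output CSV (long format: patient_id, week, hazard).
#' @return invisibly, `path`.
#' @export
write_latent <- function(latent, path) {
  dt <- as.data.table(as.table(latent$hazard))
  setnames(dt, c("patient_id", "week", "hazard"))
  dt[, week := as.integer(as.character(week))]
  fwrite(dt, path)
  invisible(path)
}
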