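# ---------------------------------------------------------------------------
# Feature engineering: transforms the EHR store into the weekly patient-week
# feature matrix. The cardinal rule is leakage safety: features at week t are
# computed only from records dated strictly before the Monday of week t, so
# current-week events inform the *next* week's features.
# ---------------------------------------------------------------------------

# (table, category, value filter) triples defining the event streams the
# default registry aggregates. `category = NA` matches every row of the table.
default_event_categories <- function() {
  rbindlist(list(
    data.table(stream = "crisis", table = "crisis", category = NA_character_,
               value_equals = NA_real_, group_id = "crisis_history"),
    data.table(stream = "hosp", table = "hospitalization", category = NA_character_,
               value_equals = NA_real_, group_id = "crisis_history"),
    data.table(stream = paste0("contact_", c("planned", "unplanned", "missed",
                                          "phone", "in_person", "carer")),
               table = "contact",
               category = c("planned", "unplanned", "missed", "phone",
                            "in_person", "carer"),
               value_equals = NA_real_, group_id = "contacts"),
    data.table(stream = paste0("referral_", c("gp", "community", "acute")),
               table = "referral", category = c("gp", "community", "acute"),
               value_equals = NA_real_, group_id = "referrals"),
    data.table(stream = c("suicide_pos", "suicide_neg", "substance_pos", "substance_neg"),
               table = "risk_assessment",
               category = c("suicide", "suicide", "substance", "substance"),
               value_equals = c(1, 0, 1, 0), group_id = "assessments"),
    data.table(stream = "wellbeing", table = "wellbeing_assessment",
               category = NA_character_, value_equals = NA_real_,
               group_id = "assessments")
  ))
}

#' Default feature registry
#'
#' Enumerates every feature column the pipeline builds, one row per feature:
#' `name`, `procedure` (one of static, diagnosis, weekly_aggregation,
#' time_elapsed, last_episode_descriptor, status, seasonality), source
#' `table`/`category`, trailing `window` length where applicable, and
#' `group_id` — the unit at which the hyperparameter search switches feature
#' groups on and off. The default registry defines ~170 features: per event
#' stream a previous-week count, trailing-window counts, a cumulative total
#' and a weeks-since-last recency; carried-forward latest assessment values;
#' care-program status; last-episode descriptors; statics; diagnosis one-hots
#' and the seasonal sine/cosine pair. The registry is data, not code: sites
#' with a different EHR taxonomy supply their own.
#'
#' @param windows integer vector of trailing-window lengths (weeks) for the
#'   windowed count features.
#' @return a `data.table`, one row per feature.
#' @export
default_feature_registry <- function(windows = c(2L, 4L, 8L, 12L, 26L, 52L)) {
  ev <- default_event_categories()
  per_event <- ev[, {
    nm <- c(paste0(stream, "_count_1w"),
            paste0(stream, "_sum_", windows, "w"),
            paste0(stream, "_total"),
            paste0(stream, "_wkssince"))
    data.table(
      name = nm,
      procedure = c(rep("weekly_aggregation", 2L + length(windows)), "time_elapsed"),
      window = c(1L, windows, NA_integer_, NA_integer_),
      table = table, category = category, value_equals = value_equals,
      group_id = group_id
    )
  }, by = stream][, stream := NULL]

  other <- rbindlist(list(
    data.table(name = c("suicide_risk_latest", "substance_risk_latest",
                        "wellbeing_latest"),
               procedure = "status", window = NA_integer_,
               table = c("risk_assessment", "risk_assessment", "wellbeing_assessment"),
               category = c("suicide", "substance", NA),
               value_equals = NA_real_, group_id = "assessments"),
    data.table(name = "status_care_program", procedure = "status",
               window = NA_integer_, table = "referral",
               category = "care_program", value_equals = NA_real_,
               group_id = "status"),
    data.table(name = c("last_episode_length", "last_episode_n_events",
                        "last_episode_n_hosp", "n_prior_episodes"),
               procedure = "last_episode_descriptor", window = NA_integer_,
               table = "crisis", category = NA_character_,
               value_equals = NA_real_, group_id = "crisis_history"),
    data.table(name = c("age", "gender_male", paste0("ethnicity_",
                        c("White", "Asian", "Black", "Mixed")),
                        "weeks_since_first_record", "weeks_since_any_record"),
               procedure = "static", window = NA_integer_,
               table = "static", category = NA_character_,
               value_equals = NA_real_, group_id = "static"),
    data.table(name = paste0("dx_", gsub("[^A-Za-z0-9]+", "_", DIAGNOSIS_GROUPS)),
               procedure = "diagnosis", window = NA_integer_,
               table = "diagnosis", category = NA_character_,
               value_equals = NA_real_, group_id = "diagnosis"),
    data.table(name = c("season_sin", "season_cos"), procedure = "seasonality",
               window = NA_integer_, table = NA_character_,
               category = NA_character_, value_equals = NA_real_,
               group_id = "seasonality")
  ), fill = TRUE)
  out <- rbind(per_event, other, fill = TRUE)
  setcolorder(out, c("name", "procedure", "group_id", "table", "category",
                     "value_equals", "window"))
  out[]
}

#' Weekly event counts per patient and category
#'
#' Consolidates a timestamped event table onto the weekly grid: the number of
#' records per (patient, calendar week, category). Weeks without events simply
#' do not appear (a count of 0).
#'
#' @param store an `ehr_store`.
#' @param table name of an event table.
#' @return `data.table` with columns `patient_id`, `week`, `category`, `n`.
#' @export
weekly_counts <- function(store, table) {
  stopifnot(inherits(store, "ehr_store"), table %in% EVENT_TABLES)
  store[[table]][, .(n = .N),
                 by = .(patient_id, week = date_to_week(date), category)]
}

#' Weeks elapsed since the last occurrence of an event
#'
#' Under the strict-precedence leakage rule only events in weeks strictly
#' before the query week count, so an event in the immediately preceding week
#' yields 1 (never 0). `NA` marks "never happened to date".
#'
#' @param event_weeks integer vector of weeks in which the event occurred.
#' @param week integer vector of query weeks.
#' @return integer vector parallel to `week`; `NA` where no prior event.
#' @export
weeks_since_last <- function(event_weeks, week) {
  ew <- sort(unique(as.integer(event_weeks)))
  if (!length(ew)) return(rep(NA_integer_, length(week)))
  pos <- findInterval(week - 1L, ew)
  out <- ifelse(pos == 0L, NA_integer_, week - ew[pmax(pos, 1L)])
  as.integer(out)
}

#' Descriptors of the most recent crisis episode
#'
#' Returns the length/severity summary of the episode containing the
#' patient's latest crisis week strictly before `week`, computed causally:
#' only events before `week` contribute, so an episode that is still ongoing
#' is summarized as observed so far. The descriptors change exactly when a
#' new crisis week is observed and are carried forward otherwise; before the
#' first crisis all descriptors are `NA` and the episode count is 0.
#'
#' @param crisis_weeks integer vector of the patient's crisis weeks.
#' @param week integer vector of query weeks.
#' @param stable_gap episode-separating stable gap (weeks), as in
#'   [segment_episodes()].
#' @param n_events_by_week,n_hosp_by_week optional per-crisis-week counts
#'   (parallel to the sorted unique `crisis_weeks`).
#' @return `data.table` with one row per query week: `length_weeks`,
#'   `n_events`, `n_hosp` (NA before any crisis), `n_prior_episodes`.
#' @export
last_episode_descriptors <- function(crisis_weeks, week, stable_gap = 1L,
                                     n_events_by_week = NULL,
                                     n_hosp_by_week = NULL) {
  wk <- sort(unique(as.integer(crisis_weeks)))
  out <- data.table(length_weeks = rep(NA_real_, length(week)),
                    n_events = NA_real_, n_hosp = NA_real_,
                    n_prior_episodes = 0)
  if (!length(wk)) return(out)
  if (is.null(n_events_by_week)) n_events_by_week <- rep(1, length(wk))
  if (is.null(n_hosp_by_week))   n_hosp_by_week   <- rep(0, length(wk))
  ep <- cumsum(c(TRUE, diff(wk) - 1L >= stable_gap))
  # prefix (causal) descriptors at each crisis week
  onset <- wk[ep != c(0L, ep[-length(ep)])][ep] # onset week of own episode
  cum_in_ep <- function(x) {
    x <- as.numeric(x)
    unlist(lapply(split(x, ep), cumsum), use.names = FALSE)
  }
  len <- wk - onset + 1
  nev <- cum_in_ep(n_events_by_week)
  nho <- cum_in_ep(n_hosp_by_week)
  pos <- findInterval(week - 1L, wk)
  has <- pos >= 1L
  out$length_weeks[has] <- len[pos[has]]
  out$n_events[has] <- nev[pos[has]]
  out$n_hosp[has] <- nho[pos[has]]
  out$n_prior_episodes[has] <- ep[pos[has]]
  out
}

#' Value of a status record at a given week
#'
#' Status records carry a start/end date pair; the feature value for a week is
#' the record's value if the week overlaps `[start, end]`, else `NA`. When
#' several records overlap the same week the one with the latest start wins.
#'
#' @param status `data.frame` with columns `start`, `end` (Dates) and `value`.
#' @param week integer vector of query weeks.
#' @return numeric vector of values (`NA` where no record overlaps).
#' @export
status_at_week <- function(status, week) {
  status <- as.data.table(status)
  stopifnot(all(c("start", "end", "value") %in% names(status)))
  if (!nrow(status)) return(rep(NA_real_, length(week)))
  stopifnot(all(status$end >= status$start))
  sw <- date_to_week(status$start); ew <- date_to_week(status$end)
  vapply(week, function(t) {
    hit <- which(sw <= t & ew >= t)
    if (!length(hit)) return(NA_real_)
    status$value[hit[which.max(sw[hit])]]
  }, numeric(1))
}

#' Cyclical encoding of the week of the year
#'
#' `sin(2*pi*week/52)` and `cos(2*pi*week/52)`, so that week 52 wraps onto
#' week 0 and the model sees the seasonal cycle as continuous.
#'
#' @param week_of_year integer vector in 1..52.
#' @return 2-column matrix `sin`, `cos`.
#' @export
seasonal_encoding <- function(week_of_year) {
  if (any(week_of_year < 1 | week_of_year > 52)) {
    stop("week_of_year must be in 1..52")
  }
  ang <- 2 * pi * week_of_year / 52
  cbind(sin = sin(ang), cos = cos(ang))
}

# counts matrix [patient x week] for one event stream, weeks T0..T1
event_count_matrix <- function(store, tab, cat, val_eq, pid, T0, T1) {
  dt <- store[[tab]]
  if (!is.na(cat)) dt <- dt[category == cat]
  if (!is.na(val_eq)) dt <- dt[!is.na(value) & value == val_eq]
  W <- T1 - T0 + 1L
  Cm <- matrix(0L, length(pid), W)
  if (nrow(dt)) {
    agg <- dt[, .(n = .N), by = .(patient_id, week = date_to_week(date))]
    agg <- agg[week >= T0 & week <= T1]
    i <- match(agg$patient_id, pid)
    keep <- !is.na(i)
    Cm[cbind(i[keep], agg$week[keep] - T0 + 1L)] <- agg$n[keep]
  }
  Cm
}

# latest value matrix: for each (patient, week) the value of the last record
# in that week (NA if none)
event_value_matrix <- function(store, tab, cat, pid, T0, T1) {
  dt <- store[[tab]]
  if (!is.na(cat)) dt <- dt[category == cat]
  Vm <- matrix(NA_real_, length(pid), T1 - T0 + 1L)
  if (nrow(dt)) {
    agg <- dt[order(date), .(v = value[.N]),
              by = .(patient_id, week = date_to_week(date))]
    agg <- agg[week >= T0 & week <= T1]
    i <- match(agg$patient_id, pid)
    keep <- !is.na(i)
    Vm[cbind(i[keep], agg$week[keep] - T0 + 1L)] <- agg$v[keep]
  }
  Vm
}

# weeks-since-last matrix from a count matrix: entry (p, j) = weeks since the
# last week strictly before T0+j-1 with a positive count (NA if none)
recency_matrix <- function(Cm) {
  P <- nrow(Cm); W <- ncol(Cm)
  R <- matrix(NA_real_, P, W)
  last <- rep(-Inf, P)
  for (j in seq_len(W)) {
    R[, j] <- j - last
    hit <- Cm[, j] > 0L
    last[hit] <- j
  }
  R[is.infinite(R)] <- NA_real_
  R
}

# carry-forward of the latest observed value strictly before each week
carry_forward_matrix <- function(Vm) {
  P <- nrow(Vm); W <- ncol(Vm)
  out <- matrix(NA_real_, P, W)
  cur <- rep(NA_real_, P)
  for (j in seq_len(W)) {
    out[, j] <- cur
    obs <- !is.na(Vm[, j])
    cur[obs] <- Vm[obs, j]
  }
  out
}

#' Build the patient-week feature matrix
#'
#' One row per eligible patient-week, one column per registry feature, with
#' every value computed exclusively from records dated strictly before the
#' row's week. Missing markers (`NA`) mean the event type has never occurred
#' to date (or no value is on record); they are passed through to the model
#' untouched — no imputation. Age changes yearly; time-varying statics such as
#' marital status are deliberately absent from the schema.
#'
#' @param store an `ehr_store`.
#' @param label_tab the `labels` table from [build_label_table()].
#' @param registry a feature registry ([default_feature_registry()]).
#' @param diagnosis_cutoff_week absolute week index at which the diagnostic
#'   grouping is frozen (default: the 80% point of the labelled span, i.e.
#'   the last training week under the default split). Records after the
#'   cutoff never influence the grouping, preventing leakage across the
#'   temporal split.
#' @param stable_gap stable gap used for episode descriptors (match the label
#'   config).
#' @return list of class `feature_matrix`: `X` numeric matrix, `meta`
#'   `data.table` (`patient_id`, `week`, `label`, `censored`, `in_crisis`),
#'   `registry`, `diagnosis_cutoff_week`.
#' @export
build_matrix <- function(store, label_tab, registry = default_feature_registry(),
                         diagnosis_cutoff_week = NULL, stable_gap = 1L) {
  stopifnot(inherits(store, "ehr_store"))
  known_tabs <- c(names(EHR_SCHEMAS), NA_character_)
  bad <- setdiff(unique(registry$table), known_tabs)
  if (length(bad)) stop("registry references unknown table(s): ",
                        paste(bad, collapse = ", "))

  meta <- as.data.table(label_tab)[eligible == TRUE,
                                   .(patient_id, week, label, censored, in_crisis)]
  setorder(meta, patient_id, week)
  if (!nrow(meta)) stop("no eligible patient-weeks")
  T0 <- min(label_tab$week); T1 <- max(label_tab$week)
  if (is.null(diagnosis_cutoff_week)) {
    diagnosis_cutoff_week <- T0 + as.integer(floor((T1 - T0) * 0.8))
  }

  pid <- store$static$patient_id
  p_i <- match(meta$patient_id, pid)
  j_i <- meta$week - T0 + 1L # column index of the row's own week
  n <- nrow(meta)
  X <- matrix(NA_real_, n, nrow(registry),
              dimnames = list(NULL, registry$name))

  # --- event-stream features (counts, windows, totals, recencies) --------
  ev <- default_event_categories()
  ev <- ev[paste(table, category, value_equals) %in%
             registry[, paste(table, category, value_equals)]]
  any_count <- NULL # summed counts across streams, for weeks_since_any_record
  for (k in seq_len(nrow(ev))) {
    Cm <- event_count_matrix(store, ev$table[k], ev$category[k],
                             ev$value_equals[k], pid, T0, T1)
    any_count <- if (is.null(any_count)) Cm else any_count + Cm
    stream_name <- ev$stream[k]
    Spad <- cbind(0L, t(apply(Cm, 1L, cumsum))) # Spad[, j+1] = sum cols 1..j
    rows <- registry[table == ev$table[k] &
                       category %eqna% ev$category[k] &
                       value_equals %eqna% ev$value_equals[k]]
    for (r in which(rows$procedure == "weekly_aggregation")) {
      L <- rows$window[r]
      if (is.na(L)) { # cumulative total up to the previous week
        X[, rows$name[r]] <- Spad[cbind(p_i, j_i)]
      } else {
        lo <- pmax(j_i - L, 0L)
        X[, rows$name[r]] <- Spad[cbind(p_i, j_i)] - Spad[cbind(p_i, lo + 1L)]
      }
    }
    if (any(rows$procedure == "time_elapsed")) {
      R <- recency_matrix(Cm)
      X[, paste0(stream_name, "_wkssince")] <- R[cbind(p_i, j_i)]
    }
  }

  # --- carried-forward latest assessment values ---------------------------
  cf <- function(tab, cat) {
    carry_forward_matrix(event_value_matrix(store, tab, cat, pid, T0, T1))
  }
  if ("suicide_risk_latest" %in% registry$name) {
    X[, "suicide_risk_latest"] <- cf("risk_assessment", "suicide")[cbind(p_i, j_i)]
  }
  if ("substance_risk_latest" %in% registry$name) {
    X[, "substance_risk_latest"] <- cf("risk_assessment", "substance")[cbind(p_i, j_i)]
  }
  if ("wellbeing_latest" %in% registry$name) {
    X[, "wellbeing_latest"] <- cf("wellbeing_assessment", NA)[cbind(p_i, j_i)]
  }

  # --- status features (start/end records, evaluated at the last completed
  #     week; the record's start must precede the row's week) --------------
  if ("status_care_program" %in% registry$name) {
    sp <- store$referral[category == "care_program" & !is.na(start) & !is.na(end)]
    if (nrow(sp)) {
      sp <- sp[, .(patient_id, sw = date_to_week(start), ew = date_to_week(end), value)]
      q <- data.table(patient_id = meta$patient_id, qw = meta$week - 1L,
                      row = seq_len(n))
      hit <- sp[q, on = .(patient_id, sw <= qw, ew >= qw),
                .(row = i.row, sw = x.sw, value = x.value),
                nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hit)) {
        best <- hit[order(sw), .(value = value[.N]), by = row]
        X[best$row, "status_care_program"] <- best$value
      }
    }
  }

  # --- last-episode descriptors (causal, per patient) ---------------------
  desc_cols <- intersect(
    c("last_episode_length", "last_episode_n_events", "last_episode_n_hosp",
      "n_prior_episodes"), registry$name)
  if (length(desc_cols)) {
    cw <- store$crisis[, .(n_events = .N),
                       by = .(patient_id, week = date_to_week(date))]
    hw <- store$hospitalization[, .(n_hosp = .N),
                                by = .(patient_id, week = date_to_week(date))]
    cw <- merge(cw, hw, by = c("patient_id", "week"), all.x = TRUE)
    cw[is.na(n_hosp), n_hosp := 0]
    setkey(cw, patient_id, week)
    idx <- split(seq_len(n), meta$patient_id)
    for (p in names(idx)) {
      rows <- idx[[p]]
      pw <- cw[.(p), nomatch = NULL]
      d <- last_episode_descriptors(pw$week, meta$week[rows], stable_gap,
                                    pw$n_events, pw$n_hosp)
      if ("last_episode_length" %in% desc_cols)
        X[rows, "last_episode_length"] <- d$length_weeks
      if ("last_episode_n_events" %in% desc_cols)
        X[rows, "last_episode_n_events"] <- d$n_events
      if ("last_episode_n_hosp" %in% desc_cols)
        X[rows, "last_episode_n_hosp"] <- d$n_hosp
      if ("n_prior_episodes" %in% desc_cols)
        X[rows, "n_prior_episodes"] <- d$n_prior_episodes
    }
  }

  # --- statics ------------------------------------------------------------
  st <- store$static
  if ("age" %in% registry$name) {
    yr <- as.POSIXlt(week_start(meta$week))$year + 1900L
    X[, "age"] <- yr - st$birth_year[p_i]
  }
  if ("gender_male" %in% registry$name) {
    X[, "gender_male"] <- as.numeric(st$gender[p_i] == "male")
  }
  for (e in c("White", "Asian", "Black", "Mixed")) {
    colname <- paste0("ethnicity_", e)
    if (colname %in% registry$name) {
      X[, colname] <- as.numeric(st$ethnicity[p_i] == e)
    }
  }
  if ("weeks_since_first_record" %in% registry$name) {
    X[, "weeks_since_first_record"] <-
      meta$week - date_to_week(st$first_record_date)[p_i]
  }
  if ("weeks_since_any_record" %in% registry$name) {
    if (is.null(any_count)) any_count <- matrix(0L, length(pid), T1 - T0 + 1L)
    R <- recency_matrix(any_count)
    X[, "weeks_since_any_record"] <- R[cbind(p_i, j_i)]
  }

  # --- diagnosis one-hots at the frozen cutoff ----------------------------
  dxcols <- registry[procedure == "diagnosis", name]
  if (length(dxcols)) {
    dx <- latest_valid_diagnosis(store, pid,
                                 cutoff_date = week_start(diagnosis_cutoff_week + 1L) - 1L)
    onehot_names <- paste0("dx_", gsub("[^A-Za-z0-9]+", "_", DIAGNOSIS_GROUPS))
    for (g in seq_along(DIAGNOSIS_GROUPS)) {
      if (onehot_names[g] %in% dxcols) {
        X[, onehot_names[g]] <- as.numeric(dx[p_i] == DIAGNOSIS_GROUPS[g])
      }
    }
  }

  # --- seasonality --------------------------------------------------------
  if (any(registry$procedure == "seasonality")) {
    enc <- seasonal_encoding(week_of_year(meta$week))
    if ("season_sin" %in% registry$name) X[, "season_sin"] <- enc[, "sin"]
    if ("season_cos" %in% registry$name) X[, "season_cos"] <- enc[, "cos"]
  }

  out <- list(X = X, meta = meta, registry = registry,
              diagnosis_cutoff_week = diagnosis_cutoff_week)
  class(out) <- "feature_matrix"
  out
}

# NA-tolerant equality (both-NA counts as equal); used for registry matching
`%eqna%` <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patient-weeks x %d features (%.1f%% positive)\n",
              nrow(x$X), ncol(x$X), 100 * mean(x$meta$label[!x$meta$censored])))
  invisible(x)
}

#' Write a feature matrix to CSV
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(fm, path) {
  out <- cbind(
    data.table(patient_id = fm$meta$patient_id,
               week_start_date = week_start(fm$meta$week),
               label = fm$meta$label, censored = fm$meta$censored),
    as.data.table(fm$X)
  )
  fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}
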