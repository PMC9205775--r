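#' Label configuration for crisis-onset prediction
#'
#' The prediction target is parameterized by three quantities: the number of
#' stable (crisis-free) weeks `s` that must precede a crisis event for it to
#' count as a new episode onset, the length `w` of the prediction window in
#' weeks, and a gap `g` between the query week and the start of the window.
#' The main target is `(s = 1, w = 4, g = 0)`: onset of a crisis episode within
#' the next 28 days, with an episode requiring at least one full stable week.
#'
#' @param stable_weeks integer >= 1, stable weeks ending an episode.
#' @param window_weeks integer >= 1, prediction window length.
#' @param gap_weeks integer >= 0, weeks between query and window start.
#' @return a `label_config` list.
#' @export
label_config <- function(stable_weeks = 1L, window_weeks = 4L, gap_weeks = 0L) {
  s <- as.integer(stable_weeks); w <- as.integer(window_weeks); g <- as.integer(gap_weeks)
  stopifnot(length(s) == 1L, length(w) == 1L, length(g) == 1L,
            s >= 1L, w >= 1L, g >= 0L)
  structure(list(stable_weeks = s, window_weeks = w, gap_weeks = g),
            class = "label_config")
}

#' @export
print.label_config <- function(x, ...) {
  cat(sprintf("<label_config> stable=%d window=%d gap=%d\n",
              x$stable_weeks, x$window_weeks, x$gap_weeks))
  invisible(x)
}

#' Enumerate the label-definition sensitivity grid
#'
#' The full grid of label definitions used to probe sensitivity to the target
#' definition: stable weeks 1-4, window length 1-4 weeks, gap 0-2 weeks —
#' 48 configurations in total, i.e. the main label plus 47 variants. The main
#' configuration `(1, 4, 0)` is listed first.
#'
#' @return list of [label_config()] objects, length 48.
#' @export
enumerate_label_variants <- function() {
  grid <- CJ(s = 1:4, w = 1:4, g = 0:2)
  main <- grid$s == 1L & grid$w == 4L & grid$g == 0L
  grid <- rbind(grid[main], grid[!main])
  lapply(seq_len(nrow(grid)), function(i) {
    label_config(grid$s[i], grid$w[i], grid$g[i])
  })
}

#' Segment crisis weeks into crisis episodes
#'
#' Crisis events cluster in time; a run of crisis weeks is treated as a single
#' episode, and a new episode starts at any crisis week preceded by at least
#' `stable_gap` crisis-free weeks. The episode onset (its first crisis week) is
#' the prediction target. Severity descriptors (event and hospitalization
#' counts) are accumulated per episode when per-week counts are supplied.
#'
#' @param crisis_weeks integer vector of week indices with >= 1 crisis event
#'   (duplicates and unsorted input are tolerated).
#' @param stable_gap integer >= 1: crisis-free weeks required before a crisis
#'   week to open a new episode.
#' @param n_events_by_week,n_hosp_by_week optional numeric vectors parallel to
#'   the *sorted unique* `crisis_weeks`, giving per-week crisis-event and
#'   hospitalization-event counts; default one event, zero hospitalizations.
#' @return `data.table` with one row per episode: `onset_week`,
#'   `last_event_week`, `length_weeks` (inclusive span), `n_weeks` (crisis
#'   weeks), `n_events`, `n_hosp`.
#' @examples
#' segment_episodes(c(5, 6, 9), stable_gap = 1) # episodes 5-6 and 9
#' segment_episodes(c(5, 6, 9), stable_gap = 3) # one episode 5-9
#' @export
segment_episodes <- function(crisis_weeks, stable_gap = 1L,
                             n_events_by_week = NULL, n_hosp_by_week = NULL) {
  stopifnot(stable_gap >= 1L)
  wk <- sort(unique(as.integer(crisis_weeks)))
  if (!length(wk)) {
    return(data.table(onset_week = integer(), last_event_week = integer(),
                      length_weeks = integer(), n_weeks = integer(),
                      n_events = numeric(), n_hosp = numeric()))
  }
  if (is.null(n_events_by_week)) n_events_by_week <- rep(1, length(wk))
  if (is.null(n_hosp_by_week))   n_hosp_by_week   <- rep(0, length(wk))
  stopifnot(length(n_events_by_week) == length(wk),
            length(n_hosp_by_week) == length(wk))
  # crisis-free weeks between consecutive crisis weeks = diff - 1
  new_ep <- c(TRUE, diff(wk) - 1L >= stable_gap)
  ep_id <- cumsum(new_ep)
  dt <- data.table(week = wk, ep = ep_id,
                   ev = as.numeric(n_events_by_week),
                   ho = as.numeric(n_hosp_by_week))
  dt[, .(
    onset_week = week[1L], last_event_week = week[.N],
    length_weeks = week[.N] - week[1L] + 1L, n_weeks = .N,
    n_events = sum(ev), n_hosp = sum(ho)
  ), by = ep][, ep := NULL][]
}

#' Build the weekly onset-label series for one patient
#'
#' Week `t` receives a positive label iff the patient has no crisis event in
#' week `t` itself and some episode onset falls in the window
#' `(t + g, t + g + w]`; otherwise the label is negative. Weeks whose window
#' extends past the end of the observation span are flagged right-censored
#' (their negative labels are unverifiable) and are excluded from training and
#' evaluation downstream. Weeks with a crisis in progress are labeled negative,
#' per the target definition, but flagged `in_crisis` so callers can exclude
#' them from evaluation if desired.
#'
#' @param crisis_weeks integer vector of the patient's crisis weeks.
#' @param onsets integer vector of episode onset weeks (from
#'   [segment_episodes()] run with the matching `stable_weeks`).
#' @param span integer vector `c(first_week, last_week)` of the observation
#'   span (inclusive).
#' @param config a [label_config()].
#' @return `data.table` with columns `week`, `label` (0/1), `in_crisis`,
#'   `censored` (logical), one row per week of the span.
#' @export
build_labels <- function(crisis_weeks, onsets, span, config = label_config()) {
  stopifnot(length(span) == 2L, span[1] <= span[2])
  weeks <- span[1]:span[2]
  g <- config$gap_weeks; w <- config$window_weeks
  onsets <- sort(unique(as.integer(onsets)))
  crisis_weeks <- unique(as.integer(crisis_weeks))
  # onsets in (t+g, t+g+w]  <=>  count(onsets <= t+g+w) - count(onsets <= t+g) > 0
  n_onsets_in_window <- findInterval(weeks + g + w, onsets) - findInterval(weeks + g, onsets)
  in_crisis <- weeks %in% crisis_weeks
  data.table(
    week = weeks,
    label = as.integer(n_onsets_in_window > 0L & !in_crisis),
    in_crisis = in_crisis,
    censored = weeks + g + w > span[2]
  )
}

#' Patient-week eligibility for querying the model
#'
#' The model is only queried for patients with a history of relapse: a
#' patient-week is eligible iff at least two episode onsets occurred strictly
#' before that week, and the patient's first record dates back at least
#' 13 weeks (3 months) before it. Patients with fewer than two episodes over
#' the whole span, or with 13 or fewer weeks of records in total, are excluded
#' outright.
#'
#' @param onsets integer vector of the patient's episode onset weeks.
#' @param first_record_week integer week of the patient's first record.
#' @param weeks integer vector of query weeks.
#' @return logical vector parallel to `weeks`.
#' @export
eligibility_mask <- function(onsets, first_record_week, weeks) {
  onsets <- sort(unique(as.integer(onsets)))
  if (length(onsets) < 2L) return(rep(FALSE, length(weeks)))
  findInterval(weeks - 1L, onsets) >= 2L & weeks - first_record_week >= 13L
}

#' Build the full label table for a cohort
#'
#' Runs [segment_episodes()], [build_labels()] and [eligibility_mask()] for
#' every patient in the store, over the span from each patient's first record
#' to the study's final week.
#'
#' @param store an `ehr_store`.
#' @param config a [label_config()].
#' @param study_end_week integer; default = the last week with any record.
#' @return list with elements `labels` (`data.table`: `patient_id`, `week`,
#'   `label`, `eligible`, `in_crisis`, `censored`) and `episodes`
#'   (`data.table` of per-patient episodes with a `patient_id` column).
#' @export
build_label_table <- function(store, config = label_config(),
                              study_end_week = NULL) {
  stopifnot(inherits(store, "ehr_store"), inherits(config, "label_config"))
  if (is.null(study_end_week)) {
    study_end_week <- max(
      date_to_week(store$crisis$date),
      date_to_week(store$contact$date),
      date_to_week(store$static$first_record_date)
    )
  }
  crisis <- copy(store$crisis)[, week := date_to_week(date)]
  hosp_by_pw <- store$hospitalization[, .(n_hosp = .N),
                                      by = .(patient_id, week = date_to_week(date))]
  cw <- crisis[, .(n_events = .N), by = .(patient_id, week)]
  cw <- merge(cw, hosp_by_pw, by = c("patient_id", "week"), all.x = TRUE)
  cw[is.na(n_hosp), n_hosp := 0]
  setkey(cw, patient_id, week)

  statics <- store$static[, .(patient_id,
                              first_week = date_to_week(first_record_date))]

  episodes_list <- vector("list", nrow(statics))
  labels_list <- vector("list", nrow(statics))
  for (i in seq_len(nrow(statics))) {
    pid <- statics$patient_id[i]
    fw <- statics$first_week[i]
    pw <- cw[.(pid), nomatch = NULL]
    eps <- segment_episodes(pw$week, config$stable_weeks, pw$n_events, pw$n_hosp)
    lab <- build_labels(pw$week, eps$onset_week, c(fw, study_end_week), config)
    lab[, `:=`(patient_id = pid,
               eligible = eligibility_mask(eps$onset_week, fw, week))]
    if (nrow(eps)) eps[, patient_id := pid]
    episodes_list[[i]] <- eps
    labels_list[[i]] <- lab
  }
  labels <- rbindlist(labels_list)
  setcolorder(labels, c("patient_id", "week", "label", "eligible", "in_crisis", "censored"))
  list(labels = labels, episodes = rbindlist(episodes_list, fill = TRUE))
}

#' Write a label table to CSV
#'
#' Emits `patient_id`, `week_start_date`, `label`, `eligible`, `censored`.
#' @param labels the `labels` table from [build_label_table()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  out <- data.table(
    patient_id = labels$patient_id,
    week_start_date = week_start(labels$week),
    label = labels$label, eligible = labels$eligible, censored = labels$censored
  )
  fwrite(out, path, dateTimeAs = "ISO")
  invisible(path)
}
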