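test_that("weekly counts aggregate per patient, week and category", {
  store <- toy_store()
  w0 <- toy_week0()
  wc <- weekly_counts(store, "contact")
  expect_equal(wc[patient_id == "A" & week == w0 + 3 & category == "unplanned", n], 2L)
  expect_equal(nrow(wc[patient_id == "A" & category == "missed"]), 0L)
  # conservation: weekly counts sum back to the raw table size
  expect_equal(sum(wc$n), nrow(store$contact))
  expect_equal(sum(weekly_counts(store, "crisis")$n), nrow(store$crisis))
})

test_that("weeks_since_last follows the strict-precedence rule", {
  expect_equal(weeks_since_last(3, 5), 2L)
  expect_equal(weeks_since_last(3, 4), 1L) # never 0
  expect_equal(weeks_since_last(3, 3), NA_integer_) # same week excluded
  expect_equal(weeks_since_last(integer(0), 10), NA_integer_)
  # property: +1 per week except a reset to 1 right after an event
  events <- c(4, 9, 10, 17)
  r <- weeks_since_last(events, 1:25)
  for (t in 2:25) {
    if ((t - 1) %in% events) {
      expect_equal(r[t], 1L)
    } else if (!is.na(r[t - 1])) {
      expect_equal(r[t], r[t - 1] + 1L)
    }
  }
})

test_that("last-episode descriptors carry forward and update causally", {
  # episode weeks 5-6 with 3 events total, then a new onset at 12
  d <- last_episode_descriptors(c(5, 6, 12), 1:20, stable_gap = 1,
                                n_events_by_week = c(2, 1, 1),
                                n_hosp_by_week = c(1, 0, 0))
  expect_true(all(is.na(d$length_weeks[1:5]))) # before any crisis
  expect_equal(d$n_prior_episodes[1:5], rep(0, 5))
  expect_equal(d$length_weeks[6], 1) # week 6 sees only the week-5 prefix
  expect_equal(d$n_events[6], 2)
  expect_equal(d$length_weeks[7:12], rep(2, 6)) # full episode 5-6 visible
  expect_equal(d$n_events[7:12], rep(3, 6))
  expect_equal(d$n_hosp[8], 1)
  # from week 13 the new single-week episode takes over
  expect_equal(d$length_weeks[13:20], rep(1, 8))
  expect_equal(d$n_events[13:20], rep(1, 8))
  expect_equal(d$n_prior_episodes[13:20], rep(2, 8))
  # descriptors change exactly at crisis-week boundaries, nowhere else
  chg <- which(diff(d$n_events) != 0 | diff(is.na(d$n_events)) != 0)
  expect_equal(chg, c(5, 6, 12)) # observable from the following week
})

test_that("status lookup respects the start-end range and later-start wins", {
  st <- data.frame(
    start = week_start(c(104, 110)), end = week_start(c(112, 115)) + 6,
    value = c(1, 2)
  )
  expect_equal(status_at_week(st, 106), 1)
  expect_equal(status_at_week(st, 111), 2) # overlap: later start wins
  expect_equal(status_at_week(st, 120), NA_real_)
  expect_equal(status_at_week(st[0, ], 106), NA_real_)
})

test_that("seasonal encoding is the unit-circle pair", {
  expect_equal(seasonal_encoding(13)[1, ], c(sin = 1, cos = 0), tolerance = 1e-12)
  expect_equal(seasonal_encoding(52)[1, ], c(sin = 0, cos = 1), tolerance = 1e-12)
  enc <- seasonal_encoding(1:52)
  expect_equal(rowSums(enc^2), rep(1, 52))
  expect_error(seasonal_encoding(0), "1..52")
  expect_error(seasonal_encoding(53), "1..52")
})

test_that("the feature matrix matches hand-computed values on the toy store", {
  store <- toy_store()
  w0 <- toy_week0()
  lt <- build_label_table(store, label_config())
  fm <- build_matrix(store, lt$labels)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm$X), sum(lt$labels$eligible))

  a13 <- fm$X[fm$meta$patient_id == "A" & fm$meta$week == w0 + 13, ]
  expect_equal(unname(a13["crisis_count_1w"]), 0)
  expect_equal(unname(a13["crisis_sum_12w"]), 4) # weeks 5 (x2), 6, 9
  expect_equal(unname(a13["crisis_total"]), 4)
  expect_equal(unname(a13["crisis_wkssince"]), 4)
  expect_equal(unname(a13["hosp_total"]), 2)
  expect_equal(unname(a13["contact_unplanned_wkssince"]), 10)
  expect_equal(unname(a13["contact_unplanned_sum_4w"]), 0)
  expect_equal(unname(a13["contact_missed_wkssince"]), NA_real_)
  expect_equal(unname(a13["last_episode_length"]), 1) # episode [9]
  expect_equal(unname(a13["last_episode_n_hosp"]), 1)
  expect_equal(unname(a13["n_prior_episodes"]), 2)
  expect_equal(unname(a13["suicide_risk_latest"]), 1)
  expect_equal(unname(a13["wellbeing_latest"]), 3) # week 8 overwrote week 4
  expect_equal(unname(a13["age"]), 35)
  expect_equal(unname(a13["gender_male"]), 0)
  expect_equal(unname(a13["ethnicity_White"]), 1)
  expect_equal(unname(a13["weeks_since_first_record"]), 13)
  expect_equal(unname(a13["weeks_since_any_record"]), 4)
  expect_equal(unname(a13["dx_F3_Mood"]), 1) # F331 at week 20 < default cutoff
  expect_equal(unname(a13["season_sin"]), sin(2 * pi * 14 / 52))

  b31 <- fm$X[fm$meta$patient_id == "B" & fm$meta$week == w0 + 31, ]
  expect_equal(unname(b31["status_care_program"]), 2) # spell covers week 30
  expect_equal(unname(b31["crisis_wkssince"]), 1)
  expect_equal(unname(b31["dx_F4_Neurotic_Stress_and_Anxiety"]), 1)
})

test_that("shifting every record by one week shifts the matrix rows equally", {
  store <- toy_store()
  shift <- function(df) {
    for (col in intersect(c("date", "start", "end", "first_record_date"), names(df))) {
      df[[col]] <- df[[col]] + 7L
    }
    df
  }
  store2 <- do.call(ehr_store, c(
    list(static = shift(store$static), diagnosis = shift(store$diagnosis)),
    lapply(store[setdiff(names(store), c("static", "diagnosis"))], shift)
  ))
  fm1 <- build_matrix(store, build_label_table(store, label_config())$labels)
  fm2 <- build_matrix(store2, build_label_table(store2, label_config())$labels)
  expect_equal(fm2$meta$week, fm1$meta$week + 1L)
  keep <- setdiff(colnames(fm1$X), c("season_sin", "season_cos"))
  expect_equal(fm2$X[, keep], fm1$X[, keep])
})

test_that("future-dated records cannot alter earlier feature rows", {
  store <- toy_store()
  w0 <- toy_week0()
  lt <- build_label_table(store, label_config(), study_end_week = w0 + 40)
  fm0 <- build_matrix(store, lt$labels)
  inject_week <- w0 + 33
  injected <- copy_store <- store
  add_row <- function(tab, extra) rbind(copy_store[[tab]], extra, fill = TRUE)
  d <- week_start(inject_week) + 1
  injected$crisis <- add_row("crisis", data.table::data.table(
    patient_id = "A", date = d, category = NA, value = NA,
    start = as.Date(NA), end = as.Date(NA)))
  injected$contact <- add_row("contact", data.table::data.table(
    patient_id = "B", date = d, category = "unplanned", value = NA,
    start = as.Date(NA), end = as.Date(NA)))
  fm1 <- build_matrix(injected, lt$labels)
  early <- fm0$meta$week <= inject_week # features at t use records < t only
  expect_identical(fm0$X[early, ], fm1$X[early, ])
})

test_that("the registry rejects unknown tables and drives the column set", {
  store <- toy_store()
  lt <- build_label_table(store, label_config())
  reg <- default_feature_registry()
  bad <- data.table::copy(reg)[1, table := "not_a_table"]
  expect_error(build_matrix(store, lt$labels, registry = bad), "unknown table")
  slim <- reg[procedure %in% c("seasonality", "static")]
  fm <- build_matrix(store, lt$labels, registry = slim)
  expect_equal(colnames(fm$X), slim$name)
})
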