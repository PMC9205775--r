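# Shared fixtures. Heavyweight objects are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# hand-sized EHR store: two patients, explicit event dates
toy_store <- function() {
  monday <- function(w) week_start(w) # absolute week index -> Date
  w0 <- date_to_week(as.Date("2015-01-05"))
  ev <- function(pid, wk, category = NA_character_, value = NA_real_,
                 start = as.Date(NA), end = as.Date(NA)) {
    data.frame(patient_id = pid, date = monday(w0 + wk) + 2L,
               category = category, value = value, start = start, end = end)
  }
  ehr_store(
    static = data.frame(
      patient_id = c("A", "B"),
      birth_year = c(1980L, 1950L),
      gender = c("female", "male"),
      ethnicity = c("White", "Asian"),
      first_record_date = monday(w0)
    ),
    diagnosis = data.frame(
      patient_id = c("A", "A", "B"),
      icd10_code = c("F200", "F331", "F411"),
      date = c(monday(w0 + 1), monday(w0 + 20), monday(w0 + 2))
    ),
    crisis = rbind(ev("A", 5), ev("A", 5), ev("A", 6), ev("A", 9),
                   ev("B", 12), ev("B", 30)),
    hospitalization = rbind(ev("A", 5), ev("A", 9)),
    contact = rbind(ev("A", 3, "unplanned"), ev("A", 3, "unplanned"),
                    ev("A", 7, "planned"), ev("B", 10, "missed"),
                    ev("B", 11, "carer"), ev("A", 35, "phone")),
    referral = rbind(
      ev("A", 4, "gp"),
      ev("B", 8, "care_program", value = 2,
         start = monday(w0 + 8), end = monday(w0 + 35) + 6L)
    ),
    risk_assessment = rbind(ev("A", 2, "suicide", value = 1),
                            ev("B", 6, "suicide", value = 0)),
    wellbeing_assessment = rbind(ev("A", 4, "wellbeing", value = 6),
                                 ev("A", 8, "wellbeing", value = 3))
  )
}

toy_week0 <- function() date_to_week(as.Date("2015-01-05"))

# small synthetic cohort for module-level model tests (fixed intercept, no
# calibration loop, to keep it fast)
tiny_gen_config <- function(seed = 7L, n_patients = 500L, n_weeks = 150L) {
  generator_config(seed = seed, n_patients = n_patients, n_weeks = n_weeks,
                   calibrate = FALSE, baseline_logit_mean = -7)
}

tiny_pipeline <- function() {
  if (is.null(.fixtures$tp)) {
    cohort <- generate_cohort(tiny_gen_config())
    lt <- build_label_table(cohort$store, label_config())
    plan <- proportional_split_plan(lt$labels$week)
    fm <- build_matrix(cohort$store, lt$labels,
                       diagnosis_cutoff_week = plan$train[2])
    split <- make_split(fm, plan)
    .fixtures$tp <- list(cohort = cohort, labels = lt, fm = fm,
                         plan = plan, split = split)
  }
  .fixtures$tp
}

tiny_model <- function() {
  if (is.null(.fixtures$tm)) {
    tp <- tiny_pipeline()
    .fixtures$tm <- train_general(tp$fm, tp$split, budget = 3L, seed = 7L,
                                  nrounds_max = 150L, early_stopping = 20L)
  }
  .fixtures$tm
}

# same protocol without feature-group flags: every registry column stays in,
# so attribution-shape checks can see each planted channel
tiny_model_all_features <- function() {
  if (is.null(.fixtures$tma)) {
    tp <- tiny_pipeline()
    .fixtures$tma <- train_general(tp$fm, tp$split,
                                   space = default_xgb_space(character(0)),
                                   budget = 2L, seed = 7L,
                                   nrounds_max = 150L, early_stopping = 20L)
  }
  .fixtures$tma
}
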