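#' @import data.table
#' @importFrom stats plogis qlogis rbinom rnorm rpois runif setNames quantile
#'   median sd qt pnorm predict coef as.formula binomial glm isoreg
#' @importFrom utils head tail write.csv
NULL

# Event tables recognised by the store. `static` and `diagnosis` have their own
# schemas; the remaining six share the generic event schema.
EVENT_TABLES <- c(
  "crisis", "hospitalization", "contact", "referral",
  "risk_assessment", "wellbeing_assessment"
)

EHR_SCHEMAS <- c(
  list(
    static    = c("patient_id", "birth_year", "gender", "ethnicity", "first_record_date"),
    diagnosis = c("patient_id", "icd10_code", "date")
  ),
  setNames(
    rep(list(c("patient_id", "date", "category", "value", "start", "end")),
        length(EVENT_TABLES)),
    EVENT_TABLES
  )
)

#' The eight first-level ICD-10 chapter-F diagnostic groups
#'
#' Level order is fixed so one-hot encodings and subgroup tables are stable.
#' @export
DIAGNOSIS_GROUPS <- c(
  "F0 Organic", "F1 Substance Misuse", "F2 Schizophrenia and Psychotic",
  "F3 Mood", "F4 Neurotic Stress and Anxiety", "F6 Personality and Behavior",
  "Other Diagnosis", "Not Diagnosed"
)

#' Construct an EHR store
#'
#' An `ehr_store` is the pipeline's typed in-memory representation of the
#' relational EHR extract: one `data.table` per source table (patient statics,
#' ICD-10 diagnoses, and six timestamped event tables). Dates are held at day
#' precision; intra-day time is discarded because all downstream computation is
#' weekly.
#'
#' @param static data.frame with columns `patient_id`, `birth_year`, `gender`,
#'   `ethnicity`, `first_record_date`.
#' @param diagnosis data.frame with columns `patient_id`, `icd10_code` (chapter
#'   F, pattern `F[0-9]{2}[0-9]?`), `date`.
#' @param ... one data.frame per event table, named among
#'   `r paste(EVENT_TABLES, collapse = ", ")`, each with columns `patient_id`,
#'   `date`, `category`, `value`, `start`, `end` (missing columns are added as
#'   `NA`).
#' @return an object of class `ehr_store`: a named list of `data.table`s.
#' @export
ehr_store <- function(static, diagnosis = NULL, ...) {
  tabs <- list(...)
  unknown <- setdiff(names(tabs), EVENT_TABLES)
  if (length(unknown)) {
    stop("unknown EHR table(s): ", paste(unknown, collapse = ", "))
  }
  store <- list(static = as.data.table(static))
  store$diagnosis <- if (is.null(diagnosis)) {
    data.table(patient_id = character(), icd10_code = character(),
               date = as.Date(character()))
  } else as.data.table(diagnosis)
  for (tb in EVENT_TABLES) {
    store[[tb]] <- if (is.null(tabs[[tb]])) empty_event_table() else {
      normalize_event_table(as.data.table(tabs[[tb]]), tb)
    }
  }
  class(store) <- "ehr_store"
  validate_ehr_store(store)
  store
}

empty_event_table <- function() {
  data.table(
    patient_id = character(), date = as.Date(character()),
    category = character(), value = NA_real_,
    start = as.Date(character()), end = as.Date(character())
  )
}

normalize_event_table <- function(dt, name) {
  for (col in c("category")) if (is.null(dt[[col]])) dt[, (col) := NA_character_]
  if (is.null(dt$value)) dt[, value := NA_real_]
  for (col in c("start", "end")) {
    if (is.null(dt[[col]])) dt[, (col) := as.Date(NA)]
  }
  setcolorder(dt, EHR_SCHEMAS[[name]])
  dt
}

validate_ehr_store <- function(store) {
  stopifnot(is.data.frame(store$static))
  miss <- setdiff(EHR_SCHEMAS$static, names(store$static))
  if (length(miss)) stop("static table lacks column(s): ", paste(miss, collapse = ", "))
  for (tb in EVENT_TABLES) {
    dt <- store[[tb]]
    miss <- setdiff(EHR_SCHEMAS[[tb]], names(dt))
    if (length(miss)) stop(tb, " table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(dt)) {
      if (anyNA(dt$date)) {
        stop(tb, ": timestamp missing on row(s) ",
             paste(head(which(is.na(dt$date)), 5L), collapse = ", "))
      }
      bad <- which(!is.na(dt$start) & !is.na(dt$end) & dt$end < dt$start)
      if (length(bad)) {
        stop(tb, ": end precedes start on row(s) ",
             paste(head(bad, 5L), collapse = ", "))
      }
    }
  }
  if (nrow(store$diagnosis)) {
    bad <- !grepl("^F[0-9]{2}[0-9]?$", store$diagnosis$icd10_code)
    if (any(bad)) {
      stop("diagnosis: invalid ICD-10 chapter-F code(s): ",
           paste(head(unique(store$diagnosis$icd10_code[bad]), 5L), collapse = ", "))
    }
  }
  invisible(store)
}

#' @export
print.ehr_store <- function(x, ...) {
  cat("<ehr_store> ", nrow(x$static), " patients\n", sep = "")
  for (tb in c("diagnosis", EVENT_TABLES)) {
    cat(sprintf("  %-22s %d records\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Read EHR tables from CSV files
#'
#' One UTF-8 CSV per table, header row mandatory, ISO-8601 dates. Malformed
#' dates are reported with their line numbers; an unknown table name is an
#' error.
#'
#' @param paths named character vector or list mapping table names (`static`,
#'   `diagnosis`, and any of the event tables) to file paths.
#' @param quiet suppress the per-table record-count message.
#' @return an `ehr_store`.
#' @seealso [write_tables()]
#' @export
read_tables <- function(paths, quiet = TRUE) {
  paths <- unlist(paths)
  unknown <- setdiff(names(paths), names(EHR_SCHEMAS))
  if (length(unknown)) stop("unknown EHR table(s): ", paste(unknown, collapse = ", "))
  missing <- !file.exists(paths)
  if (any(missing)) stop("file not found: ", paste(paths[missing], collapse = ", "))

  parse_date_col <- function(x, table, col) {
    if (!length(x)) return(as.Date(character()))
    x <- as.character(x)
    out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
    nonblank <- !is.na(x) & nzchar(x)
    parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
    bad <- is.na(parsed)
    if (any(bad)) {
      stop(sprintf("%s: malformed date in column '%s' at data row(s) %s",
                   table, col,
                   paste(head(which(nonblank)[bad], 5L), collapse = ", ")))
    }
    out[nonblank] <- parsed
    out
  }

  tabs <- list()
  for (tb in names(paths)) {
    dt <- fread(paths[[tb]], colClasses = "character", na.strings = c("NA", ""))
    miss <- setdiff(EHR_SCHEMAS[[tb]], names(dt))
    if (length(miss)) {
      stop(tb, ": header lacks column(s): ", paste(miss, collapse = ", "))
    }
    date_cols <- intersect(c("date", "start", "end", "first_record_date"), names(dt))
    for (col in date_cols) set(dt, j = col, value = parse_date_col(dt[[col]], tb, col))
    if (tb == "static" && !is.null(dt$birth_year)) {
      set(dt, j = "birth_year", value = as.integer(dt$birth_year))
    }
    if (!is.null(dt$value)) {
      set(dt, j = "value", value = suppressWarnings(as.numeric(dt$value)))
    }
    tabs[[tb]] <- dt
  }
  if (!quiet) {
    for (tb in names(tabs)) message(sprintf("%s: %d records", tb, nrow(tabs[[tb]])))
  }
  args <- c(list(static = tabs$static, diagnosis = tabs$diagnosis),
            tabs[intersect(names(tabs), EVENT_TABLES)])
  do.call(ehr_store, args)
}

#' Write an EHR store to CSV files
#'
#' Inverse of [read_tables()]: one CSV per non-empty table, ISO-8601 dates.
#'
#' @param store an `ehr_store`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_tables <- function(store, dir) {
  stopifnot(inherits(store, "ehr_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (tb in names(EHR_SCHEMAS)) {
    dt <- store[[tb]]
    if (is.null(dt) || (!nrow(dt) && tb %in% EVENT_TABLES)) next
    p <- file.path(dir, paste0(tb, ".csv"))
    fwrite(dt, p, dateTimeAs = "ISO")
    paths[tb] <- p
  }
  invisible(paths)
}

#' Map an ICD-10 chapter-F code to its first-level diagnostic group
#'
#' Codes are grouped by their first-level ICD-10 category: F00-F09 organic,
#' F10-F19 substance misuse, F20-F29 schizophrenia/psychotic, F30-F39 mood,
#' F40-F49 neurotic/stress/anxiety, F60-F69 personality and behavior; F50-F59
#' and F70-F99 fall into "Other Diagnosis". A missing code means the patient
#' has no diagnosed disorder on record ("Not Diagnosed").
#'
#' @param code character vector of ICD-10 codes (e.g. `"F200"`, `"F33"`), or
#'   `NA` for no diagnosis.
#' @return factor with levels [DIAGNOSIS_GROUPS].
#' @examples
#' map_icd10_group(c("F200", "F33", NA, "F55"))
#' @export
map_icd10_group <- function(code) {
  code <- as.character(code)
  out <- rep(NA_character_, length(code))
  out[is.na(code)] <- "Not Diagnosed"
  present <- !is.na(code)
  if (any(present)) {
    bad <- present & !grepl("^F[0-9]{2}[0-9]?$", code)
    if (any(bad)) {
      stop("not an ICD-10 chapter-F code: ",
           paste(head(unique(code[bad]), 5L), collapse = ", "))
    }
    first <- substr(code[present], 2L, 2L)
    out[present] <- c(
      "0" = "F0 Organic", "1" = "F1 Substance Misuse",
      "2" = "F2 Schizophrenia and Psychotic", "3" = "F3 Mood",
      "4" = "F4 Neurotic Stress and Anxiety", "5" = "Other Diagnosis",
      "6" = "F6 Personality and Behavior", "7" = "Other Diagnosis",
      "8" = "Other Diagnosis", "9" = "Other Diagnosis"
    )[first]
  }
  factor(out, levels = DIAGNOSIS_GROUPS)
}

#' Latest valid diagnosis at a cutoff date
#'
#' Returns each queried patient's most recent diagnosis record dated on or
#' before `cutoff_date`, mapped to its diagnostic group; patients with no such
#' record are "Not Diagnosed". The cutoff is fixed (by default the last
#' training week) so the diagnostic grouping cannot leak post-training
#' information into validation or test rows.
#'
#' @param store an `ehr_store`.
#' @param patient_id character vector of patients to query (default: all
#'   patients in the static table).
#' @param cutoff_date a `Date`.
#' @return named factor of diagnostic groups, one per queried patient.
#' @export
latest_valid_diagnosis <- function(store, patient_id = NULL, cutoff_date) {
  stopifnot(inherits(store, "ehr_store"), inherits(cutoff_date, "Date"))
  if (is.null(patient_id)) patient_id <- store$static$patient_id
  dx <- store$diagnosis[date <= cutoff_date]
  latest <- dx[order(date), .(icd10_code = icd10_code[.N]), by = patient_id]
  code <- latest$icd10_code[match(patient_id, latest$patient_id)]
  setNames(map_icd10_group(code), patient_id)
}
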