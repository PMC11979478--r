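#' Construct an EHR cohort from patient and event tables
#'
#' A cohort is the package's central container: a patient table (one row per
#' patient: demographics, practice, registration and index dates, optional
#' death date) and an event table (one row per coded clinical event). Events
#' are kept sorted by patient and date. All downstream stages — filtering,
#' splitting, vectorisation, clustering, outcome analysis — consume this
#' object.
#'
#' @param patients A data frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `birth_year`, `practice_id`, `registration_start`,
#'   `index_date` and `death_date` (NA = alive). Dates as `Date` or ISO-8601
#'   strings.
#' @param events A data frame with columns `patient_id`, `date`, `code`,
#'   `code_type` (`"diagnosis"`, `"procedure"` or `"medication"`) and `source`
#'   (`"primary_care"` or `"secondary_care"`).
#'
#' @return An object of class `ehr_cohort`: a list with tibbles `patients`
#'   and `events`. Data-quality oddities (death before index, index before
#'   registration) are recorded in `attr(, "flags")`, never rejected.
#' @export
ehr_cohort <- function(patients, events) {
  patients <- as_tibble(patients)
  events <- as_tibble(events)
  need_p <- c("patient_id", "sex", "birth_year", "practice_id",
              "registration_start", "index_date", "death_date")
  need_e <- c("patient_id", "date", "code", "code_type", "source")
  miss_p <- setdiff(need_p, names(patients))
  miss_e <- setdiff(need_e, names(events))
  if (length(miss_p)) abort(sprintf("patient table is missing column(s): %s",
                                    paste(miss_p, collapse = ", ")))
  if (length(miss_e)) abort(sprintf("event table is missing column(s): %s",
                                    paste(miss_e, collapse = ", ")))
  for (col in c("registration_start", "index_date", "death_date")) {
    patients[[col]] <- parse_iso_date(patients[[col]], col)
  }
  events$date <- parse_iso_date(events$date, "date")
  patients$patient_id <- as.character(patients$patient_id)
  patients$practice_id <- as.character(patients$practice_id)
  patients$birth_year <- as.integer(patients$birth_year)
  events$patient_id <- as.character(events$patient_id)
  events$code <- as.character(events$code)
  if (any(!nzchar(events$code))) abort("event codes must be non-empty strings")
  bad_type <- setdiff(unique(events$code_type),
                      c("diagnosis", "procedure", "medication"))
  if (length(bad_type)) {
    abort(sprintf("unknown code_type value(s): %s", paste(bad_type, collapse = ", ")))
  }
  if (anyDuplicated(patients$patient_id)) abort("duplicate patient_id in patient table")

  orphans <- setdiff(unique(events$patient_id), patients$patient_id)
  events <- events[order(events$patient_id, events$date), , drop = FALSE]

  flags <- tibble(
    patient_id = character(), flag = character()
  )
  died_pre_index <- patients$patient_id[!is.na(patients$death_date) &
                                          patients$death_date < patients$index_date]
  if (length(died_pre_index)) {
    flags <- bind_rows(flags, tibble(patient_id = died_pre_index,
                                     flag = "death_before_index"))
  }
  reg_after_index <- patients$patient_id[patients$index_date < patients$registration_start]
  if (length(reg_after_index)) {
    flags <- bind_rows(flags, tibble(patient_id = reg_after_index,
                                     flag = "index_before_registration"))
  }
  age_at_index <- as.integer(format(patients$index_date, "%Y")) - patients$birth_year
  if (any(age_at_index < 0, na.rm = TRUE)) {
    abort("birth_year after index year: age at index would be negative")
  }

  out <- structure(list(patients = patients, events = events), class = "ehr_cohort")
  attr(out, "orphans") <- orphans
  attr(out, "flags") <- flags
  out
}

parse_iso_date <- function(x, col) {
  if (inherits(x, "Date")) return(x)
  x_chr <- as.character(x)
  x_chr[!is.na(x_chr) & !nzchar(trimws(x_chr))] <- NA_character_
  parsed <- as.Date(x_chr, format = "%Y-%m-%d")
  bad <- which(!is.na(x_chr) & is.na(parsed))
  if (length(bad)) {
    abort(sprintf("column `%s`: unparseable date %s at row %d",
                  col, x_chr[bad[1]], bad[1]))
  }
  parsed
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients, %d events, %d practices\n",
              nrow(x$patients), nrow(x$events),
              length(unique(x$patients$practice_id))))
  orph <- attr(x, "orphans")
  if (length(orph)) cat(sprintf("  %d orphaned event patient id(s)\n", length(orph)))
  invisible(x)
}

#' Read a cohort from delimited patient and event files
#'
#' Reads the two flat files that define a cohort (see [ehr_cohort()] for the
#' column schema) and joins them. Event rows whose `patient_id` has no row in
#' the patient table are kept out of the cohort but reported in the ingest
#' attributes rather than silently dropped.
#'
#' @param patients_path,events_path Paths to delimited text files.
#' @param delim Field delimiter (default `","`).
#' @return An `ehr_cohort`; `attr(, "orphans")` lists event-table patient ids
#'   absent from the patient table.
#' @export
read_cohort <- function(patients_path, events_path, delim = ",") {
  patients <- readr::read_delim(patients_path, delim = delim,
                                col_types = readr::cols(.default = readr::col_character()),
                                progress = FALSE)
  events <- readr::read_delim(events_path, delim = delim,
                              col_types = readr::cols(.default = readr::col_character()),
                              progress = FALSE)
  cohort <- ehr_cohort(patients, events)
  orphans <- attr(cohort, "orphans")
  if (length(orphans)) {
    inform(sprintf("event table references %d patient id(s) absent from the patient table: %s",
                   length(orphans), paste(head(orphans, 5), collapse = ", ")))
  }
  # orphaned events cannot be analysed; keep them out of the cohort proper
  cohort$events <- cohort$events[cohort$events$patient_id %in% cohort$patients$patient_id, ]
  attr(cohort, "orphans") <- orphans
  cohort
}

#' Write a cohort to delimited patient and event files
#'
#' Inverse of [read_cohort()]: round-trips the two tables (up to column
#' order). Dates are written ISO-8601.
#'
#' @param cohort An `ehr_cohort`.
#' @param patients_path,events_path Output paths.
#' @param delim Field delimiter.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, patients_path, events_path, delim = ",") {
  stopifnot(inherits(cohort, "ehr_cohort"))
  readr::write_delim(cohort$patients, patients_path, delim = delim, na = "")
  readr::write_delim(cohort$events, events_path, delim = delim, na = "")
  invisible(cohort)
}

#' Number of patients in a cohort
#' @param cohort An `ehr_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

# Subset a cohort to a set of patient ids (internal).
subset_cohort <- function(cohort, patient_ids) {
  out <- structure(list(
    patients = cohort$patients[cohort$patients$patient_id %in% patient_ids, , drop = FALSE],
    events = cohort$events[cohort$events$patient_id %in% patient_ids, , drop = FALSE]
  ), class = "ehr_cohort")
  attr(out, "flags") <- attr(cohort, "flags")
  out
}

# Pre-index events (strictly before each patient's index date), internal.
pre_index_events <- function(cohort) {
  ev <- dplyr::inner_join(cohort$events,
                          cohort$patients[, c("patient_id", "index_date")],
                          by = "patient_id")
  ev[ev$date < ev$index_date, setdiff(names(ev), "index_date"), drop = FALSE]
}
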