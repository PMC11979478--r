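# Reserved token ids shared by the vocabulary and the encoder embeddings.
RESERVED_TOKENS <- c(PAD = 0L, CLS = 1L, SEP = 2L, UNK = 3L)

#' Build the code vocabulary for tokenisation
#'
#' Maps clinical codes to contiguous integer ids. The four reserved tokens
#' (PAD, CLS, SEP, UNK) occupy ids 0-3; codes follow, ordered by corpus
#' frequency (descending) then lexicographically, so the mapping is
#' deterministic. Codes observed fewer than `min_code_count` times across the
#' whole corpus are not given ids and tokenise to UNK. The vocabulary also
#' fixes the calendar-year range and the age cap used for the encoder's year
#' and age embedding tables.
#'
#' @param cohort An `ehr_cohort` (typically the derivation cohort).
#' @param min_code_count Minimum corpus frequency for a code to receive its
#'   own id (default 5).
#' @param age_cap Ages above this are clamped to it (default 110).
#' @return An `ehr_vocab`: list with `codes` (tibble: code, id, n), reserved
#'   ids, `year_min`/`year_max`, and `age_cap`.
#' @export
build_vocabulary <- function(cohort, min_code_count = 5, age_cap = 110L) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!nrow(cohort$patients)) abort("cannot build a vocabulary from an empty cohort")
  ev <- pre_index_events(cohort)
  freq <- ev %>% count(.data$code, name = "n") %>%
    filter(.data$n >= min_code_count) %>%
    arrange(dplyr::desc(.data$n), .data$code)
  freq$id <- seq_len(nrow(freq)) + max(RESERVED_TOKENS)
  years <- as.integer(format(ev$date, "%Y"))
  structure(list(
    codes = freq[, c("code", "id", "n")],
    reserved = RESERVED_TOKENS,
    min_code_count = min_code_count,
    year_min = if (length(years)) min(years) else 2000L,
    year_max = if (length(years)) max(years) else 2000L,
    age_cap = as.integer(age_cap)
  ), class = "ehr_vocab")
}

#' @export
print.ehr_vocab <- function(x, ...) {
  cat(sprintf("<ehr_vocab> %d codes + %d reserved tokens; years %d-%d\n",
              nrow(x$codes), length(x$reserved), x$year_min, x$year_max))
  invisible(x)
}

#' Total number of token ids (reserved + codes)
#' @param vocab An `ehr_vocab`.
#' @return Integer.
#' @export
vocab_size <- function(vocab) length(vocab$reserved) + nrow(vocab$codes)

code_to_id <- function(vocab, codes) {
  id <- vocab$codes$id[match(codes, vocab$codes$code)]
  id[is.na(id)] <- vocab$reserved[["UNK"]]
  id
}

#' Tokenise one patient's pre-index history
#'
#' Turns the events strictly before the patient's index date into the four
#' parallel integer streams the encoder consumes: code ids, age-at-event ids
#' (1-year buckets), calendar-year ids, and visit-position ids. A visit is a
#' distinct calendar date; events sharing a date share a visit id and visit
#' ids increment by 1 per distinct date. A leading CLS token carries the
#' patient's age and year at index with visit id 0. Sequences longer than
#' `max_len` keep the most recent tokens (CLS always retained) and visit ids
#' are renumbered to start at 1 after truncation.
#'
#' @param cohort An `ehr_cohort`.
#' @param patient_id Id of the patient to tokenise.
#' @param vocab An `ehr_vocab`.
#' @param max_len Maximum total sequence length including CLS (default 64).
#' @return A `token_sequence`: list with equal-length integer vectors
#'   `token_ids`, `age_ids`, `year_ids`, `visit_ids`, plus `patient_id` and
#'   `empty` (TRUE when the patient had no pre-index events and the sequence
#'   is the minimal CLS-only one).
#' @export
tokenise_patient <- function(cohort, patient_id, vocab, max_len = 64L) {
  p <- cohort$patients[cohort$patients$patient_id == patient_id, , drop = FALSE]
  if (!nrow(p)) abort(sprintf("patient %s not in cohort", patient_id))
  ev <- cohort$events[cohort$events$patient_id == patient_id, , drop = FALSE]
  ev <- ev[ev$date < p$index_date, , drop = FALSE]
  ev <- ev[order(ev$date), , drop = FALSE]
  build_token_sequence(patient_id, ev$code, ev$date,
                       birth_year = p$birth_year, index_date = p$index_date,
                       vocab = vocab, max_len = max_len)
}

build_token_sequence <- function(patient_id, codes, dates, birth_year, index_date,
                                 vocab, max_len) {
  stopifnot(max_len >= 2)
  idx_year <- as.integer(format(index_date, "%Y"))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  n <- length(codes)
  if (n > 0) {
    ids <- code_to_id(vocab, codes)
    yrs <- as.integer(format(dates, "%Y"))
    ages <- clamp(yrs - birth_year, 0L, vocab$age_cap)
    year_ids <- clamp(yrs - vocab$year_min, 0L, vocab$year_max - vocab$year_min)
    visit_ids <- match(dates, unique(dates))  # dates already sorted ascending
    keep <- max_len - 1L
    if (n > keep) {
      sel <- (n - keep + 1L):n
      ids <- ids[sel]; ages <- ages[sel]; year_ids <- year_ids[sel]
      visit_ids <- visit_ids[sel] - min(visit_ids[sel]) + 1L
    }
  } else {
    ids <- integer(); ages <- integer(); year_ids <- integer(); visit_ids <- integer()
  }
  cls_age <- clamp(idx_year - birth_year, 0L, vocab$age_cap)
  cls_year <- clamp(idx_year - vocab$year_min, 0L, vocab$year_max - vocab$year_min)
  structure(list(
    patient_id = patient_id,
    token_ids = c(vocab$reserved[["CLS"]], ids),
    age_ids = c(cls_age, ages),
    year_ids = c(cls_year, year_ids),
    visit_ids = c(0L, as.integer(visit_ids)),
    empty = n == 0L
  ), class = "token_sequence")
}

#' Tokenise every patient of a cohort
#'
#' @inheritParams tokenise_patient
#' @param patient_ids Optional subset of patients (default: all).
#' @return A named list of `token_sequence` objects, keyed by patient id.
#' @export
tokenise_cohort <- function(cohort, vocab, max_len = 64L, patient_ids = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(vocab, "ehr_vocab"))
  ids <- patient_ids %||% cohort$patients$patient_id
  p <- cohort$patients[match(ids, cohort$patients$patient_id), , drop = FALSE]
  if (anyNA(p$patient_id)) abort("some requested patient ids are not in the cohort")
  ev <- pre_index_events(cohort)
  ev <- ev[ev$patient_id %in% ids, , drop = FALSE]
  ev_split <- split(ev[, c("code", "date")], factor(ev$patient_id, levels = ids))
  seqs <- vector("list", length(ids))
  names(seqs) <- ids
  for (i in seq_along(ids)) {
    e <- ev_split[[i]]
    ord <- order(e$date)
    seqs[[i]] <- build_token_sequence(ids[i], e$code[ord], e$date[ord],
                                      birth_year = p$birth_year[i],
                                      index_date = p$index_date[i],
                                      vocab = vocab, max_len = max_len)
  }
  n_empty <- sum(vapply(seqs, `[[`, logical(1), "empty"))
  if (n_empty) inform(sprintf("%d patient(s) with no pre-index events tokenised as CLS-only", n_empty))
  seqs
}
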