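#' Apply the cohort eligibility filters
#'
#' Retains patients aged at least `min_age` years at their index date (age
#' derived from birth year and index year) and registered with their practice
#' for at least `min_registration_months` months before index (months
#' converted at 30.4375 days/month). Filters never error; an attrition count
#' per filter is attached to the result.
#'
#' @param cohort An `ehr_cohort`.
#' @param min_age Minimum age in whole years at index (default 35).
#' @param min_registration_months Minimum pre-index registration, months
#'   (default 12).
#' @return The filtered `ehr_cohort` with `attr(, "attrition")`: a tibble of
#'   per-filter exclusion counts.
#' @export
apply_cohort_filters <- function(cohort, min_age = 35, min_registration_months = 12) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  p <- cohort$patients
  if (nrow(p) && any(is.na(p$index_date))) abort("index_date missing for some patients")
  age <- as.integer(format(p$index_date, "%Y")) - p$birth_year
  keep_age <- age >= min_age
  reg_days <- as.numeric(p$index_date - p$registration_start)
  keep_reg <- reg_days >= min_registration_months * days_per_month
  keep <- keep_age & keep_reg
  attrition <- tibble(
    filter = c("age_at_index", "registration"),
    threshold = c(sprintf(">= %d years", min_age),
                  sprintf(">= %d months", min_registration_months)),
    excluded = c(sum(!keep_age), sum(keep_age & !keep_reg)),
    remaining = c(sum(keep_age), sum(keep))
  )
  out <- subset_cohort(cohort, p$patient_id[keep])
  attr(out, "attrition") <- attrition
  out
}

#' Split a cohort into derivation and validation sets by practice
#'
#' Practices — not patients — are randomly assigned, so that every patient of
#' a practice lands on the same side. This mirrors a geography-stratified
#' derivation/validation design and prevents practice-level leakage.
#'
#' @param cohort An `ehr_cohort`.
#' @param derivation_fraction Fraction of practices assigned to the
#'   derivation set (default 0.8). `1.0` is allowed as a degenerate case.
#' @param seed Integer seed; the split is a deterministic function of it.
#' @return A `cohort_split`: list with `derivation` and `validation` patient
#'   id vectors and a `practices` tibble (practice_id, arm).
#' @export
split_by_practice <- function(cohort, derivation_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (derivation_fraction <= 0 || derivation_fraction > 1) {
    abort("`derivation_fraction` must be in (0, 1]")
  }
  practices <- sort(unique(cohort$patients$practice_id))
  n_prac <- length(practices)
  if (derivation_fraction < 1 && n_prac < 2) {
    abort("practice-level split needs at least 2 practices when derivation_fraction < 1")
  }
  if (derivation_fraction == 1) {
    deriv_prac <- practices
  } else {
    n_deriv <- round(derivation_fraction * n_prac)
    n_deriv <- min(max(n_deriv, 1L), n_prac - 1L)  # both arms non-empty
    deriv_prac <- with_seed(derive_seed(seed, "practice-split"),
                            sort(sample(practices, n_deriv)))
  }
  arm <- ifelse(practices %in% deriv_prac, "derivation", "validation")
  p <- cohort$patients
  structure(list(
    derivation = p$patient_id[p$practice_id %in% deriv_prac],
    validation = p$patient_id[!(p$practice_id %in% deriv_prac)],
    practices = tibble(practice_id = practices, arm = arm),
    derivation_fraction = derivation_fraction,
    seed = seed
  ), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d derivation / %d validation patients (%d/%d practices)\n",
              length(x$derivation), length(x$validation),
              sum(x$practices$arm == "derivation"),
              sum(x$practices$arm == "validation")))
  invisible(x)
}
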