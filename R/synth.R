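#' Define a latent subtype for the synthetic-cohort generator
#'
#' A subtype plants structure in two places: in the pre-index history, each
#' patient carries every signature code with probability
#' `signature_prevalence` (non-signature codes with `background_prevalence`),
#' so the subtype is identifiable from code content; and after the index
#' date, death / heart-failure hospitalisation / comorbidity onsets are drawn
#' with subtype-specific constant hazards, so clusters that recover subtypes
#' also separate prognostically.
#'
#' @param subtype_id Integer label of the subtype.
#' @param signature_codes Character vector of codes over-represented in this
#'   subtype.
#' @param signature_prevalence Per-patient carrier probability of each
#'   signature code.
#' @param background_prevalence Per-patient carrier probability of each
#'   non-signature code.
#' @param age_mean,age_sd Age at index, years (normal).
#' @param visit_rate Expected visits per year of history (Poisson process).
#' @param death_hazard,hospitalisation_hazard Constant hazards, events per
#'   person-year, for post-index death and first HF hospitalisation.
#' @param comorbidity_hazards Named numeric: condition code -> post-index
#'   onset hazard (events per person-year).
#' @param pre_index_comorbidity_prob Named numeric (or single value recycled
#'   over `names(comorbidity_hazards)`): probability that the condition is
#'   already present before index, to exercise prevalent-case exclusion.
#' @return A `subtype_profile` list.
#' @export
subtype_profile <- function(subtype_id, signature_codes,
                            signature_prevalence = 0.9,
                            background_prevalence = 0.05,
                            age_mean = 75, age_sd = 10,
                            visit_rate = 6,
                            death_hazard = 0.2,
                            hospitalisation_hazard = 0.3,
                            comorbidity_hazards = numeric(),
                            pre_index_comorbidity_prob = numeric()) {
  assert_scalar_number(signature_prevalence, "signature_prevalence", 0, 1)
  assert_scalar_number(background_prevalence, "background_prevalence", 0, 1)
  assert_scalar_number(death_hazard, "death_hazard", 0)
  assert_scalar_number(hospitalisation_hazard, "hospitalisation_hazard", 0)
  if (any(comorbidity_hazards < 0)) abort("comorbidity hazards must be >= 0")
  if (length(pre_index_comorbidity_prob) == 1 && length(comorbidity_hazards) > 1) {
    pre_index_comorbidity_prob <- setNames(
      rep(pre_index_comorbidity_prob, length(comorbidity_hazards)),
      names(comorbidity_hazards))
  }
  structure(list(
    subtype_id = as.integer(subtype_id),
    signature_codes = as.character(signature_codes),
    signature_prevalence = signature_prevalence,
    background_prevalence = background_prevalence,
    age_mean = age_mean, age_sd = age_sd,
    visit_rate = visit_rate,
    death_hazard = death_hazard,
    hospitalisation_hazard = hospitalisation_hazard,
    comorbidity_hazards = comorbidity_hazards,
    pre_index_comorbidity_prob = pre_index_comorbidity_prob
  ), class = "subtype_profile")
}

#' Configuration for the synthetic-cohort generator
#'
#' @param n_patients Number of patients to simulate.
#' @param profiles List of [subtype_profile()]s.
#' @param weights Mixture weights over subtypes (must sum to 1).
#' @param n_practices Number of GP practices (patients assigned uniformly;
#'   at least 2 so a practice-level split is possible).
#' @param background_codes Character vector of non-signature codes.
#' @param years_history Length of pre-index observation window, years.
#' @param horizon_days Post-index follow-up horizon used downstream (days).
#' @param visit_emission Probability that a carried code is recorded at any
#'   given visit (each carried code is guaranteed at least one record).
#' @param index_window Two dates bounding the uniform index-date draw.
#' @param seed Integer seed; generation is a deterministic function of it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients, profiles, weights = NULL,
                         n_practices = 10,
                         background_codes = sprintf("B%03d", 1:85),
                         years_history = 3,
                         horizon_days = 365,
                         visit_emission = 0.35,
                         index_window = as.Date(c("2010-01-01", "2017-12-31")),
                         seed = 1L) {
  if (n_patients < 0) abort("`n_patients` must be >= 0")
  if (!length(profiles)) abort("at least one subtype profile is required")
  if (n_practices < 2) abort("`n_practices` must be >= 2")
  weights <- weights %||% rep(1 / length(profiles), length(profiles))
  if (length(weights) != length(profiles)) abort("one weight per profile required")
  if (abs(sum(weights) - 1) > 1e-8) abort("mixture weights must sum to 1")
  all_codes <- unique(c(unlist(lapply(profiles, `[[`, "signature_codes")),
                        background_codes,
                        unlist(lapply(profiles, function(p) names(p$comorbidity_hazards)))))
  if (!length(all_codes)) abort("config defines an empty vocabulary")
  structure(list(
    n_patients = as.integer(n_patients),
    profiles = profiles,
    weights = weights,
    n_practices = as.integer(n_practices),
    background_codes = as.character(background_codes),
    years_history = years_history,
    horizon_days = horizon_days,
    visit_emission = visit_emission,
    index_window = index_window,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' The strong-signal three-subtype preset
#'
#' The canonical test cohort: three equally weighted subtypes, five signature
#' codes each at carrier prevalence 0.9 against a background prevalence of
#' 0.05 over 85 background codes, with well separated post-index hazards
#' (death 0.45/0.25/0.10 per person-year; HF hospitalisation 0.6/0.35/0.2).
#' One condition code per subtype carries a post-index onset hazard of
#' 0.4/year and a pre-index prevalence of 0.3 in its own subtype (0.05
#' elsewhere) so that prevalent-case exclusion is exercised.
#'
#' @param n_patients Cohort size (default 2000).
#' @param seed Generator seed.
#' @return A `synth_config`.
#' @export
default_synth_config <- function(n_patients = 2000, seed = 1L) {
  sig <- function(s) sprintf("S%d_%d", s, 1:5)
  cond <- c("COND_HTN", "COND_IHD", "COND_COPD")
  mk <- function(s) {
    # own-subtype condition gets the high hazard / planting probability
    hz <- setNames(rep(0.05, 3), cond); hz[[cond[s]]] <- 0.4
    pre <- setNames(rep(0.05, 3), cond); pre[[cond[s]]] <- 0.3
    subtype_profile(s, sig(s),
                    signature_prevalence = 0.9, background_prevalence = 0.05,
                    age_mean = 75, age_sd = 10, visit_rate = 6,
                    death_hazard = c(0.45, 0.25, 0.10)[s],
                    hospitalisation_hazard = c(0.6, 0.35, 0.2)[s],
                    comorbidity_hazards = hz,
                    pre_index_comorbidity_prob = pre)
  }
  synth_config(n_patients, profiles = lapply(1:3, mk), seed = seed)
}

#' Generate a synthetic cohort with planted subtypes
#'
#' For each patient a subtype is drawn from the mixture, a practice assigned
#' uniformly, visits placed as a homogeneous Poisson process over the
#' pre-index history window, and the patient's carried codes (signature codes
#' with `signature_prevalence`, background codes with
#' `background_prevalence`) recorded at visits with the configured emission
#' probability — always at least once, so the per-patient carrier fraction
#' matches the configured prevalence exactly in expectation. The index event
#' itself is recorded as code `"HF_INDEX"` on the index date.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (an `ehr_cohort`, death dates still NA) and
#'   `truth` (tibble: patient_id, subtype_id).
#' @seealso [generate_outcomes()] to add post-index outcomes,
#'   [simulate_cohort()] for both steps in one call.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  if (n == 0) {
    empty <- ehr_cohort(
      tibble(patient_id = character(), sex = character(), birth_year = integer(),
             practice_id = character(), registration_start = as.Date(character()),
             index_date = as.Date(character()), death_date = as.Date(character())),
      tibble(patient_id = character(), date = as.Date(character()),
             code = character(), code_type = character(), source = character()))
    return(list(cohort = empty,
                truth = tibble(patient_id = character(), subtype_id = integer())))
  }
  with_seed(derive_seed(config$seed, "cohort"), {
    ids <- sprintf("P%05d", seq_len(n))
    subtype <- sample.int(length(config$profiles), n, replace = TRUE,
                          prob = config$weights)
    practice <- sprintf("G%03d", sample.int(config$n_practices, n, replace = TRUE))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    idx_days <- as.numeric(config$index_window[2] - config$index_window[1])
    index_date <- config$index_window[1] + floor(runif(n, 0, idx_days + 1))
    prof <- config$profiles
    age <- vapply(seq_len(n), function(i) {
      p <- prof[[subtype[i]]]
      max(36, round(rnorm(1, p$age_mean, p$age_sd)))
    }, numeric(1))
    birth_year <- as.integer(format(index_date, "%Y")) - as.integer(age)
    # registration comfortably precedes the history window
    registration_start <- index_date - round(config$years_history * 365.25) - 400L

    hist_days <- round(config$years_history * 365.25)
    ev_id <- vector("list", n); ev_date <- vector("list", n); ev_code <- vector("list", n)
    for (i in seq_len(n)) {
      p <- prof[[subtype[i]]]
      n_visits <- rpois(1, p$visit_rate * config$years_history)
      if (n_visits == 0) next
      visit_dates <- sort(as.numeric(index_date[i]) -
                            sample.int(hist_days, n_visits, replace = TRUE))
      sig <- p$signature_codes
      bg <- setdiff(config$background_codes, sig)
      carried <- c(sig[runif(length(sig)) < p$signature_prevalence],
                   bg[runif(length(bg)) < p$background_prevalence])
      if (!length(carried)) next
      recs <- lapply(carried, function(code) {
        at <- visit_dates[runif(n_visits) < config$visit_emission]
        if (!length(at)) at <- visit_dates[sample.int(n_visits, 1)]
        at
      })
      ev_date[[i]] <- unlist(recs)
      ev_code[[i]] <- rep(carried, lengths(recs))
      ev_id[[i]] <- rep(ids[i], length(ev_date[[i]]))
    }
    events <- tibble(
      patient_id = unlist(ev_id) %||% character(),
      date = as.Date(unlist(ev_date) %||% numeric(), origin = "1970-01-01"),
      code = unlist(ev_code) %||% character(),
      code_type = "diagnosis",
      source = "primary_care")
    index_events <- tibble(patient_id = ids, date = index_date, code = "HF_INDEX",
                           code_type = "diagnosis", source = "primary_care")
    patients <- tibble(
      patient_id = ids, sex = sex, birth_year = birth_year,
      practice_id = practice, registration_start = registration_start,
      index_date = index_date, death_date = as.Date(NA))
    list(cohort = ehr_cohort(patients, bind_rows(events, index_events)),
         truth = tibble(patient_id = ids, subtype_id = subtype))
  })
}

#' Add post-index outcomes (and pre-index comorbidities) to a cohort
#'
#' Event times are exponential with each subtype's hazard: death sets
#' `death_date`; the first HF hospitalisation is recorded as a
#' `"HF_HOSP"` secondary-care event if it precedes death; each condition's
#' onset is recorded as a diagnosis event if it precedes death. Events are
#' recorded up to `max_follow_years` after index (analyses apply their own
#' administrative horizon). Conditions are additionally planted before index
#' with the profile's `pre_index_comorbidity_prob`, to exercise
#' prevalent-case exclusion downstream.
#'
#' @param cohort An `ehr_cohort` from [generate_cohort()].
#' @param truth Its ground-truth tibble.
#' @param config The same [synth_config()].
#' @param max_follow_years Recording window after index, years (default 5).
#' @return The cohort with outcomes filled in.
#' @export
generate_outcomes <- function(cohort, truth, config, max_follow_years = 5) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(config, "synth_config"))
  n <- nrow(cohort$patients)
  if (n == 0) return(cohort)
  with_seed(derive_seed(config$seed, "outcomes"), {
    p <- cohort$patients
    subtype <- truth$subtype_id[match(p$patient_id, truth$patient_id)]
    max_days <- round(max_follow_years * 365.25)
    ne_id <- list(); ne_date <- list(); ne_code <- list(); ne_src <- list()
    push <- function(pid, date, code, src) {
      k <- length(ne_id) + 1L
      ne_id[[k]] <<- pid; ne_date[[k]] <<- as.numeric(date)
      ne_code[[k]] <<- code; ne_src[[k]] <<- src
    }
    death_date <- as.Date(rep(NA, n))
    for (i in seq_len(n)) {
      prof <- config$profiles[[subtype[i]]]
      t_death <- if (prof$death_hazard > 0) rexp(1, prof$death_hazard) * 365.25 else Inf
      if (t_death <= max_days) death_date[i] <- p$index_date[i] + round(t_death)
      t_hosp <- if (prof$hospitalisation_hazard > 0)
        rexp(1, prof$hospitalisation_hazard) * 365.25 else Inf
      if (t_hosp <= max_days && t_hosp < t_death) {
        push(p$patient_id[i], p$index_date[i] + round(t_hosp), "HF_HOSP",
             "secondary_care")
      }
      for (cond in names(prof$comorbidity_hazards)) {
        pre_p <- prof$pre_index_comorbidity_prob[[cond]] %||% 0
        if (runif(1) < pre_p) {
          # prevalent before index
          offset <- sample.int(round(config$years_history * 365.25), 1)
          push(p$patient_id[i], p$index_date[i] - offset, cond, "primary_care")
        } else {
          lam <- prof$comorbidity_hazards[[cond]]
          t_on <- if (lam > 0) rexp(1, lam) * 365.25 else Inf
          if (t_on <= max_days && t_on < t_death) {
            push(p$patient_id[i], p$index_date[i] + round(t_on), cond, "primary_care")
          }
        }
      }
    }
    p$death_date <- death_date
    new_events <- tibble(
      patient_id = unlist(ne_id) %||% character(),
      date = as.Date(unlist(ne_date) %||% numeric(), origin = "1970-01-01"),
      code = unlist(ne_code) %||% character(),
      code_type = "diagnosis",
      source = unlist(ne_src) %||% character())
    ehr_cohort(p, bind_rows(cohort$events, new_events))
  })
}

#' Generate a cohort with outcomes in one call
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (outcomes included) and `truth`.
#' @export
simulate_cohort <- function(config) {
  gen <- generate_cohort(config)
  gen$cohort <- generate_outcomes(gen$cohort, gen$truth, config)
  gen
}
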