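#' Kaplan-Meier cumulative incidence over a fixed horizon
#'
#' Fits the Kaplan-Meier estimator (via [survival::survfit()]) after
#' administrative censoring at `horizon`, and reports the curve as cumulative
#' incidence `1 - S(t)`. Events and censorings tied at the same time are
#' resolved events-first, the Kaplan-Meier convention. Confidence bands come
#' from [greenwood_exponential_ci()].
#'
#' @param time_to_event Days from index to event or censoring (>= 0).
#' @param event_flag 1/TRUE = event, 0/FALSE = censored.
#' @param horizon Administrative censoring horizon in days (default 365).
#' @param conf_level Confidence level (default 0.95).
#' @param conf_type `"log-log"` (Greenwood exponential, default) or
#'   `"plain"` (linear Greenwood).
#' @return A `survival_curve`: tibble (time, n_risk, n_event, n_censor,
#'   surv, cuminc, ci_lo, ci_hi) over the distinct event times, including a
#'   row at `horizon`.
#' @export
km_cumulative_incidence <- function(time_to_event, event_flag, horizon = 365,
                                    conf_level = 0.95,
                                    conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  if (!length(time_to_event)) abort("no subjects")
  if (any(time_to_event < 0)) abort("negative time to event")
  event_flag <- as.integer(event_flag)
  over <- time_to_event > horizon
  event_flag[over] <- 0L
  time_to_event[over] <- horizon
  fit <- survival::survfit(survival::Surv(time_to_event, event_flag) ~ 1,
                           conf.type = "none")
  curve <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  if (!any(curve$time == horizon)) {
    last_surv <- if (nrow(curve)) tail(curve$surv, 1) else 1
    curve <- bind_rows(curve, tibble(time = horizon, n_risk = 0L, n_event = 0L,
                                     n_censor = 0L, surv = last_surv))
  }
  curve$cuminc <- 1 - curve$surv
  curve <- structure(curve, class = c("survival_curve", class(curve)),
                     conf_level = conf_level, horizon = horizon)
  greenwood_exponential_ci(curve, conf_level = conf_level, conf_type = conf_type)
}

#' Greenwood confidence bands for a Kaplan-Meier curve
#'
#' Default is the exponential (log-minus-log) Greenwood formula: with the
#' Greenwood variance `V(t) = sum_{t_j <= t} d_j / (n_j (n_j - d_j))` and
#' `se(t) = sqrt(V(t)) / |log S(t)|`, the survival bounds are
#' `S(t) ^ exp(+/- z * se(t))`, guaranteed inside (0, 1); incidence bands
#' are one minus the bounds, order-swapped. Where `S(t)` is 0 or 1 the band
#' is undefined and reported as NA. `conf_type = "plain"` gives the linear
#' Greenwood band `S +/- z * S * sqrt(V)`, clipped to [0, 1].
#'
#' @param curve A `survival_curve` (needs columns time, n_risk, n_event,
#'   surv).
#' @param conf_level Confidence level.
#' @param conf_type `"log-log"` or `"plain"`.
#' @return The curve with `ci_lo`/`ci_hi` columns on the incidence scale.
#' @export
greenwood_exponential_ci <- function(curve, conf_level = 0.95,
                                     conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  z <- qnorm(1 - (1 - conf_level) / 2)
  with_events <- curve$n_risk > 0 & curve$n_event > 0
  dv <- ifelse(with_events,
               curve$n_event / (curve$n_risk * pmax(curve$n_risk - curve$n_event, 0)),
               0)
  dv[with_events & curve$n_risk == curve$n_event] <- Inf
  V <- cumsum(dv)
  s <- curve$surv
  if (conf_type == "log-log") {
    se <- sqrt(V) / abs(log(s))
    lo_surv <- s^exp(z * se)    # lower survival bound
    hi_surv <- s^exp(-z * se)
    # no events yet: V = 0, band collapses to the estimate (including S = 1)
    collapse <- V == 0
    lo_surv[collapse] <- s[collapse]
    hi_surv[collapse] <- s[collapse]
    # S = 0 (or a degenerate S = 1 after events): transformation undefined
    undef <- (s <= 0 | s >= 1) & !collapse
    lo_surv[undef] <- NA_real_
    hi_surv[undef] <- NA_real_
    ci_lo <- 1 - hi_surv
    ci_hi <- 1 - lo_surv
  } else {
    half <- z * s * sqrt(V)
    ci_lo <- pmax(1 - (s + half), 0)
    ci_hi <- pmin(1 - (s - half), 1)
  }
  curve$ci_lo <- ci_lo
  curve$ci_hi <- ci_hi
  attr(curve, "conf_level") <- conf_level
  attr(curve, "conf_type") <- conf_type
  curve
}

#' Cumulative incidence at a time point
#' @param curve A `survival_curve`.
#' @param at Time in days (default: the curve's horizon).
#' @return Named numeric: estimate, ci_lo, ci_hi.
#' @export
incidence_at <- function(curve, at = attr(curve, "horizon")) {
  i <- findInterval(at, curve$time)
  if (i == 0) return(c(estimate = 0, ci_lo = 0, ci_hi = 0))
  c(estimate = curve$cuminc[i], ci_lo = curve$ci_lo[i], ci_hi = curve$ci_hi[i])
}

# time to outcome and event indicator per patient, from the data model
outcome_times <- function(cohort, outcome, horizon) {
  p <- cohort$patients
  death_days <- as.numeric(p$death_date - p$index_date)
  if (outcome == "death") {
    time <- ifelse(is.na(death_days), horizon, death_days)
    event <- as.integer(!is.na(death_days) & death_days <= horizon)
    time <- pmin(time, horizon)
  } else {
    code <- if (outcome == "hf_hospitalisation") "HF_HOSP" else outcome
    ev <- cohort$events[cohort$events$code == code, c("patient_id", "date")]
    ev <- dplyr::inner_join(ev, p[, c("patient_id", "index_date")], by = "patient_id")
    ev <- ev[ev$date > ev$index_date, , drop = FALSE]
    first_ev <- if (nrow(ev)) {
      ev %>% group_by(.data$patient_id) %>%
        summarise(onset = min(.data$date), .groups = "drop")
    } else tibble(patient_id = character(), onset = as.Date(character()))
    onset_days <- as.numeric(first_ev$onset[match(p$patient_id, first_ev$patient_id)] -
                               p$index_date)
    # death before the outcome censors at death
    cens <- pmin(ifelse(is.na(death_days), horizon, death_days), horizon)
    time <- pmin(ifelse(is.na(onset_days), Inf, onset_days), cens)
    event <- as.integer(!is.na(onset_days) & onset_days <= cens)
  }
  tibble(patient_id = p$patient_id, time = time, event = event)
}

#' Per-cluster one-year outcome curves
#'
#' Fits one Kaplan-Meier cumulative-incidence curve per cluster for the
#' requested outcome — all-cause death, first HF hospitalisation (death
#' before hospitalisation censors at death), or onset of a condition code —
#' and summarises between-cluster prognostic separation as the range of
#' incidence at the horizon.
#'
#' @param cohort An `ehr_cohort` (typically the validation arm).
#' @param labels Tibble (patient_id, cluster) covering the cohort.
#' @param outcome `"death"`, `"hf_hospitalisation"`, or a condition code.
#' @param horizon Days (default 365).
#' @param conf_level,conf_type Passed to the confidence bands.
#' @return A `survival_curve_set`: tibble of per-cluster curve rows with a
#'   `cluster` column; `attr(, "at_horizon")` holds per-cluster incidence at
#'   the horizon and `attr(, "range")` its max - min.
#' @export
per_cluster_curves <- function(cohort, labels, outcome = "death", horizon = 365,
                               conf_level = 0.95, conf_type = "log-log") {
  stopifnot(inherits(cohort, "ehr_cohort"))
  labels <- as_tibble(labels)
  if (!all(c("patient_id", "cluster") %in% names(labels))) {
    abort("`labels` must have columns patient_id and cluster")
  }
  missing_ids <- setdiff(cohort$patients$patient_id, labels$patient_id)
  if (length(missing_ids)) abort("`labels` do not cover every cohort patient")
  times <- outcome_times(cohort, outcome, horizon)
  times <- left_join(times, labels, by = "patient_id")
  curves <- list()
  at_h <- list()
  for (cl in sort(unique(labels$cluster))) {
    tt <- times[times$cluster == cl, , drop = FALSE]
    if (!nrow(tt)) {
      warn(sprintf("cluster %s is empty; skipped", cl))
      next
    }
    cv <- km_cumulative_incidence(tt$time, tt$event, horizon = horizon,
                                  conf_level = conf_level, conf_type = conf_type)
    cv$cluster <- cl
    curves[[length(curves) + 1L]] <- as_tibble(cv)
    inc <- incidence_at(cv)
    at_h[[length(at_h) + 1L]] <- tibble(cluster = cl, n = nrow(tt),
                                        incidence = inc[["estimate"]],
                                        ci_lo = inc[["ci_lo"]], ci_hi = inc[["ci_hi"]])
  }
  at_horizon <- bind_rows(at_h)
  out <- bind_rows(curves)
  structure(out, class = c("survival_curve_set", class(out)),
            at_horizon = at_horizon,
            range = if (nrow(at_horizon)) diff(range(at_horizon$incidence)) else 0,
            outcome = outcome, horizon = horizon)
}

#' Per-cluster incidence at the horizon
#' @param curves A `survival_curve_set`.
#' @return Tibble (cluster, n, incidence, ci_lo, ci_hi).
#' @export
horizon_incidence <- function(curves) attr(curves, "at_horizon")

#' Between-cluster incidence range at the horizon
#' @param curves A `survival_curve_set`.
#' @return Scalar: max - min cluster incidence at the horizon.
#' @export
incidence_range <- function(curves) attr(curves, "range")

#' Post-index incidence with prevalent-case exclusion
#'
#' For incident-disease analyses, patients with any pre-index record of the
#' condition are excluded from that condition's risk set before per-cluster
#' Kaplan-Meier curves are fitted; remaining patients contribute time from
#' index to onset, censored at death or the horizon.
#'
#' @param cohort An `ehr_cohort`.
#' @param labels Tibble (patient_id, cluster).
#' @param condition Condition code to analyse.
#' @param horizon Days (default 365).
#' @return A `survival_curve_set` (see [per_cluster_curves()]);
#'   `attr(, "risk_set")` reports per-cluster sizes before/after exclusion.
#' @export
post_index_incidence <- function(cohort, labels, condition, horizon = 365) {
  if (!condition %in% cohort$events$code) {
    abort(sprintf("condition code `%s` is absent from the event table", condition))
  }
  ev <- pre_index_events(cohort)
  prevalent <- unique(ev$patient_id[ev$code == condition])
  keep <- setdiff(cohort$patients$patient_id, prevalent)
  labels <- as_tibble(labels)
  risk_set <- labels %>% group_by(.data$cluster) %>%
    summarise(n_total = dplyr::n(),
              n_at_risk = sum(.data$patient_id %in% keep), .groups = "drop")
  sub <- subset_cohort(cohort, keep)
  out <- per_cluster_curves(sub, labels[labels$patient_id %in% keep, , drop = FALSE],
                            outcome = condition, horizon = horizon)
  attr(out, "risk_set") <- risk_set
  out
}

#' Write per-cluster curves to a delimited file
#' @param curves A `survival_curve_set` or `survival_curve`.
#' @param path Output path.
#' @return Invisibly, the input.
#' @export
write_curves <- function(curves, path) {
  readr::write_delim(as_tibble(curves), path, delim = "\t")
  invisible(curves)
}
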