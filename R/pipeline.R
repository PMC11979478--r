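#' Configuration for an end-to-end subtyping run
#'
#' @param vectoriser `"tfidf"` or `"transformer"`.
#' @param encoder An [encoder_config()] (transformer arm only).
#' @param ks Candidate cluster numbers (contiguous, from 1).
#' @param ps_threshold Prediction-strength selection threshold.
#' @param derivation_fraction Practice-level split fraction.
#' @param min_age,min_registration_months Cohort filters.
#' @param min_code_count Vocabulary frequency floor.
#' @param max_len Token-sequence cap (transformer arm).
#' @param encoder_train_max Cap on the number of derivation sequences used
#'   for contrastive training (sampled, seeded); keeps CPU training short.
#' @param horizon Outcome horizon in days.
#' @param conf_level Confidence level for incidence bands.
#' @param min_spread Prevalence-spread cutoff for discriminative codes.
#' @param n_folds,n_restarts Prediction-strength CV folds / K-means restarts.
#' @param seed Global seed; every stage derives its own stream from it.
#' @param output_dir If non-NULL, persist intermediate artifacts there.
#' @return A `run_config` list.
#' @export
run_config <- function(vectoriser = c("tfidf", "transformer"),
                       encoder = encoder_config(),
                       ks = 1:8, ps_threshold = 0.8,
                       derivation_fraction = 0.8,
                       min_age = 35, min_registration_months = 12,
                       min_code_count = 5, max_len = 64L,
                       encoder_train_max = 600L,
                       horizon = 365, conf_level = 0.95, min_spread = 0.30,
                       n_folds = 5L, n_restarts = 10L,
                       seed = 1L, output_dir = NULL) {
  vectoriser <- match.arg(vectoriser)
  if (min(ks) != 1) abort("`ks` must start at 1 (prediction strength is anchored at ps(1) = 1)")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full subtyping workflow on a cohort
#'
#' Executes ingest-side filtering, the practice-level derivation/validation
#' split, vectoriser fitting on the derivation cohort only, cross-validated
#' prediction-strength selection of the number of clusters, the final
#' K-means fit on derivation vectors, assignment of validation patients to
#' derivation centroids, and the evaluation battery on the validation
#' cohort: silhouette and Calinski-Harabasz, per-cluster one-year
#' cumulative-incidence curves for death and HF hospitalisation, and the
#' prevalence-spread code characterisation. Reruns with an identical config
#' reproduce the report.
#'
#' @param cohort An `ehr_cohort`.
#' @param config A [run_config()].
#' @return A `run_report` (see [print.run_report()]); if
#'   `config$output_dir` is set, intermediate tables are persisted there.
#' @export
run_subtyping <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(config, "run_config"))
  filtered <- apply_cohort_filters(cohort, config$min_age, config$min_registration_months)
  attrition <- attr(filtered, "attrition")
  split <- split_by_practice(filtered, config$derivation_fraction,
                             seed = derive_seed(config$seed, "split"))
  deriv <- subset_cohort(filtered, split$derivation)
  valid <- subset_cohort(filtered, split$validation)

  if (config$vectoriser == "tfidf") {
    idf <- fit_tfidf(deriv)
    vec_deriv <- suppressWarnings(vectorise_tfidf(deriv, idf))
    vec_valid <- suppressWarnings(vectorise_tfidf(valid, idf))
    fitted_vectoriser <- idf
  } else {
    vocab <- build_vocabulary(deriv, config$min_code_count)
    seq_deriv <- tokenise_cohort(deriv, vocab, config$max_len)
    train_ids <- split$derivation
    if (length(train_ids) > config$encoder_train_max) {
      train_ids <- with_seed(derive_seed(config$seed, "train-sample"),
                             sample(train_ids, config$encoder_train_max))
    }
    enc_cfg <- config$encoder
    enc_cfg$seed <- derive_seed(config$seed, "encoder")
    enc_cfg$max_len <- config$max_len
    model <- train_encoder(seq_deriv[train_ids], enc_cfg, vocab)
    vec_deriv <- embed_cohort(seq_deriv, model)
    seq_valid <- tokenise_cohort(valid, vocab, config$max_len)
    vec_valid <- embed_cohort(seq_valid, model)
    fitted_vectoriser <- model
  }
  # zero vectors (patients with no usable pre-index history) leave the analysis
  keep_d <- setdiff(vec_deriv$patient_id, vec_deriv$zero_vector)
  keep_v <- setdiff(vec_valid$patient_id, vec_valid$zero_vector)
  xd <- unclass_vectors(vec_deriv)[keep_d, , drop = FALSE]
  xv <- unclass_vectors(vec_valid)[keep_v, , drop = FALSE]

  ps <- prediction_strength(xd, ks = config$ks, n_folds = config$n_folds,
                            seed = derive_seed(config$seed, "ps"),
                            n_restarts = config$n_restarts)
  k_star <- select_optimal_k(ps, config$ps_threshold)
  km <- fit_kmeans(xd, k_star, seed = derive_seed(config$seed, "final-kmeans"),
                   n_restarts = config$n_restarts)
  labels_valid <- tibble(patient_id = keep_v,
                         cluster = assign_clusters(km, xv))
  valid_eval <- subset_cohort(valid, keep_v)

  quality <- if (k_star >= 2) {
    cluster_quality(xv, labels_valid$cluster)
  } else {
    tibble(metric = c("silhouette", "calinski_harabasz"), value = NA_real_)
  }
  curves_death <- per_cluster_curves(valid_eval, labels_valid, "death",
                                     horizon = config$horizon,
                                     conf_level = config$conf_level)
  curves_hosp <- per_cluster_curves(valid_eval, labels_valid, "hf_hospitalisation",
                                    horizon = config$horizon,
                                    conf_level = config$conf_level)
  pm <- prevalence_matrix(valid_eval, labels_valid)
  disc <- select_discriminative_codes(pm, config$min_spread)

  audit <- list(
    n_derivation = length(keep_d),
    n_validation = length(keep_v),
    fit_ids_in_validation = length(intersect(keep_d, split$validation)),
    practices_in_both = sum(table(split$practices$practice_id,
                                  split$practices$arm) %>% apply(1, min) > 0)
  )
  report <- structure(list(
    vectoriser = config$vectoriser,
    attrition = attrition,
    split = split,
    ps_curve = ps,
    k = k_star,
    kmeans = km,
    quality = quality,
    cluster_sizes = labels_valid %>% count(.data$cluster, name = "n"),
    labels = labels_valid,
    curves_death = curves_death,
    curves_hospitalisation = curves_hosp,
    prevalence = pm,
    discriminative_codes = disc,
    fitted_vectoriser = fitted_vectoriser,
    audit = audit,
    config = config
  ), class = "run_report")
  if (!is.null(config$output_dir)) persist_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s arm\n", x$vectoriser))
  cat(sprintf("  chosen k: %d\n", x$k))
  q <- setNames(x$quality$value, x$quality$metric)
  cat(sprintf("  validation silhouette: %.3f, Calinski-Harabasz: %.1f\n",
              q[["silhouette"]], q[["calinski_harabasz"]]))
  cat(sprintf("  one-year mortality range across clusters: %.3f\n",
              incidence_range(x$curves_death)))
  cat(sprintf("  one-year HF-hospitalisation range: %.3f\n",
              incidence_range(x$curves_hospitalisation)))
  cat(sprintf("  discriminative codes (spread >= %.2f): %d\n",
              x$config$min_spread, nrow(x$discriminative_codes)))
  invisible(x)
}

persist_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_delim(report$attrition, file.path(dir, "attrition.tsv"), delim = "\t")
  write_ps_curve(report$ps_curve, file.path(dir, "ps_curve.tsv"))
  readr::write_delim(report$labels, file.path(dir, "assignments.tsv"), delim = "\t")
  readr::write_delim(report$quality, file.path(dir, "quality.tsv"), delim = "\t")
  write_curves(report$curves_death, file.path(dir, "curves_death.tsv"))
  write_curves(report$curves_hospitalisation, file.path(dir, "curves_hosp.tsv"))
  readr::write_delim(as_tibble(report$prevalence), file.path(dir, "prevalence.tsv"), delim = "\t")
  readr::write_delim(report$discriminative_codes,
                     file.path(dir, "discriminative_codes.tsv"), delim = "\t")
  jsonlite::write_json(report_summary(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

report_summary <- function(report) {
  list(
    vectoriser = report$vectoriser,
    k = report$k,
    quality = as.list(setNames(report$quality$value, report$quality$metric)),
    cluster_sizes = as.list(setNames(report$cluster_sizes$n,
                                     paste0("cluster_", report$cluster_sizes$cluster))),
    mortality_range = incidence_range(report$curves_death),
    hospitalisation_range = incidence_range(report$curves_hospitalisation),
    n_discriminative_codes = nrow(report$discriminative_codes),
    audit = report$audit,
    seed = report$config$seed
  )
}

#' Write the canonical demo dataset and its headline digest
#'
#' Simulates the strong-signal preset, writes the patients/events/truth
#' files in the package's delimited format, runs the TF-IDF arm end to end,
#' and stores a JSON digest of the headline outputs (chosen k, quality,
#' incidence ranges) for regression checking.
#'
#' @param config A [synth_config()] (default: the preset).
#' @param dir Output directory.
#' @return Invisibly, the digest list.
#' @export
make_demo <- function(config = default_synth_config(), dir = "demo") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  write_cohort(sim$cohort, file.path(dir, "patients.csv"), file.path(dir, "events.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  report <- run_subtyping(sim$cohort,
                          run_config(vectoriser = "tfidf", seed = config$seed))
  digest <- report_summary(report)
  jsonlite::write_json(digest, file.path(dir, "digest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(digest)
}
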