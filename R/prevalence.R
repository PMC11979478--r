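#' Per-cluster prevalence of codes at index time
#'
#' For each code and cluster, the proportion of the cluster's patients with
#' at least one pre-index record of the code, plus the per-code prevalence
#' spread (most minus least prevalent cluster) used to pick discriminative
#' characteristics.
#'
#' @param cohort An `ehr_cohort`.
#' @param labels Tibble (patient_id, cluster) covering the cohort.
#' @param codes Code universe to tabulate (default: every code observed
#'   pre-index).
#' @return A `prevalence_matrix`: tibble with `code`, one prevalence column
#'   per cluster (`cluster_<j>`), and `spread`.
#' @export
prevalence_matrix <- function(cohort, labels, codes = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  labels <- as_tibble(labels)
  ev <- pre_index_events(cohort)
  codes <- codes %||% sort(unique(ev$code))
  carriers <- ev %>% filter(.data$code %in% codes) %>%
    distinct(.data$patient_id, .data$code) %>%
    left_join(labels, by = "patient_id")
  sizes <- labels %>% count(.data$cluster, name = "size")
  counts <- carriers %>% count(.data$code, .data$cluster, name = "carriers")
  grid <- tidyr::expand_grid(code = codes, cluster = sizes$cluster)
  prev <- grid %>%
    left_join(counts, by = c("code", "cluster")) %>%
    left_join(sizes, by = "cluster") %>%
    mutate(prevalence = dplyr::coalesce(.data$carriers, 0L) / .data$size)
  wide <- prev %>% select("code", "cluster", "prevalence") %>%
    tidyr::pivot_wider(names_from = "cluster", values_from = "prevalence",
                       names_prefix = "cluster_")
  prev_cols <- setdiff(names(wide), "code")
  m <- as.matrix(wide[, prev_cols])
  wide$spread <- apply(m, 1, max) - apply(m, 1, min)
  structure(wide, class = c("prevalence_matrix", class(wide)),
            clusters = sizes$cluster)
}

#' Select discriminative codes by prevalence spread
#'
#' Codes whose prevalence differs by at least `min_spread` between the most
#' and least prevalent clusters, ordered by decreasing spread (ties broken
#' lexicographically by code).
#'
#' @param pm A `prevalence_matrix`.
#' @param min_spread Minimum spread (default 0.30).
#' @return Tibble (code, spread), ordered.
#' @export
select_discriminative_codes <- function(pm, min_spread = 0.30) {
  sel <- as_tibble(pm) %>%
    filter(.data$spread >= min_spread) %>%
    arrange(dplyr::desc(.data$spread), .data$code) %>%
    select("code", "spread")
  sel
}
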