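#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted K-means model
#'
#' One row per cluster with its size (on the training vectors), within-
#' cluster sum of squares share, and centroid norm.
#'
#' @param x A `kmeans_model`.
#' @param ... Unused.
#' @return A tibble (cluster, size, centroid_norm).
#' @method tidy kmeans_model
#' @export
tidy.kmeans_model <- function(x, ...) {
  tibble(cluster = seq_len(x$k),
         size = as.integer(table(factor(x$labels, levels = seq_len(x$k)))),
         centroid_norm = sqrt(rowSums(x$centroids^2)))
}

#' One-row summary of a K-means model
#' @param x A `kmeans_model`.
#' @param ... Unused.
#' @return Tibble (k, inertia, n).
#' @method glance kmeans_model
#' @export
glance.kmeans_model <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, n = length(x$labels))
}

#' Tidy a prediction-strength curve (fold-level values)
#' @param x A `ps_curve`.
#' @param ... Unused.
#' @return Tibble (k, fold, ps).
#' @method tidy ps_curve
#' @export
tidy.ps_curve <- function(x, ...) as_tibble(x)

#' One row per candidate k with the fold-mean prediction strength
#' @param x A `ps_curve`.
#' @param ... Unused.
#' @return Tibble (k, mean_ps).
#' @method glance ps_curve
#' @export
glance.ps_curve <- function(x, ...) ps_means(x)

#' Tidy a prevalence matrix into long form
#' @param x A `prevalence_matrix`.
#' @param ... Unused.
#' @return Tibble (code, cluster, prevalence, spread).
#' @method tidy prevalence_matrix
#' @export
tidy.prevalence_matrix <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(dplyr::starts_with("cluster_"),
                        names_to = "cluster", values_to = "prevalence",
                        names_prefix = "cluster_") %>%
    select("code", "cluster", "prevalence", "spread")
}

#' Tidy a subtyping run report
#'
#' One row per cluster with size, one-year mortality and hospitalisation
#' incidence (with bands).
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy run_report
#' @export
tidy.run_report <- function(x, ...) {
  death <- horizon_incidence(x$curves_death) %>%
    rename(mortality = "incidence", mortality_lo = "ci_lo", mortality_hi = "ci_hi")
  hosp <- horizon_incidence(x$curves_hospitalisation) %>%
    select("cluster", hospitalisation = "incidence",
           hospitalisation_lo = "ci_lo", hospitalisation_hi = "ci_hi")
  left_join(death, hosp, by = "cluster")
}

#' One-row summary of a subtyping run
#' @param x A `run_report`.
#' @param ... Unused.
#' @return Tibble (vectoriser, k, silhouette, calinski_harabasz,
#'   mortality_range, hospitalisation_range).
#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  q <- setNames(x$quality$value, x$quality$metric)
  tibble(vectoriser = x$vectoriser, k = x$k,
         silhouette = q[["silhouette"]],
         calinski_harabasz = q[["calinski_harabasz"]],
         mortality_range = incidence_range(x$curves_death),
         hospitalisation_range = incidence_range(x$curves_hospitalisation))
}
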