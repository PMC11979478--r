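#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_ribbon geom_line
#'   geom_point geom_hline geom_tile labs theme_minimal scale_fill_gradient
#' @export
ggplot2::autoplot

#' Plot per-cluster cumulative-incidence curves
#'
#' Step curves of cumulative incidence by cluster with the confidence bands
#' as ribbons.
#'
#' @param object A `survival_curve_set` (or single `survival_curve`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot survival_curve_set
#' @export
autoplot.survival_curve_set <- function(object, ...) {
  df <- as_tibble(object)
  if (!"cluster" %in% names(df)) df$cluster <- 1L
  df$cluster <- factor(df$cluster)
  ggplot(df, aes(x = .data$time, y = .data$cuminc, colour = .data$cluster)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi, fill = .data$cluster),
                alpha = 0.15, colour = NA) +
    geom_step() +
    labs(x = "days since index", y = "cumulative incidence",
         title = attr(object, "outcome")) +
    theme_minimal()
}

#' @export
autoplot.survival_curve <- autoplot.survival_curve_set

#' Plot a prediction-strength curve
#'
#' Fold-level values as points, fold means as a line, with the selection
#' threshold drawn.
#'
#' @param object A `ps_curve`.
#' @param threshold Selection threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ps_curve
#' @export
autoplot.ps_curve <- function(object, threshold = 0.8, ...) {
  ggplot(as_tibble(object), aes(x = .data$k, y = .data$ps)) +
    geom_point(alpha = 0.5) +
    geom_line(data = ps_means(object), aes(y = .data$mean_ps)) +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = "number of clusters k", y = "prediction strength") +
    theme_minimal()
}

#' Heatmap of per-cluster code prevalence
#'
#' @param object A `prevalence_matrix`.
#' @param min_spread Show only codes with at least this spread (default 0:
#'   all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prevalence_matrix
#' @export
autoplot.prevalence_matrix <- function(object, min_spread = 0, ...) {
  long <- tidy.prevalence_matrix(object) %>% filter(.data$spread >= min_spread)
  ggplot(long, aes(x = .data$cluster, y = stats::reorder(.data$code, .data$spread),
                   fill = .data$prevalence)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = "cluster", y = NULL, fill = "prevalence") +
    theme_minimal()
}
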