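#' Cross-validated prediction strength over a range of cluster numbers
#'
#' Prediction strength asks how reproducibly a K-means solution co-clusters
#' pairs of patients across data subsets. For each cross-validation fold and
#' each candidate `k`, K-means is fitted independently on the training and
#' test parts; each test-side cluster contributes the proportion of its
#' unordered pairs that the training-side centroids also place together, and
#' the fold score is the minimum of those proportions (singleton test
#' clusters contribute 1, the vacuous-minimum convention). `ps(1) = 1` by
#' definition.
#'
#' @param vectors Matrix or `patient_vectors` (derivation cohort).
#' @param ks Candidate cluster numbers, a contiguous range starting at 1.
#' @param n_folds Cross-validation folds (default 5, >= 2).
#' @param seed Seed fixing fold membership and K-means restarts.
#' @param n_restarts K-means restarts per fit.
#' @return A `ps_curve`: tibble (k, fold, ps) with attribute `means`, a
#'   tibble (k, mean_ps).
#' @export
prediction_strength <- function(vectors, ks = 1:8, n_folds = 5L, seed = 1L,
                                n_restarts = 10L) {
  x <- as_vector_matrix(vectors)
  if (n_folds < 2) abort("`n_folds` must be >= 2")
  n <- nrow(x)
  folds <- with_seed(derive_seed(seed, "ps-folds"),
                     sample(rep_len(seq_len(n_folds), n)))
  min_test <- min(table(folds))
  if (max(ks) > min_test) {
    abort(sprintf("k = %d exceeds the smallest fold's test size (%d)", max(ks), min_test))
  }
  rows <- list()
  for (fold in seq_len(n_folds)) {
    test_idx <- which(folds == fold)
    train_idx <- which(folds != fold)
    for (k in ks) {
      if (k == 1) {
        ps <- 1
      } else {
        m_train <- fit_kmeans(x[train_idx, , drop = FALSE], k,
                              seed = derive_seed(seed, "ps", fold, k, "train"),
                              n_restarts = n_restarts)
        m_test <- fit_kmeans(x[test_idx, , drop = FALSE], k,
                             seed = derive_seed(seed, "ps", fold, k, "test"),
                             n_restarts = n_restarts)
        ps <- ps_fold_score(x[test_idx, , drop = FALSE], m_test$labels, m_train)
      }
      rows[[length(rows) + 1L]] <- tibble(k = k, fold = fold, ps = ps)
    }
  }
  curve <- bind_rows(rows)
  means <- curve %>% group_by(.data$k) %>%
    summarise(mean_ps = mean(.data$ps), .groups = "drop")
  structure(curve, class = c("ps_curve", class(curve)), means = means,
            n_folds = n_folds, seed = seed)
}

# minimum over test clusters of the co-assignment proportion under the
# training-side centroids
ps_fold_score <- function(test_x, test_labels, train_model) {
  train_assign <- assign_clusters(train_model, test_x)
  scores <- vapply(sort(unique(test_labels)), function(cl) {
    members <- which(test_labels == cl)
    m <- length(members)
    if (m < 2) return(1)   # singleton: vacuous minimum over zero pairs
    lab <- train_assign[members]
    same <- sum(choose(table(lab), 2))
    same / choose(m, 2)
  }, numeric(1))
  min(scores)
}

#' Fold-mean prediction-strength values
#' @param curve A `ps_curve`.
#' @return Tibble (k, mean_ps).
#' @export
ps_means <- function(curve) attr(curve, "means")

#' Select the number of clusters from a prediction-strength curve
#'
#' Returns the largest `k` whose fold-mean prediction strength is at least
#' `threshold`. If only `k = 1` qualifies, returns 1 with a warning.
#'
#' @param curve A `ps_curve`.
#' @param threshold Acceptance threshold (default 0.8).
#' @return Integer `k*`.
#' @export
select_optimal_k <- function(curve, threshold = 0.8) {
  means <- ps_means(curve)
  if (is.null(means) || !nrow(means)) abort("empty prediction-strength curve")
  ok <- means$k[means$mean_ps >= threshold]
  if (length(ok) == 0 || max(ok) == 1) {
    if (max(means$k) > 1) {
      warn("only k = 1 meets the prediction-strength threshold; the data show no reproducible cluster structure")
    }
    return(1L)
  }
  as.integer(max(ok))
}

#' Write a prediction-strength curve to a delimited file
#' @param curve A `ps_curve`.
#' @param path Output path.
#' @return Invisibly, the curve.
#' @export
write_ps_curve <- function(curve, path) {
  readr::write_delim(as_tibble(curve), path, delim = "\t")
  invisible(curve)
}
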