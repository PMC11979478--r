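#' Fit the TF-IDF weighting on a derivation cohort
#'
#' The baseline vectoriser treats each patient's pre-index code multiset as a
#' document. The inverse document frequency uses the smoothed form
#' `idf(code) = ln((1 + N) / (1 + df(code))) + 1`, where `N` is the number of
#' patients and `df` the number of patients carrying the code at least once;
#' the smoothing keeps every weight finite and at least 1.
#'
#' @param cohort The derivation `ehr_cohort`.
#' @return An `idf_table`: tibble (code, df, idf) with `attr(, "n_patients")`.
#' @export
fit_tfidf <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  n_pat <- nrow(cohort$patients)
  if (n_pat == 0) abort("cannot fit TF-IDF on an empty cohort")
  ev <- pre_index_events(cohort)
  df_tbl <- ev %>% distinct(.data$patient_id, .data$code) %>%
    count(.data$code, name = "df") %>% arrange(.data$code)
  df_tbl$idf <- log((1 + n_pat) / (1 + df_tbl$df)) + 1
  out <- structure(df_tbl, class = c("idf_table", class(df_tbl)))
  attr(out, "n_patients") <- n_pat
  out
}

#' Vectorise patients with fitted TF-IDF weights
#'
#' `entry(code) = tf * idf` with `tf` the raw within-patient pre-index count.
#' Codes unseen at fit time are dropped. With `normalise = TRUE` (default)
#' each vector is scaled to unit Euclidean norm; patients with no in-vocabulary
#' pre-index events keep a zero vector and are flagged, since a zero vector
#' cannot be normalised and should be excluded downstream.
#'
#' @param cohort An `ehr_cohort` (any split arm).
#' @param idf An `idf_table` from [fit_tfidf()].
#' @param normalise Scale vectors to unit norm (default TRUE).
#' @param patient_ids Optional subset of patients to vectorise.
#' @return A `patient_vectors` object: list with `matrix` (patients x codes),
#'   `patient_id`, `tag = "tfidf"`, and `zero_vector` (ids flagged as empty).
#' @export
vectorise_tfidf <- function(cohort, idf, normalise = TRUE, patient_ids = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(idf, "idf_table"))
  ids <- patient_ids %||% cohort$patients$patient_id
  ev <- pre_index_events(cohort)
  ev <- ev[ev$patient_id %in% ids & ev$code %in% idf$code, , drop = FALSE]
  m <- matrix(0, nrow = length(ids), ncol = nrow(idf),
              dimnames = list(ids, idf$code))
  if (nrow(ev)) {
    counts <- ev %>% count(.data$patient_id, .data$code, name = "tf")
    i <- match(counts$patient_id, ids)
    j <- match(counts$code, idf$code)
    m[cbind(i, j)] <- counts$tf * idf$idf[j]
  }
  norms <- sqrt(rowSums(m^2))
  zero <- ids[norms == 0]
  if (normalise) {
    nz <- norms > 0
    m[nz, ] <- m[nz, , drop = FALSE] / norms[nz]
  }
  if (length(zero)) {
    warn(sprintf("%d patient(s) have no in-vocabulary pre-index events (zero vector)",
                 length(zero)))
  }
  new_patient_vectors(m, ids, tag = "tfidf", zero_vector = zero)
}

new_patient_vectors <- function(matrix, patient_id, tag, zero_vector = character()) {
  rownames(matrix) <- patient_id
  structure(list(matrix = matrix, patient_id = patient_id, tag = tag,
                 zero_vector = zero_vector),
            class = "patient_vectors")
}

#' @export
print.patient_vectors <- function(x, ...) {
  cat(sprintf("<patient_vectors:%s> %d patients x %d dims\n",
              x$tag, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Tidy patient vectors into a long tibble
#'
#' @param x A `patient_vectors` object.
#' @param ... Unused.
#' @return Tibble with columns patient_id, dimension, value.
#' @method tidy patient_vectors
#' @export
tidy.patient_vectors <- function(x, ...) {
  dims <- colnames(x$matrix) %||% as.character(seq_len(ncol(x$matrix)))
  tibble(patient_id = rep(x$patient_id, each = ncol(x$matrix)),
         dimension = rep(dims, times = nrow(x$matrix)),
         value = as.vector(t(x$matrix)))
}

#' Write an IDF table to a delimited file
#' @param idf An `idf_table`.
#' @param path Output path.
#' @return Invisibly, the table.
#' @export
write_idf <- function(idf, path) {
  readr::write_delim(as_tibble(idf), path, delim = "\t")
  invisible(idf)
}
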