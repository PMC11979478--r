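# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps every stage of the pipeline on its own stream while staying a
# deterministic function of the one user-facing seed. Result is < 2^31.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Coerce patient-vector inputs (matrix or patient_vectors) to a plain matrix
# with patient ids as rownames.
as_vector_matrix <- function(x) {
  if (inherits(x, "patient_vectors")) x <- unclass_vectors(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("patient vectors must be a numeric matrix or a `patient_vectors` object")
  }
  x
}

unclass_vectors <- function(pv) {
  m <- pv$matrix
  rownames(m) <- pv$patient_id
  m
}

days_per_month <- 30.4375
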