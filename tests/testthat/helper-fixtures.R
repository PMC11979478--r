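# Shared fixtures and independent brute-force oracles.
# Oracles are written as plain double loops over definitions, deliberately
# independent of the package's implementations.

# Three-patient hand cohort: P1 has 3 pre-index events (two sharing a date)
# plus one post-index event; P2 has 1 pre-index event but only ~6 months of
# registration; P3 (age 30 at index) has none. One orphan event row (P9).
tiny_patients <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    sex = c("male", "female", "male"),
    birth_year = c(1950L, 1940L, 1985L),
    practice_id = c("G1", "G1", "G2"),
    registration_start = as.Date(c("2000-01-01", "2014-12-01", "2000-01-01")),
    index_date = as.Date(rep("2015-06-01", 3)),
    death_date = as.Date(c("2015-09-01", NA, NA))
  )
}

tiny_events <- function(with_orphan = FALSE) {
  ev <- tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P1", "P2"),
    date = as.Date(c("2014-01-10", "2014-01-10", "2014-05-05", "2015-07-01",
                     "2015-01-01")),
    code = c("A", "B", "A", "C", "A"),
    code_type = c("diagnosis", "diagnosis", "diagnosis", "diagnosis", "medication"),
    source = "primary_care"
  )
  if (with_orphan) {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      patient_id = "P9", date = as.Date("2014-01-01"), code = "Z",
      code_type = "diagnosis", source = "primary_care"))
  }
  ev
}

tiny_cohort <- function(with_orphan = FALSE) {
  ehr_cohort(tiny_patients(), tiny_events(with_orphan))
}

# well-separated 2-D blobs for clustering tests
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
    }))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, d, numeric(1), i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, d, numeric(1), i = i)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_ch <- function(x, labels) {
  n <- nrow(x); cl <- unique(labels); k <- length(cl)
  gm <- colMeans(x)
  trB <- 0; trW <- 0
  for (c in cl) {
    xc <- x[labels == c, , drop = FALSE]
    cm <- colMeans(xc)
    trB <- trB + nrow(xc) * sum((cm - gm)^2)
    for (i in seq_len(nrow(xc))) trW <- trW + sum((xc[i, ] - cm)^2)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

oracle_assign <- function(centroids, x) {
  vapply(seq_len(nrow(x)), function(i) {
    d2 <- vapply(seq_len(nrow(centroids)), function(j) sum((x[i, ] - centroids[j, ])^2),
                 numeric(1))
    which(d2 == min(d2))[1]   # lowest index on ties
  }, integer(1))
}

# prediction-strength fold score: min over test clusters of the pairwise
# co-assignment proportion under the training centroids
oracle_ps_fold <- function(test_x, test_labels, centroids) {
  train_lab <- oracle_assign(centroids, test_x)
  worst <- 1
  for (cl in unique(test_labels)) {
    members <- which(test_labels == cl)
    m <- length(members)
    if (m < 2) next
    same <- 0; total <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      total <- total + 1
      if (train_lab[members[i]] == train_lab[members[j]]) same <- same + 1
    }
    worst <- min(worst, same / total)
  }
  worst
}

# hand Kaplan-Meier (events-first ties), returns S(t) at each distinct event time
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  list(time = ts, surv = out)
}
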