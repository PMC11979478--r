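prevalence_fixture <- function() {
  # 2 clusters x 2 codes with hand-countable carriers:
  # cluster 1 = {P1, P2}: A carried by both, B by P1 only
  # cluster 2 = {P3, P4}: A by P3, B by neither
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    sex = "male", birth_year = 1950L, practice_id = "G1",
    registration_start = as.Date("2000-01-01"),
    index_date = as.Date("2015-06-01"), death_date = as.Date(NA))
  events <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3"),
    date = as.Date("2014-01-01"),
    code = c("A", "B", "A", "A"),
    code_type = "diagnosis", source = "primary_care")
  list(cohort = ehr_cohort(patients, events),
       labels = tibble::tibble(patient_id = c("P1", "P2", "P3", "P4"),
                               cluster = c(1L, 1L, 2L, 2L)))
}

test_that("prevalence entries equal hand counts and spreads follow", {
  fx <- prevalence_fixture()
  pm <- prevalence_matrix(fx$cohort, fx$labels)
  expect_equal(pm$cluster_1[pm$code == "A"], 1.0)
  expect_equal(pm$cluster_2[pm$code == "A"], 0.5)
  expect_equal(pm$cluster_1[pm$code == "B"], 0.5)
  expect_equal(pm$cluster_2[pm$code == "B"], 0.0)
  expect_equal(pm$spread, c(0.5, 0.5))
  # a code carried by everyone: row of 1s, spread 0
  fx2 <- fx
  fx2$cohort$events <- dplyr::bind_rows(
    fx2$cohort$events,
    tibble::tibble(patient_id = c("P1", "P2", "P3", "P4"),
                   date = as.Date("2014-06-01"), code = "EVERY",
                   code_type = "diagnosis", source = "primary_care"))
  pm2 <- prevalence_matrix(fx2$cohort, fx2$labels)
  expect_equal(unlist(pm2[pm2$code == "EVERY", c("cluster_1", "cluster_2", "spread")],
                      use.names = FALSE), c(1, 1, 0))
  # entries are proportions: carrier counts never exceed cluster sizes
  expect_true(all(pm2$cluster_1 <= 1 & pm2$cluster_2 <= 1 & pm2$spread <= 1))
})

test_that("the spread filter keeps exactly the codes at or above the cutoff, ordered", {
  pm <- tibble::tibble(code = c("low", "mid", "high", "tie_b", "tie_a"),
                       cluster_1 = c(0.25, 0.50, 0.90, 0.70, 0.70),
                       cluster_2 = c(0.05, 0.10, 0.10, 0.30, 0.30))
  pm$spread <- pm$cluster_1 - pm$cluster_2
  class(pm) <- c("prevalence_matrix", class(pm))
  sel <- select_discriminative_codes(pm, min_spread = 0.30)
  # {0.5, 0.1} -> 0.4 selected; {0.25, 0.05} -> 0.2 excluded; ties lexicographic
  expect_equal(sel$code, c("high", "mid", "tie_a", "tie_b"))
  expect_equal(sel$spread, c(0.8, 0.4, 0.4, 0.4))
  expect_false("low" %in% sel$code)
})

test_that("on the preset, truth-labelled clusters select the signature codes", {
  sim <- generate_cohort(default_synth_config(900, seed = 71))
  labels <- dplyr::rename(sim$truth, cluster = subtype_id)
  pm <- prevalence_matrix(sim$cohort, labels)
  sel <- select_discriminative_codes(pm, 0.30)
  signatures <- sprintf("S%d_%d", rep(1:3, each = 5), 1:5)
  expect_setequal(sel$code, signatures)
})

test_that("prevalent cases are excluded from post-index incidence risk sets", {
  sim <- simulate_cohort(default_synth_config(1200, seed = 72))
  labels <- dplyr::rename(sim$truth, cluster = subtype_id)
  curves <- post_index_incidence(sim$cohort, labels, "COND_HTN")
  rs <- attr(curves, "risk_set")
  # subtype 1 plants COND_HTN pre-index with probability 0.3 (0.05 elsewhere)
  frac1 <- rs$n_at_risk[rs$cluster == 1] / rs$n_total[rs$cluster == 1]
  se <- sqrt(0.3 * 0.7 / rs$n_total[rs$cluster == 1])
  expect_lt(abs(frac1 - 0.7), 3 * se)
  # exclusion rule: the risk set is exactly the non-carriers, per cluster
  pre <- hfsubtype:::pre_index_events(sim$cohort)
  carriers <- unique(pre$patient_id[pre$code == "COND_HTN"])
  keep <- setdiff(sim$cohort$patients$patient_id, carriers)
  expected_rs <- labels %>% dplyr::group_by(cluster) %>%
    dplyr::summarise(n_at_risk = sum(patient_id %in% keep), .groups = "drop")
  expect_equal(rs$n_at_risk, expected_rs$n_at_risk)
  expect_error(post_index_incidence(sim$cohort, labels, "NOT_A_CODE"), "NOT_A_CODE")
})

test_that("zero post-index hazard yields a flat zero incidence curve", {
  prof <- subtype_profile(1, "X1", visit_rate = 1,
                          death_hazard = 0, hospitalisation_hazard = 0,
                          comorbidity_hazards = c(CONDZ = 0),
                          pre_index_comorbidity_prob = c(CONDZ = 0.5))
  cfg <- synth_config(300, list(prof), background_codes = sprintf("B%02d", 1:5),
                      seed = 73)
  sim <- simulate_cohort(cfg)
  labels <- tibble::tibble(patient_id = sim$cohort$patients$patient_id, cluster = 1L)
  curves <- post_index_incidence(sim$cohort, labels, "CONDZ")
  expect_true(all(curves$cuminc == 0))
})
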