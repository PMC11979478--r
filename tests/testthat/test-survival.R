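test_that("the 4-subject worked example reproduces the hand KM estimate", {
  # events at days 10 and 20, censorings at 15 and 365
  curve <- km_cumulative_incidence(c(10, 15, 20, 365), c(1, 0, 1, 0))
  s20 <- curve$surv[curve$time == 20]
  expect_equal(s20, 0.375)                       # (3/4) * (1/2)
  expect_equal(curve$cuminc[curve$time == 20], 0.625)
  expect_error(km_cumulative_incidence(c(-1, 3), c(1, 1)), "negative")
  expect_error(km_cumulative_incidence(numeric(), integer()), "no subjects")
})

test_that("no events means zero cumulative incidence throughout", {
  curve <- km_cumulative_incidence(rep(400, 5), rep(1, 5), horizon = 365)
  expect_true(all(curve$cuminc == 0))
  expect_true(all(curve$ci_lo == 0 & curve$ci_hi == 0, na.rm = TRUE))
})

test_that("KM equals the empirical complementary CDF when nothing is censored", {
  for (seed in 1:5) {
    times <- withr::with_seed(seed, sample(1:300, 40, replace = TRUE))
    curve <- km_cumulative_incidence(times, rep(1, 40), horizon = 365)
    ecdf_t <- ecdf(times)
    for (t in unique(times)) {
      expect_equal(curve$cuminc[curve$time == t], ecdf_t(t), tolerance = 1e-12)
    }
  }
})

test_that("Greenwood exponential bands match hand arithmetic on the worked example", {
  curve <- km_cumulative_incidence(c(10, 15, 20, 365), c(1, 0, 1, 0))
  i <- which(curve$time == 20)
  # V(20) = 1/(4*3) + 1/(2*1); se = sqrt(V)/|ln S|; bounds S^exp(+/- z se)
  V <- 1 / 12 + 1 / 2
  se <- sqrt(V) / abs(log(0.375))
  z <- qnorm(0.975)
  lo_surv <- 0.375^exp(z * se)
  hi_surv <- 0.375^exp(-z * se)
  expect_equal(curve$ci_lo[i], 1 - hi_surv, tolerance = 1e-12)
  expect_equal(curve$ci_hi[i], 1 - lo_surv, tolerance = 1e-12)
  # agreement with the survival package's log-log intervals
  fit <- survival::survfit(survival::Surv(c(10, 15, 20, 365), c(1, 0, 1, 0)) ~ 1,
                           conf.type = "log-log")
  expect_equal(curve$ci_lo[i], 1 - fit$upper[fit$time == 20], tolerance = 1e-9)
  expect_equal(curve$ci_hi[i], 1 - fit$lower[fit$time == 20], tolerance = 1e-9)
})

test_that("bands collapse to the estimate before any event and stay inside [0, 1]", {
  curve <- km_cumulative_incidence(c(50, 100, 200, 300), c(0, 0, 1, 1))
  pre <- curve$time < 200
  expect_true(all(curve$ci_lo[pre] == curve$cuminc[pre]))
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(5:40, 1)
      times <- sample(1:400, n, replace = TRUE)
      events <- rbinom(n, 1, 0.7)
    })
    curve <- km_cumulative_incidence(times, events)
    ok <- !is.na(curve$ci_lo)
    expect_true(all(curve$ci_lo[ok] >= 0 & curve$ci_hi[ok] <= 1))
    expect_true(all(curve$ci_lo[ok] <= curve$cuminc[ok] &
                      curve$cuminc[ok] <= curve$ci_hi[ok]))
  }
})

test_that("per-cluster curves separate planted hazards and collapse under the null", {
  # two planted hazards 0.1 vs 0.6 per year
  profs <- list(
    subtype_profile(1, "X1", visit_rate = 1, death_hazard = 0.1,
                    hospitalisation_hazard = 0),
    subtype_profile(2, "Y1", visit_rate = 1, death_hazard = 0.6,
                    hospitalisation_hazard = 0))
  cfg <- synth_config(4000, profs, background_codes = sprintf("B%02d", 1:10),
                      seed = 61)
  sim <- simulate_cohort(cfg)
  labels <- dplyr::rename(sim$truth, cluster = subtype_id)
  curves <- per_cluster_curves(sim$cohort, labels, "death")
  expected_range <- (1 - exp(-0.6)) - (1 - exp(-0.1))
  n_cl <- min(table(labels$cluster))
  se <- sqrt(0.25 / n_cl) * sqrt(2)
  expect_lt(abs(incidence_range(curves) - expected_range), 3 * se)

  # single cluster: range 0 by definition
  one <- per_cluster_curves(sim$cohort,
                            dplyr::mutate(labels, cluster = 1L), "death")
  expect_equal(incidence_range(one), 0)

  # shared hazard: range shrinks towards 0
  cfg_null <- synth_config(4000, list(
    subtype_profile(1, "X1", visit_rate = 1, death_hazard = 0.3,
                    hospitalisation_hazard = 0),
    subtype_profile(2, "Y1", visit_rate = 1, death_hazard = 0.3,
                    hospitalisation_hazard = 0)), seed = 62,
    background_codes = sprintf("B%02d", 1:10))
  sim_null <- simulate_cohort(cfg_null)
  null_curves <- per_cluster_curves(sim_null$cohort,
                                    dplyr::rename(sim_null$truth,
                                                  cluster = subtype_id), "death")
  expect_lt(incidence_range(null_curves), 0.05)
})

test_that("death censors the hospitalisation analysis at the death date", {
  p <- tiny_patients()[1, ]                     # dies day 92 after index
  ev <- tibble::tibble(patient_id = "P1", date = p$index_date + 200,
                       code = "HF_HOSP", code_type = "diagnosis",
                       source = "secondary_care")
  cohort <- ehr_cohort(p, ev)
  tt <- hfsubtype:::outcome_times(cohort, "hf_hospitalisation", 365)
  expect_equal(tt$event, 0L)                    # hospitalisation after death: censored
  expect_equal(tt$time, as.numeric(p$death_date - p$index_date))
})
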