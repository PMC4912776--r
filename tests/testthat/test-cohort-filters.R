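test_that("early samples are dropped with an inclusive 12 h boundary", {
  cfg <- filter_config()
  s <- make_series(c(6, 18, 30), c(0.9, 0.8, 0.6))
  expect_equal(drop_early_samples(s, cfg)$time_h, c(18, 30))
  s2 <- make_series(c(12, 24), c(0.9, 0.7))
  expect_equal(nrow(drop_early_samples(s2, cfg)), 2L)
  s3 <- make_series(c(4, 8, 11.9), c(0.9, 0.8, 0.7))
  expect_equal(nrow(drop_early_samples(s3, cfg)), 0L)
})

test_that("secondary-peak rule flags post-peak rises above 0.05 ug/L per 12 h", {
  cfg <- filter_config()
  # rising series whose last interval straddles the expected peak
  rising <- make_series(c(12, 24, 36), c(0.50, 0.60, 0.68))
  res <- detect_secondary_peak(rising, cfg)
  expect_true(res$flagged)
  expect_equal(res$rate, 0.08, tolerance = 1e-12)
  expect_equal(c(res$from_h, res$to_h), c(24, 36))
  # monotone decay never flags
  falling <- make_series(c(18, 30, 42, 54), c(1.2, 0.9, 0.7, 0.6))
  expect_false(detect_secondary_peak(falling, cfg)$flagged)
  # the inequality is strict: a rise exactly at threshold passes
  # (binary-exact values so the comparison is a true tie)
  cfg_tie <- filter_config(secondary_peak_threshold = 0.0625)
  exact <- make_series(c(18, 30, 42), c(1.0, 0.5, 0.5625))
  expect_false(detect_secondary_peak(exact, cfg_tie)$flagged)
  expect_true(detect_secondary_peak(
    make_series(c(18, 30, 42), c(1.0, 0.5, 0.564)), cfg_tie)$flagged)
  just_over <- make_series(c(18, 30, 42), c(1.0, 0.60, 0.651))
  expect_true(detect_secondary_peak(just_over, cfg)$flagged)
  # rises wholly before the expected peak are wash-in, not secondary injury
  washin <- make_series(c(13, 20), c(0.40, 0.55))
  expect_false(detect_secondary_peak(washin, cfg)$flagged)
  # a single post-peak sample cannot be assessed
  expect_false(detect_secondary_peak(make_series(30, 0.7), cfg)$flagged)
})

test_that("filters apply in order and record one reason per excluded patient", {
  cfg <- filter_config(manual_exclusions = "PM")
  cohort <- rbind(
    make_series(c(14, 26, 38, 50), c(0.8, 0.9, 0.7, 0.6), "OK1"),
    make_series(c(8, 16, 28), c(1.0, 0.9, 0.8), "FEW"),    # 2 left after cut
    make_series(c(50, 62, 74), c(0.8, 0.7, 0.6), "LATE"),
    make_series(c(5, 14, 26, 38), c(1.2, 0.8, 0.9, 0.7), "OK2"),
    make_series(c(14, 26, 38, 50), c(0.8, 0.9, 0.7, 0.9), "SEC"),
    make_series(c(14, 26, 38), c(0.8, 0.7, 0.6), "PM")
  )
  res <- apply_cohort_filters(cohort, cfg)
  reasons <- setNames(res$exclusions$reason, res$exclusions$patient_id)
  expect_equal(reasons[["FEW"]], "too_few_samples")
  expect_equal(reasons[["LATE"]], "late_start")
  expect_equal(reasons[["SEC"]], "secondary_peak")
  expect_equal(reasons[["PM"]], "manual")
  expect_setequal(unique(res$included$patient_id), c("OK1", "OK2"))
  # early samples of included patients are gone
  expect_true(all(res$included$time_h >= 12))
  # a patient with no sample at/after the cutoff is a late start
  res2 <- apply_cohort_filters(make_series(c(4, 8, 11), c(1, 0.9, 0.8), "E"),
                               cfg)
  expect_equal(res2$exclusions$reason, "late_start")
})

test_that("included and excluded patients partition the cohort; filtering is idempotent", {
  sim <- simulate_cohort(simulation_config(
    n_patients = 40, contamination_rate = 0.15, seed = 51
  ))
  res <- apply_cohort_filters(sim$cohort)
  inc <- unique(res$included$patient_id)
  exc <- res$exclusions$patient_id
  expect_length(intersect(inc, exc), 0)
  expect_setequal(c(inc, exc), unique(sim$cohort$patient_id))
  expect_false(anyDuplicated(exc) > 0)
  # re-filtering the included output excludes no one
  res2 <- apply_cohort_filters(res$included)
  expect_equal(nrow(res2$exclusions), 0L)
  expect_equal(res2$included, res$included)
})

test_that("noise-free on-model cohorts are never flagged for secondary peaks", {
  sim <- simulate_cohort(simulation_config(
    n_patients = 60, noise_sd_log = 0, seed = 52
  ))
  res <- apply_cohort_filters(sim$cohort)
  expect_equal(nrow(res$exclusions), 0L)
  expect_equal(length(unique(res$included$patient_id)), 60L)
})

test_that("noise-free contamination is excluded exactly per the truth table", {
  sim <- simulate_cohort(simulation_config(
    n_patients = 100, contamination_rate = 0.1, noise_sd_log = 0, seed = 53
  ))
  expect_gt(sum(sim$truth$contaminated), 0)
  res <- apply_cohort_filters(sim$cohort)
  flagged <- res$exclusions$patient_id[res$exclusions$reason == "secondary_peak"]
  expect_setequal(flagged, sim$truth$patient_id[sim$truth$contaminated])
  expect_equal(nrow(res$exclusions), length(flagged))
})
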