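test_that("series on the anchored curve are consistent; degenerate inputs are not assessed", {
  kin <- ref_kinetics()
  cfg <- monitor_config(noise_sd_log = 0)
  t_h <- c(14, 26, 38, 52, 64)
  y <- gamma_variate(t_h / 24, 0.8, kin)
  v <- monitor_series(make_series(t_h, y), kin, cfg)
  expect_equal(v$status, "consistent")
  expect_true(is.na(v$first_deviation_time_h))
  expect_equal(v$evidence$observed, y)
  # single sample
  v1 <- monitor_series(make_series(30, 0.8), kin, cfg)
  expect_equal(v1$status, "insufficient_data")
  # first sample at the baseline cannot anchor an amplitude
  v2 <- monitor_series(make_series(c(14, 26), c(0.11, 0.5)), kin, cfg)
  expect_equal(v2$status, "insufficient_data")
  expect_match(v2$notes, "anchor")
})

test_that("noise-free on-model series are never flagged (specificity 1)", {
  sim <- simulate_cohort(simulation_config(n_patients = 200,
                                           noise_sd_log = 0, seed = 310))
  verdicts <- monitor_cohort(sim$cohort, sim$kinetics,
                             monitor_config(noise_sd_log = 0))
  expect_true(all(verdicts$status == "consistent"))
})

test_that("false-flag rate at default noise stays below 10 %", {
  sim <- simulate_cohort(simulation_config(n_patients = 200, seed = 311))
  verdicts <- monitor_cohort(sim$cohort, sim$kinetics, monitor_config())
  flagged <- mean(verdicts$status == "secondary_injury_suspected")
  expect_lt(flagged, 0.10)
})

test_that("an injected secondary bump is detected near its onset", {
  cfg_sim <- simulation_config(n_patients = 30, contamination_rate = 1,
                               noise_sd_log = 0, seed = 312)
  sim <- simulate_cohort(cfg_sim)
  mc <- monitor_config(noise_sd_log = 0)
  verdicts <- monitor_cohort(sim$cohort, sim$kinetics, mc)
  # detected iff the sampling actually covers the elevation window
  hit <- verdicts$status == "secondary_injury_suspected"
  expect_equal(verdicts$patient_id[hit],
               sim$truth$patient_id[sim$truth$contaminated])
  expect_gt(sum(hit), 20)
  # deviation localised to the bump window (onset 48 h, one interval wide)
  dev_t <- verdicts$first_deviation_time_h[hit]
  expect_true(all(dev_t >= 40))
  expect_true(all(dev_t <= 66))
})

test_that("sensitivity is monotone in the bump height", {
  kin <- ref_kinetics()
  mc <- monitor_config(noise_sd_log = 0)
  t_h <- seq(14, 86, by = 12)
  base <- gamma_variate(t_h / 24, 1, kin)
  bump_at <- which(t_h >= 48)[1]
  flagged_at <- function(h) {
    y <- base
    y[bump_at] <- y[bump_at] + h
    v <- monitor_series(make_series(t_h, y), kin, mc)
    v$status == "secondary_injury_suspected"
  }
  heights <- seq(0, 0.6, by = 0.05)
  flags <- vapply(heights, flagged_at, TRUE)
  expect_false(flags[1])
  expect_true(any(flags))
  # once flagged, enlarging the bump never unflags
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("posterior draws serve as the monitoring reference", {
  clean <- get_clean_fit()
  fit <- clean$fit
  kin <- ref_kinetics()
  t_h <- c(14, 26, 38, 52, 64)
  on_model <- gamma_variate(t_h / 24, 0.9, kin)
  v_ok <- monitor_series(make_series(t_h, on_model), fit, monitor_config())
  expect_equal(v_ok$status, "consistent")
  y_bump <- on_model
  y_bump[4] <- y_bump[4] + 0.3
  v_bad <- monitor_series(make_series(t_h, y_bump), fit, monitor_config())
  expect_equal(v_bad$status, "secondary_injury_suspected")
  expect_equal(v_bad$first_deviation_time_h, 52)
})
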