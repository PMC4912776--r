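test_that("posterior summaries match direct quantile computation", {
  # constant draws: degenerate summary
  const <- coda::mcmc.list(coda::mcmc(matrix(2.5, 100, 1,
                                             dimnames = list(NULL, "theta"))),
                           coda::mcmc(matrix(2.5, 100, 1,
                                             dimnames = list(NULL, "theta"))))
  s <- posterior_summary(const)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)
  expect_equal(c(s$q2.5, s$q97.5), c(2.5, 2.5))
  # large normal sample: equal-tailed interval near +/- 1.96
  withr::with_seed(101, {
    z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  })
  sz <- posterior_summary(coda::mcmc.list(coda::mcmc(z[1:50000, , drop = FALSE]),
                                          coda::mcmc(z[50001:1e5, , drop = FALSE])))
  expect_equal(sz$q2.5, qnorm(0.025), tolerance = 0.03)
  expect_equal(sz$q97.5, qnorm(0.975), tolerance = 0.03)
})

test_that("the peak-time summary is the summary of the per-draw product", {
  fit <- get_clean_fit()$fit
  m <- as.matrix(fit$draws)
  s <- posterior_summary(fit)
  tp <- s[s$parameter == "t_peak_h", ]
  expect_equal(tp$mean, mean(24 * m[, "alpha"] * m[, "beta"]))
  expect_equal(tp$sd, sd(24 * m[, "alpha"] * m[, "beta"]))
  expect_equal(tp$q2.5,
               unname(quantile(24 * m[, "alpha"] * m[, "beta"], 0.025)))
})

test_that("split-Rhat and ESS separate mixed from unmixed chains", {
  withr::with_seed(103, {
    good <- coda::mcmc.list(lapply(1:3, function(i) {
      coda::mcmc(matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x")))
    }))
    bad <- coda::mcmc.list(
      coda::mcmc(matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))),
      coda::mcmc(matrix(rnorm(2000, mean = 5), ncol = 1,
                        dimnames = list(NULL, "x"))))
  })
  dg <- convergence_diagnostics(good)
  expect_true(dg$pass)
  expect_lt(dg$parameters$rhat, 1.05)
  expect_gt(dg$parameters$ess, 400)
  db <- convergence_diagnostics(bad)
  expect_false(db$pass)
  expect_gt(db$parameters$rhat, 2)
  expect_error(convergence_diagnostics(coda::mcmc.list(good[[1]])),
               "at least 2 chains")
})

test_that("split-Rhat is stable under thinning", {
  # slowly mixing AR(1) chains with distinct starts
  withr::with_seed(107, {
    chains <- lapply(c(-1, 1), function(mu0) {
      x <- numeric(4000); x[1] <- mu0
      for (i in 2:4000) x[i] <- 0.9 * x[i - 1] + rnorm(1, sd = sqrt(1 - 0.81))
      x
    })
  })
  full <- coda::mcmc.list(lapply(chains, function(x)
    coda::mcmc(matrix(x, ncol = 1, dimnames = list(NULL, "x")))))
  thinned <- coda::mcmc.list(lapply(chains, function(x)
    coda::mcmc(matrix(x[seq(1, 4000, by = 4)], ncol = 1,
                      dimnames = list(NULL, "x")))))
  r_full <- convergence_diagnostics(full)$parameters$rhat
  r_thin <- convergence_diagnostics(thinned)$parameters$rhat
  expect_equal(r_full, r_thin, tolerance = 0.05)
})

test_that("fitting low-noise data recovers the generating parameters", {
  # at 1 % observation noise the finite-sample wobble of the estimates is
  # itself a few percent; recovery is asserted at that scale
  clean <- get_clean_fit()
  s <- posterior_summary(clean$fit)
  est <- setNames(s$mean, s$parameter)
  expect_equal(est[["alpha"]], 0.69, tolerance = 0.05)
  expect_equal(est[["beta"]], 1.65, tolerance = 0.05)
  expect_equal(est[["B"]], 0.11, tolerance = 0.05)
  expect_equal(est[["t_peak_h"]], 27.324, tolerance = 0.05)
  # the observation-noise scale itself is recovered
  expect_equal(est[["sigma"]], 0.01, tolerance = 0.2)
  # per-patient amplitudes are pinned by the data in this limit
  amp_hat <- colMeans(as.matrix(clean$fit$amplitude_draws))
  expect_equal(unname(amp_hat), clean$sim$truth$amplitude, tolerance = 0.05)
})

test_that("sampling is deterministic given cohort, config and seed", {
  sim <- simulate_cohort(simulation_config(n_patients = 8, seed = 41))
  cfg <- inference_config(n_chains = 2, n_iterations = 700, n_burnin = 200,
                          n_adapt = 200, seed = 42)
  f1 <- suppressWarnings(fit_model(sim, cfg))
  f2 <- suppressWarnings(fit_model(sim, cfg))
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
  f3 <- suppressWarnings(fit_model(sim, inference_config(
    n_chains = 2, n_iterations = 700, n_burnin = 200, n_adapt = 200,
    seed = 43)))
  expect_false(identical(as.matrix(f1$draws), as.matrix(f3$draws)))
})

test_that("both parameterizations agree on the peak time posterior", {
  sim <- simulate_cohort(simulation_config(n_patients = 40, seed = 47))
  base <- inference_config(n_chains = 2, n_iterations = 3500, n_burnin = 1000,
                           n_adapt = 600, seed = 48)
  alt <- base
  alt$parameterization <- "alpha_tpeak"
  f_ab <- suppressWarnings(fit_model(sim, base))
  f_tp <- suppressWarnings(fit_model(sim, alt))
  tp_ab <- posterior_summary(f_ab)
  tp_tp <- posterior_summary(f_tp)
  m_ab <- tp_ab$mean[tp_ab$parameter == "t_peak_h"]
  m_tp <- tp_tp$mean[tp_tp$parameter == "t_peak_h"]
  expect_equal(m_ab, m_tp, tolerance = 0.1)
})

test_that("degenerate posteriors give a zero-width band equal to the curve", {
  kin <- ref_kinetics()
  n <- 50
  m <- cbind(alpha = rep(kin$alpha, n), beta = rep(kin$beta, n),
             B = rep(kin$baseline, n), sigma = rep(0.1, n))
  amp <- matrix(1.3, n, 2, dimnames = list(NULL, c("A[1]", "A[2]")))
  fake <- structure(
    list(draws = coda::mcmc.list(coda::mcmc(m)),
         amplitude_draws = coda::mcmc.list(coda::mcmc(amp)),
         patient_ids = c("a", "b")),
    class = "s100b_fit")
  band <- posterior_prediction_band(fake, times_h = seq(12, 240, by = 4))
  curve <- gamma_variate(band$time_h / 24, 1.3, kin)
  expect_equal(band$mean, curve, tolerance = 1e-12)
  expect_equal(band$lo2.5, curve, tolerance = 1e-12)
  expect_equal(band$hi97.5, curve, tolerance = 1e-12)
  # far tail concentrates at the baseline
  tail_band <- posterior_prediction_band(fake, times_h = c(700, 800))
  expect_equal(tail_band$mean, rep(kin$baseline, 2), tolerance = 1e-3)
})

test_that("band maximum sits at the posterior mean peak time", {
  fit <- get_clean_fit()$fit
  band <- posterior_prediction_band(fit, times_h = seq(12, 72, by = 1))
  s <- posterior_summary(fit)
  tp_hat <- s$mean[s$parameter == "t_peak_h"]
  expect_lt(abs(band$time_h[which.max(band$mean)] - tp_hat), 1.5)
})

test_that("degenerate cohorts and invalid data are refused", {
  one <- make_series(c(14, 26, 38), c(0.9, 0.8, 0.6), "solo")
  expect_error(fit_model(one), "at least 2 patients")
  zero <- rbind(make_series(c(14, 26), c(0, 0.8), "a"),
                make_series(c(14, 26), c(0.9, 0.8), "b"))
  expect_error(fit_model(zero), "strictly positive")
  early <- rbind(make_series(c(6, 26, 38), c(0.9, 0.8, 0.7), "a"),
                 make_series(c(14, 26), c(0.9, 0.8), "b"))
  cfg <- inference_config(n_chains = 2, n_iterations = 220, n_burnin = 20,
                          n_adapt = 100, seed = 1)
  w <- capture_warnings(fit_model(early, cfg))
  expect_true(any(grepl("earlier than 12 h", w)))
})
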