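# Reference posterior-mean kinetics used throughout the tests.
ref_kinetics <- function() population_kinetics(0.69, 1.65, 0.11)

make_series <- function(time_h, conc, id = "X") {
  data.frame(patient_id = id, time_h = time_h, s100b_ugL = conc,
             stringsAsFactors = FALSE)
}

# Small-but-informative fit shared across inference/monitor tests: 15
# patients at near-zero observation noise, short chains. Cached so the
# sampler runs once per suite.
.fit_cache <- new.env(parent = emptyenv())
get_clean_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    sim <- simulate_cohort(simulation_config(
      n_patients = 15, noise_sd_log = 0.01, seed = 90
    ))
    .fit_cache$sim <- sim
    # short desk-scale chains: the ESS>400 rule may warn, which is expected
    .fit_cache$fit <- suppressWarnings(fit_model(sim, inference_config(
      n_chains = 2, n_iterations = 2600, n_burnin = 600, n_adapt = 600,
      seed = 91
    )))
  }
  list(sim = .fit_cache$sim, fit = .fit_cache$fit)
}

# Per-patient least-squares amplitude given known kinetics: the exact
# identification check for noise-free data.
ls_amplitude <- function(series, kinetics) {
  t_d <- series$time_h / 24
  f <- t_d^kinetics$alpha * exp(-t_d / kinetics$beta)
  sum(f * (series$s100b_ugL - kinetics$baseline)) / sum(f^2)
}
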