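# Builds the JAGS model specification for the hierarchical gamma-variate
# model. Time enters in days; positivity of alpha, beta, B, A_i and sigma is
# enforced by truncation or by the prior's support.
jags_model_string <- function(config) {
  likelihood <- switch(config$likelihood,
    lognormal = "    y[k] ~ dlnorm(log(mu[k]), tau)",
    gaussian  = "    y[k] ~ dnorm(mu[k], tau)"
  )
  amplitude <- switch(config$amplitude_prior,
    hierarchical = sprintf(
      "  for (i in 1:P) { A[i] ~ dlnorm(muA, tauA) }
  muA ~ dnorm(0, %g)
  tauA <- pow(sdA, -2)
  sdA ~ dnorm(0, %g) T(0,)",
      config$hyper_mu_sd^-2, config$hyper_sd_scale^-2),
    independent = sprintf(
      "  for (i in 1:P) { A[i] ~ dnorm(0, %g) T(0,) }",
      config$prior_scale_amplitude^-2)
  )
  shape <- switch(config$parameterization,
    alpha_beta = sprintf(
      "  alpha ~ dnorm(0, %g) T(0,)
  beta ~ dnorm(0, %g) T(0,)",
      config$prior_scale_alpha^-2, config$prior_scale_beta^-2),
    alpha_tpeak = sprintf(
      "  alpha ~ dnorm(0, %g) T(0,)
  tp ~ dgamma(%g, %g)
  beta <- tp / alpha",
      config$prior_scale_alpha^-2,
      config$tpeak_gamma_shape, config$tpeak_gamma_rate)
  )
  sprintf(
    "model {
  for (k in 1:N) {
    mu[k] <- A[pid[k]] * pow(t[k], alpha) * exp(-t[k] / beta) + B
%s
  }
%s
%s
  B ~ dgamma(%g, %g)
  tau <- pow(sigma, -2)
  sigma ~ dnorm(0, %g) T(0,)
}",
    likelihood, amplitude, shape,
    config$baseline_gamma_shape, config$baseline_gamma_rate,
    config$sigma_scale^-2)
}

# Deterministic per-chain initial values. Chains start at alpha = beta = 1 d
# (scaled by a per-chain spread so R-hat is meaningful) with amplitudes at
# the peak-value heuristic (max observed minus baseline guess, rescaled by
# the curve's peak factor e^{alpha0} (alpha0 beta0)^{-alpha0} at the
# starting shape).
jags_inits <- function(config, y, pid, n_patients) {
  b_init <- max(min(y) * 0.5, 0.01)
  a_heur <- as.numeric(tapply(y, pid, max)) - b_init
  a_heur <- pmax(a_heur, 0.05) * exp(1)
  spread <- rep(c(0.7, 1.0, 1.4, 0.85, 1.2), length.out = config$n_chains)
  lapply(seq_len(config$n_chains), function(ch) {
    init <- list(
      alpha = 1 * spread[ch],
      B = b_init,
      sigma = if (config$likelihood == "lognormal") 0.2 else 0.1,
      A = a_heur,
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = ((as.numeric(config$seed) %% 1e5) * 1009 + 101 * ch) %%
        2147483647
    )
    if (config$parameterization == "alpha_beta") {
      init$beta <- 1 * spread[config$n_chains + 1L - ch]
    } else {
      init$tp <- 1.1 * spread[config$n_chains + 1L - ch]
    }
    if (config$amplitude_prior == "hierarchical") {
      init$muA <- log(stats::median(a_heur))
      init$sdA <- 0.5
    }
    init
  })
}
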