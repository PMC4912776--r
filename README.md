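# s100kinetics

Hierarchical Bayesian gamma-variate kinetics of serum S100B after
traumatic brain injury (TBI).

Serum S100B, an astrocyte-associated calcium-binding protein, is the most
widely used blood biomarker of brain injury, yet its concentration changes
so quickly in the first days after trauma that two samples drawn a few
hours apart can tell very different stories. This package is for
biostatisticians and neurocritical-care researchers who want to model that
temporal course explicitly: it fits a population kinetic curve to
irregularly timed serial measurements, quantifies the uncertainty of the
peak time and baseline, and turns the fitted curve into practical tools —
time-standardised comparison of measurements, trajectory normalisation,
and prospective screening of serial samples for deviations suggestive of
secondary injury.

## The model

The serum concentration of patient *i* at time *t* (days since trauma) is
modelled as a gamma-variate wash-in/wash-out curve,

    S_i(t) = A_i · t^α · exp(−t/β) + B

where `A_i` is a patient-specific amplitude (insult severity), `α` is a
dimensionless shape parameter (the number of theoretical mixing chambers
of the release–elimination cascade), `β` a time scale in days
(chamber volume-to-flow ratio), and `B` the population baseline in µg/L.
The curve peaks at `t_peak = α·β`; with `α = 0` it collapses to pure
exponential elimination. Patient amplitudes follow a lognormal population
law, observations carry multiplicative lognormal error, and the joint
posterior of `{α, β, B, σ, A_1…A_n}` is sampled by MCMC (JAGS via rjags)
under vague positivity-constrained priors. Derived clinical quantities —
time to peak, peak height `A(αβ)^α e^{−α} + B`, and the area under the
baseline-subtracted curve `A β^(α+1) Γ(α+1)` — are closed-form.

Cohort construction follows the clinical rules: samples earlier than 12 h
post trauma are discarded (extracranial S100B confounding), patients need
at least 3 samples starting within 48 h of trauma, and a post-peak rise
greater than 0.05 µg/L per 12 h excludes a patient as a suspected
secondary injury.

## Worked example

Fit the model to a synthetic 80-patient cohort generated at the reference
kinetics (α = 0.69, β = 1.65 d, B = 0.11 µg/L):

```r
library(s100kinetics)

sim <- simulate_cohort(simulation_config(n_patients = 80, seed = 7))
fit <- fit_model(sim, inference_config(
  n_chains = 3, n_iterations = 6000, n_burnin = 1000, seed = 7))
summary(fit)
#>   parameter   mean      sd    q2.5   q97.5
#> 1         B  0.114 0.0129  0.0875   0.138
#> 2     alpha  0.612 0.0847  0.4476   0.774
#> 3      beta  1.664 0.1279  1.4543   1.949
#> 6     sigma  0.155 0.0055  0.1451   0.167
#> 7  t_peak_h 24.213 1.8297 20.3355  27.468
```

The 95 % credible intervals cover the generating truth; the peak-time row
is summarised from the per-draw product `24·α·β`, in hours. The
parameter-uncertainty band around the population curve:

```r
round(posterior_prediction_band(fit, times_h = seq(12, 96, by = 12)), 3)
#>   time_h  mean lo2.5 hi97.5
#> 1     12 0.699 0.638  0.767
#> 2     24 0.774 0.744  0.805
#> 3     36 0.739 0.722  0.757
#> 4     48 0.665 0.651  0.679
#> ...
```

Exclusion filtering and bedside monitoring, shown on a noise-free cohort
with 10 % of patients given an injected post-peak rise:

```r
sim2 <- simulate_cohort(simulation_config(n_patients = 80, noise_sd_log = 0,
                                          contamination_rate = 0.1, seed = 8))
flt <- apply_cohort_filters(sim2$cohort)
table(flt$exclusions$reason)
#> secondary_peak
#>             11     # exactly the contaminated patients of the truth table

first_bad <- sim2$truth$patient_id[sim2$truth$contaminated][1]
monitor_series(sim2$cohort[sim2$cohort$patient_id == first_bad, ],
               fit, monitor_config(noise_sd_log = 0))
#> Deviation monitor (P0006): secondary_injury_suspected
#>   first deviation at 48.7 h post trauma
```

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) sequences
all of the above — filtering, fitting, summaries, band, per-patient
alignment and monitoring — and writes a seed-stamped CSV bundle.

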