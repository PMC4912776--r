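#' Population kinetic parameters of the gamma-variate model
#'
#' Container for the population-level parameters of the serum S100B kinetic
#' model
#' \deqn{S_i(t) = A_i t^{\alpha} e^{-t/\beta} + B,}
#' where \eqn{t} is time since trauma in days, \eqn{A_i} is a patient-specific
#' amplitude, and the population parameters are the shape \eqn{\alpha}
#' (dimensionless, related to the number of theoretical mixing chambers of the
#' wash-in/wash-out process), the time scale \eqn{\beta} (days, mixing-chamber
#' volume-to-flow ratio), and the baseline physiological concentration
#' \eqn{B} (\eqn{\mu}g/L).
#'
#' Time is measured in days internally; all user-facing reports (e.g.
#' [time_to_peak()]) are in hours since trauma. With \eqn{\alpha = 0} the
#' curve reduces to exponential elimination with rate constant \eqn{1/\beta}.
#'
#' @param alpha Dimensionless shape parameter, `>= 0`.
#' @param beta Time scale in days, `> 0`.
#' @param baseline Baseline serum concentration in \eqn{\mu}g/L, `>= 0`.
#'
#' @return An object of class `population_kinetics`.
#' @examples
#' kin <- population_kinetics(alpha = 0.69, beta = 1.65, baseline = 0.11)
#' time_to_peak(kin)  # hours
#' @export
population_kinetics <- function(alpha, beta, baseline) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0,
    is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0,
    is.numeric(baseline), length(baseline) == 1L, is.finite(baseline),
    baseline >= 0
  )
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         baseline = as.numeric(baseline)),
    class = "population_kinetics"
  )
}

#' @export
print.population_kinetics <- function(x, ...) {
  cat("Gamma-variate population kinetics\n")
  cat(sprintf("  shape alpha     : %.4g\n", x$alpha))
  cat(sprintf("  time scale beta : %.4g days\n", x$beta))
  cat(sprintf("  baseline B      : %.4g ug/L\n", x$baseline))
  cat(sprintf("  time to peak    : %.1f h\n", time_to_peak(x)))
  invisible(x)
}

#' Evaluate the gamma-variate concentration curve
#'
#' Computes \eqn{A t^{\alpha} e^{-t/\beta} + B} at times `t` (days since
#' trauma). At `t = 0` with `alpha > 0` this is the baseline; with
#' `alpha = 0` it is `amplitude + baseline` (the exponential limit).
#'
#' @param t Time since trauma in days; non-negative, may be a vector.
#' @param amplitude Patient amplitude \eqn{A} in
#'   \eqn{\mu}g/L \eqn{\cdot} day\eqn{^{-\alpha}}; a severity scale.
#' @param kinetics A [population_kinetics()] object.
#'
#' @return Concentrations in \eqn{\mu}g/L, same length as `t`.
#' @examples
#' kin <- population_kinetics(0.69, 1.65, 0.11)
#' gamma_variate(c(0.5, 1.1385, 3), amplitude = 1, kinetics = kin)
#' @export
gamma_variate <- function(t, amplitude, kinetics) {
  stopifnot(inherits(kinetics, "population_kinetics"),
            is.numeric(t), is.numeric(amplitude))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative (days since trauma)")
  }
  amplitude * t^kinetics$alpha * exp(-t / kinetics$beta) + kinetics$baseline
}

#' Time of the population curve maximum
#'
#' The gamma-variate curve attains its unique maximum at
#' \eqn{t_{peak} = \alpha\beta} (days); this returns it in hours. For
#' `alpha = 0` (pure exponential decay) the peak time is 0.
#'
#' @inheritParams gamma_variate
#' @return Time to peak in hours since trauma.
#' @export
time_to_peak <- function(kinetics) {
  stopifnot(inherits(kinetics, "population_kinetics"))
  kinetics$alpha * kinetics$beta * HOURS_PER_DAY
}

#' Peak concentration of the curve
#'
#' Evaluates the curve at its maximum \eqn{t = \alpha\beta}, i.e.
#' \eqn{A (\alpha\beta)^{\alpha} e^{-\alpha} + B}. For `alpha = 0` the curve
#' is monotone decreasing and the supremum is the limit at \eqn{t \to 0},
#' `amplitude + baseline`; a warning is issued in that case.
#'
#' @inheritParams gamma_variate
#' @return Peak concentration in \eqn{\mu}g/L.
#' @export
peak_concentration <- function(amplitude, kinetics) {
  stopifnot(inherits(kinetics, "population_kinetics"))
  if (kinetics$alpha == 0) {
    warning("alpha = 0: curve is monotone decreasing; ",
            "returning the t -> 0 limit amplitude + baseline")
    return(amplitude + kinetics$baseline)
  }
  gamma_variate(kinetics$alpha * kinetics$beta, amplitude, kinetics)
}

#' Area under the baseline-subtracted curve
#'
#' Closed-form integral of \eqn{A t^{\alpha} e^{-t/\beta}} over
#' \eqn{[0, \infty)}:
#' \deqn{\mathrm{AUC} = A \beta^{\alpha+1} \Gamma(\alpha+1),}
#' in \eqn{\mu}g \eqn{\cdot} day / L. Together with the peak height this is a
#' candidate summary of total insult severity.
#'
#' @inheritParams gamma_variate
#' @return Area under the curve, baseline excluded.
#' @export
area_under_curve <- function(amplitude, kinetics) {
  stopifnot(inherits(kinetics, "population_kinetics"))
  amplitude * kinetics$beta^(kinetics$alpha + 1) * gamma(kinetics$alpha + 1)
}
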