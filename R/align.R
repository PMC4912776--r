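#' Build a reference curve function
#'
#' Returns a function of time in hours evaluating the reference population
#' curve, from either a fitted model (posterior mean of the population
#' curve, using each draw's mean patient amplitude), a
#' [population_kinetics()] object (with a fixed amplitude), or any function
#' of time in hours.
#'
#' @param x An `s100b_fit`, a `population_kinetics`, or a function.
#' @param amplitude Amplitude used with a `population_kinetics` reference
#'   (default 1).
#' @param max_draws Posterior draws are thinned to at most this many when
#'   `x` is a fit (default 4000).
#' @return A vectorised function `f(time_h)` returning \eqn{\mu}g/L.
#' @export
reference_curve <- function(x, amplitude = 1, max_draws = 4000) {
  if (is.function(x)) return(x)
  if (inherits(x, "population_kinetics")) {
    force(amplitude)
    return(function(time_h) gamma_variate(time_h / HOURS_PER_DAY,
                                          amplitude, x))
  }
  if (inherits(x, "s100b_fit")) {
    m <- as.matrix(x$draws)
    a_pop <- rowMeans(as.matrix(x$amplitude_draws))
    keep <- thin_index(nrow(m), max_draws)
    alpha <- m[keep, "alpha"]; beta <- m[keep, "beta"]; B <- m[keep, "B"]
    a_pop <- a_pop[keep]
    return(function(time_h) {
      t_d <- time_h / HOURS_PER_DAY
      vapply(t_d, function(td) mean(a_pop * td^alpha * exp(-td / beta) + B), 0)
    })
  }
  stop("cannot build a reference curve from class ",
       paste(class(x), collapse = "/"))
}

thin_index <- function(n, max_draws) {
  if (n <= max_draws) seq_len(n) else
    unique(round(seq(1, n, length.out = max_draws)))
}

#' Affine alignment of a trajectory to the reference curve
#'
#' Finds the scale and offset minimising the mean-square deviation of the
#' transformed observations from the model curve,
#' \deqn{\sum_j (s\, y_j + o - m(t_j))^2,}
#' in closed form (ordinary least squares of the curve values on the
#' observations), and returns the transformed samples — the normalisation
#' used to overlay all patient trajectories on the population curve.
#'
#' A constant series (zero variance) is degenerate: the returned scale is 0
#' with offset equal to the mean curve value, flagged via `degenerate`. A
#' negative scale is mathematically admissible but flagged
#' (`negative_scale`): it indicates an inverted, uncharacteristic
#' trajectory, a candidate for manual exclusion.
#'
#' @param series A patient series data frame (columns `time_h`,
#'   `s100b_ugL`) with at least 2 samples.
#' @param reference A reference curve accepted by [reference_curve()].
#' @param scale_only If `TRUE`, fit the rescaling only (offset fixed at 0).
#' @return An object of class `s100b_alignment`: a list with `patient_id`,
#'   `scale`, `offset`, `msd` (residual mean square, \eqn{(\mu g/L)^2}),
#'   `transformed` (data frame `time_h`, `aligned_ugL`, `reference_ugL`),
#'   `degenerate` and `negative_scale`.
#' @export
align_series <- function(series, reference, scale_only = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "s100b_ugL") %in% names(series)))
  if (nrow(series) < 2L) {
    stop("alignment requires at least 2 samples (two free parameters)")
  }
  f <- reference_curve(reference)
  ord <- order(series$time_h)
  t_h <- series$time_h[ord]
  y <- series$s100b_ugL[ord]
  m <- f(t_h)
  degenerate <- FALSE
  if (scale_only) {
    denom <- sum(y^2)
    if (denom == 0) {
      degenerate <- TRUE
      s <- 0
    } else {
      s <- sum(y * m) / denom
    }
    o <- 0
  } else if (var(y) == 0) {
    degenerate <- TRUE
    s <- 0
    o <- mean(m)
  } else {
    s <- sum((y - mean(y)) * (m - mean(m))) / sum((y - mean(y))^2)
    o <- mean(m) - s * mean(y)
  }
  aligned <- s * y + o
  structure(
    list(patient_id = if ("patient_id" %in% names(series))
           series$patient_id[1] else NA_character_,
         scale = s, offset = o,
         msd = mean((aligned - m)^2),
         transformed = data.frame(time_h = t_h, aligned_ugL = aligned,
                                  reference_ugL = m),
         degenerate = degenerate,
         negative_scale = is.finite(s) && s < 0),
    class = "s100b_alignment"
  )
}

#' @export
print.s100b_alignment <- function(x, ...) {
  cat(sprintf("Trajectory alignment%s: scale %.4g, offset %.4g ug/L, MSD %.3g\n",
              if (is.na(x$patient_id)) "" else paste0(" (", x$patient_id, ")"),
              x$scale, x$offset, x$msd))
  if (x$degenerate) cat("  flagged: degenerate (constant series)\n")
  if (x$negative_scale) cat("  flagged: negative scale (inverted trajectory)\n")
  invisible(x)
}

#' Align every patient in a cohort
#'
#' Applies [align_series()] per patient and collects the results in a
#' table.
#'
#' @param cohort A cohort data frame.
#' @inheritParams align_series
#' @return A data frame with one row per patient: `patient_id`, `scale`,
#'   `offset`, `msd`, `degenerate`, `negative_scale`.
#' @export
align_cohort <- function(cohort, reference, scale_only = FALSE) {
  f <- reference_curve(reference)
  res <- lapply(split_cohort(cohort), align_series, reference = f,
                scale_only = scale_only)
  data.frame(
    patient_id = names(res),
    scale = vapply(res, `[[`, 0, "scale"),
    offset = vapply(res, `[[`, 0, "offset"),
    msd = vapply(res, `[[`, 0, "msd"),
    degenerate = vapply(res, `[[`, TRUE, "degenerate"),
    negative_scale = vapply(res, `[[`, TRUE, "negative_scale"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
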