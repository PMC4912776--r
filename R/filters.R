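#' Cohort inclusion/exclusion settings
#'
#' Thresholds of the rules that reduce an admitted-TBI cohort to the
#' analysis cohort: serum S100B sampled earlier than `early_cutoff_h` hours
#' post trauma may be confounded by extracranial release and is dropped;
#' patients must then have at least `min_samples` samples, the first within
#' `first_sample_deadline_h` hours of trauma; and patients showing evidence
#' of secondary injury — a post-peak concentration rise strictly greater
#' than `secondary_peak_threshold` \eqn{\mu}g/L per 12 h — are excluded.
#'
#' Time-window boundaries are inclusive (a sample at exactly 12 h is kept, a
#' first sample at exactly 48 h is accepted); the rise rule is strict,
#' matching its printed form (`> 0.05`). "Post-peak" is assessed against the
#' expected population peak time `peak_time_h` (default \eqn{\alpha\beta} of
#' the reference kinetics, 27.3 h): a consecutive-sample rise counts when
#' the midpoint of its interval falls at or after that time. Rise rates are
#' computed on raw consecutive samples, normalised to a 12-h interval.
#'
#' @param early_cutoff_h Hours; samples before this are dropped (default 12).
#' @param min_samples Minimum retained samples per patient (default 3).
#' @param first_sample_deadline_h Hours; latest acceptable first retained
#'   sample (default 48).
#' @param secondary_peak_threshold Post-peak rise threshold in \eqn{\mu}g/L
#'   per 12 h (default 0.05, strict inequality).
#' @param peak_time_h Reference peak time in hours used by the "after peak"
#'   clause (default 27.324 h, the reference-model \eqn{\alpha\beta}).
#' @param manual_exclusions Character vector of patient ids excluded by
#'   manual review (uncharacteristic curves); no automatic rule is applied
#'   for these.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(early_cutoff_h = 12,
                          min_samples = 3,
                          first_sample_deadline_h = 48,
                          secondary_peak_threshold = 0.05,
                          peak_time_h = 0.69 * 1.65 * HOURS_PER_DAY,
                          manual_exclusions = character()) {
  stopifnot(early_cutoff_h > 0, min_samples > 0, first_sample_deadline_h > 0,
            secondary_peak_threshold > 0, peak_time_h > 0,
            is.character(manual_exclusions))
  structure(
    list(early_cutoff_h = early_cutoff_h,
         min_samples = as.integer(min_samples),
         first_sample_deadline_h = first_sample_deadline_h,
         secondary_peak_threshold = secondary_peak_threshold,
         peak_time_h = peak_time_h,
         manual_exclusions = manual_exclusions),
    class = "filter_config"
  )
}

#' Drop samples earlier than the extracranial-confounding cutoff
#'
#' Removes samples taken before `early_cutoff_h` hours post trauma
#' (boundary inclusive: a sample at exactly the cutoff is retained). Works
#' on a whole cohort or a single patient's series; order is preserved and
#' the result may be empty.
#'
#' @param series A cohort or per-patient series data frame with columns
#'   `time_h` and `s100b_ugL`.
#' @param config A [filter_config()].
#' @return The series restricted to `time_h >= early_cutoff_h`.
#' @export
drop_early_samples <- function(series, config = filter_config()) {
  stopifnot(is.data.frame(series), "time_h" %in% names(series))
  out <- series[series$time_h >= config$early_cutoff_h, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Consecutive-sample rise rates normalised to a 12-h interval, with the
# interval midpoints used by the post-peak clause.
rise_rates <- function(time_h, conc) {
  n <- length(time_h)
  if (n < 2L) {
    return(data.frame(from_h = numeric(0), to_h = numeric(0),
                      mid_h = numeric(0), rate = numeric(0)))
  }
  dt <- diff(time_h)
  data.frame(from_h = time_h[-n], to_h = time_h[-1],
             mid_h = (time_h[-n] + time_h[-1]) / 2,
             rate = diff(conc) * 12 / dt)
}

#' Detect a secondary S100B peak in one patient's series
#'
#' Flags evidence of secondary injury: a rise between consecutive samples,
#' normalised to a 12-h interval, strictly exceeding
#' `secondary_peak_threshold` after the expected peak of the kinetic curve
#' (a pair counts as post-peak when its interval midpoint is at or after
#' `peak_time_h`). Series with fewer than two post-peak samples cannot be
#' flagged.
#'
#' @param series A single patient's series data frame (columns `time_h`,
#'   `s100b_ugL`), time-ordered.
#' @param config A [filter_config()].
#' @return A list with `flagged` (logical) and, when flagged, the first
#'   offending interval: `from_h`, `to_h` and its `rate` in \eqn{\mu}g/L
#'   per 12 h.
#' @export
detect_secondary_peak <- function(series, config = filter_config()) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "s100b_ugL") %in% names(series)))
  ord <- order(series$time_h)
  r <- rise_rates(series$time_h[ord], series$s100b_ugL[ord])
  r <- r[r$mid_h >= config$peak_time_h &
           r$rate > config$secondary_peak_threshold, , drop = FALSE]
  if (nrow(r) == 0L) {
    list(flagged = FALSE, from_h = NA_real_, to_h = NA_real_, rate = NA_real_)
  } else {
    list(flagged = TRUE, from_h = r$from_h[1], to_h = r$to_h[1],
         rate = r$rate[1])
  }
}

#' Apply the cohort inclusion/exclusion rules
#'
#' Applies, per patient and in a fixed order: manual exclusion list; early
#' sample removal; first-retained-sample-within-deadline check; minimum
#' sample count; secondary-peak detection. Each excluded patient yields
#' exactly one exclusion record naming the first failed rule. Included
#' patients are returned with their early samples already removed.
#'
#' @param cohort A cohort data frame (see [as_cohort()]).
#' @param config A [filter_config()].
#' @return A list with `included` (cohort data frame of retained samples of
#'   retained patients) and `exclusions` (data frame with `patient_id`,
#'   `reason` in `manual`, `late_start`, `too_few_samples`,
#'   `secondary_peak`, and free-text `detail`).
#' @export
apply_cohort_filters <- function(cohort, config = filter_config()) {
  series_list <- split_cohort(cohort)
  kept <- list()
  excl <- list()
  note <- function(id, reason, detail) {
    data.frame(patient_id = id, reason = reason, detail = detail,
               stringsAsFactors = FALSE)
  }
  for (id in names(series_list)) {
    s <- series_list[[id]]
    if (id %in% config$manual_exclusions) {
      excl[[id]] <- note(id, "manual", "on manual exclusion list")
      next
    }
    s <- drop_early_samples(s, config)
    if (nrow(s) == 0L ||
        s$time_h[1] > config$first_sample_deadline_h) {
      detail <- if (nrow(s)) {
        sprintf("first retained sample at %.1f h exceeds the %g h deadline",
                s$time_h[1], config$first_sample_deadline_h)
      } else {
        sprintf("no sample at/after the %g h cutoff", config$early_cutoff_h)
      }
      excl[[id]] <- note(id, "late_start", detail)
      next
    }
    if (nrow(s) < config$min_samples) {
      excl[[id]] <- note(id, "too_few_samples",
                         sprintf("%d retained sample(s), need >= %d",
                                 nrow(s), config$min_samples))
      next
    }
    peak <- detect_secondary_peak(s, config)
    if (peak$flagged) {
      excl[[id]] <- note(id, "secondary_peak",
                         sprintf("rise %.3f ug/L per 12 h over [%.1f, %.1f] h",
                                 peak$rate, peak$from_h, peak$to_h))
      next
    }
    kept[[id]] <- s
  }
  included <- if (length(kept)) {
    as_cohort(do.call(rbind, kept))
  } else {
    data.frame(patient_id = character(0), time_h = numeric(0),
               s100b_ugL = numeric(0), stringsAsFactors = FALSE)
  }
  exclusions <- if (length(excl)) {
    do.call(rbind, c(excl, list(make.row.names = FALSE)))
  } else {
    data.frame(patient_id = character(0), reason = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
  list(included = included, exclusions = exclusions)
}
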