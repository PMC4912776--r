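#' Plot the fitted population curve with its prediction band
#'
#' Displays the posterior mean population curve with the 95 % envelope from
#' [posterior_prediction_band()], optionally overlaying observed samples.
#' Requires ggplot2.
#'
#' @param band A prediction-band data frame (`time_h`, `mean`, `lo2.5`,
#'   `hi97.5`).
#' @param cohort Optional cohort data frame of samples to overlay.
#' @return A ggplot object.
#' @export
plot_prediction_band <- function(band, cohort = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo2.5, ymax = .data$hi97.5),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue4") +
    ggplot2::labs(x = "Time since trauma (h)",
                  y = expression(paste("Serum S100B (", mu, "g/L)")))
  if (!is.null(cohort)) {
    p <- p + ggplot2::geom_point(
      data = as_cohort(cohort),
      ggplot2::aes(x = .data$time_h, y = .data$s100b_ugL),
      alpha = 0.3, size = 0.8)
  }
  p
}

#' Plot aligned patient trajectories over the reference curve
#'
#' Rescales and translates each patient's trajectory to minimise its
#' mean-square deviation from the reference curve ([align_series()]) and
#' overlays all transformed trajectories on that curve. Requires ggplot2.
#'
#' @param cohort A cohort data frame.
#' @param reference A reference accepted by [reference_curve()].
#' @param scale_only If `TRUE`, rescale only (no translation).
#' @return A ggplot object.
#' @export
plot_aligned_trajectories <- function(cohort, reference, scale_only = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  f <- reference_curve(reference)
  series_list <- split_cohort(cohort)
  aligned <- do.call(rbind, lapply(names(series_list), function(id) {
    a <- align_series(series_list[[id]], f, scale_only = scale_only)
    cbind(patient_id = id, a$transformed)
  }))
  grid_h <- seq(min(aligned$time_h), max(aligned$time_h), length.out = 200)
  curve <- data.frame(time_h = grid_h, value = f(grid_h))
  ggplot2::ggplot(aligned,
                  ggplot2::aes(x = .data$time_h, y = .data$aligned_ugL,
                               group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time_h, y = .data$value,
                                    group = NULL),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "Time since trauma (h)",
                  y = expression(paste("Aligned S100B (", mu, "g/L)")))
}
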