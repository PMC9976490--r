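#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot epoched traces
#'
#' Median trace per channel (over all trials), faceted by channel, with the
#' end of the stimulation pulse marked.
#'
#' @param object An `esr_epochs`.
#' @param channels Optional channel subset.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esr_epochs <- function(object, channels = NULL, ...) {
  med <- if (dim(object$data)[1] > 1) median_waveform(object, "all") else object
  df <- as_tibble.esr_epochs(med)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value_uV, group = .data$trial)) +
    ggplot2::geom_vline(xintercept = object$stim_end_ms, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), scales = "free_y") +
    ggplot2::labs(
      x = "time from pulse onset (ms)", y = "potential (uV)",
      title = sprintf("median traces (%s reference)", object$reference)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a conduction-velocity fit
#'
#' @param object An `esr_cv`.
#' @param ... Unused.
#' @return A ggplot of peak time vs distance with the OLS line.
#' @export
autoplot.esr_cv <- function(object, ...) {
  lab <- if (object$non_propagating) {
    "non-propagating"
  } else {
    sprintf("%.1f m/s (r² = %.3f)", object$velocity_m_per_s, object$r_squared)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(.data$distance_mm, .data$peak_time_ms)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept_ms, slope = object$slope_ms_per_mm,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "stimulation-recording distance (mm)", y = "negative-peak time (ms)",
      title = paste("conduction velocity:", lab)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response curve
#'
#' AUC vs stimulation amplitude with the baseline criterion and the detected
#' threshold.
#'
#' @param object An `esr_dose_response`.
#' @param k Baseline SD multiplier passed to [detect_threshold()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esr_dose_response <- function(object, k = 3, ...) {
  thr <- detect_threshold(object, k = k)
  crit <- (attr(object, "baseline_mean") %||% 0) + k * (attr(object, "baseline_sd") %||% 0)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$amplitude_mA, .data$auc_uVms)) +
    ggplot2::geom_hline(yintercept = crit, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "stimulation amplitude (mA)", y = "AUC (uV·ms)",
      title = sprintf(
        "dose-response (%s)%s",
        attr(object, "component") %||% "component",
        if (is.na(thr)) ", threshold undefined" else sprintf(", threshold %.1f mA", thr)
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.na(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a migration report
#'
#' Feature changes with their dispersion; flagged features in red.
#'
#' @param object An `esr_migration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esr_migration <- function(object, ...) {
  df <- tidy.esr_migration(object)
  df$flagged <- df$significant & df$above_floor
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$estimate, fill = .data$flagged)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$sd, ymax = .data$estimate + .data$sd),
      width = 0.15
    ) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3"), guide = "none") +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free") +
    ggplot2::labs(
      x = NULL, y = "change (ms / %)",
      title = sprintf(
        "session comparison: %s (%s)",
        if (object$migration_flag) "migration flagged" else "no migration",
        object$direction_hint
      )
    ) +
    ggplot2::theme_minimal()
}
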