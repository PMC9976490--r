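#' Most negative peak within a window
#'
#' Finds the most negative sample of a trace inside a component window and
#' reports its latency from the end of the stimulation pulse — the standard
#' ECAP latency definition (time from the end of the stimulus artifact to the
#' largest negative peak). Ties go to the earlier sample; peaks are resolved
#' at sample resolution (0.04 ms at 25 kHz), with no sub-sample interpolation.
#' If no sample in the window is negative, the least positive sample is
#' returned with `no_negative_peak = TRUE`.
#'
#' @param trace Numeric trace, uV.
#' @param time_ms Epoch time axis, ms relative to pulse onset.
#' @param window_ms Length-2 window, ms relative to the pulse end.
#' @param stim_end_ms Pulse end, ms after onset (default 0.48).
#' @return List: `latency_ms` (from pulse end), `peak_time_ms` (from pulse
#'   onset), `amplitude_uV`, `no_negative_peak`.
#' @export
negative_peak <- function(trace, time_ms, window_ms, stim_end_ms = 0.48) {
  idx <- window_index(time_ms, window_ms, stim_end_ms)
  i_min <- idx[which.min(trace[idx])]
  list(
    latency_ms = time_ms[i_min] - stim_end_ms,
    peak_time_ms = time_ms[i_min],
    amplitude_uV = trace[i_min],
    no_negative_peak = trace[i_min] >= 0
  )
}

#' Peak-to-peak amplitude within a window
#'
#' @inheritParams negative_peak
#' @return Scalar, uV (max - min, always >= 0).
#' @export
peak_to_peak <- function(trace, time_ms, window_ms, stim_end_ms = 0.48) {
  idx <- window_index(time_ms, window_ms, stim_end_ms)
  max(trace[idx]) - min(trace[idx])
}

#' Rectified area under the curve (absolute-value sum)
#'
#' Component magnitude as the plain sum of rectified samples times the sample
#' period: `sum(|x_i|) * dt`, in uV.ms.
#'
#' @inheritParams negative_peak
#' @return Scalar, uV.ms.
#' @export
auc_abs <- function(trace, time_ms, window_ms, stim_end_ms = 0.48) {
  idx <- window_index(time_ms, window_ms, stim_end_ms)
  dt <- time_ms[2] - time_ms[1]
  sum(abs(trace[idx])) * dt
}

window_index <- function(time_ms, window_ms, stim_end_ms) {
  lo <- window_ms[1] + stim_end_ms
  hi <- window_ms[2] + stim_end_ms
  idx <- which(time_ms >= lo - 1e-9 & time_ms <= hi + 1e-9)
  if (length(idx) == 0) {
    rlang::abort("window contains no samples", class = "esrkit_error_window")
  }
  idx
}

#' Per-trial, per-channel component features
#'
#' Quantifies a component window on every trace of an epochs object (usually
#' grouped medians from [median_waveform()]): negative-peak latency,
#' peak-to-peak amplitude, rectified AUC, AUC normalized to the stimulation
#' amplitude, and a baseline AUC measured on the pre-stimulus interval and
#' rescaled to the window duration (the noise reference used for threshold
#' detection).
#'
#' @param epochs An `esr_epochs`.
#' @param windows An [analysis_windows()].
#' @param component `"ecap"`, `"emg"` (uses the EMG AUC window for AUC and the
#'   full EMG window for peaks/p2p), or `"custom"` with `window_ms` supplied.
#' @param window_ms Custom window (ms post pulse end) when
#'   `component = "custom"`.
#' @param channels Optional subset of channel numbers.
#' @return A tibble with one row per trial x channel: `trial`, `channel`,
#'   `label`, `lead`, `distance_mm`, `amplitude_mA`, `n_trials`, `component`,
#'   `latency_ms`, `peak_time_ms`, `peak_uV`, `no_negative_peak`, `p2p_uV`,
#'   `auc_uVms`, `auc_norm`, `baseline_auc_uVms`.
#' @export
extract_features <- function(epochs,
                             windows = analysis_windows(),
                             component = c("ecap", "emg", "custom"),
                             window_ms = NULL,
                             channels = NULL) {
  stopifnot(inherits(epochs, "esr_epochs"))
  component <- match.arg(component)
  peak_win <- switch(component,
    ecap = windows$ecap_window_ms,
    emg = windows$emg_window_ms,
    custom = window_ms
  )
  auc_win <- switch(component,
    ecap = windows$ecap_window_ms,
    emg = windows$emg_auc_window_ms,
    custom = window_ms
  )
  if (is.null(peak_win)) {
    rlang::abort("component = 'custom' requires window_ms", class = "esrkit_error_window")
  }
  se <- epochs$stim_end_ms
  t_ms <- epochs$time_ms
  dt <- t_ms[2] - t_ms[1]

  ch_tbl <- epochs$channels
  ch_rows <- seq_len(nrow(ch_tbl))
  if (!is.null(channels)) ch_rows <- ch_rows[ch_tbl$channel %in% channels]

  pre_idx <- which(t_ms < 0)
  auc_idx <- window_index(t_ms, auc_win, se)

  rows <- vector("list", dim(epochs$data)[1] * length(ch_rows))
  n <- 0L
  for (k in seq_len(dim(epochs$data)[1])) {
    amp <- epochs$trials$amplitude_mA[k]
    for (j in ch_rows) {
      tr <- epochs$data[k, j, ]
      pk <- negative_peak(tr, t_ms, peak_win, se)
      auc <- sum(abs(tr[auc_idx])) * dt
      base <- if (length(pre_idx) > 0) {
        sum(abs(tr[pre_idx])) * dt * (length(auc_idx) / length(pre_idx))
      } else {
        NA_real_
      }
      n <- n + 1L
      rows[[n]] <- tibble::tibble(
        trial = epochs$trials$trial[k],
        channel = ch_tbl$channel[j],
        label = ch_tbl$label[j],
        lead = ch_tbl$lead[j],
        distance_mm = ch_tbl$distance_mm[j],
        amplitude_mA = amp,
        n_trials = epochs$trials$n_trials[k],
        component = component,
        latency_ms = pk$latency_ms,
        peak_time_ms = pk$peak_time_ms,
        peak_uV = pk$amplitude_uV,
        no_negative_peak = pk$no_negative_peak,
        p2p_uV = max(tr[auc_idx]) - min(tr[auc_idx]),
        auc_uVms = auc,
        auc_norm = auc / amp,
        baseline_auc_uVms = base
      )
    }
  }
  dplyr::bind_rows(rows[seq_len(n)])
}

#' Conduction velocity by linear regression
#'
#' Ordinary least squares of negative-peak time on stimulation-recording
#' contact distance; the conduction velocity is the inverse slope (mm/ms =
#' m/s). Points flagged as having no negative peak are excluded. A
#' non-positive slope yields a "non-propagating" fit with undefined velocity.
#'
#' @param distance_mm Stimulation-recording distances, mm.
#' @param peak_time_ms Negative-peak times, ms (any fixed origin; the origin
#'   is absorbed by the intercept).
#' @param exclude Logical vector: points to drop (e.g. `no_negative_peak`).
#' @param min_channels Minimum usable points (default 3).
#' @return An object of class `esr_cv`: `velocity_m_per_s`, `intercept_ms`,
#'   `slope_ms_per_mm`, `slope_se`, `r_squared`, `n_channels`,
#'   `non_propagating`, and `data`, the (distance, time) pairs used.
#' @examples
#' conduction_velocity(c(0, 7, 14), c(0, 0.1, 0.2)) # 70 m/s
#' @export
conduction_velocity <- function(distance_mm, peak_time_ms, exclude = NULL,
                                min_channels = 3) {
  keep <- rep(TRUE, length(distance_mm))
  if (!is.null(exclude)) keep <- keep & !exclude
  keep <- keep & is.finite(distance_mm) & is.finite(peak_time_ms)
  d <- distance_mm[keep]
  t <- peak_time_ms[keep]
  if (length(d) < min_channels) {
    rlang::abort(sprintf("need at least %d usable channels", min_channels),
      class = "esrkit_error_cv"
    )
  }
  if (length(unique(d)) < 2) {
    rlang::abort("distances must not all coincide", class = "esrkit_error_cv")
  }
  fit <- stats::lm(t ~ d)
  slope <- unname(stats::coef(fit)[2])
  # zero-residual fits trip a harmless "essentially perfect fit" warning
  se <- tryCatch(
    suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2])),
    error = function(e) NA_real_
  )
  r2 <- if (stats::var(t) > 0) suppressWarnings(summary(fit)$r.squared) else NA_real_
  non_prop <- slope <= 0
  structure(
    list(
      velocity_m_per_s = if (non_prop) NA_real_ else 1 / slope,
      intercept_ms = unname(stats::coef(fit)[1]),
      slope_ms_per_mm = slope,
      slope_se = se,
      r_squared = r2,
      n_channels = length(d),
      non_propagating = non_prop,
      data = tibble::tibble(distance_mm = d, peak_time_ms = t)
    ),
    class = "esr_cv"
  )
}

#' @export
print.esr_cv <- function(x, ...) {
  if (x$non_propagating) {
    cat("<esr_cv> non-propagating (slope <= 0)\n")
  } else {
    cat(sprintf(
      "<esr_cv> %.2f m/s (%s), r^2 = %.3f, n = %d\n",
      x$velocity_m_per_s, classify_fiber(x$velocity_m_per_s), x$r_squared, x$n_channels
    ))
  }
  invisible(x)
}

#' Estimate conduction velocity from a feature table
#'
#' Convenience wrapper: pools the (distance, latency) pairs of a feature
#' table — typically grouped medians over the recording-lead channels — and
#' fits [conduction_velocity()].
#'
#' @param features A tibble from [extract_features()].
#' @param channels Optional channel subset (e.g. `9:16`).
#' @return An `esr_cv`.
#' @export
estimate_cv <- function(features, channels = NULL) {
  f <- features
  if (!is.null(channels)) f <- dplyr::filter(f, .data$channel %in% channels)
  conduction_velocity(f$distance_mm, f$latency_ms, exclude = f$no_negative_peak)
}

#' Classify a conduction velocity by fiber type
#'
#' Half-open physiological bins: A-delta 5-35 m/s, A-beta 35-80 m/s, A-alpha
#' 80-120 m/s; anything outside 5-120 m/s is `"out-of-range"`. The lower edge
#' belongs to the bin (35 m/s is A-beta); 120 m/s is included in A-alpha.
#'
#' @param velocity_m_per_s Velocities, m/s.
#' @return Character vector: `"Adelta"`, `"Abeta"`, `"Aalpha"`,
#'   `"out-of-range"`.
#' @examples
#' classify_fiber(c(4, 35, 60, 100, 121))
#' @export
classify_fiber <- function(velocity_m_per_s) {
  vapply(velocity_m_per_s, function(v) {
    if (!is.finite(v)) {
      "out-of-range"
    } else if (v >= 5 && v < 35) {
      "Adelta"
    } else if (v >= 35 && v < 80) {
      "Abeta"
    } else if (v >= 80 && v <= 120) {
      "Aalpha"
    } else {
      "out-of-range"
    }
  }, character(1))
}

#' Dose-response curve of a component
#'
#' Mean component AUC per stimulation amplitude, amplitudes sorted ascending.
#' Baseline statistics (mean and SD of the pre-stimulus AUC rescaled to the
#' component window) are attached for threshold detection.
#'
#' @param features A feature table from [extract_features()] (one component).
#' @return A tibble of class `esr_dose_response` with columns `amplitude_mA`,
#'   `auc_uVms`, `n`; attributes `baseline_mean`, `baseline_sd`, `component`.
#' @export
dose_response <- function(features) {
  stopifnot(all(c("amplitude_mA", "auc_uVms") %in% names(features)))
  curve <- features |>
    dplyr::group_by(.data$amplitude_mA) |>
    dplyr::summarise(
      auc_uVms = mean(.data$auc_uVms),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$amplitude_mA)
  base <- features$baseline_auc_uVms
  structure(
    curve,
    baseline_mean = if (all(is.na(base))) NA_real_ else mean(base, na.rm = TRUE),
    baseline_sd = if (all(is.na(base))) NA_real_ else stats::sd(base, na.rm = TRUE),
    component = if ("component" %in% names(features)) features$component[1] else NA_character_,
    class = c("esr_dose_response", class(curve))
  )
}

#' Detection threshold from a dose-response curve
#'
#' The smallest stimulation amplitude whose response exceeds
#' `baseline_mean + k * baseline_sd` *and* whose every larger amplitude also
#' exceeds it (a single noisy excursion below threshold does not count). If
#' the criterion is never sustained the threshold is undefined (`NA`).
#'
#' @param dr An [dose_response()] tibble.
#' @param k Baseline SD multiplier (default 3).
#' @param baseline_mean,baseline_sd Override the baseline statistics attached
#'   to `dr` (e.g. from a separate noise recording).
#' @return Threshold amplitude in mA, or `NA_real_`.
#' @export
detect_threshold <- function(dr, k = 3, baseline_mean = NULL, baseline_sd = NULL) {
  if (nrow(dr) < 2) {
    rlang::abort("threshold detection needs at least 2 amplitudes", class = "esrkit_error_threshold")
  }
  m <- baseline_mean %||% attr(dr, "baseline_mean")
  s <- baseline_sd %||% attr(dr, "baseline_sd")
  if (is.null(m) || is.na(m)) m <- 0
  if (is.null(s) || is.na(s)) s <- 0
  crit <- m + k * s
  above <- dr$auc_uVms > crit
  sustained <- rev(cumprod(rev(above))) == 1
  if (!any(sustained)) {
    return(NA_real_)
  }
  dr$amplitude_mA[which(sustained)[1]]
}

#' Summarise per-subject EMG vs ECAP detection thresholds
#'
#' Given per-subject ECAP and EMG detection thresholds (mA), computes the
#' per-subject EMG/ECAP threshold ratio, the cohort mean ratio, and the mean
#' percentage by which the EMG threshold exceeds the ECAP threshold.
#'
#' @param thresholds A data frame with columns `subject`, `ecap_threshold_mA`,
#'   `emg_threshold_mA`. Defaults to the bundled porcine cohort table
#'   (`subject_thresholds.csv`).
#' @return A list with `per_subject` (tibble incl. `ratio`), `mean_ratio`,
#'   `mean_excess_pct` (= 100 * (mean_ratio - 1)).
#' @examples
#' threshold_summary()
#' @export
threshold_summary <- function(thresholds = example_thresholds()) {
  stopifnot(all(c("subject", "ecap_threshold_mA", "emg_threshold_mA") %in% names(thresholds)))
  per <- tibble::as_tibble(thresholds)
  per$ratio <- per$emg_threshold_mA / per$ecap_threshold_mA
  list(
    per_subject = per,
    mean_ratio = mean(per$ratio),
    mean_excess_pct = 100 * (mean(per$ratio) - 1)
  )
}

#' Bundled per-subject detection thresholds
#'
#' ECAP and intercostal-EMG detection thresholds (mA) for five porcine
#' subjects, as published for epidural stimulation dose-response studies.
#'
#' @return A tibble with columns `subject`, `emg_threshold_mA`,
#'   `ecap_threshold_mA`.
#' @export
example_thresholds <- function() {
  readr::read_csv(
    system.file("extdata", "subject_thresholds.csv", package = "esrkit"),
    show_col_types = FALSE
  )
}
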