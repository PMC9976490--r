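#' Analysis windows for ESR components
#'
#' Time windows delimiting the components of a stimulation-evoked epidural
#' recording. Unless stated otherwise, windows are in ms **relative to the end
#' of the stimulation pulse** (`stim_end_ms`, 0.48 ms for the default 400 +
#' 80 us waveform); the epoch time axis is relative to pulse onset and
#' conversion between the two is explicit via [window_in_epoch_time()].
#'
#' Defaults: ECAP window 0.33-1.80 ms; EMG window 1.8-13 ms; EMG AUC window
#' 3.5-9 ms. Two further presets are carried along: an alternative ECAP
#' window specified in *recording* coordinates (2.1-5 ms from the start of an
#' epoch that begins 1.3 ms before the pulse) and the 5-18 ms window used for
#' intramuscular evoked potentials. The 0.33 ms gap between pulse end and the
#' ECAP window start doubles as the artifact blanking margin: the visual
#' "end of the stimulation artifact" criterion is operationalized as pulse
#' end + this configurable margin.
#'
#' @param stim_end_ms End of the stimulation pulse, ms after pulse onset.
#' @param ecap_window_ms ECAP component window (post pulse end).
#' @param ecap_window_alt_ms Alternative ECAP window, in recording
#'   coordinates (an epoch starting `pre_stim_ms` before the pulse).
#' @param emg_window_ms EMG component window (post pulse end).
#' @param emg_auc_window_ms Window for EMG AUC quantification (post pulse end).
#' @param semp_window_ms Intramuscular evoked-potential window (post pulse end).
#' @param pre_stim_ms Recording lead-in used to interpret recording-coordinate
#'   windows (default 1.3).
#' @return An object of class `esr_windows`.
#' @examples
#' analysis_windows()
#' @export
analysis_windows <- function(stim_end_ms = 0.48,
                             ecap_window_ms = c(0.33, 1.80),
                             ecap_window_alt_ms = c(2.1, 5.0),
                             emg_window_ms = c(1.8, 13),
                             emg_auc_window_ms = c(3.5, 9),
                             semp_window_ms = c(5, 18),
                             pre_stim_ms = 1.3) {
  w <- list(
    stim_end_ms = stim_end_ms,
    ecap_window_ms = ecap_window_ms,
    ecap_window_alt_ms = ecap_window_alt_ms,
    emg_window_ms = emg_window_ms,
    emg_auc_window_ms = emg_auc_window_ms,
    semp_window_ms = semp_window_ms,
    pre_stim_ms = pre_stim_ms
  )
  for (nm in c(
    "ecap_window_ms", "ecap_window_alt_ms", "emg_window_ms",
    "emg_auc_window_ms", "semp_window_ms"
  )) {
    if (diff(w[[nm]]) <= 0) {
      rlang::abort(sprintf("%s must be a non-empty interval", nm), class = "esrkit_error_window")
    }
  }
  if (ecap_window_ms[1] >= emg_window_ms[2]) {
    rlang::abort("the ECAP window must precede the end of the EMG window",
      class = "esrkit_error_window"
    )
  }
  structure(w, class = "esr_windows")
}

#' @export
print.esr_windows <- function(x, ...) {
  cat(sprintf(
    "<esr_windows> (ms post pulse end) ECAP %.2f-%.2f | EMG %.1f-%.1f | EMG AUC %.1f-%.1f\n",
    x$ecap_window_ms[1], x$ecap_window_ms[2],
    x$emg_window_ms[1], x$emg_window_ms[2],
    x$emg_auc_window_ms[1], x$emg_auc_window_ms[2]
  ))
  invisible(x)
}

#' Convert a window to epoch time
#'
#' Expresses a component window on the epoch time axis (0 = pulse onset).
#'
#' @param window_ms Length-2 numeric window.
#' @param windows An [analysis_windows()] (supplies `stim_end_ms` and
#'   `pre_stim_ms`).
#' @param origin `"stim_end"` (default) or `"recording"` (window measured from
#'   the start of an epoch with `pre_stim_ms` lead-in).
#' @return Length-2 numeric, ms relative to pulse onset.
#' @examples
#' window_in_epoch_time(c(0.33, 1.8), analysis_windows())
#' window_in_epoch_time(c(2.1, 5), analysis_windows(), origin = "recording")
#' @export
window_in_epoch_time <- function(window_ms, windows = analysis_windows(),
                                 origin = c("stim_end", "recording")) {
  origin <- match.arg(origin)
  switch(origin,
    stim_end = window_ms + windows$stim_end_ms,
    recording = window_ms - windows$pre_stim_ms
  )
}
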