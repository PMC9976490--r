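#' Stimulation protocol
#'
#' Parameters of the charge-balanced, anodic-leading stimulation waveform and
#' of the recording setup. The pulse is a 400 us anodic rectangle followed by
#' an 80 us cathodic rectangle whose amplitude is five times the anodic one,
#' so the two phases carry equal charge (400 x 1 = 80 x 5). The stimulation
#' amplitude is, by convention, the amplitude of the cathodic phase.
#'
#' @param anodic_phase_us Anodic phase duration, us (default 400).
#' @param cathodic_phase_us Cathodic phase duration, us (default 80).
#' @param cathodic_to_anodic_ratio Cathodic/anodic amplitude ratio (default 5).
#' @param frequency_hz Pulse repetition rate, Hz (default 38, avoiding 60 Hz
#'   harmonics).
#' @param amplitude_mA Amplitudes swept in the session (cathodic amplitude,
#'   mA); default 0.5 to 10 mA in 0.5 mA steps.
#' @param pulses_per_amplitude Pulses delivered at each amplitude (default 300).
#' @param pre_stim_ms Recording lead-in before each pulse, ms (default 1.3).
#' @param sampling_rate_hz Sampling rate, Hz (default 25000).
#' @return An object of class `esr_protocol`.
#' @examples
#' stim_protocol(amplitude_mA = 2.4, pulses_per_amplitude = 50)
#' @export
stim_protocol <- function(anodic_phase_us = 400,
                          cathodic_phase_us = 80,
                          cathodic_to_anodic_ratio = 5,
                          frequency_hz = 38,
                          amplitude_mA = seq(0.5, 10, by = 0.5),
                          pulses_per_amplitude = 300,
                          pre_stim_ms = 1.3,
                          sampling_rate_hz = 25000) {
  if (length(amplitude_mA) == 0) {
    rlang::abort("amplitude_mA must list at least one amplitude", class = "esrkit_error_protocol")
  }
  if (!isTRUE(all.equal(
    anodic_phase_us * 1,
    cathodic_phase_us * cathodic_to_anodic_ratio
  ))) {
    rlang::abort(
      "charge balance violated: anodic_phase_us must equal cathodic_phase_us * ratio",
      class = "esrkit_error_protocol"
    )
  }
  structure(
    list(
      anodic_phase_us = anodic_phase_us,
      cathodic_phase_us = cathodic_phase_us,
      cathodic_to_anodic_ratio = cathodic_to_anodic_ratio,
      frequency_hz = frequency_hz,
      amplitude_mA = as.numeric(amplitude_mA),
      pulses_per_amplitude = as.integer(pulses_per_amplitude),
      pre_stim_ms = pre_stim_ms,
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "esr_protocol"
  )
}

#' End of the stimulation pulse
#'
#' Time at which the biphasic pulse ends, in ms after pulse onset
#' (0.48 ms for the default 400 + 80 us waveform). Analysis windows are
#' defined relative to this instant.
#'
#' @param protocol An [stim_protocol()] object.
#' @return Scalar, ms.
#' @export
stim_end_ms <- function(protocol) {
  (protocol$anodic_phase_us + protocol$cathodic_phase_us) / 1000
}

#' @export
print.esr_protocol <- function(x, ...) {
  cat(sprintf(
    "<esr_protocol> %g+%g us pulse (ratio %g), %g Hz, %d amplitude(s) x %d pulses, fs %g Hz\n",
    x$anodic_phase_us, x$cathodic_phase_us, x$cathodic_to_anodic_ratio,
    x$frequency_hz, length(x$amplitude_mA), x$pulses_per_amplitude, x$sampling_rate_hz
  ))
  invisible(x)
}

# sampled biphasic pulse for a 1 mA (cathodic) stimulus; anodic positive
stim_pulse_samples <- function(protocol, fs) {
  dt_us <- 1e6 / fs
  n_an <- max(1L, round(protocol$anodic_phase_us / dt_us))
  n_ca <- max(1L, round(protocol$cathodic_phase_us / dt_us))
  c(rep(1 / protocol$cathodic_to_anodic_ratio, n_an), rep(-1, n_ca))
}
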