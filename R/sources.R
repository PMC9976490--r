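#' ECAP source model
#'
#' Generative model of the evoked compound action potential (ECAP): a
#' triphasic template (P1-N1-P2, built from a difference of Gaussians plus a
#' delayed Gaussian) that propagates rostrally from the stimulation site at a
#' fixed conduction velocity, attenuates exponentially with axial distance and
#' as a Gaussian with medio-lateral offset, and is gated by a recruitment
#' function of the stimulation current.
#'
#' Recruitment is a gated logistic: exactly zero below `threshold_mA` and
#' `max_gain / (1 + exp(-(I - threshold) / slope))` at or above it, hence
#' monotone non-decreasing in current. The axial attenuation default
#' (`axial_decay_mm = 11`) makes a 3.5 mm increase in stimulation-recording
#' distance shave about 24% off the ECAP magnitude, the sensitivity reported
#' for small postural lead displacements in large-animal epidural stimulation
#' studies; neither decay constant is directly measurable from published
#' recordings, so both are free parameters.
#'
#' @param velocity_m_per_s Conduction velocity (default 60, mid A-beta range).
#' @param onset_latency_ms Initiation delay at the stimulation site, ms after
#'   pulse onset (default 0.6; the 0.48 ms pulse must complete first).
#' @param width_ms Gaussian width of the template lobes, ms (default 0.12).
#' @param amplitude_at_stim_uV N1 peak amplitude at zero distance and full
#'   recruitment, uV (default 2000).
#' @param axial_decay_mm Exponential axial attenuation constant (default 11).
#' @param lateral_decay_mm Gaussian medio-lateral attenuation constant
#'   (default 5): coupling gain `exp(-offset^2 / (2 * lateral_decay^2))`.
#' @param threshold_mA,slope_mA,max_gain Recruitment parameters (defaults
#'   1.2 mA, 0.3 mA, 1).
#' @return An object of class `esr_ecap_source`.
#' @examples
#' ecap_source(velocity_m_per_s = 72.29)
#' @export
ecap_source <- function(velocity_m_per_s = 60,
                        onset_latency_ms = 0.6,
                        width_ms = 0.12,
                        amplitude_at_stim_uV = 2000,
                        axial_decay_mm = 11,
                        lateral_decay_mm = 5,
                        threshold_mA = 1.2,
                        slope_mA = 0.3,
                        max_gain = 1) {
  if (velocity_m_per_s <= 0) {
    rlang::abort("conduction velocity must be positive", class = "esrkit_error_source")
  }
  if (threshold_mA < 0) {
    rlang::abort("recruitment threshold must be >= 0", class = "esrkit_error_source")
  }
  structure(
    list(
      velocity_m_per_s = velocity_m_per_s,
      onset_latency_ms = onset_latency_ms,
      width_ms = width_ms,
      amplitude_at_stim_uV = amplitude_at_stim_uV,
      axial_decay_mm = axial_decay_mm,
      lateral_decay_mm = lateral_decay_mm,
      threshold_mA = threshold_mA,
      slope_mA = slope_mA,
      max_gain = max_gain
    ),
    class = "esr_ecap_source"
  )
}

#' Triphasic ECAP template
#'
#' Evaluates the P1-N1-P2 template at times `t_ms` relative to the arrival of
#' the main negative (N1) peak. The template is a central negative Gaussian
#' with two smaller positive lobes at -2.5 and +2.5 widths, normalized so the
#' most negative value is exactly -1.
#'
#' @param t_ms Times, ms, relative to the N1 peak.
#' @param width_ms Gaussian lobe width, ms.
#' @return Numeric vector, unit negative peak.
#' @export
ecap_template <- function(t_ms, width_ms = 0.12) {
  w <- width_ms
  d <- 2.5 * w
  shape <- function(t) {
    0.35 * exp(-(t + d)^2 / (2 * w^2)) -
      exp(-t^2 / (2 * w^2)) +
      0.45 * exp(-(t - d)^2 / (2 * w^2))
  }
  # normalize on a fine grid so min == -1 regardless of lobe overlap
  fine <- shape(seq(-4 * w, 4 * w, by = w / 200))
  shape(t_ms) / abs(min(fine))
}

#' Recruitment gain of a source
#'
#' Gated logistic recruitment: exactly 0 below threshold, logistic in the
#' supra-threshold current. Monotone non-decreasing in the current.
#'
#' @param amplitude_mA Stimulation current(s), mA.
#' @param threshold_mA,slope_mA,max_gain Recruitment parameters.
#' @return Gain in `[0, max_gain]`, same length as `amplitude_mA`.
#' @examples
#' recruitment_gain(c(1, 1.2, 3), threshold_mA = 1.2, slope_mA = 0.3)
#' @export
recruitment_gain <- function(amplitude_mA, threshold_mA, slope_mA, max_gain = 1) {
  ifelse(
    amplitude_mA < threshold_mA,
    0,
    max_gain / (1 + exp(-(amplitude_mA - threshold_mA) / slope_mA))
  )
}

#' EMG source model
#'
#' Generative model of the stimulation-evoked myogenic (EMG) component seen on
#' the epidural contacts: a band-limited oscillatory burst (sinusoidal carrier
#' under a Gaussian envelope) that appears *simultaneously* on all contacts
#' (zero propagation delay, i.e. a common-mode component), with a per-contact
#' gain close to 1 (small multiplicative jitter drawn once per session) and a
#' non-zero pickup on the tissue reference electrode, which sits in muscle.
#'
#' The envelope is centred `onset_latency_ms + duration_ms / 2` after the end
#' of the stimulation pulse with standard deviation `duration_ms / 2.8`; its
#' leading tail is what can spill into the ECAP analysis window at high
#' currents. Recruitment uses the same gated logistic as [ecap_source()], with
#' a threshold above the ECAP threshold (default 1.56 x 1.2 mA, the mean
#' EMG/ECAP threshold ratio observed across subjects).
#'
#' @param threshold_mA Recruitment threshold (default 1.872 = 1.56 x 1.2).
#' @param slope_mA,max_gain Recruitment slope and ceiling (defaults 0.3, 1).
#' @param onset_latency_ms Burst onset, ms after the stimulation pulse end
#'   (default 3.5).
#' @param duration_ms Nominal burst duration, ms (default 8).
#' @param carrier_hz Oscillation frequency of the burst, Hz (default 300).
#' @param amplitude_uV Envelope peak amplitude at full recruitment (default 400).
#' @param gain_jitter_sd SD of the per-contact multiplicative gain jitter
#'   (default 0.02).
#' @param reference_pickup Fraction of the burst seen by the tissue reference
#'   electrode (default 0.5; must be > 0 for a realistic muscle reference).
#' @return An object of class `esr_emg_source`.
#' @export
emg_source <- function(threshold_mA = 1.56 * 1.2,
                       slope_mA = 0.3,
                       max_gain = 1,
                       onset_latency_ms = 3.5,
                       duration_ms = 8,
                       carrier_hz = 300,
                       amplitude_uV = 400,
                       gain_jitter_sd = 0.02,
                       reference_pickup = 0.5) {
  if (threshold_mA < 0) {
    rlang::abort("recruitment threshold must be >= 0", class = "esrkit_error_source")
  }
  structure(
    list(
      threshold_mA = threshold_mA,
      slope_mA = slope_mA,
      max_gain = max_gain,
      onset_latency_ms = onset_latency_ms,
      duration_ms = duration_ms,
      carrier_hz = carrier_hz,
      amplitude_uV = amplitude_uV,
      gain_jitter_sd = gain_jitter_sd,
      reference_pickup = reference_pickup
    ),
    class = "esr_emg_source"
  )
}

# burst waveform at full recruitment; t_ms relative to stimulation pulse END
emg_burst <- function(emg, t_ms) {
  center <- emg$onset_latency_ms + emg$duration_ms / 2
  sigma <- emg$duration_ms / 2.8
  env <- exp(-(t_ms - center)^2 / (2 * sigma^2))
  emg$amplitude_uV * env * sin(2 * pi * emg$carrier_hz * (t_ms - center) / 1000)
}

#' Stimulation artifact model
#'
#' The stimulation artifact is the biphasic pulse convolved with a first-order
#' exponential electrode/tissue impulse response. It is time-locked to the
#' pulse with zero inter-contact delay; the per-electrode gain decays
#' exponentially with axial distance from the stimulation site, and a small
#' fraction is picked up by the tissue reference electrode.
#'
#' @param amplitude_uV_per_mA Peak artifact amplitude at the stimulation site
#'   per mA of cathodic current (default 500).
#' @param tau_ms Exponential impulse-response time constant, ms (default 0.08).
#' @param decay_mm Axial attenuation constant, mm (default 40; the artifact is
#'   a far-field volume-conducted signal, so it falls off much more gently
#'   than the ECAP and remains well above the remote-reference pickup on
#'   every contact).
#' @param reference_pickup Gain of the artifact on the reference electrode
#'   (default 0.02).
#' @return An object of class `esr_artifact_model`.
#' @export
artifact_model <- function(amplitude_uV_per_mA = 500,
                           tau_ms = 0.08,
                           decay_mm = 40,
                           reference_pickup = 0.02) {
  structure(
    list(
      amplitude_uV_per_mA = amplitude_uV_per_mA,
      tau_ms = tau_ms,
      decay_mm = decay_mm,
      reference_pickup = reference_pickup
    ),
    class = "esr_artifact_model"
  )
}

# sampled artifact shape for 1 mA, starting at pulse onset; unit peak scaled
# to amplitude_uV_per_mA
artifact_shape <- function(artifact, protocol, fs, n_samples) {
  pulse <- stim_pulse_samples(protocol, fs)
  dt_ms <- 1000 / fs
  t <- seq(0, by = dt_ms, length.out = max(n_samples, length(pulse)))
  h <- exp(-t / artifact$tau_ms)
  h <- h / sum(h)
  y <- stats::convolve(c(pulse, rep(0, length(t) - length(pulse))), rev(h), type = "open")
  y <- y[seq_len(n_samples)]
  if (max(abs(y)) > 0) y <- y / max(abs(y))
  artifact$amplitude_uV_per_mA * y
}

#' Additive noise model
#'
#' White Gaussian noise per electrode, optional 60 Hz line hum (common to all
#' electrodes) and an optional common-mode cardiac artifact modelled as a
#' periodic train of Gaussian-shaped deflections at about 1.2 Hz.
#'
#' @param white_sd_uV SD of the white noise, uV (default 5).
#' @param line_hum_uV Peak amplitude of the line hum (default 0 = off).
#' @param line_hz Line frequency (default 60).
#' @param cardiac_uV Peak amplitude of the cardiac train (default 0 = off).
#' @param cardiac_hz Cardiac rate (default 1.2).
#' @param cardiac_width_ms Width of each cardiac deflection (default 15).
#' @return An object of class `esr_noise_model`.
#' @export
noise_model <- function(white_sd_uV = 5,
                        line_hum_uV = 0,
                        line_hz = 60,
                        cardiac_uV = 0,
                        cardiac_hz = 1.2,
                        cardiac_width_ms = 15) {
  structure(
    list(
      white_sd_uV = white_sd_uV,
      line_hum_uV = line_hum_uV,
      line_hz = line_hz,
      cardiac_uV = cardiac_uV,
      cardiac_hz = cardiac_hz,
      cardiac_width_ms = cardiac_width_ms
    ),
    class = "esr_noise_model"
  )
}
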