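# shared builders for simulated test sessions

# recording lead parked close to the stimulation site, on its own lateral
# track (side-by-side placement); good SNR on all 8 recording channels
near_geometry <- function(offset = 30) {
  lead_geometry(recording_offset_mm = offset, lateral_offset_mm = c(0, 1))
}

quiet_noise <- function() noise_model(white_sd_uV = 0)
no_emg <- function() emg_source(amplitude_uV = 0)
no_artifact <- function() artifact_model(amplitude_uV_per_mA = 0)
no_ecap <- function() ecap_source(amplitude_at_stim_uV = 0)

# ECAP-only, noiseless session (the clean regime for exact latency checks)
sim_clean_ecap <- function(geometry = near_geometry(), velocity = 60,
                           amplitude_mA = 2.4, pulses = 3, seed = 1, ...) {
  simulate_session(
    geometry,
    stim_protocol(amplitude_mA = amplitude_mA, pulses_per_amplitude = pulses),
    ecap = ecap_source(velocity_m_per_s = velocity, ...),
    emg = no_emg(), artifact = no_artifact(), noise = quiet_noise(),
    seed = seed
  )
}

# full pipeline to grouped-median features on one channel
ltr_median_features <- function(session, group = 5, channels = 16,
                                bandpass = TRUE, component = "ecap") {
  ep <- apply_reference(epoch_session(session), "LTR")
  ep <- subset_channels(ep, channels)
  if (bandpass) ep <- bandpass_epochs(ep)
  extract_features(median_waveform(ep, group), component = component)
}

# median-of-all-trials features per channel
ltr_all_median_features <- function(session, channels = 9:16, component = "ecap",
                                    ...) {
  med <- median_waveform(apply_reference(epoch_session(session), "LTR"), "all")
  extract_features(med, channels = channels, component = component, ...)
}
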