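#' Simulate a stimulation-evoked epidural recording session
#'
#' Generates continuous potentials, against an ideal remote ground, for the 16
#' lead contacts plus the tissue reference electrode ("REF", electrode 17),
#' with one stimulation pulse train per amplitude in the protocol sweep. Per
#' pulse, three deterministic components are summed:
#'
#' * the propagating ECAP, whose N1 peak reaches contact *i* at
#'   `onset_latency + distance(i, stim) / velocity` and whose amplitude decays
#'   with distance (zero on the reference electrode, which sits in non-neural
#'   tissue);
#' * the common-mode stimulation artifact, time-locked to the pulse with zero
#'   inter-contact delay;
#' * the common-mode EMG burst, simultaneous on all contacts with a small
#'   fixed per-contact gain jitter and a non-zero reference pickup.
#'
#' Additive noise (white, optional hum/cardiac) is drawn from `seed`; with the
#' seed fixed the session is bit-reproducible. Potentials are quantized to
#' IEEE single precision, the precision at which sessions are stored on disk.
#'
#' @param geometry An [lead_geometry()].
#' @param protocol An [stim_protocol()].
#' @param ecap,emg,artifact,noise Source models; see [ecap_source()],
#'   [emg_source()], [artifact_model()], [noise_model()]. Set a source's
#'   amplitude to 0 to omit it.
#' @param seed Integer seed for the noise and gain-jitter draws.
#' @param label Session label (e.g. a position tag "I".."IV").
#' @return An object of class `esr_session`: list with `potentials`
#'   (electrode x sample matrix, uV), `sampling_rate_hz`, `events` (tibble
#'   with `sample`, `amplitude_mA`), `geometry`, `protocol`, `label`.
#' @examples
#' ses <- simulate_session(
#'   lead_geometry(),
#'   stim_protocol(amplitude_mA = 2.4, pulses_per_amplitude = 10),
#'   seed = 1
#' )
#' ses
#' @export
simulate_session <- function(geometry = lead_geometry(),
                             protocol = stim_protocol(),
                             ecap = ecap_source(),
                             emg = emg_source(),
                             artifact = artifact_model(),
                             noise = noise_model(),
                             seed = NULL,
                             label = "session") {
  validate_geometry(geometry)
  fs <- protocol$sampling_rate_hz
  dt_ms <- 1000 / fs
  if (length(protocol$amplitude_mA) == 0) {
    rlang::abort("amplitude list is empty", class = "esrkit_error_protocol")
  }
  # sampling must resolve the ECAP template (spectrum down ~40 dB by f99)
  f99_hz <- sqrt(log(100) / 2) / (pi * ecap$width_ms / 1000)
  if (fs < 2 * f99_hz) {
    rlang::abort(
      sprintf("sampling rate %g Hz below 2x template bandwidth (%.0f Hz)", fs, f99_hz),
      class = "esrkit_error_protocol"
    )
  }

  n_contacts <- nrow(geometry$contacts)
  n_elec <- n_contacts + 1L # + reference electrode
  ipi <- round(fs / protocol$frequency_hz)
  pre_n <- round(protocol$pre_stim_ms * fs / 1000)
  lead_in <- pre_n + round(0.005 * fs)
  n_per_amp <- protocol$pulses_per_amplitude
  amps <- protocol$amplitude_mA
  n_events <- length(amps) * n_per_amp
  n_total <- lead_in + n_events * ipi + ipi

  event_sample <- lead_in + (seq_len(n_events) - 1L) * ipi + 1L
  event_amp <- rep(amps, each = n_per_amp)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  on.exit({
    if (!is.null(seed)) {
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }
  })

  # fixed per-contact EMG gains for this session (common-mode up to jitter)
  emg_gain <- c(
    1 + stats::rnorm(n_contacts, 0, emg$gain_jitter_sd),
    emg$reference_pickup
  )

  span <- ipi
  t_ms <- (seq_len(span) - 1) * dt_ms # time within a pulse window, onset at 0
  pulse_end <- stim_end_ms(protocol)

  d_ax <- geometry$contacts$distance_mm
  lat_stim <- geometry$contacts$lateral_mm[geometry$contacts$contact == geometry$stim_cathode]
  lat_gain <- exp(-(geometry$contacts$lateral_mm^2 + lat_stim^2) / (2 * ecap$lateral_decay_mm^2))
  art_shape <- artifact_shape(artifact, protocol, fs, span)
  art_gain <- c(exp(-d_ax / artifact$decay_mm), artifact$reference_pickup)
  burst <- emg_burst(emg, t_ms - pulse_end)

  pot <- matrix(0, nrow = n_elec, ncol = n_total)
  for (a in amps) {
    g_ecap <- recruitment_gain(a, ecap$threshold_mA, ecap$slope_mA, ecap$max_gain)
    g_emg <- recruitment_gain(a, emg$threshold_mA, emg$slope_mA, emg$max_gain)
    block <- matrix(0, nrow = n_elec, ncol = span)
    if (g_ecap > 0 && ecap$amplitude_at_stim_uV != 0) {
      t_peak <- ecap$onset_latency_ms + d_ax / ecap$velocity_m_per_s
      amp_i <- ecap$amplitude_at_stim_uV * g_ecap * exp(-d_ax / ecap$axial_decay_mm) * lat_gain
      for (i in seq_len(n_contacts)) {
        block[i, ] <- block[i, ] + amp_i[i] * ecap_template(t_ms - t_peak[i], ecap$width_ms)
      }
    }
    if (artifact$amplitude_uV_per_mA != 0) {
      block <- block + (a * art_gain) %o% art_shape
    }
    if (g_emg > 0 && emg$amplitude_uV != 0) {
      block <- block + (g_emg * emg_gain) %o% burst
    }
    for (s0 in event_sample[event_amp == a]) {
      idx <- s0:(s0 + span - 1L)
      pot[, idx] <- pot[, idx] + block
    }
  }

  if (noise$white_sd_uV > 0) {
    pot <- pot + matrix(stats::rnorm(length(pot), 0, noise$white_sd_uV), nrow = n_elec)
  }
  tt_s <- (seq_len(n_total) - 1) / fs
  if (noise$line_hum_uV > 0) {
    hum <- noise$line_hum_uV * sin(2 * pi * noise$line_hz * tt_s)
    pot <- pot + matrix(hum, nrow = n_elec, ncol = n_total, byrow = TRUE)
  }
  if (noise$cardiac_uV > 0) {
    beat <- tt_s %% (1 / noise$cardiac_hz)
    beat <- pmin(beat, 1 / noise$cardiac_hz - beat) * 1000 # ms to nearest beat
    card <- noise$cardiac_uV * exp(-beat^2 / (2 * (noise$cardiac_width_ms / 2.355)^2))
    pot <- pot + matrix(card, nrow = n_elec, ncol = n_total, byrow = TRUE)
  }

  pot <- quantize_f32(pot)
  rownames(pot) <- c(as.character(seq_len(n_contacts)), "REF")

  new_esr_session(
    potentials = pot,
    sampling_rate_hz = fs,
    events = tibble::tibble(sample = as.integer(event_sample), amplitude_mA = event_amp),
    geometry = geometry,
    protocol = protocol,
    label = label
  )
}

# round-trip through IEEE binary32 so in-memory values match on-disk storage
quantize_f32 <- function(x) {
  dims <- dim(x)
  y <- readBin(
    writeBin(as.vector(x), raw(), size = 4L, endian = "little"),
    what = "double", n = length(x), size = 4L, endian = "little"
  )
  dim(y) <- dims
  y
}
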