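new_esr_session <- function(potentials, sampling_rate_hz, events, geometry, protocol,
                            label = "session") {
  stopifnot(is.matrix(potentials))
  if (nrow(events) > 0) {
    if (any(diff(events$sample) <= 0)) {
      rlang::abort("stimulation events must be strictly increasing", class = "esrkit_error_session")
    }
    if (min(events$sample) < 1 || max(events$sample) > ncol(potentials)) {
      rlang::abort("stimulation events must lie inside the record", class = "esrkit_error_session")
    }
  }
  structure(
    list(
      potentials = potentials,
      sampling_rate_hz = sampling_rate_hz,
      events = events,
      geometry = geometry,
      protocol = protocol,
      label = label
    ),
    class = "esr_session"
  )
}

#' @export
print.esr_session <- function(x, ...) {
  cat(sprintf(
    "<esr_session '%s'> %d electrodes x %d samples @ %g Hz, %d stimulation events\n",
    x$label, nrow(x$potentials), ncol(x$potentials), x$sampling_rate_hz, nrow(x$events)
  ))
  invisible(x)
}

#' Electrode metadata of a session
#'
#' One row per electrode: the 16 lead contacts plus the tissue reference
#' electrode ("REF"), with lead membership, rostro-caudal position and axial
#' distance to the stimulation site (NA for the reference electrode).
#'
#' @param session An `esr_session`.
#' @return A tibble.
#' @export
session_channels <- function(session) {
  ct <- session$geometry$contacts
  dplyr::bind_rows(
    tibble::tibble(
      channel = ct$contact,
      label = as.character(ct$contact),
      lead = ct$lead,
      pos_mm = ct$pos_mm,
      distance_mm = ct$distance_mm,
      is_stim = ct$is_stim,
      is_ref = FALSE
    ),
    tibble::tibble(
      channel = nrow(ct) + 1L, label = "REF", lead = NA_integer_,
      pos_mm = NA_real_, distance_mm = NA_real_, is_stim = FALSE, is_ref = TRUE
    )
  )
}

#' Cut a session into stimulation-aligned epochs
#'
#' Extracts one fixed-length epoch per stimulation event. The sample at epoch
#' time 0 is the pulse-onset sample; `pre_ms` of lead-in precedes it. The time
#' axis is computed from integer sample counts, so epoch arithmetic is exact.
#'
#' @param session An `esr_session`.
#' @param pre_ms Pre-stimulus lead-in, ms (default 1.3).
#' @param post_ms Post-onset duration, ms (default 20).
#' @return An object of class `esr_epochs`: list with `data` (trial x channel
#'   x sample array), `time_ms` (relative to pulse onset), `channels` (see
#'   [session_channels()]), `trials` (tibble: `trial`, `sample`,
#'   `amplitude_mA`, `n_trials`), `sampling_rate_hz`, `stim_end_ms`,
#'   `reference` ("ground" for simulator output).
#' @examples
#' ses <- simulate_session(
#'   protocol = stim_protocol(amplitude_mA = 2.4, pulses_per_amplitude = 5),
#'   seed = 1
#' )
#' ep <- epoch_session(ses)
#' dim(ep$data)
#' @export
epoch_session <- function(session, pre_ms = 1.3, post_ms = 20) {
  fs <- session$sampling_rate_hz
  ipi_ms <- 1000 / session$protocol$frequency_hz
  if (pre_ms + post_ms > ipi_ms) {
    rlang::abort(
      sprintf(
        "epochs would overlap: pre + post = %.2f ms exceeds the %.2f ms inter-pulse interval",
        pre_ms + post_ms, ipi_ms
      ),
      class = "esrkit_error_epoch"
    )
  }
  pre_n <- round(pre_ms * fs / 1000)
  post_n <- round(post_ms * fs / 1000)
  n_len <- pre_n + post_n
  n_ch <- nrow(session$potentials)
  ev <- session$events
  n_tr <- nrow(ev)

  data <- array(0, dim = c(n_tr, n_ch, n_len))
  if (n_tr > 0) {
    if (min(ev$sample) - pre_n < 1 || max(ev$sample) + post_n - 1 > ncol(session$potentials)) {
      rlang::abort("an epoch extends outside the record", class = "esrkit_error_epoch")
    }
    for (k in seq_len(n_tr)) {
      idx <- (ev$sample[k] - pre_n):(ev$sample[k] + post_n - 1L)
      data[k, , ] <- session$potentials[, idx]
    }
  }

  new_esr_epochs(
    data = data,
    time_ms = (seq_len(n_len) - 1 - pre_n) * 1000 / fs,
    channels = session_channels(session),
    trials = tibble::tibble(
      trial = seq_len(n_tr),
      sample = if (n_tr) as.integer(ev$sample) else integer(),
      amplitude_mA = if (n_tr) ev$amplitude_mA else numeric(),
      n_trials = rep(1L, n_tr)
    ),
    sampling_rate_hz = fs,
    stim_end_ms = stim_end_ms(session$protocol),
    reference = "ground"
  )
}

new_esr_epochs <- function(data, time_ms, channels, trials, sampling_rate_hz,
                           stim_end_ms, reference) {
  stopifnot(
    length(dim(data)) == 3,
    dim(data)[1] == nrow(trials),
    dim(data)[2] == nrow(channels),
    dim(data)[3] == length(time_ms)
  )
  structure(
    list(
      data = data,
      time_ms = time_ms,
      channels = channels,
      trials = trials,
      sampling_rate_hz = sampling_rate_hz,
      stim_end_ms = stim_end_ms,
      reference = reference
    ),
    class = "esr_epochs"
  )
}

#' @export
print.esr_epochs <- function(x, ...) {
  cat(sprintf(
    "<esr_epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz, reference %s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate_hz, x$reference
  ))
  invisible(x)
}

#' Keep a subset of channels
#'
#' Restricts an epochs object to the given channel numbers (useful before
#' expensive per-trace operations such as filtering).
#'
#' @param epochs An `esr_epochs`.
#' @param channels Channel numbers to keep.
#' @return An `esr_epochs`.
#' @export
subset_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "esr_epochs"))
  keep <- which(epochs$channels$channel %in% channels)
  if (length(keep) == 0) {
    rlang::abort("no matching channels", class = "esrkit_error_session")
  }
  epochs$data <- epochs$data[, keep, , drop = FALSE]
  epochs$channels <- epochs$channels[keep, ]
  epochs
}

#' Long-format view of epoched traces
#'
#' @param x An `esr_epochs`.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `label`, `time_ms`,
#'   `amplitude_mA`, `value_uV`.
#' @export
as_tibble.esr_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(x$trials$trial, times = d[2] * d[3]),
    channel = rep(rep(x$channels$channel, each = d[1]), times = d[3]),
    label = rep(rep(x$channels$label, each = d[1]), times = d[3]),
    time_ms = rep(x$time_ms, each = d[1] * d[2]),
    amplitude_mA = rep(x$trials$amplitude_mA, times = d[2] * d[3]),
    value_uV = as.vector(x$data)
  )
}
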