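SESSION_SCHEMA <- "esr-session/1"

geometry_to_list <- function(geo) {
  out <- unclass(geo)
  out$contacts <- as.data.frame(out$contacts)
  out
}

geometry_from_list <- function(lst) {
  lst$contacts <- tibble::as_tibble(lst$contacts)
  lst$contacts$contact <- as.integer(lst$contacts$contact)
  lst$contacts$lead <- as.integer(lst$contacts$lead)
  lst$n_leads <- as.integer(lst$n_leads)
  lst$contacts_per_lead <- as.integer(lst$contacts_per_lead)
  lst$stim_anode <- as.integer(lst$stim_anode)
  lst$stim_cathode <- as.integer(lst$stim_cathode)
  validate_geometry(structure(lst, class = "esr_geometry"))
}

protocol_from_list <- function(lst) {
  do.call(stim_protocol, lst)
}

#' Write / read a recording session
#'
#' A session directory holds `potentials.f32`, a flat little-endian 32-bit
#' float file in channel-major order (all samples of electrode 1, then
#' electrode 2, ...), and `meta.json`, a sidecar carrying the schema version,
#' sampling rate, array shape, channel labels, stimulation events, geometry,
#' protocol and label. Because session potentials are held in single
#' precision in memory, a write/read round trip is bit-exact.
#'
#' @param session An `esr_session`.
#' @param path Directory to create/read.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns an `esr_session`.
#' @examples
#' ses <- simulate_session(
#'   protocol = stim_protocol(amplitude_mA = 2, pulses_per_amplitude = 3),
#'   seed = 1
#' )
#' dir <- file.path(tempdir(), "ses")
#' write_session(ses, dir)
#' ses2 <- read_session(dir)
#' identical(ses$potentials, ses2$potentials)
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "esr_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pot <- session$potentials
  con <- file(file.path(path, "potentials.f32"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(t(pot)), con, size = 4L, endian = "little")

  meta <- list(
    schema_version = SESSION_SCHEMA,
    sampling_rate_hz = session$sampling_rate_hz,
    n_channels = nrow(pot),
    n_samples = ncol(pot),
    channel_labels = rownames(pot),
    label = session$label,
    events = as.data.frame(session$events),
    geometry = geometry_to_list(session$geometry),
    protocol = unclass(session$protocol)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  arr_path <- file.path(path, "potentials.f32")
  if (!file.exists(meta_path)) {
    rlang::abort(sprintf("missing metadata sidecar: %s", meta_path),
      class = "esrkit_error_missing_sidecar"
    )
  }
  if (!file.exists(arr_path)) {
    rlang::abort(sprintf("missing array file: %s", arr_path),
      class = "esrkit_error_missing_array"
    )
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SESSION_SCHEMA)) {
    rlang::abort(
      sprintf("unknown session schema version: %s", meta$schema_version %||% "<none>"),
      class = "esrkit_error_schema"
    )
  }
  n_ch <- meta$n_channels
  n_samp <- meta$n_samples
  expected <- 4 * n_ch * n_samp
  if (file.info(arr_path)$size != expected) {
    rlang::abort(
      sprintf(
        "array shape mismatch: expected %d bytes (%d x %d float32), found %d",
        expected, n_ch, n_samp, file.info(arr_path)$size
      ),
      class = "esrkit_error_shape"
    )
  }
  con <- file(arr_path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double", n = n_ch * n_samp, size = 4L, endian = "little")
  pot <- t(matrix(x, nrow = n_samp, ncol = n_ch))
  rownames(pot) <- meta$channel_labels

  events <- tibble::as_tibble(meta$events)
  if (nrow(events) == 0) {
    events <- tibble::tibble(sample = integer(), amplitude_mA = numeric())
  }
  events$sample <- as.integer(events$sample)

  new_esr_session(
    potentials = pot,
    sampling_rate_hz = meta$sampling_rate_hz,
    events = events,
    geometry = geometry_from_list(meta$geometry),
    protocol = protocol_from_list(meta$protocol),
    label = meta$label
  )
}

#' Write / read a feature table
#'
#' Feature tables are plain CSV with one row per (trial, channel) and the
#' documented columns produced by [extract_features()]. Reading restores
#' column types, so a write/read round trip returns an equal table.
#'
#' @param features A tibble from [extract_features()].
#' @param path CSV file path.
#' @return `write_features()` returns `path` invisibly; `read_features()` a
#'   tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      trial = "i", channel = "i", lead = "i", n_trials = "i",
      no_negative_peak = "l", label = "c", component = "c",
      .default = readr::col_double()
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
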