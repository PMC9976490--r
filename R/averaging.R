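#' Grouped median waveforms
#'
#' Per-channel, per-sample median across groups of consecutive trials, the
#' robust averaging step used before feature extraction: with 300 trials and
#' `group_size = 5`, 60 median traces result. Groups are formed within each
#' stimulation amplitude in trial order; a trailing incomplete group is
#' dropped. `group_size = "all"` collapses each amplitude to a single median
#' trace (e.g. the median of 150-300 trials shown in published figures).
#'
#' @param epochs An `esr_epochs`.
#' @param group_size `"all"` or an integer >= 2.
#' @return An `esr_epochs` whose trials are the grouped medians; the `trials`
#'   tibble records the group's amplitude and the number of trials pooled.
#' @export
median_waveform <- function(epochs, group_size = 5) {
  stopifnot(inherits(epochs, "esr_epochs"))
  n_tr <- dim(epochs$data)[1]
  if (!identical(group_size, "all")) {
    group_size <- as.integer(group_size)
    if (group_size < 2) {
      rlang::abort("group_size must be 'all' or an integer >= 2", class = "esrkit_error_average")
    }
    if (group_size > n_tr) {
      rlang::abort("group_size exceeds the number of trials", class = "esrkit_error_average")
    }
  }

  amp <- epochs$trials$amplitude_mA
  # consecutive runs of equal amplitude
  run_id <- cumsum(c(1L, as.integer(diff(as.numeric(factor(amp))) != 0)))
  groups <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (identical(group_size, "all")) {
      groups[[length(groups) + 1L]] <- idx
    } else {
      n_full <- length(idx) %/% group_size
      for (g in seq_len(n_full)) {
        groups[[length(groups) + 1L]] <- idx[((g - 1L) * group_size + 1L):(g * group_size)]
      }
    }
  }
  n_g <- length(groups)
  d <- dim(epochs$data)
  out <- array(0, dim = c(n_g, d[2], d[3]))
  for (g in seq_len(n_g)) {
    idx <- groups[[g]]
    if (length(idx) == 1L) {
      out[g, , ] <- epochs$data[idx, , ]
    } else {
      D <- matrix(epochs$data[idx, , , drop = FALSE], nrow = length(idx))
      out[g, , ] <- colwise_median(D)
    }
  }

  new_esr_epochs(
    data = out,
    time_ms = epochs$time_ms,
    channels = epochs$channels,
    trials = tibble::tibble(
      trial = seq_len(n_g),
      sample = vapply(groups, function(i) as.integer(epochs$trials$sample[i[1]]), integer(1)),
      amplitude_mA = vapply(groups, function(i) epochs$trials$amplitude_mA[i[1]], numeric(1)),
      n_trials = vapply(groups, length, integer(1))
    ),
    sampling_rate_hz = epochs$sampling_rate_hz,
    stim_end_ms = epochs$stim_end_ms,
    reference = epochs$reference
  )
}

# per-column median via a single order() pass (columns sorted independently)
colwise_median <- function(D) {
  k <- nrow(D)
  S <- matrix(D[order(col(D), D)], nrow = k)
  if (k %% 2 == 1L) S[(k + 1L) / 2L, ] else (S[k / 2L, ] + S[k / 2L + 1L, ]) / 2
}
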