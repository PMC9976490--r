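#' Band-pass filter epoched traces
#'
#' Applies the standard offline filter pair to every trace: a first-order
#' Butterworth high-pass (default 100 Hz) run causally (forward only, so
#' onsets stay causal; its constant group delay cancels in every
#' between-channel difference), followed by a zero-phase Gaussian low-pass
#' whose frequency response is -3 dB at the cutoff (default 3 kHz). The
#' Gaussian kernel standard deviation follows from `|G(fc)| = 1/sqrt(2)` with
#' `G(f) = exp(-2 (pi sigma f)^2)`, i.e. `sigma = sqrt(log(2)) / (2 pi fc)`;
#' the kernel is truncated at +/- 4 sigma and edge samples are handled by
#' replicate padding.
#'
#' @param epochs An `esr_epochs`.
#' @param hp_hz High-pass cutoff, Hz (default 100); `NULL` disables.
#' @param lp_hz Gaussian low-pass -3 dB point, Hz (default 3000); `NULL`
#'   disables.
#' @return Filtered `esr_epochs`.
#' @export
bandpass_epochs <- function(epochs, hp_hz = 100, lp_hz = 3000) {
  stopifnot(inherits(epochs, "esr_epochs"))
  fs <- epochs$sampling_rate_hz
  for (fc in c(hp_hz, lp_hz)) {
    if (!is.null(fc) && fc >= fs / 2) {
      rlang::abort(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)", fc, fs / 2),
        class = "esrkit_error_filter"
      )
    }
  }

  bw <- if (!is.null(hp_hz)) signal::butter(1, hp_hz / (fs / 2), type = "high") else NULL
  kern <- if (!is.null(lp_hz)) gaussian_lp_kernel(lp_hz, fs) else NULL

  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- out[i, j, ]
      if (!is.null(bw)) x <- as.numeric(signal::filter(bw, x))
      if (!is.null(kern)) x <- conv_same(x, kern)
      out[i, j, ] <- x
    }
  }
  epochs$data <- out
  epochs
}

#' Gaussian low-pass kernel
#'
#' Symmetric discrete Gaussian kernel (unit sum, truncated at 4 sigma) whose
#' continuous frequency response is -3 dB at `fc_hz`.
#'
#' @param fc_hz Cutoff (-3 dB) frequency, Hz.
#' @param fs_hz Sampling rate, Hz.
#' @return Odd-length numeric kernel.
#' @export
gaussian_lp_kernel <- function(fc_hz, fs_hz) {
  sigma_s <- sqrt(log(2)) / (2 * pi * fc_hz)
  sigma_n <- sigma_s * fs_hz
  half <- max(1L, ceiling(4 * sigma_n))
  k <- exp(-((-half):half)^2 / (2 * sigma_n^2))
  k / sum(k)
}

# zero-phase convolution with replicate padding, output length == input length
conv_same <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + length(x))])
}
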