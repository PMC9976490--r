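make_epochs <- function(seed = 1, ...) {
  ses <- simulate_session(
    lead_geometry(),
    stim_protocol(amplitude_mA = 2.4, pulses_per_amplitude = 3),
    seed = seed, ...
  )
  epoch_session(ses)
}

trace_of <- function(ep, channel, trial = 1) {
  ep$data[trial, which(ep$channels$channel == channel), ]
}

test_that("REFk re-referencing of channel k is dropped (identically zero trace)", {
  ep <- make_epochs()
  r9 <- apply_reference(ep, "REF9")
  expect_false(9 %in% r9$channels$channel)
  # and the stimulation contacts never survive any scheme
  for (sch in c("LTR", "DIFF", "REF9", "REF3")) {
    out <- apply_reference(ep, sch)
    expect_false(any(out$channels$channel %in% c(7, 8)))
  }
  # LTR keeps the 14 non-stimulation contacts
  expect_equal(nrow(apply_reference(ep, "LTR")$channels), 14L)
})

test_that("REF9 equals the difference of the two LTR recordings", {
  ep <- make_epochs(seed = 3)
  ltr <- apply_reference(ep, "LTR")
  r9 <- apply_reference(ep, "REF9")
  direct <- trace_of(r9, 1)
  via_ltr <- trace_of(ltr, 1) - trace_of(ltr, 9)
  expect_lt(max(abs(direct - via_ltr)), 1e-9)
  # re-referencing the LTR data gives the same answer as ground-based data
  r9_from_ltr <- apply_reference(ltr, ref_scheme("REF", k = 9))
  expect_equal(trace_of(r9_from_ltr, 1), direct)
})

test_that("DIFF cancels a pure common-mode input exactly", {
  ep <- make_epochs(
    ecap = no_ecap(), emg = no_emg(), artifact = no_artifact(),
    noise = quiet_noise()
  )
  # identical synthetic signal on every electrode
  sig <- sin(seq_along(ep$time_ms) / 5)
  for (k in seq_len(dim(ep$data)[1])) {
    ep$data[k, , ] <- matrix(sig, nrow = dim(ep$data)[2], ncol = length(sig), byrow = TRUE)
  }
  dif <- apply_reference(ep, "DIFF")
  expect_true(all(dif$data == 0))
  # DIFF pairs each channel with its next more caudal neighbour, so the last
  # caudal contact of the recording lead is dropped
  expect_false(16 %in% dif$channels$channel)
})

test_that("referencing is linear in the input potentials", {
  e1 <- make_epochs(seed = 1)
  e2 <- make_epochs(seed = 2)
  mix <- e1
  mix$data <- 2 * e1$data - 3 * e2$data
  for (sch in c("LTR", "DIFF", "REF9", "REF3")) {
    got <- apply_reference(mix, sch)$data
    want <- 2 * apply_reference(e1, sch)$data - 3 * apply_reference(e2, sch)$data
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("DIFF suppresses the stimulation artifact relative to LTR", {
  # artifact-only session: neighbouring contacts see similar artifact gains
  ses <- simulate_session(
    lead_geometry(),
    stim_protocol(amplitude_mA = 2.4, pulses_per_amplitude = 3),
    ecap = no_ecap(), emg = no_emg(), noise = quiet_noise(), seed = 1
  )
  ep <- epoch_session(ses)
  win <- c(-0.48, 1) # over the pulse, in post-pulse-end coordinates
  p2p <- function(sch) {
    out <- median_waveform(apply_reference(ep, sch), "all")
    f <- extract_features(out, component = "custom", window_ms = win)
    f[, c("channel", "p2p_uV")]
  }
  m <- dplyr::inner_join(p2p("DIFF"), p2p("LTR"), by = "channel", suffix = c("_diff", "_ltr"))
  expect_true(all(m$p2p_uV_diff <= m$p2p_uV_ltr))
})

test_that("an on-lead reference adds the inverse of its own ECAP", {
  ses <- sim_clean_ecap(lead_geometry(), seed = 1)
  ep <- epoch_session(ses)
  r9 <- apply_reference(ep, "REF9")
  # ground-referenced data are the pure per-contact ECAPs here
  expect_equal(
    trace_of(r9, 1) - trace_of(ep, 1),
    -trace_of(ep, 9)
  )
})

test_that("REF3 collapses the apparent conduction delay rostral of contact 3", {
  ses <- sim_clean_ecap(lead_geometry(), seed = 1)
  ep <- epoch_session(ses)
  lat <- function(sch, chs) {
    f <- extract_features(median_waveform(apply_reference(ep, sch), "all"), channels = chs)
    f$latency_ms[order(f$channel)]
  }
  ltr_rostral <- lat("LTR", 1:2)
  ref3_rostral <- lat("REF3", 1:2)
  # the inter-contact delay between the channels rostral of the reference
  # contact shrinks because contact 3 records the ECAP too
  expect_lt(ref3_rostral[1] - ref3_rostral[2], ltr_rostral[1] - ltr_rostral[2])
  # polarity flip: the subtracted contact-3 ECAP shows up as a positive
  # deflection on the rostral channels
  max_in_win <- function(sch) {
    med <- median_waveform(apply_reference(ep, sch), "all")
    tr <- med$data[1, which(med$channels$channel == 1), ]
    idx <- med$time_ms >= 0.48 + 0.33 & med$time_ms <= 0.48 + 1.8
    max(tr[idx])
  }
  expect_gt(max_in_win("REF3"), 2 * max_in_win("LTR"))
  # caudal of contact 3 the ordering is untouched: latency still grows with
  # distance from the stimulation site
  ref3_caudal <- lat("REF3", 4:6)
  expect_true(all(diff(ref3_caudal) < 0)) # channels 4 > 5 > 6 in distance
})

test_that("invalid reference requests are rejected", {
  ep <- make_epochs()
  expect_error(apply_reference(ep, "REF7"), class = "esrkit_error_reference")
  expect_error(ref_scheme("REF"), class = "esrkit_error_reference")
  ltr <- apply_reference(ep, "LTR")
  expect_error(apply_reference(ltr, "LTR"), class = "esrkit_error_reference")
})
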