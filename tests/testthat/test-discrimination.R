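test_that("propagation_test separates travelling from simultaneous components", {
  # simulated ECAP at 60 m/s, noiseless: propagating
  ses <- sim_clean_ecap(near_geometry(), velocity = 60, seed = 1)
  f <- ltr_all_median_features(ses)
  pt <- propagation_test(f$distance_mm, f$peak_time_ms)
  expect_equal(pt$verdict, "propagating")
  expect_equal(pt$implied_velocity_m_per_s, 60, tolerance = 0.03)

  # simulated EMG burst (zero inter-contact delay) plus noise: common-mode
  ses_cm <- simulate_session(
    near_geometry(),
    stim_protocol(amplitude_mA = 3, pulses_per_amplitude = 10),
    ecap = no_ecap(), emg = emg_source(threshold_mA = 2), artifact = no_artifact(),
    noise = noise_model(white_sd_uV = 5), seed = 2
  )
  f_cm <- ltr_all_median_features(ses_cm, component = "emg")
  pt_cm <- propagation_test(f_cm$distance_mm, f_cm$peak_time_ms)
  expect_true(pt_cm$verdict %in% c("common-mode", "indeterminate"))

  # exact delays implying 500 m/s: significant slope, non-physiological
  d <- c(0, 7, 14, 21, 28)
  pt_fast <- propagation_test(d, d / 500)
  expect_equal(pt_fast$verdict, "indeterminate")

  expect_error(propagation_test(c(0, 7, 14), c(0, 0.1, 0.2)),
    class = "esrkit_error_propagation"
  )
})

test_that("the test controls its type-I error on common-mode sessions", {
  geo <- near_geometry(15)
  pr <- stim_protocol(amplitude_mA = 3, pulses_per_amplitude = 10)
  n_sim <- 120
  verdicts <- vapply(seq_len(n_sim), function(s) {
    ses <- simulate_session(geo, pr,
      ecap = no_ecap(), emg = emg_source(threshold_mA = 2), artifact = no_artifact(),
      noise = noise_model(white_sd_uV = 5), seed = 10000 + s
    )
    f <- ltr_all_median_features(ses, component = "emg")
    propagation_test(f$distance_mm, f$peak_time_ms)$verdict
  }, character(1))
  rate <- mean(verdicts == "propagating")
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("power at 60 m/s with SNR >= 5 exceeds 95%", {
  # nearest-contact ECAP ~ 430 uV, sigma 5 uV; the weakest channel still has
  # peak SNR > 5 after the median of 20 trials
  geo <- near_geometry(15)
  n_sim <- 60
  verdicts <- vapply(seq_len(n_sim), function(s) {
    ses <- simulate_session(geo,
      stim_protocol(amplitude_mA = 1.8, pulses_per_amplitude = 20),
      emg = no_emg(), noise = noise_model(white_sd_uV = 5), seed = 20000 + s
    )
    med <- median_waveform(bandpass_epochs(subset_channels(
      apply_reference(epoch_session(ses), "LTR"), 9:16
    )), "all")
    f <- extract_features(med)
    propagation_test(f$distance_mm, f$peak_time_ms)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "propagating"), 0.95)
})

test_that("spillover is flagged above both thresholds and only there", {
  geo <- lead_geometry()
  run <- function(amp, seed = 7) {
    ses <- simulate_session(geo,
      stim_protocol(amplitude_mA = amp, pulses_per_amplitude = 10),
      emg = emg_source(threshold_mA = 2),
      noise = noise_model(white_sd_uV = 5), seed = seed
    )
    flag_spillover(median_waveform(apply_reference(epoch_session(ses), "LTR"), "all"))
  }
  # 3 mA: EMG recruited, its leading tail swamps the attenuated ECAP window
  sp3 <- run(3)
  expect_true(sp3$any_spillover)
  expect_true(glance(sp3)$ecap_window_verdict != "propagating")
  expect_gt(sum(tidy(sp3)$spillover), 0)

  # 1.2 mA: distinguishable ECAP, no EMG, nothing to flag
  sp12 <- run(1.2)
  expect_false(sp12$any_spillover)
  expect_true(all(!tidy(sp12)$emg_above))

  # zero-signal session: clean report
  ses0 <- simulate_session(geo,
    stim_protocol(amplitude_mA = 2, pulses_per_amplitude = 10),
    ecap = no_ecap(), emg = no_emg(), artifact = no_artifact(),
    noise = noise_model(white_sd_uV = 5), seed = 3
  )
  sp0 <- flag_spillover(median_waveform(apply_reference(epoch_session(ses0), "LTR"), "all"))
  expect_false(sp0$any_spillover)
})
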