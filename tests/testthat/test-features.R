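test_that("negative_peak reports latency from the pulse end with tie-breaks", {
  fs <- 25000
  t <- (0:75) * 1000 / fs - 1.28 # epoch axis, onset at 0
  win <- c(0.33, 1.8)

  tr <- rep(0, length(t))
  tr[which.min(abs(t - (0.48 + 1.0)))] <- -5 # single deflection 1 ms after pulse end
  pk <- negative_peak(tr, t, win)
  expect_equal(pk$latency_ms, 1.0)
  expect_equal(pk$amplitude_uV, -5)
  expect_false(pk$no_negative_peak)

  # all-positive trace: least positive sample, flagged
  pos <- 2 + abs(sin(seq_along(t) / 3))
  expect_true(negative_peak(pos, t, win)$no_negative_peak)

  # two equal minima: the earlier one wins
  tr2 <- rep(0, length(t))
  i <- which(t >= 0.48 + win[1] & t <= 0.48 + win[2])
  tr2[i[5]] <- tr2[i[20]] <- -3
  expect_equal(negative_peak(tr2, t, win)$peak_time_ms, t[i[5]])

  expect_error(negative_peak(tr, t, c(30, 31)), class = "esrkit_error_window")
})

test_that("peak_to_peak and auc_abs follow their closed forms", {
  fs <- 25000
  t <- (0:99) * 1000 / fs
  win <- c(0, t[100] - 0.48)
  expect_equal(peak_to_peak(rep(0, 100), t, win), 0)
  # unit square pulse of height h
  sq <- rep(0, 100)
  sq[30:40] <- 7
  expect_equal(peak_to_peak(sq, t, win), 7)
  expect_equal(peak_to_peak(sq + 3, t, win), 7) # offset invariant

  expect_equal(auc_abs(rep(0, 100), t, win), 0)
  # constant 10 uV over 2 ms -> 20 uV.ms (plain sum x dt)
  t2 <- seq(0, 2, by = 0.04)
  c10 <- rep(10, length(t2))
  expect_equal(auc_abs(c10, t2, c(-0.48, 2 - 0.48)), 10 * length(t2) * 0.04)
  expect_equal(auc_abs(-c10, t2, c(-0.48, 2 - 0.48)), auc_abs(c10, t2, c(-0.48, 2 - 0.48)))
})

test_that("conduction_velocity inverts the latency-distance slope", {
  cv <- conduction_velocity(c(0, 7, 14), c(0, 0.1, 0.2))
  expect_equal(cv$velocity_m_per_s, 70)
  expect_false(cv$non_propagating)
  expect_equal(glance(cv)$fiber_class, "Abeta")

  flat <- conduction_velocity(c(0, 7, 14, 21), c(0.5, 0.5, 0.5, 0.5))
  expect_true(flat$non_propagating)
  expect_true(is.na(flat$velocity_m_per_s))

  expect_error(conduction_velocity(c(0, 7), c(0, 0.1)), class = "esrkit_error_cv")
  expect_error(conduction_velocity(rep(3, 4), c(1, 2, 3, 4)), class = "esrkit_error_cv")
  # flagged channels are excluded
  cv2 <- conduction_velocity(
    c(0, 7, 14, 21), c(0, 0.1, 0.2, 9),
    exclude = c(FALSE, FALSE, FALSE, TRUE)
  )
  expect_equal(cv2$velocity_m_per_s, 70)
  expect_equal(cv2$n_channels, 3L)
})

test_that("fiber classification follows the physiological bins", {
  expect_equal(
    classify_fiber(c(4, 5, 34.9, 35, 60, 79.9, 80, 120, 121, NA)),
    c(
      "out-of-range", "Adelta", "Adelta", "Abeta", "Abeta", "Abeta",
      "Aalpha", "Aalpha", "out-of-range", "out-of-range"
    )
  )
})

test_that("a noiseless simulated ECAP at 72.29 m/s is recovered within 1%", {
  ses <- sim_clean_ecap(near_geometry(30), velocity = 72.29, seed = 1)
  cv <- estimate_cv(ltr_all_median_features(ses), channels = 9:16)
  expect_equal(cv$velocity_m_per_s, 72.29, tolerance = 0.01)
  expect_gt(cv$r_squared, 0.99)
})

test_that("the noisy recovery suite stays within 5% across the A-beta range", {
  geo <- near_geometry(18)
  for (v in c(35, 60, 80)) {
    ses <- simulate_session(
      geo,
      stim_protocol(amplitude_mA = 2.4, pulses_per_amplitude = 200),
      ecap = ecap_source(velocity_m_per_s = v, amplitude_at_stim_uV = 10000),
      emg = no_emg(), noise = noise_model(white_sd_uV = 5), seed = 1
    )
    ep <- bandpass_epochs(subset_channels(
      apply_reference(epoch_session(ses), "LTR"), 9:16
    ))
    f <- extract_features(median_waveform(ep, 5),
      component = "custom", window_ms = c(0.33, 2.6)
    )
    expect_equal(nrow(f), 40 * 8) # 200 trials -> 40 grouped medians
    cv <- estimate_cv(f)
    expect_lt(abs(cv$velocity_m_per_s - v) / v, 0.05)
  }
})

test_that("dose-response curves are sorted, monotone above threshold", {
  ses <- simulate_session(
    lead_geometry(),
    stim_protocol(amplitude_mA = seq(3, 0.5, by = -0.5), pulses_per_amplitude = 4),
    emg = no_emg(), noise = quiet_noise(), seed = 1
  )
  f <- ltr_all_median_features(ses, channels = 16)
  dr <- dose_response(f)
  expect_true(all(diff(dr$amplitude_mA) > 0))
  expect_true(all(diff(dr$auc_uVms) >= 0))

  # all-zero responses: flat curve, threshold undefined
  f0 <- f
  f0$auc_uVms <- 0
  f0$baseline_auc_uVms <- 0
  expect_true(is.na(detect_threshold(dose_response(f0))))

  # single amplitude: threshold undefined by contract
  expect_error(detect_threshold(dose_response(f[f$amplitude_mA == 2, ])),
    class = "esrkit_error_threshold"
  )
})

test_that("detect_threshold demands a sustained supra-criterion response", {
  dr <- tibble::tibble(
    amplitude_mA = seq(0.5, 2, by = 0.25),
    auc_uVms = c(0, 8, 0, 0, 2, 5, 9), n = 1
  )
  class(dr) <- c("esr_dose_response", class(tibble::tibble()))
  # the isolated excursion at 0.75 mA does not count
  expect_equal(detect_threshold(dr, baseline_mean = 0.5, baseline_sd = 0.2), 1.5)
  expect_true(is.na(detect_threshold(dr, baseline_mean = 20, baseline_sd = 1)))
})

test_that("configured ECAP and EMG thresholds are recovered from a 0.1 mA sweep", {
  ses <- simulate_session(
    lead_geometry(),
    stim_protocol(amplitude_mA = seq(0.5, 4, by = 0.1), pulses_per_amplitude = 10),
    emg = emg_source(threshold_mA = 2),
    noise = noise_model(white_sd_uV = 5), seed = 11
  )
  med <- median_waveform(apply_reference(epoch_session(ses), "LTR"), "all")
  thr_ecap <- detect_threshold(dose_response(
    extract_features(med, component = "ecap", channels = 16)
  ))
  thr_emg <- detect_threshold(dose_response(
    extract_features(med, component = "emg", channels = 16)
  ))
  expect_equal(thr_ecap, 1.2)
  expect_equal(thr_emg, 2.0)
  expect_equal(round(thr_emg / thr_ecap, 2), 1.67)
})

test_that("per-subject threshold arithmetic matches the published cohort", {
  ts <- threshold_summary()
  expect_equal(nrow(ts$per_subject), 5L)
  expect_equal(ts$per_subject$ratio[ts$per_subject$subject == "S1"], 1.67, tolerance = 0.005)
  expect_equal(ts$mean_excess_pct, 56, tolerance = 1)
})
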