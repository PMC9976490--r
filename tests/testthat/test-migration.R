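session_features <- function(geometry, seed, amplitude = 1.8, pulses = 60) {
  ses <- simulate_session(
    geometry,
    stim_protocol(amplitude_mA = amplitude, pulses_per_amplitude = pulses),
    noise = noise_model(white_sd_uV = 5), seed = seed
  )
  ltr_median_features(ses, group = 5, channels = 16)
}

test_that("identical sessions produce no migration flag", {
  geo <- near_geometry(35)
  b <- session_features(geo, 1)
  m <- compare_sessions(b, b)
  expect_equal(m$delta_latency_ms, 0)
  expect_equal(m$pct_change_auc, 0)
  expect_false(m$migration_flag)
  expect_equal(m$direction_hint, "none")
})

test_that("a 3.5 mm rostral shift of the recording lead is flagged", {
  geo <- near_geometry(35)
  b <- session_features(geo, 101)
  t <- session_features(shift_lead(geo, 2, 3.5), 201)
  m <- compare_sessions(b, t)
  expect_gt(m$delta_latency_ms, 0)
  expect_lt(m$pct_change_auc, 0)
  expect_true(m$migration_flag)
  expect_equal(m$direction_hint, "rostro-caudal-consistent")
  # the latency grows by added distance / velocity, within one sample period
  expect_lt(abs(m$delta_latency_ms - 3.5 / 60), 0.04)
})

test_that("a lateral stimulation-lead shift changes amplitude but not latency", {
  geo <- near_geometry(35)
  b <- session_features(geo, 301)
  t <- session_features(shift_lead(geo, 1, 0, 3.5), 401)
  m <- compare_sessions(b, t)
  expect_gte(m$latency_p, m$alpha)
  expect_lt(m$auc_p, m$alpha)
  expect_lt(m$pct_change_auc, 0)
  expect_equal(m$direction_hint, "amplitude-only")
})

test_that("latency rises and AUC falls monotonically across rostral shifts", {
  # the shift pattern 0 / 3.5 / 28 / 52.5 mm, noiseless for exact ordering
  geo <- near_geometry(35)
  stats <- vapply(c(0, 3.5, 28, 52.5), function(dd) {
    g <- if (dd == 0) geo else shift_lead(geo, 2, dd)
    ses <- sim_clean_ecap(g, velocity = 60, amplitude_mA = 1.8, pulses = 5, seed = 1)
    f <- ltr_all_median_features(ses, channels = 16)
    c(lat = mean(f$latency_ms), auc = mean(f$auc_norm))
  }, numeric(2))
  expect_true(all(diff(stats["lat", ]) > 0))
  expect_true(all(diff(stats["auc", ]) < 0))
  # each latency step equals added distance / velocity to one sample period
  expect_true(all(abs(diff(stats["lat", ]) - diff(c(0, 3.5, 28, 52.5)) / 60) <= 0.04))
})

test_that("the false-alarm rate on identical configurations respects alpha", {
  geo <- near_geometry(35)
  n_pair <- 60
  flags <- vapply(seq_len(n_pair), function(i) {
    b <- session_features(geo, 30000 + 2 * i, pulses = 25)
    t <- session_features(geo, 30001 + 2 * i, pulses = 25)
    compare_sessions(b, t)$migration_flag
  }, logical(1))
  expect_lte(mean(flags), 0.05 + 2 * sqrt(0.05 * 0.95 / n_pair))
})

test_that("comparisons demand at least five grouped medians", {
  geo <- near_geometry(35)
  b <- session_features(geo, 1, pulses = 25)
  expect_error(compare_sessions(b[1:4, ], b), class = "esrkit_error_migration")
})

test_that("normality_check follows the Shapiro-Wilk contract", {
  expect_error(normality_check(c(1, 2)), class = "esrkit_error_stats")
  expect_error(normality_check(rep(1, 10)), class = "esrkit_error_stats")
  nc <- normality_check(stats::qnorm((1:50) / 51))
  expect_true(nc$W > 0.95 && nc$p > 0.05)
  # seeded Monte-Carlo: normal samples pass in at least 90% of repeats
  ok <- with(list(), {
    set.seed(2024)
    vapply(1:100, function(i) normality_check(rnorm(50))$p > 0.05, logical(1))
  })
  expect_gte(mean(ok), 0.90)
})

test_that("group_comparison runs ANOVA with a Tukey HSD table", {
  # identical groups: F ~ 0 and no significant pair
  v <- rep(c(1, 2, 3, 4), times = 3)
  g <- rep(c("I", "II", "III"), each = 4)
  gc0 <- group_comparison(v, g)
  expect_lt(gc0$f_statistic, 1e-10)
  expect_true(all(gc0$tukey$p_adj > 0.99))

  # one group shifted by 10 SD: that pair significant
  set.seed(1)
  v2 <- c(rnorm(8), rnorm(8), rnorm(8) + 10)
  g2 <- rep(c("I", "II", "III"), each = 8)
  gc1 <- group_comparison(v2, g2)
  expect_lt(gc1$p, 1e-6)
  expect_lt(gc1$tukey$p_adj[gc1$tukey$contrast == "III-I"], 0.001)

  expect_error(group_comparison(1:5, rep("a", 5)), class = "esrkit_error_stats")

  # simulated four-position latency data: monotone group means (shifts kept
  # within the range where the recorded ECAP stays above the noise floor)
  geo <- near_geometry(35)
  feats <- lapply(c(0, 3.5, 14, 24.5), function(dd) {
    g <- if (dd == 0) geo else shift_lead(geo, 2, dd)
    session_features(g, seed = 500 + dd, pulses = 25)$latency_ms
  })
  gc2 <- group_comparison(
    unlist(feats),
    rep(c("I", "II", "III", "IV"), times = vapply(feats, length, integer(1)))
  )
  expect_lt(gc2$p, 0.001)
  expect_true(all(diff(gc2$group_means$mean) > 0))
})
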