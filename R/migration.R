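#' Shapiro-Wilk normality check
#'
#' Thin, validated wrapper around [stats::shapiro.test()], used to gate the
#' parametric two-sample comparison in [compare_sessions()]: clearly
#' non-normal feature distributions fall back to a rank-based test.
#'
#' @param samples Numeric vector, n >= 3, not all identical.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 3) {
    rlang::abort("normality check needs at least 3 observations", class = "esrkit_error_stats")
  }
  if (stats::sd(samples) == 0) {
    rlang::abort("normality check is undefined for a constant sample", class = "esrkit_error_stats")
  }
  ht <- stats::shapiro.test(samples)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Standard one-way ANOVA across location groups (e.g. lead positions I-IV)
#' followed by Tukey's Honestly Significant Difference pairwise table.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 values for a
#'   residual df).
#' @return List: `f_statistic`, `p`, `df`, `tukey` (tibble: `contrast`,
#'   `diff`, `lwr`, `upr`, `p_adj`), `group_means` (tibble).
#' @export
group_comparison <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    rlang::abort("group comparison needs at least 2 groups", class = "esrkit_error_stats")
  }
  df <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    f_statistic = an[["F value"]][1],
    p = an[["Pr(>F)"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    tukey = tibble::tibble(
      contrast = rownames(tk),
      diff = tk[, "diff"],
      lwr = tk[, "lwr"],
      upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    ),
    group_means = df |>
      dplyr::group_by(.data$g) |>
      dplyr::summarise(mean = mean(.data$y), sd = stats::sd(.data$y), n = dplyr::n()) |>
      dplyr::rename(group = "g")
  )
}

# two-sample comparison robust to discrete / degenerate feature distributions:
# Shapiro-gated Welch t-test with a rank-based fallback
two_sample_p <- function(x, y, alpha = 0.05) {
  if (stats::sd(c(x, y)) == 0) {
    return(list(statistic = 0, p = 1, method = "degenerate"))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # two distinct constants: the difference is exact
    return(list(statistic = Inf, p = 0, method = "degenerate"))
  }
  normal_ok <- function(v) {
    if (stats::sd(v) == 0 || length(v) < 3) {
      return(FALSE)
    }
    stats::shapiro.test(v)$p.value > alpha
  }
  if (normal_ok(x) && normal_ok(y)) {
    ht <- stats::t.test(x, y)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = "t-test")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value, method = "wilcoxon")
  }
}

#' Compare two sessions' ECAP features for lead migration
#'
#' Detects lead migration from between-session changes in the two ECAP
#' features that track electrode displacement: negative-peak latency (path
#' length / conduction velocity) and amplitude-normalized AUC (tissue
#' coupling). Inputs are per-grouped-median feature tables (see
#' [median_waveform()] and [extract_features()]) from the same channel(s) at
#' comparable stimulation amplitudes; AUC is normalized to the stimulation
#' amplitude before comparison.
#'
#' Latency is compared with a two-sample test on the grouped-median latency
#' distributions (Welch t-test, gated by Shapiro-Wilk with a Wilcoxon
#' fallback). The percent AUC change `100 * (AUC_test - AUC_base) / AUC_base`
#' gets a bootstrap SD and two-sided p (resampling grouped medians within each
#' session, `n_boot` draws, seeded). The migration flag requires at least one
#' feature change that is both significant at `alpha` and above its magnitude
#' floor — by default 0.08 ms (two samples at 25 kHz) for latency and 20% for
#' AUC — so that huge-n statistical flukes alone cannot raise it. A direction
#' hint summarizes the pattern: significant latency increase with AUC decrease
#' is consistent with rostro-caudal migration; a significant AUC change with
#' stable latency is the amplitude-only signature of medio-lateral shifts.
#'
#' @param baseline_features,test_features Feature tibbles (>= 5 grouped
#'   medians each).
#' @param alpha Significance level (default 0.05).
#' @param floors List with `latency_ms` (default 0.08) and `pct_auc`
#'   (default 20): minimum magnitudes for flagging.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `esr_migration`: `delta_latency_ms`
#'   (mean +/- sd), `latency_p`, `latency_method`, `pct_change_auc`,
#'   `pct_change_auc_sd`, `auc_p`, `migration_flag`, `direction_hint`,
#'   `alpha`, `floors`, `n_baseline`, `n_test`.
#' @export
compare_sessions <- function(baseline_features, test_features, alpha = 0.05,
                             floors = list(latency_ms = 0.08, pct_auc = 20),
                             n_boot = 1000, seed = 1L) {
  for (f in list(baseline_features, test_features)) {
    if (nrow(f) < 5) {
      rlang::abort("need at least 5 grouped medians per session", class = "esrkit_error_migration")
    }
  }
  lat_b <- baseline_features$latency_ms
  lat_t <- test_features$latency_ms
  auc_b <- baseline_features$auc_norm
  auc_t <- test_features$auc_norm

  delta_lat <- mean(lat_t) - mean(lat_b)
  # SD of the difference of two independent grouped-median draws
  delta_lat_sd <- sqrt(stats::var(lat_t) + stats::var(lat_b))
  lat_test <- two_sample_p(lat_b, lat_t, alpha = alpha)

  pct <- 100 * (mean(auc_t) - mean(auc_b)) / mean(auc_b)
  boot <- with_seed_local(seed, {
    vapply(seq_len(n_boot), function(i) {
      b <- sample(auc_b, replace = TRUE)
      t <- sample(auc_t, replace = TRUE)
      100 * (mean(t) - mean(b)) / mean(b)
    }, numeric(1))
  })
  pct_sd <- stats::sd(boot)
  auc_p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  auc_p <- min(1, max(auc_p, 2 / (n_boot + 1))) # resolution floor of the bootstrap

  lat_sig <- lat_test$p < alpha
  auc_sig <- auc_p < alpha
  flag <- (lat_sig && abs(delta_lat) >= floors$latency_ms) ||
    (auc_sig && abs(pct) >= floors$pct_auc)
  hint <- if (lat_sig && delta_lat > 0 && auc_sig && pct < 0) {
    "rostro-caudal-consistent"
  } else if (auc_sig && !lat_sig) {
    "amplitude-only"
  } else {
    "none"
  }

  structure(
    list(
      delta_latency_ms = delta_lat,
      delta_latency_sd = delta_lat_sd,
      latency_p = lat_test$p,
      latency_method = lat_test$method,
      pct_change_auc = pct,
      pct_change_auc_sd = pct_sd,
      auc_p = auc_p,
      migration_flag = flag,
      direction_hint = hint,
      alpha = alpha,
      floors = floors,
      n_baseline = nrow(baseline_features),
      n_test = nrow(test_features)
    ),
    class = "esr_migration"
  )
}

#' @export
print.esr_migration <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<esr_migration> %s (hint: %s)\n",
      "  latency: %+.3f ms (sd %.3f), p = %.3g [%s]\n",
      "  AUC: %+.1f%% (boot sd %.1f), p = %.3g\n"
    ),
    if (x$migration_flag) "MIGRATION FLAGGED" else "no migration",
    x$direction_hint,
    x$delta_latency_ms, x$delta_latency_sd, x$latency_p, x$latency_method,
    x$pct_change_auc, x$pct_change_auc_sd, x$auc_p
  ))
  invisible(x)
}

# run code with a local RNG state
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  code
}
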