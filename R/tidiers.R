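#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conduction-velocity fit
#'
#' @param x An `esr_cv`.
#' @param ... Unused.
#' @return One row per regression point: `distance_mm`, `peak_time_ms`,
#'   `fitted_ms`, `residual_ms`.
#' @export
tidy.esr_cv <- function(x, ...) {
  d <- x$data
  d$fitted_ms <- x$intercept_ms + x$slope_ms_per_mm * d$distance_mm
  d$residual_ms <- d$peak_time_ms - d$fitted_ms
  d
}

#' @rdname tidy.esr_cv
#' @return `glance()`: a one-row tibble with `velocity_m_per_s`,
#'   `fiber_class`, `slope_ms_per_mm`, `slope_se`, `intercept_ms`,
#'   `r_squared`, `n_channels`, `non_propagating`.
#' @export
glance.esr_cv <- function(x, ...) {
  tibble::tibble(
    velocity_m_per_s = x$velocity_m_per_s,
    fiber_class = if (x$non_propagating) NA_character_ else classify_fiber(x$velocity_m_per_s),
    slope_ms_per_mm = x$slope_ms_per_mm,
    slope_se = x$slope_se,
    intercept_ms = x$intercept_ms,
    r_squared = x$r_squared,
    n_channels = x$n_channels,
    non_propagating = x$non_propagating
  )
}

#' Tidy a propagation verdict
#'
#' @param x An `esr_propagation`.
#' @param ... Unused.
#' @return `tidy()`: the per-channel (distance, peak time) pairs;
#'   `glance()`: a one-row tibble with `verdict`, `slope_ms_per_mm`,
#'   `conf_low`, `conf_high`, `implied_velocity_m_per_s`, `alpha`,
#'   `n_channels`.
#' @export
tidy.esr_propagation <- function(x, ...) x$data

#' @rdname tidy.esr_propagation
#' @export
glance.esr_propagation <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    slope_ms_per_mm = x$slope_ms_per_mm,
    conf_low = x$conf_int[1],
    conf_high = x$conf_int[2],
    implied_velocity_m_per_s = x$implied_velocity_m_per_s,
    alpha = x$alpha,
    n_channels = x$n_channels
  )
}

#' Tidy a migration report
#'
#' @param x An `esr_migration`.
#' @param ... Unused.
#' @return `tidy()`: one row per feature (`latency`, `auc`) with `estimate`,
#'   `sd`, `p.value`, `significant`, `above_floor`; `glance()`: one row with
#'   the flag and direction hint.
#' @export
tidy.esr_migration <- function(x, ...) {
  tibble::tibble(
    feature = c("latency_ms", "pct_auc"),
    estimate = c(x$delta_latency_ms, x$pct_change_auc),
    sd = c(x$delta_latency_sd, x$pct_change_auc_sd),
    p.value = c(x$latency_p, x$auc_p),
    significant = c(x$latency_p < x$alpha, x$auc_p < x$alpha),
    above_floor = c(
      abs(x$delta_latency_ms) >= x$floors$latency_ms,
      abs(x$pct_change_auc) >= x$floors$pct_auc
    )
  )
}

#' @rdname tidy.esr_migration
#' @export
glance.esr_migration <- function(x, ...) {
  tibble::tibble(
    migration_flag = x$migration_flag,
    direction_hint = x$direction_hint,
    delta_latency_ms = x$delta_latency_ms,
    pct_change_auc = x$pct_change_auc,
    latency_p = x$latency_p,
    auc_p = x$auc_p,
    alpha = x$alpha,
    n_baseline = x$n_baseline,
    n_test = x$n_test
  )
}

#' Tidy a spillover report
#'
#' @param x An `esr_spillover`.
#' @param ... Unused.
#' @return `tidy()`: the per-channel report; `glance()`: one row with
#'   `any_spillover` and the ECAP-window propagation verdict.
#' @export
tidy.esr_spillover <- function(x, ...) x$report

#' @rdname tidy.esr_spillover
#' @export
glance.esr_spillover <- function(x, ...) {
  tibble::tibble(
    any_spillover = x$any_spillover,
    ecap_window_verdict = x$propagation$verdict,
    n_flagged = sum(x$report$spillover)
  )
}
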