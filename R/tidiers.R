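#' Tidy a COSH model comparison
#'
#' @param x A `cosh_comparison`.
#' @param ... Unused.
#' @return One row per model with `model`, `n`, `mean_s_v`, `cosh` and
#'   `frac_below_0.2`.
#' @export
tidy.cosh_comparison <- function(x, ...) {
  x$table
}

#' @rdname tidy.cosh_comparison
#' @export
glance.cosh_comparison <- function(x, ...) {
  tibble::tibble(
    reduction_total = x$reduction_total,
    reduction_capillary = x$reduction_capillary,
    reduction_rbc = x$reduction_rbc,
    share_capillary = x$share_capillary,
    share_rbc = x$share_rbc
  )
}

#' Tidy a heterogeneity summary
#'
#' @param x A `heterogeneity_summary`.
#' @param ... Unused.
#' @return The correlation table (one row per variable pair).
#' @export
tidy.heterogeneity_summary <- function(x, ...) {
  x$correlations
}

#' @rdname tidy.heterogeneity_summary
#' @export
glance.heterogeneity_summary <- function(x, ...) {
  tibble::tibble(
    mean_s_v = x$mean_s_v, cosh = x$cosh,
    mean_delta_s = x$mean_delta_s, cov_delta_s = x$cov_delta_s,
    mean_tau = x$mean_tau, cth = x$cth, cov_tau = x$cov_tau,
    frac_below_0.2 = x$frac_below_0.2, n_paths = x$n_paths
  )
}

#' Tidy an exponential decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `rate`, `r_squared`, `n_used`, `truncated`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, r_squared = x$r_squared, n_used = x$n_used,
                 truncated = x$truncated)
}

#' Tidy a Lagrangian run
#'
#' @param x A `lagrangian_run`.
#' @param ... Unused.
#' @return Per-vessel inlet/outlet saturation moments over the averaging
#'   window.
#' @export
tidy.lagrangian_run <- function(x, ...) {
  x$vessel_stats
}

#' @rdname tidy.lagrangian_run
#' @export
glance.lagrangian_run <- function(x, ...) {
  w <- x$exits[x$exits$in_window, ]
  tibble::tibble(
    n_exits = nrow(w), mean_s_v = mean(w$s_out), cosh = stats::sd(w$s_out),
    mean_transit = mean(w$transit_time), cth = stats::sd(w$transit_time),
    balance_error = x$balance$relative_error,
    injected = x$counters$injected, deferred = x$counters$deferred
  )
}

#' Tidy a COSH study
#'
#' @param x A `cosh_study`.
#' @param ... Unused.
#' @return The per-vessel territory/radius table.
#' @export
tidy.cosh_study <- function(x, ...) {
  x$territories
}

#' @rdname tidy.cosh_study
#' @export
glance.cosh_study <- function(x, ...) {
  dplyr::bind_cols(
    glance.cosh_comparison(x$comparison),
    tibble::tibble(conservation_discrepancy = x$conservation$discrepancy),
    glance.heterogeneity_summary(x$summary)
  )
}
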