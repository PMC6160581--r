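#' Capillary diffusive-interaction coefficient
#'
#' K_CI = K_IV + (log(r_t_mean / r_w) - 1/2) / (2 pi D_t alpha_t): the
#' resistance-like coefficient controlling how fast a saturation difference
#' between neighboring capillaries decays by passive oxygen exchange through
#' the shared tissue. The tissue term is the Krogh-cylinder spreading
#' resistance between the vessel wall and the volume-averaged tissue of a
#' slice of mean radius `r_t_mean`.
#'
#' @param k_iv Intravascular resistance coefficient, mmHg s um/(um^3 O2).
#' @param d_t Tissue oxygen diffusivity, um^2/s.
#' @param alpha_t Tissue oxygen solubility, (um^3 O2)/(um^3 mmHg).
#' @param r_t_mean Mean tissue radius of the slice, um.
#' @param r_w Vessel wall outer radius, um.
#' @return K_CI, same units as `k_iv`.
#' @export
capillary_interaction_coefficient <- function(k_iv, d_t, alpha_t, r_t_mean,
                                              r_w) {
  stopifnot(r_t_mean > 0, r_w > 0, r_t_mean >= r_w)
  k_iv + (log(r_t_mean / r_w) - 0.5) / (2 * pi * d_t * alpha_t)
}

# shared integrator for the heterogeneity decay equations:
#   Q_O2(Sbar) dSbar/dx = -j_t
#   Q_O2(Sbar) dH/dx    = -(H / K) dP_eq/dS|Sbar
# where H is either the pair difference (K = K_CI) or the within-capillary
# SD (K = K_RI). With `frozen = TRUE` the coefficients are evaluated once at
# the inlet mean, making the decay exactly exponential.
decay_ode <- function(h0, s_bar0, j_t, k_coef, v_rbc, mu_ld, r_c, r_p,
                      length, params, frozen, n_out) {
  x_out <- seq(0, length, length.out = max(2, n_out))
  if (frozen) {
    q0 <- convective_capacity(s_bar0, v_rbc, mu_ld, r_c, r_p, params)
    dp0 <- hill_dpeq_ds(s_bar0, params$p50, params$hill_n)
    rate <- dp0 / (k_coef * q0)
    s_bar <- pmax(0, s_bar0 - j_t * x_out / q0)
    return(tibble::tibble(x = x_out, s_bar = s_bar,
                          value = h0 * exp(-rate * x_out)))
  }
  deriv <- function(x, y, parms) {
    s <- max(y[1], 1e-12)
    q <- convective_capacity(s, v_rbc, mu_ld, r_c, r_p, params)
    dp <- hill_dpeq_ds(s, params$p50, params$hill_n)
    ds <- if (y[1] <= 0) 0 else -j_t / q
    dh <- -(y[2] / k_coef) * dp / q
    list(c(ds, dh))
  }
  sol <- deSolve::ode(y = c(s_bar0, h0), times = x_out, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = params$ode_rtol, atol = params$ode_atol)
  tibble::tibble(x = x_out, s_bar = pmax(0, sol[, 2]),
                 value = pmax(0, sol[, 3]))
}

#' Predicted decay of a paired-capillary saturation difference
#'
#' Integrates the capillary diffusive-interaction model: the saturation
#' difference between two interacting capillaries decays at a rate set by
#' `K_CI`, jointly with the mean-saturation transport equation. With frozen
#' coefficients the decay is exactly exponential with rate
#' `dP_eq/dS / (K_CI Q_O2)`.
#'
#' @param delta_s0 Inlet saturation difference (>= 0).
#' @param s_bar0 Inlet mean saturation.
#' @param j_t Extraction rate acting on the mean, (um^3 O2)/(um s).
#' @param k_ci Interaction coefficient from
#'   [capillary_interaction_coefficient()].
#' @param v_rbc,mu_ld,r_c,r_p,length Shared vessel state/geometry.
#' @param params An [oxygen_params()] list.
#' @param frozen Evaluate coefficients at the inlet mean only.
#' @param n_out Number of output positions.
#' @return Tibble with columns `x`, `s_bar`, `delta_s`.
#' @export
predict_deltaS_decay <- function(delta_s0, s_bar0, j_t, k_ci, v_rbc, mu_ld,
                                 r_c, r_p, length,
                                 params = oxygen_params(), frozen = FALSE,
                                 n_out = 101) {
  stopifnot(delta_s0 >= 0)
  out <- decay_ode(delta_s0, s_bar0, j_t, k_ci, v_rbc, mu_ld, r_c, r_p,
                   length, params, frozen, n_out)
  dplyr::rename(out, delta_s = "value")
}

#' Predicted decay of within-capillary saturation heterogeneity
#'
#' Same structure as [predict_deltaS_decay()] with the RBC-interaction
#' coefficient `K_RI`: the standard deviation of saturation among RBCs in a
#' single capillary decays exponentially (rate `dP_eq/dS / (K_RI Q_O2)`),
#' because the oxygen flux out of each RBC is proportional to its own excess
#' partial pressure over the shared tissue.
#'
#' @inheritParams predict_deltaS_decay
#' @param sigma_s0 Inlet saturation SD (>= 0).
#' @param k_ri RBC interaction coefficient.
#' @return Tibble with columns `x`, `s_bar`, `sigma_s`.
#' @export
predict_sigmaS_decay <- function(sigma_s0, s_bar0, j_t, k_ri, v_rbc, mu_ld,
                                 r_c, r_p, length,
                                 params = oxygen_params(), frozen = FALSE,
                                 n_out = 101) {
  stopifnot(sigma_s0 >= 0)
  out <- decay_ode(sigma_s0, s_bar0, j_t, k_ri, v_rbc, mu_ld, r_c, r_p,
                   length, params, frozen, n_out)
  dplyr::rename(out, sigma_s = "value")
}

#' Fit an exponential decay rate to a heterogeneity profile
#'
#' Least-squares slope of log(value) against position. Non-positive values
#' (and everything after the first one) are excluded and flagged.
#'
#' @param x Positions, um (>= 5 samples).
#' @param value Positive profile values (sigma_S or delta_S).
#' @return A list of class `decay_fit` with elements `rate` (1/um),
#'   `r_squared`, `n_used` and `truncated`.
#' @export
fit_decay_rate <- function(x, value) {
  stopifnot(length(x) == length(value), length(x) >= 5)
  pos <- value > 0
  n_use <- if (all(pos)) length(x) else max(0, which.min(pos) - 1)
  if (n_use < 3) {
    stop("fewer than 3 positive values; cannot fit a decay rate",
         call. = FALSE)
  }
  y <- log(value[seq_len(n_use)])
  fit <- stats::lm(y ~ x[seq_len(n_use)])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(rate = -unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n_used = n_use, truncated = n_use < length(x)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> rate %.4g /um (R^2 %.4f, n = %d%s)\n", x$rate,
              x$r_squared, x$n_used,
              if (x$truncated) ", truncated at first non-positive" else ""))
  invisible(x)
}
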