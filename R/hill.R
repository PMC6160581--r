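#' Hill oxygen-hemoglobin equilibrium
#'
#' The equilibrium between oxygen partial pressure and hemoglobin saturation
#' is modeled with the Hill curve S = P^n / (P^n + P50^n). `hill_peq` is its
#' inverse P_eq(S), the partial pressure in equilibrium with saturation S;
#' `hill_seq` maps pressure to saturation; `hill_dpeq_ds` is the closed-form
#' derivative dP_eq/dS.
#'
#' Saturations are clipped to `[eps, 1 - eps]` (default 1e-9) before
#' evaluating P_eq and its derivative, which avoids the singular endpoints
#' while perturbing interior results at below the 1e-8 level.
#'
#' @param s Hemoglobin saturation(s) in (0, 1).
#' @param po2 Oxygen partial pressure(s), mmHg, >= 0.
#' @param p50 Half-saturation pressure, mmHg.
#' @param hill_n Hill exponent.
#' @param eps Boundary clipping width.
#' @return Numeric vector: mmHg for `hill_peq`, saturation for `hill_seq`,
#'   mmHg per unit saturation for `hill_dpeq_ds`.
#' @export
hill_peq <- function(s, p50 = 47.9, hill_n = 2.64, eps = 1e-9) {
  s <- pmin(pmax(s, eps), 1 - eps)
  p50 * (s / (1 - s))^(1 / hill_n)
}

#' @rdname hill_peq
#' @export
hill_seq <- function(po2, p50 = 47.9, hill_n = 2.64) {
  stopifnot(all(po2 >= 0))
  pn <- po2^hill_n
  pn / (pn + p50^hill_n)
}

#' @rdname hill_peq
#' @export
hill_dpeq_ds <- function(s, p50 = 47.9, hill_n = 2.64, eps = 1e-9) {
  s <- pmin(pmax(s, eps), 1 - eps)
  hill_peq(s, p50, hill_n, eps) / (hill_n * s * (1 - s))
}
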