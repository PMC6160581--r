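#' Physiological and numerical parameters for oxygen transport
#'
#' Bundles the parameters of the hemoglobin-saturation transport model into a
#' single validated list. All quantities use micrometre / second / mmHg units;
#' oxygen amounts are volumes of gaseous O2 (um^3).
#'
#' @param c0 Oxygen binding capacity of a red blood cell,
#'   (um^3 O2)/(um^3 RBC). Product of heme concentration and the molar volume
#'   of oxygen; ~0.5 for mammalian blood.
#' @param p50 Half-saturation oxygen partial pressure of the Hill equilibrium
#'   curve, mmHg.
#' @param hill_n Hill exponent (dimensionless, > 1).
#' @param alpha_eff Effective oxygen solubility of the capillary interior,
#'   (um^3 O2)/(um^3 mmHg). Defaults to 0: plasma-dissolved oxygen advection
#'   contributes under 2.5 percent of the convective capacity at capillary
#'   saturations and excluding it keeps the particle-based and
#'   differential-equation model variants exactly consistent. A physical
#'   value is about 3.3e-5.
#' @param alpha_t Tissue oxygen solubility, (um^3 O2)/(um^3 mmHg).
#' @param d_t Tissue oxygen diffusivity, um^2/s.
#' @param m0 Metabolic oxygen consumption rate per unit tissue volume,
#'   (um^3 O2)/(um^3 s). The default is consistent with the oxygen budget of
#'   a capillary-bed box at physiological perfusion (~55 mL/100 g/min),
#'   inflow tube hematocrit 0.25 and an oxygen extraction fraction of ~0.17,
#'   which reproduces mean saturation drops of ~0.1 across a ~200 um
#'   capillary bed.
#' @param k_iv Intravascular resistance coefficient, mmHg s um/(um^3 O2);
#'   pressure drop between RBC interior and the outer vessel wall per unit
#'   oxygen flux per unit vessel length.
#' @param k_ri RBC diffusive-interaction resistance coefficient, same units
#'   and convention as `k_iv`.
#' @param v_rbc_vol Red blood cell volume, um^3 (mouse erythrocyte).
#' @param mu_plasma Plasma viscosity, mmHg s (1.2 mPa s by default).
#' @param ode_rtol,ode_atol Relative/absolute tolerances for the adaptive
#'   saturation ODE solves.
#'
#' @return A list of class `oxygen_params`.
#' @export
oxygen_params <- function(c0 = 0.5,
                          p50 = 47.9,
                          hill_n = 2.64,
                          alpha_eff = 0,
                          alpha_t = 3e-5,
                          d_t = 2000,
                          m0 = 2e-4,
                          k_iv = 1.0,
                          k_ri = 4.0,
                          v_rbc_vol = 49,
                          mu_plasma = 1.2e-3 / 133.322,
                          ode_rtol = 1e-8,
                          ode_atol = 1e-10) {
  p <- list(
    c0 = c0, p50 = p50, hill_n = hill_n, alpha_eff = alpha_eff,
    alpha_t = alpha_t, d_t = d_t, m0 = m0, k_iv = k_iv, k_ri = k_ri,
    v_rbc_vol = v_rbc_vol, mu_plasma = mu_plasma,
    ode_rtol = ode_rtol, ode_atol = ode_atol
  )
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all oxygen parameters must be finite scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  strictly_pos <- setdiff(names(p), "alpha_eff")
  bad <- vapply(p[strictly_pos], function(x) x <= 0, logical(1))
  if (any(bad)) {
    stop("oxygen parameters must be strictly positive: ",
         paste(strictly_pos[bad], collapse = ", "), call. = FALSE)
  }
  if (p$alpha_eff < 0) stop("alpha_eff must be >= 0", call. = FALSE)
  if (p$hill_n <= 1) stop("hill_n must be > 1", call. = FALSE)
  structure(p, class = "oxygen_params")
}

#' @export
print.oxygen_params <- function(x, ...) {
  cat("<oxygen_params>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

as_oxygen_params <- function(params) {
  if (inherits(params, "oxygen_params")) return(params)
  if (is.null(params)) return(oxygen_params())
  do.call(oxygen_params, params)
}
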