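#' Blood rheology closures for microvascular network hydraulics
#'
#' Apparent blood viscosity follows the Pries-Secomb "in vivo" law for
#' microvessels; the hematocrit split at diverging bifurcations follows the
#' Pries empirical phase-separation law. Because red-blood-cell velocity is
#' taken equal to the bulk velocity (no Fahraeus correction), tube and
#' discharge hematocrit coincide and the laws are evaluated at the tube
#' hematocrit.
#'
#' @name rheology
NULL

#' Relative apparent viscosity (Pries-Secomb in vivo law)
#'
#' @param d Vessel lumen diameter, um.
#' @param h Hematocrit (dimensionless, in `[0, 1)`).
#' @return Apparent viscosity relative to plasma (dimensionless, >= 1).
#' @export
pries_viscosity <- function(d, h) {
  stopifnot(all(d > 0), all(h >= 0), all(h < 1))
  mu45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  denom <- 1 + 1e-11 * d^12
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / denom) + 1 / denom
  fh <- ifelse(h > 0, ((1 - h)^cc - 1) / ((1 - 0.45)^cc - 1), 0)
  dd <- d / (d - 1.1)
  (1 + (mu45 - 1) * fh * dd^2) * dd^2
}

#' Poiseuille resistance of a vessel segment
#'
#' R = 128 mu_app L / (pi d^4) with the apparent viscosity law above.
#'
#' @param diameter Lumen diameter, um.
#' @param length Vessel length, um.
#' @param h_t Tube hematocrit.
#' @param mu_plasma Plasma viscosity, mmHg s.
#' @param viscosity_law `"pries"` (default) or `"plasma"` (hematocrit
#'   independent).
#' @return Hydraulic resistance, mmHg s / um^3.
#' @export
vessel_resistance <- function(diameter, length, h_t,
                              mu_plasma = oxygen_params()$mu_plasma,
                              viscosity_law = c("pries", "plasma")) {
  stopifnot(all(diameter > 0), all(length > 0))
  viscosity_law <- match.arg(viscosity_law)
  mu_rel <- switch(viscosity_law,
    pries = pries_viscosity(diameter, h_t),
    plasma = rep(1, length(diameter))
  )
  128 * mu_plasma * mu_rel * length / (pi * diameter^4)
}

#' RBC flux fraction at a diverging bifurcation (Pries phase separation)
#'
#' Fraction of the parent RBC flux entering daughter "a", given the fraction
#' of bulk flow it receives.
#'
#' @param fq_blood Fraction of parent bulk flow entering daughter a, in
#'   `[0, 1]`.
#' @param d_parent,d_a,d_b Diameters of the parent and the two daughters, um.
#' @param h Parent hematocrit.
#' @return RBC flux fraction to daughter a, in `[0, 1]`.
#' @export
pries_phase_separation <- function(fq_blood, d_parent, d_a, d_b, h) {
  stopifnot(fq_blood >= 0, fq_blood <= 1)
  x0 <- 0.964 * (1 - h) / d_parent
  if (fq_blood <= x0) return(0)
  if (fq_blood >= 1 - x0) return(1)
  a <- -13.29 * ((d_a^2 - d_b^2) / (d_a^2 + d_b^2)) * (1 - h) / d_parent
  b <- 1 + 6.98 * (1 - h) / d_parent
  xi <- (fq_blood - x0) / (1 - 2 * x0)
  stats::plogis(a + b * stats::qlogis(xi))
}

#' Linear density of red blood cells
#'
#' mu_LD = H_T (r_p / r_c)^2: the fraction of vessel length occupied by
#' cylindrical RBCs of radius `r_c` in a lumen of radius `r_p`.
#'
#' @param h_t Tube hematocrit in `[0, 1)`.
#' @param r_p Plasma (lumen) radius, um.
#' @param r_c RBC radius, um.
#' @return Linear density in `[0, 1]`; values above 1 are clipped with a
#'   warning.
#' @export
linear_density <- function(h_t, r_p, r_c) {
  stopifnot(all(h_t >= 0), all(h_t < 1))
  mu <- h_t * (r_p / r_c)^2
  if (any(mu > 1)) {
    warning(sum(mu > 1), " linear density value(s) exceeded 1; clipped")
    mu <- pmin(mu, 1)
  }
  mu
}
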