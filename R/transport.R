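#' Convective oxygen carrying capacity
#'
#' Q_O2(S) = v_rbc (mu_LD pi r_c^2 C0 + pi r_p^2 alpha_eff dP_eq/dS): the
#' amount of oxygen advected past a cross-section per unit drop in
#' saturation, combining hemoglobin-bound oxygen in the RBC phase and
#' (optionally) plasma-dissolved oxygen in Hill equilibrium.
#'
#' @param s Saturation in (0, 1).
#' @param v_rbc RBC velocity, um/s.
#' @param mu_ld Linear density.
#' @param r_c,r_p RBC and plasma radii, um.
#' @param params An [oxygen_params()] list.
#' @return Capacity, (um^3 O2)/s per unit saturation.
#' @export
convective_capacity <- function(s, v_rbc, mu_ld, r_c, r_p,
                                params = oxygen_params()) {
  core <- mu_ld * pi * r_c^2 * params$c0
  extra <- if (params$alpha_eff > 0) {
    pi * r_p^2 * params$alpha_eff *
      hill_dpeq_ds(s, params$p50, params$hill_n)
  } else 0
  v_rbc * (core + extra)
}

#' Local oxygen extraction rate of a tissue sleeve
#'
#' j_t = M0 pi (r_t^2 - r_w^2): oxygen consumed per unit vessel length by a
#' concentric tissue cylinder of radius `r_t` around a wall of radius `r_w`,
#' at uniform consumption `m0`.
#'
#' @param r_t Tissue cylinder radius, um (`>= r_w`).
#' @param r_w Vessel wall outer radius, um.
#' @param m0 Metabolic consumption rate, (um^3 O2)/(um^3 s).
#' @return Extraction rate, (um^3 O2)/(um s).
#' @export
extraction_rate <- function(r_t, r_w, m0 = oxygen_params()$m0) {
  if (any(r_t < r_w - 1e-12)) {
    stop("tissue radius smaller than wall radius", call. = FALSE)
  }
  m0 * pi * (pmax(r_t, r_w)^2 - r_w^2)
}

# saturation at the distal end of a vessel given inlet saturation(s);
# closed form in the hemoglobin-only (alpha_eff = 0) limit, adaptive ODE
# otherwise. Saturation is floored at zero.
vessel_forward <- function(s_in, j_t, v_rbc, mu_ld, r_c, r_p, length,
                           params = oxygen_params()) {
  if (params$alpha_eff == 0) {
    cap <- v_rbc * mu_ld * pi * r_c^2 * params$c0
    return(pmax(0, s_in - j_t * length / cap))
  }
  prof <- integrate_vessel(s_in, j_t, v_rbc, mu_ld, r_c, r_p, length,
                           params = params, n_out = 2)
  prof$s[nrow(prof$s), ]
}

#' Integrate the saturation transport equation along one vessel
#'
#' Solves dS/dx = -j_t(x) / Q_O2(S) for each atom of a discrete saturation
#' distribution with an adaptive solver (lsoda, tolerances from `params`).
#' Atoms are floored at S = 0 (a fully desaturated RBC stops supplying the
#' tissue) and, sharing the same extraction profile, never cross.
#'
#' @param s_in Numeric vector of inlet saturations (one per atom).
#' @param j_t Extraction rate: scalar or function of arc position x.
#' @param v_rbc,mu_ld,r_c,r_p,length Vessel flow state and geometry.
#' @param params An [oxygen_params()] list.
#' @param n_out Number of equally spaced output positions (>= 2).
#' @return List with `x` (positions), `s` (length(x) by length(s_in) matrix)
#'   and `floored` (logical per atom).
#' @export
integrate_vessel <- function(s_in, j_t, v_rbc, mu_ld, r_c, r_p, length,
                             params = oxygen_params(), n_out = 51) {
  stopifnot(length > 0, v_rbc > 0, mu_ld > 0)
  jt_fun <- if (is.function(j_t)) j_t else function(x) j_t
  if (any(jt_fun(0) < 0) || any(jt_fun(length) < 0)) {
    stop("extraction profile must be non-negative", call. = FALSE)
  }
  x_out <- seq(0, length, length.out = max(2, n_out))
  if (params$alpha_eff == 0 && !is.function(j_t)) {
    # S-independent capacity: the transport equation is linear and its
    # exact solution (with the zero floor) is used directly
    cap <- v_rbc * mu_ld * pi * r_c^2 * params$c0
    s <- outer(x_out, as.numeric(s_in), function(x, s0) s0 - j_t * x / cap)
    s[s < 0] <- 0
    return(list(x = x_out, s = s, floored = s[nrow(s), ] <= 0))
  }
  deriv <- function(x, y, parms) {
    q <- convective_capacity(pmax(y, 1e-12), v_rbc, mu_ld, r_c, r_p, params)
    dy <- -jt_fun(x) / q
    dy[y <= 0] <- 0
    list(dy)
  }
  sol <- deSolve::ode(y = as.numeric(s_in), times = x_out, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = params$ode_rtol, atol = params$ode_atol)
  if (attr(sol, "istate")[1] < 0 || anyNA(sol[, -1])) {
    stop("saturation ODE solver failed (state: ",
         paste(signif(s_in, 4), collapse = ", "), ")", call. = FALSE)
  }
  s <- pmax(unname(sol[, -1, drop = FALSE]), 0)
  list(x = x_out, s = s, floored = s[nrow(s), ] <= 0)
}

# mass-conservative reduction of an atom set to at most `cap` atoms by
# repeatedly merging the two closest saturations
merge_atoms <- function(s, w, cap = 32) {
  while (length(s) > cap) {
    o <- order(s)
    s <- s[o]; w <- w[o]
    i <- which.min(diff(s))
    s_new <- (s[i] * w[i] + s[i + 1] * w[i + 1]) / (w[i] + w[i + 1])
    w_new <- w[i] + w[i + 1]
    s <- c(s[-c(i, i + 1)], s_new)
    w <- c(w[-c(i, i + 1)], w_new)
  }
  list(s = s, w = w)
}

#' Propagate hemoglobin saturation through the network
#'
#' Processes vessels in topological (pressure) order. At converging
#' bifurcations the child inlet distribution collects the parents' distal
#' atoms with RBC-flux weights `w_i = q_rbc,i / sum(q_rbc)`, carrying
#' upstream weights recursively; at diverging bifurcations each child
#' inherits the parent distribution unchanged. Each vessel is integrated
#' with [integrate_vessel()] using the extraction rate implied by its tissue
#' radius.
#'
#' @param net A `capnet` with a solved flow + hematocrit state.
#' @param inflow_s Tibble (`vessel`, `s_a`) from
#'   [assign_inflow_saturation()].
#' @param r_t Tibble (`vessel`, `r_t`): tissue radii (geometric or
#'   functional) defining each vessel's extraction rate.
#' @param params An [oxygen_params()] list.
#' @param atom_cap Maximum atoms per distribution before mass-conservative
#'   merging.
#' @param profile_points Output positions per vessel for the saturation
#'   profiles.
#' @return A list of class `saturation_propagation` with elements `vessels`
#'   (per-vessel inlet/outlet moments and flags), `distributions` (per-vessel
#'   inlet/outlet atom sets), `outflow` (pooled flow-weighted outflow
#'   distribution), `profiles` (long tibble of mean/sd saturation along each
#'   vessel) and `skipped` (zero-flow vessel ids).
#' @export
propagate_network <- function(net, inflow_s, r_t, params = oxygen_params(),
                              atom_cap = 32, profile_points = 21) {
  stop_if_no_flow(net)
  if (!"q_rbc" %in% names(net$vessels)) {
    stop("hematocrit has not been distributed; run solve_network_flow()",
         call. = FALSE)
  }
  v <- net$vessels
  de <- directed_ends(net)
  n_v <- nrow(v)
  jt <- extraction_rate(r_t$r_t[match(v$vessel, r_t$vessel)], v$r_w,
                        params$m0)
  if (anyNA(jt)) stop("r_t missing for some vessels", call. = FALSE)
  press <- net$nodes$pressure[match(de$tail, net$nodes$node)]
  ord <- order(-press)
  bnd_nodes <- net$nodes$node[net$nodes$boundary != "interior"]
  s_a_map <- inflow_s$s_a[match(v$vessel, inflow_s$vessel)]
  s_fallback <- stats::weighted.mean(inflow_s$s_a,
                                     rep(1, nrow(inflow_s)))
  dist_out <- vector("list", n_v)
  dist_in <- vector("list", n_v)
  profs <- vector("list", n_v)
  rows <- vector("list", n_v)
  unperfused <- de$zero_flow | v$mu_ld <= 0 | v$q_rbc <= 0
  for (i in ord) {
    if (unperfused[i]) next
    n <- de$tail[i]
    if (n %in% bnd_nodes) {
      s0 <- s_a_map[i]
      if (is.na(s0)) s0 <- s_fallback
      din <- list(s = s0, w = 1)
    } else {
      parents <- which(de$head == n & !unperfused)
      parents <- parents[!vapply(dist_out[parents], is.null, logical(1))]
      if (length(parents) == 0) {
        din <- list(s = s_fallback, w = 1)
      } else {
        qr <- v$q_rbc[parents]
        if (sum(qr) <= 0) qr <- rep(1, length(parents))
        s <- unlist(purrr::map(parents, ~ dist_out[[.x]]$s))
        w <- unlist(purrr::map(seq_along(parents), function(k)
          dist_out[[parents[k]]]$w * qr[k]))
        w <- w / sum(w)
        din <- merge_atoms(s, w, atom_cap)
      }
    }
    dist_in[[i]] <- din
    prof <- integrate_vessel(din$s, jt[i], abs(v$v_rbc[i]), v$mu_ld[i],
                             v$r_c[i], v$r_p[i], v$length[i], params,
                             n_out = max(2, profile_points))
    s_end <- prof$s[nrow(prof$s), ]
    dist_out[[i]] <- list(s = s_end, w = din$w)
    wm <- function(x) sum(x * din$w)
    wsd <- function(x) sqrt(pmax(0, wm(x^2) - wm(x)^2))
    profs[[i]] <- tibble::tibble(
      vessel = v$vessel[i], x = prof$x,
      s_mean = apply(prof$s, 1, function(r) sum(r * din$w)),
      s_sd = apply(prof$s, 1, function(r)
        sqrt(pmax(0, sum(r^2 * din$w) - sum(r * din$w)^2)))
    )
    rows[[i]] <- tibble::tibble(
      vessel = v$vessel[i],
      s_a = wm(din$s), s_v = wm(s_end),
      sigma_a = wsd(din$s), sigma_v = wsd(s_end),
      floored = any(prof$floored), n_atoms = length(din$s)
    )
  }
  skipped <- v$vessel[unperfused]
  out_idx <- which(de$head %in% bnd_nodes & !unperfused)
  qr_out <- v$q_rbc[out_idx]
  outflow <- purrr::map_dfr(seq_along(out_idx), function(k) {
    i <- out_idx[k]
    tibble::tibble(vessel = v$vessel[i], s = dist_out[[i]]$s,
                   w = dist_out[[i]]$w * qr_out[k] / sum(qr_out))
  })
  structure(list(
    vessels = dplyr::bind_rows(rows),
    distributions = list(inlet = dist_in, outlet = dist_out,
                         vessel = v$vessel),
    outflow = outflow,
    profiles = dplyr::bind_rows(profs),
    skipped = skipped,
    jt = tibble::tibble(vessel = v$vessel, j_t = jt)
  ), class = "saturation_propagation")
}

#' @export
print.saturation_propagation <- function(x, ...) {
  cat(sprintf("<saturation_propagation> %d vessels (%d skipped)\n",
              nrow(x$vessels), length(x$skipped)))
  cat(sprintf("  outflow: mean S_v %.3f, flow-weighted SD %.4f\n",
              weighted_mean(x$outflow$s, x$outflow$w),
              weighted_sd(x$outflow$s, x$outflow$w)))
  invisible(x)
}

#' Total oxygen released by a propagation result
#'
#' Sums, over vessels, the flow-weighted saturation drops converted through
#' the convective capacity (hemoglobin-bound plus plasma-dissolved terms).
#'
#' @param prop A `saturation_propagation`.
#' @param net The network it was computed on.
#' @param params The same [oxygen_params()].
#' @param per_vessel Return a per-vessel tibble instead of the total.
#' @return Released oxygen, (um^3 O2)/s (scalar, or per-vessel tibble).
#' @export
oxygen_release <- function(prop, net, params = oxygen_params(),
                           per_vessel = FALSE) {
  v <- net$vessels
  rel <- rep(NA_real_, nrow(v))
  for (k in seq_len(nrow(v))) {
    dout <- prop$distributions$outlet[[k]]
    din <- prop$distributions$inlet[[k]]
    if (is.null(dout)) next
    rbc <- abs(v$v_rbc[k]) * v$mu_ld[k] * pi * v$r_c[k]^2 * params$c0 *
      sum(din$w * (din$s - dout$s))
    plasma <- if (params$alpha_eff > 0) {
      abs(v$v_rbc[k]) * pi * v$r_p[k]^2 * params$alpha_eff *
        sum(din$w * (hill_peq(din$s, params$p50, params$hill_n) -
                       hill_peq(dout$s, params$p50, params$hill_n)))
    } else 0
    rel[k] <- rbc + plasma
  }
  if (per_vessel) {
    return(tibble::tibble(vessel = v$vessel, release = rel))
  }
  sum(rel, na.rm = TRUE)
}
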