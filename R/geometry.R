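#' Rescale the vessel diameter distribution
#'
#' Applies an affine map to the diameters so the distribution attains the
#' target mean and standard deviation, then clamps at `floor` (reconstructed
#' calibers are distorted by imaging; rescaling to a reference distribution
#' with a lower bound is the standard correction). A zero-variance input
#' cannot be mapped affinely and is replaced by the constant target mean with
#' a warning.
#'
#' @param net A `capnet`.
#' @param target_mean,target_sd Target diameter mean/SD, um.
#' @param floor Lower diameter bound, um.
#' @return The network with rescaled diameters and derived radii removed;
#'   achieved moments are attached as attribute `"achieved"`.
#' @export
rescale_diameters <- function(net, target_mean = 5, target_sd = 1.5,
                              floor = 3) {
  stopifnot(target_mean > floor, floor > 0)
  d <- net$vessels$diameter
  s <- stats::sd(d)
  if (length(d) < 2 || !is.finite(s) || s < 1e-12) {
    warning("degenerate diameter distribution (zero SD); ",
            "setting all diameters to the target mean")
    d_new <- rep(target_mean, length(d))
  } else {
    a <- target_sd / s
    d_new <- a * (d - mean(d)) + target_mean
    d_new <- pmax(d_new, floor)
  }
  net$vessels$diameter <- d_new
  attr(net, "achieved") <- c(mean = mean(d_new), sd = stats::sd(d_new))
  net
}

#' Derive plasma, RBC and wall radii from the diameters
#'
#' Sets the plasma radius `r_p = diameter / 2`, the RBC radius
#' `r_c = 0.8 r_p` with the RBC diameter clamped between `rbc_d_min` and
#' `rbc_d_max`, and the endothelium outer radius `r_w = 1.25 r_p`.
#'
#' @param net A `capnet`.
#' @param r_c_ratio,r_w_ratio RBC and wall radius ratios relative to `r_p`.
#' @param rbc_d_min,rbc_d_max RBC diameter clamp, um.
#' @return The network with columns `r_p`, `r_c`, `r_w` added.
#' @export
derive_radii <- function(net, r_c_ratio = 0.8, r_w_ratio = 1.25,
                         rbc_d_min = 3, rbc_d_max = 8) {
  r_p <- net$vessels$diameter / 2
  net$vessels$r_p <- r_p
  net$vessels$r_c <- pmin(pmax(r_c_ratio * r_p, rbc_d_min / 2), rbc_d_max / 2)
  net$vessels$r_w <- r_w_ratio * r_p
  net
}

flow_is_solved <- function(net) {
  all(c("q", "v_rbc") %in% names(net$vessels))
}

stop_if_no_flow <- function(net) {
  if (!flow_is_solved(net)) {
    stop("network has no flow solution; run solve_network_flow() or ",
         "reconstruct_flow() first", call. = FALSE)
  }
}

#' Flow-directed endpoints of each vessel
#'
#' @param net A `capnet` with a flow solution.
#' @param q_tol Relative flow threshold below which a vessel is treated as
#'   zero-flow.
#' @return Tibble with columns `vessel`, `tail` (upstream node), `head`
#'   (downstream node) and `zero_flow` (logical; direction undefined).
#' @export
directed_ends <- function(net, q_tol = 1e-12) {
  stop_if_no_flow(net)
  v <- net$vessels
  qref <- mean(abs(v$q))
  zero <- abs(v$q) <= q_tol * max(qref, 1e-300)
  tibble::tibble(
    vessel = v$vessel,
    tail = ifelse(v$q >= 0, v$from, v$to),
    head = ifelse(v$q >= 0, v$to, v$from),
    zero_flow = zero
  )
}

#' Classify vessels by their upstream bifurcation type
#'
#' A vessel is `"after_converging"` if its upstream node receives flow from
#' two or more vessels, `"inflow"` if it starts at an inflow boundary node,
#' and `"other"` otherwise. Vessels with (numerically) zero flow have no
#' defined direction; they are classified `"other"` and flagged.
#'
#' @param net A `capnet` with a flow solution.
#' @return Tibble with columns `vessel`, `class`, `zero_flow`; the number of
#'   converging bifurcation nodes is attached as attribute `"n_converging"`.
#' @export
classify_bifurcations <- function(net) {
  de <- directed_ends(net)
  live <- de[!de$zero_flow, ]
  in_deg <- table(live$head)
  conv_nodes <- as.integer(names(in_deg)[in_deg >= 2])
  inflow_nodes <- net$nodes$node[net$nodes$boundary == "inflow"]
  cls <- dplyr::case_when(
    de$zero_flow ~ "other",
    de$tail %in% inflow_nodes ~ "inflow",
    de$tail %in% conv_nodes ~ "after_converging",
    TRUE ~ "other"
  )
  out <- tibble::tibble(vessel = de$vessel, class = cls,
                        zero_flow = de$zero_flow)
  attr(out, "n_converging") <- length(conv_nodes)
  out
}
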