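#' Network hydraulics
#'
#' Pressures and flows on the capillary graph follow linear network
#' hydraulics: each vessel is a Poiseuille resistor (apparent viscosity from
#' the Pries in vivo law), volume flux is conserved at interior nodes, and
#' boundary nodes carry Dirichlet pressures. RBC velocity is `q / (pi r_p^2)`
#' (no Fahraeus correction), so tube and discharge hematocrit coincide.
#'
#' @name flow_solver
NULL

# conductances and node bookkeeping for the linear system
flow_system <- function(net, h_t, viscosity_law = "pries") {
  v <- net$vessels
  R <- vessel_resistance(v$diameter, v$length, h_t,
                         viscosity_law = viscosity_law)
  nodes <- net$nodes$node
  list(R = R, g = 1 / R,
       from = match(v$from, nodes), to = match(v$to, nodes),
       n_nodes = length(nodes))
}

laplacian <- function(sys) {
  i <- c(sys$from, sys$to, sys$from, sys$to)
  j <- c(sys$to, sys$from, sys$from, sys$to)
  x <- c(-sys$g, -sys$g, sys$g, sys$g)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(sys$n_nodes, sys$n_nodes))
}

check_boundary_pressures <- function(net, p_boundary) {
  bnd <- net$nodes$node[net$nodes$boundary != "interior"]
  given <- as.integer(names(p_boundary))
  missing <- setdiff(bnd, given)
  if (length(missing) > 0) {
    stop("no boundary pressure for node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p_boundary[as.character(bnd)]
}

#' Solve node pressures and vessel flows at fixed hematocrit
#'
#' @param net A `capnet`.
#' @param p_boundary Named numeric vector of boundary pressures (names are
#'   node ids), mmHg.
#' @param h_t Per-vessel tube hematocrit used for the apparent viscosity
#'   (scalar or vector); defaults to the stored `h_t` column or 0.25.
#' @param viscosity_law Passed to [vessel_resistance()].
#' @return The network with per-vessel `q` (um^3/s, signed `from -> to`) and
#'   `v_rbc` (um/s), and node `pressure` (mmHg).
#' @export
solve_pressures <- function(net, p_boundary, h_t = NULL,
                            viscosity_law = "pries") {
  if (is.null(h_t)) {
    h_t <- if ("h_t" %in% names(net$vessels)) net$vessels$h_t else 0.25
  }
  h_t <- rep(h_t, length.out = nrow(net$vessels))
  p_b <- check_boundary_pressures(net, p_boundary)
  sys <- flow_system(net, h_t, viscosity_law)
  L <- laplacian(sys)
  is_bnd <- net$nodes$boundary != "interior"
  p <- numeric(sys$n_nodes)
  p[is_bnd] <- p_b
  if (any(!is_bnd)) {
    LII <- L[!is_bnd, !is_bnd, drop = FALSE]
    rhs <- -L[!is_bnd, is_bnd, drop = FALSE] %*% p_b
    p[!is_bnd] <- as.numeric(Matrix::solve(LII, rhs))
  }
  q <- sys$g * (p[sys$from] - p[sys$to])
  net$nodes$pressure <- p
  net$vessels$h_t <- h_t
  net$vessels$q <- q
  net$vessels$v_rbc <- q / (pi * net$vessels$r_p^2)
  net
}

#' Distribute hematocrit through a solved network
#'
#' Vessels are processed in topological (decreasing upstream pressure) order.
#' Vessels fed by a boundary node receive the inflow tube hematocrit. At
#' diverging bifurcations with two daughters the RBC flux splits by the Pries
#' empirical phase-separation law (proportional split for higher-order
#' branchings); at converging nodes fluxes mix conservatively. Daughter
#' hematocrit is capped at `h_cap` with the excess flux routed to the sibling.
#'
#' @param net A `capnet` with solved flows.
#' @param inflow_ht Tube hematocrit at vessels fed from outside, default 0.25.
#' @param split `"pries"` (default) or `"proportional"`.
#' @param h_cap Daughter hematocrit cap.
#' @return The network with `h_t`, `mu_ld` and `q_rbc` columns updated;
#'   zero-flow vessels are flagged in the logical column `zero_flow`.
#' @export
distribute_hematocrit <- function(net, inflow_ht = 0.25,
                                  split = c("pries", "proportional"),
                                  h_cap = 0.8) {
  stop_if_no_flow(net)
  split <- match.arg(split)
  v <- net$vessels
  de <- directed_ends(net)
  n_v <- nrow(v)
  h <- rep(NA_real_, n_v)
  qabs <- abs(v$q)
  h[de$zero_flow] <- 0
  press <- net$nodes$pressure[match(de$tail, net$nodes$node)]
  bnd_nodes <- net$nodes$node[net$nodes$boundary != "interior"]
  ord_nodes <- unique(de$tail[order(-press)])
  for (n in ord_nodes) {
    out_v <- which(de$tail == n & !de$zero_flow)
    out_v <- out_v[is.na(h[out_v])]
    if (length(out_v) == 0) next
    if (n %in% bnd_nodes) {
      h[out_v] <- inflow_ht
      next
    }
    in_v <- which(de$head == n & !de$zero_flow)
    if (length(in_v) == 0 || anyNA(h[in_v])) {
      stop("hematocrit traversal reached node ", n,
           " before its parents; the flow-directed graph is not acyclic",
           call. = FALSE)
    }
    rbc_in <- sum(h[in_v] * qabs[in_v])
    q_out <- qabs[out_v]
    if (length(out_v) == 1) {
      h[out_v] <- rbc_in / q_out
    } else if (length(out_v) == 2 && split == "pries") {
      q_in <- qabs[in_v]
      d_f <- sum(v$diameter[in_v] * q_in) / sum(q_in)
      h_f <- rbc_in / sum(q_in)
      fq_a <- q_out[1] / sum(q_out)
      fe_a <- pries_phase_separation(fq_a, d_f, v$diameter[out_v[1]],
                                     v$diameter[out_v[2]], min(h_f, 0.99))
      flux <- rbc_in * c(fe_a, 1 - fe_a)
      # cap daughter hematocrit, conserving flux
      for (k in 1:2) {
        if (flux[k] > h_cap * q_out[k]) {
          excess <- flux[k] - h_cap * q_out[k]
          flux[k] <- h_cap * q_out[k]
          flux[3 - k] <- flux[3 - k] + excess
        }
      }
      h[out_v] <- flux / q_out
    } else {
      h[out_v] <- rbc_in / sum(q_out)  # proportional split
    }
  }
  h[is.na(h)] <- 0
  h <- pmin(h, 0.99)
  net$vessels$h_t <- h
  net$vessels$mu_ld <- linear_density(h, v$r_p, v$r_c)
  net$vessels$q_rbc <- h * qabs
  net$vessels$zero_flow <- de$zero_flow
  net
}

#' Solve the coupled flow-hematocrit fixed point at fixed boundary pressures
#'
#' Alternates the linear pressure solve (viscosity depends on hematocrit)
#' with the phase-separation hematocrit distribution until the flows change
#' by less than `tol` (relative), with under-relaxation on hematocrit.
#'
#' @inheritParams solve_pressures
#' @inheritParams distribute_hematocrit
#' @param max_iter Maximum outer iterations.
#' @param tol Relative flow-change convergence tolerance.
#' @return The network with a converged flow + hematocrit state.
#' @export
solve_network_flow <- function(net, p_boundary, inflow_ht = 0.25,
                               split = "pries", max_iter = 20, tol = 1e-6,
                               viscosity_law = "pries") {
  h <- rep(inflow_ht, nrow(net$vessels))
  q_prev <- NULL
  for (it in seq_len(max_iter)) {
    net <- solve_pressures(net, p_boundary, h_t = h,
                           viscosity_law = viscosity_law)
    net <- distribute_hematocrit(net, inflow_ht = inflow_ht, split = split)
    h_new <- net$vessels$h_t
    if (!is.null(q_prev)) {
      dq <- max(abs(net$vessels$q - q_prev)) / max(mean(abs(net$vessels$q)),
                                                   1e-300)
      if (dq < tol) break
    }
    q_prev <- net$vessels$q
    h <- 0.5 * h + 0.5 * h_new
  }
  net
}

# velocity map: vessel velocities as a linear function of boundary pressures
velocity_map <- function(net, h_t, viscosity_law = "pries") {
  sys <- flow_system(net, h_t, viscosity_law)
  L <- laplacian(sys)
  is_bnd <- net$nodes$boundary != "interior"
  n_b <- sum(is_bnd)
  # full pressure vector as p = P %*% p_b
  P <- matrix(0, sys$n_nodes, n_b)
  P[which(is_bnd), ] <- diag(n_b)
  if (any(!is_bnd)) {
    LII <- L[!is_bnd, !is_bnd, drop = FALSE]
    LIB <- L[!is_bnd, is_bnd, drop = FALSE]
    P[!is_bnd, ] <- as.matrix(Matrix::solve(LII, -LIB))
  }
  Qmat <- sys$g * (P[sys$from, , drop = FALSE] - P[sys$to, , drop = FALSE])
  list(Qmat = Qmat, Vmat = Qmat / (pi * net$vessels$r_p^2), R = sys$R,
       P = P, bnd_nodes = net$nodes$node[is_bnd])
}

#' Reconstruct network flow from sparse velocity measurements
#'
#' Finds the boundary pressures that minimize the dissipated hydraulic power
#' `sum(q_i^2 R_i)` plus a weighted velocity-misfit term
#' `lambda * sum(w_i (|v_i| - v_meas_i)^2)`, iterated to a fixed point with
#' the phase-separation hematocrit distribution. Because the flows are linear
#' in the boundary pressures at fixed hematocrit, the objective is solved
#' exactly for each flow-direction iterate (the measured speeds are signed by
#' the current direction estimate), giving a sequence of equality-constrained
#' quadratic problems. The pressure gauge is fixed by the mean boundary
#' pressure. Without measurements, the minimizer collapses toward zero flow;
#' a mean inflow-outflow pressure-drop constraint is then activated.
#'
#' @param net A `capnet` with derived radii and labelled boundary nodes.
#' @param measurements Tibble from [sample_measurements()] (columns `vessel`,
#'   `v_meas`, optionally `noise_sd`), or `NULL`.
#' @param inflow_ht Inflow tube hematocrit.
#' @param lambda Misfit weight; by default set so the misfit term dominates
#'   (100x the hydraulic power at the initial guess).
#' @param p_ref Gauge: mean boundary pressure, mmHg.
#' @param dp_min Mean pressure drop below which the zero-flow guard engages.
#' @param dp_target Mean inflow-outflow pressure drop enforced when the
#'   guard is active, mmHg.
#' @param max_outer Maximum hematocrit outer iterations.
#' @param tol Relative flow-change tolerance of the outer loop.
#' @return The network with the reconstructed flow state; reconstruction
#'   diagnostics (misfit table, lambda, iteration history) are attached as
#'   attribute `"reconstruction"`.
#' @export
reconstruct_flow <- function(net, measurements, inflow_ht = 0.25,
                             lambda = NULL, p_ref = 50, dp_min = 0.5,
                             dp_target = 5, max_outer = 150, tol = 1e-6) {
  has_meas <- !is.null(measurements) && nrow(measurements) > 0
  if (has_meas) {
    midx <- match(measurements$vessel, net$vessels$vessel)
    if (anyNA(midx)) {
      stop("measurement references unknown vessel id(s): ",
           paste(measurements$vessel[is.na(midx)], collapse = ", "),
           call. = FALSE)
    }
    nsd <- if ("noise_sd" %in% names(measurements)) {
      measurements$noise_sd
    } else 0
    w <- 1 / pmax(nsd, 1)^2  # 1 um/s floor keeps weights finite
    if (all(w <= 0)) stop("all measurement weights are zero", call. = FALSE)
    m <- measurements$v_meas
  }
  is_bnd <- net$nodes$boundary != "interior"
  b_in <- net$nodes$boundary[is_bnd] == "inflow"
  n_b <- sum(is_bnd)
  p_b <- p_ref + ifelse(b_in, dp_target / 2, -dp_target / 2)
  h <- rep(inflow_ht, nrow(net$vessels))
  history <- numeric(0)
  q_prev <- NULL
  converged <- FALSE
  stabilized <- FALSE
  relax <- 0.5
  best_dq <- Inf
  stall <- 0L
  # limit-cycle stabilization: when the hematocrit fixed point oscillates
  # (bistable phase-separation switching), average the hematocrit over the
  # cycle and finish with the viscosity field frozen at that average; only
  # engaged once the residual has clearly stalled (damping already deepened)
  avg_len <- 30L
  h_accum <- NULL
  n_accum <- 0L
  n_deepened <- 0L
  for (outer in seq_len(max_outer)) {
    vm <- velocity_map(net, h)
    pow <- crossprod(vm$Qmat, vm$R * vm$Qmat)  # hydraulic power matrix
    if (has_meas) {
      Am <- vm$Vmat[midx, , drop = FALSE]
      if (is.null(lambda)) {
        v0 <- as.numeric(Am %*% p_b)
        pw0 <- as.numeric(t(p_b) %*% pow %*% p_b)
        mis0 <- sum(w * (abs(v0) - m)^2)
        lambda <- 1e4 * pw0 / max(mis0, 1e-12)
      }
      s <- sign(as.numeric(Am %*% p_b))
      s[s == 0] <- 1
      H <- 2 * pow + 2 * lambda * crossprod(Am, w * Am)
      K <- rbind(cbind(as.matrix(H), rep(1, n_b)),
                 c(rep(1, n_b), 0))
      objective <- function(p) {
        as.numeric(t(p) %*% pow %*% p) +
          lambda * sum(w * (abs(as.numeric(Am %*% p)) - m)^2)
      }
      best_p <- p_b; best_j <- Inf
      for (sit in 1:40) {
        cvec <- 2 * lambda * as.numeric(crossprod(Am, w * (s * m)))
        sol <- solve(K, c(cvec, n_b * p_ref))
        p_try <- sol[seq_len(n_b)]
        j_try <- objective(p_try)
        if (j_try < best_j) { best_j <- j_try; best_p <- p_try }
        s_new <- sign(as.numeric(Am %*% p_try))
        s_new[s_new == 0] <- 1
        if (all(s_new == s)) break   # sign pattern is self-consistent
        s <- s_new
      }
      p_b <- best_p  # on a sign limit cycle, keep the best iterate
    } else {
      # power-only problem with gauge (and, if needed, pressure-drop)
      # constraints
      cons <- matrix(1, 1, n_b)
      rhs <- n_b * p_ref
      drop_row <- b_in / sum(b_in) - (!b_in) / sum(!b_in)
      solve_cons <- function(cons, rhs) {
        K <- rbind(cbind(2 * as.matrix(pow), t(cons)),
                   cbind(cons, matrix(0, nrow(cons), nrow(cons))))
        solve(K, c(rep(0, n_b), rhs))[seq_len(n_b)]
      }
      p_b <- solve_cons(cons, rhs)
      if (sum(drop_row * p_b) < dp_min) {
        p_b <- solve_cons(rbind(cons, drop_row), c(rhs, dp_target))
      }
    }
    names(p_b) <- vm$bnd_nodes
    net <- solve_pressures(net, p_b, h_t = h)
    net <- distribute_hematocrit(net, inflow_ht = inflow_ht)
    if (stabilized) { converged <- TRUE; break }
    if (!is.null(q_prev)) {
      dq <- max(abs(net$vessels$q - q_prev)) /
        max(mean(abs(net$vessels$q)), 1e-300)
      history <- c(history, dq)
      if (dq < tol) { converged <- TRUE; break }
    }
    q_prev <- net$vessels$q
    if (n_deepened >= 2L || outer >= max_outer - avg_len - 5L) {
      if (is.null(h_accum)) h_accum <- numeric(nrow(net$vessels))
      h_accum <- h_accum + net$vessels$h_t
      n_accum <- n_accum + 1L
      if (n_accum >= avg_len) {
        # freeze the viscosity field at the cycle-averaged hematocrit and
        # run one final optimization + distribution pass
        h <- h_accum / n_accum
        stabilized <- TRUE
        next
      }
    }
    # under-relaxation suppresses limit cycles from the discrete switching
    # of the phase-separation law; deepen the damping when the residual
    # stalls (period-two cycles on larger networks)
    if (length(history) > 0) {
      if (history[length(history)] < best_dq * 0.98) {
        best_dq <- history[length(history)]
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= 8L) {
          relax <- max(relax / 2, 0.02)
          n_deepened <- n_deepened + 1L
          stall <- 0L
        }
      }
    }
    h <- (1 - relax) * h + relax * net$vessels$h_t
  }
  if (!converged && max_outer > 1) {
    stop("flow reconstruction did not converge within ", max_outer,
         " outer iterations; relative flow changes: ",
         paste(signif(utils::tail(history, 5), 3), collapse = ", "),
         call. = FALSE)
  }
  report <- list(lambda = if (has_meas) lambda else NA_real_,
                 outer_iterations = outer, history = history,
                 stabilized = stabilized)
  if (stabilized) {
    warning("hematocrit fixed point oscillated; flow solved at the ",
            "cycle-averaged viscosity field", call. = FALSE)
  }
  if (has_meas) {
    v_model <- abs(net$vessels$v_rbc[midx])
    report$misfit <- tibble::tibble(vessel = measurements$vessel,
                                    v_meas = m, v_model = v_model,
                                    residual = v_model - m)
    report$misfit_rms <- sqrt(mean((v_model - m)^2))
  }
  attr(net, "reconstruction") <- report
  net
}

#' Check volume and RBC-flux conservation at interior nodes
#'
#' @param net A solved `capnet`.
#' @return Tibble with one row per interior node: net volume flux and net
#'   RBC flux imbalance, both relative to the mean absolute vessel flux.
#' @export
flow_conservation <- function(net) {
  stop_if_no_flow(net)
  v <- net$vessels
  interior <- net$nodes$node[net$nodes$boundary == "interior"]
  qs <- c(-v$q, v$q)          # signed flux into from/to node
  nodes_at <- c(v$from, v$to)
  rbc <- if ("q_rbc" %in% names(v)) {
    sign(c(-v$q, v$q)) * abs(c(v$q_rbc, v$q_rbc))
  } else NULL
  qref <- mean(abs(v$q))
  out <- tibble::tibble(
    node = interior,
    volume_imbalance = vapply(interior, function(n)
      sum(qs[nodes_at == n]) / qref, numeric(1))
  )
  if (!is.null(rbc)) {
    rbc_ref <- max(mean(abs(v$q_rbc)), 1e-300)
    out$rbc_imbalance <- vapply(interior, function(n)
      sum(rbc[nodes_at == n]) / rbc_ref, numeric(1))
  }
  out
}
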