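#' Target statistics for synthetic capillary networks
#'
#' Defaults emulate the topology and flow statistics reported for
#' reconstructed mouse somatosensory cortex capillary networks (about 90
#' vessels, diameters 5 +/- 1.5 um bounded below by 3 um, vessel lengths
#' around 57 +/- 41 um, RBC speeds around 0.9 mm/s, inflow tube hematocrit
#' 0.25, roughly 22 converging bifurcations in a ~220 x 220 x 170 um box).
#'
#' @param n_vessels Number of vessels.
#' @param diameter_mean,diameter_sd,diameter_floor Diameter distribution, um.
#' @param length_mean,length_sd Vessel length distribution, um.
#' @param box Bounding box extents `c(x, y, z)`, um.
#' @param n_converging Target number of converging bifurcations (used for
#'   generator bookkeeping; the realized count is an emergent property).
#' @param n_inflow,n_outflow Optional boundary node counts (`NA` = emergent).
#' @param v_rbc_mean,v_rbc_sd Target mean/SD of the RBC speed distribution,
#'   um/s.
#' @param inflow_ht Tube hematocrit at inflow vessels.
#' @param pressure_noise Boundary pressure SD as a fraction of the mean
#'   inflow-outflow pressure drop; controls flow heterogeneity.
#' @return A list of class `network_stats_target`.
#' @export
network_stats_target <- function(n_vessels = 92,
                                 diameter_mean = 5, diameter_sd = 1.5,
                                 diameter_floor = 3,
                                 length_mean = 57.3, length_sd = 41.1,
                                 box = c(219, 220, 168),
                                 n_converging = 22,
                                 n_inflow = NA, n_outflow = NA,
                                 v_rbc_mean = 900, v_rbc_sd = 475,
                                 inflow_ht = 0.25,
                                 pressure_noise = 0.15) {
  stopifnot(n_vessels >= 3, diameter_mean > 0, diameter_sd >= 0,
            length_mean > 0, length_sd >= 0, all(box > 0),
            length(box) == 3, v_rbc_mean > 0,
            inflow_ht >= 0, inflow_ht < 1)
  structure(as.list(environment()), class = "network_stats_target")
}

rtnorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

# perpendicular unit vectors to u
perp_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# tortuous polyline from a to b with arc length ~ target (>= chord)
tortuous_polyline <- function(a, b, target_len) {
  chord <- sqrt(sum((b - a)^2))
  if (target_len <= chord * (1 + 1e-9)) return(rbind(a, b))
  m <- max(7, round(chord / 5))
  tt <- seq(0, 1, length.out = m + 2)
  base <- outer(1 - tt, a) + outer(tt, b)
  pb <- perp_basis(b - a)
  # short-wavelength wiggles keep lateral excursions small relative to the
  # extra arc length
  c1 <- stats::rnorm(2); c2 <- stats::rnorm(2) * 0.7
  nrm <- sqrt(sum(c1^2) + sum(c2^2))
  c1 <- c1 / nrm; c2 <- c2 / nrm
  shape <- outer(sin(2 * pi * tt), c1[1] * pb$e1 + c1[2] * pb$e2) +
    outer(sin(3 * pi * tt), c2[1] * pb$e1 + c2[2] * pb$e2)
  f <- function(amp) polyline_length(base + amp * shape) - target_len
  hi <- chord
  while (f(hi) < 0) hi <- hi * 2
  amp <- stats::uniroot(f, c(0, hi), tol = 1e-11 * target_len)$root
  base + amp * shape
}

lattice_dims <- function(n_nodes, box) {
  base <- box / (prod(box) / n_nodes)^(1 / 3)
  best <- NULL; best_err <- Inf
  for (f in seq(0.7, 1.5, by = 0.01)) {
    dims <- pmax(2L, as.integer(round(base * f)))
    err <- abs(prod(dims) - n_nodes) + 0.5 * (prod(dims) < 0.9 * n_nodes)
    if (err < best_err) { best <- dims; best_err <- err }
  }
  best
}

lattice_edges <- function(dims) {
  idx <- function(i, j, k) (k - 1) * dims[1] * dims[2] + (j - 1) * dims[1] + i
  e <- list()
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  for (d in 1:3) {
    ok <- g[[d]] < dims[d]
    g2 <- g[ok, ]
    shift <- g2
    shift[[d]] <- shift[[d]] + 1
    e[[d]] <- cbind(idx(g2$i, g2$j, g2$k), idx(shift$i, shift$j, shift$k))
  }
  do.call(rbind, e)
}

generate_topology <- function(stats) {
  n_target <- stats$n_vessels
  dims <- lattice_dims(max(4, round(0.75 * n_target)), stats$box)
  # the node cloud fills a slightly shrunk core so that tortuous excursions
  # stay near the target box; strong jitter (+/- half a cell) reproduces the
  # irregular internode spacing of real capillary meshes
  core <- stats$box * 0.72
  spacing <- core / pmax(dims - 1, 1)
  offset <- (stats$box - core) / 2
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  pos <- cbind(offset[1] + (g$i - 1) * spacing[1],
               offset[2] + (g$j - 1) * spacing[2],
               offset[3] + (g$k - 1) * spacing[3])
  jit <- matrix(stats::runif(length(pos), -0.5, 0.5), ncol = 3)
  pos <- pos + jit %*% diag(spacing)
  edges <- lattice_edges(dims)
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  # nodes on the outer lattice shell: candidates for cut-end boundary stubs
  # (an imaged tissue box truncates the mesh at its faces)
  on_face <- g$i %in% c(1L, dims[1]) | g$j %in% c(1L, dims[2]) |
    g$k %in% c(1L, dims[3])
  # prune non-bridge edges down to the target count, biased toward
  # high-degree endpoints (degree three dominates in capillary meshes) and
  # toward stranding face nodes as degree-one boundary stubs
  while (igraph::ecount(gr) > n_target) {
    br <- igraph::bridges(gr)
    cand <- setdiff(seq_len(igraph::ecount(gr)), br)
    if (length(cand) == 0) break
    ends <- igraph::ends(gr, cand)
    deg <- igraph::degree(gr)
    stub <- (on_face[ends[, 1]] & deg[ends[, 1]] == 2) +
      (on_face[ends[, 2]] & deg[ends[, 2]] == 2)
    score <- deg[ends[, 1]] + deg[ends[, 2]] + 2.5 * stub
    if (stats::runif(1) < 0.55) {
      pick <- cand[sample.int(length(cand), 1, prob = exp(score))]
    } else {
      pick <- cand[sample.int(length(cand), 1)]
    }
    gr <- igraph::delete_edges(gr, pick)
  }
  # drop nodes that lost all their edges
  keep <- which(igraph::degree(gr) > 0)
  if (length(keep) < igraph::vcount(gr)) {
    gr <- igraph::induced_subgraph(gr, keep)
    pos <- pos[keep, , drop = FALSE]
  }
  comp <- igraph::components(gr)
  if (comp$no > 1) {  # keep largest component
    main <- which(comp$membership == which.max(comp$csize))
    gr <- igraph::induced_subgraph(gr, main)
    pos <- pos[main, , drop = FALSE]
  }
  list(edges = igraph::as_edgelist(gr, names = FALSE), pos = pos)
}

#' Generate a synthetic capillary network
#'
#' Builds a connected three-dimensional capillary mesh from a jittered cubic
#' lattice with random edge pruning, draws diameters and (tortuosity-realized)
#' vessel lengths from truncated normal distributions matching the target
#' statistics, labels degree-one nodes on the top/side of the box as inflow
#' and the remainder as outflow, and solves a ground-truth flow field whose
#' boundary pressures are calibrated to the target mean RBC speed.
#'
#' @param stats A [network_stats_target()].
#' @param seed Integer seed; generation is fully reproducible.
#' @param solve_flow Solve and store the ground-truth flow (default `TRUE`).
#' @return A validated `capnet` with derived radii and (by default) a flow
#'   solution.
#' @export
generate_network <- function(stats = network_stats_target(), seed = 1L,
                             solve_flow = TRUE) {
  stopifnot(inherits(stats, "network_stats_target"))
  failures <- character(0)
  for (attempt in 1:8) {
    set.seed(seed + 7919L * (attempt - 1L))
    net <- try(generate_network_once(stats, solve_flow), silent = TRUE)
    if (!inherits(net, "try-error")) {
      attr(net, "seed") <- seed
      return(net)
    }
    failures <- c(failures, conditionMessage(attr(net, "condition")))
  }
  stop("network generation failed after 8 attempts for the requested ",
       "statistics; reasons: ", paste(unique(failures), collapse = "; "),
       call. = FALSE)
}

generate_network_once <- function(stats, solve_flow) {
  topo <- generate_topology(stats)
  edges <- topo$edges
  pos <- topo$pos
  n_v <- nrow(edges)
  if (n_v < max(3, 0.7 * stats$n_vessels)) {
    stop("pruning left only ", n_v, " vessels (target ", stats$n_vessels, ")")
  }
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(pos))
  if (sum(deg == 1) < 3) {
    # force boundary stubs: detach one edge at degree-2 nodes on cycles
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    for (it in 1:50) {
      if (sum(igraph::degree(gr) == 1) >= 3) break
      br <- igraph::bridges(gr)
      cand <- setdiff(seq_len(igraph::ecount(gr)), br)
      if (length(cand) == 0) break
      ends <- igraph::ends(gr, cand)
      dg <- igraph::degree(gr)
      ok <- dg[ends[, 1]] == 2 | dg[ends[, 2]] == 2
      pick <- if (any(ok)) cand[which(ok)[1]] else {
        cand[which.max(dg[ends[, 1]] + dg[ends[, 2]])]
      }
      gr <- igraph::delete_edges(gr, pick)
    }
    keep <- which(igraph::degree(gr) > 0)
    comp <- igraph::components(igraph::induced_subgraph(gr, keep))
    main <- keep[comp$membership == which.max(comp$csize)]
    gr <- igraph::induced_subgraph(gr, main)
    pos <- pos[main, , drop = FALSE]
    edges <- igraph::as_edgelist(gr, names = FALSE)
    n_v <- nrow(edges)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(pos))
  }
  bnd <- which(deg == 1)
  if (length(bnd) < 3) stop("fewer than 3 boundary (degree-1) nodes")
  # inflow: boundary nodes near the top face or the low-x side
  zrel <- pos[bnd, 3] / max(stats$box[3], 1e-12)
  xrel <- pos[bnd, 1] / max(stats$box[1], 1e-12)
  is_in <- zrel > 0.55 | xrel < 0.15
  if (!is.na(stats$n_inflow)) {
    ord <- order(-(zrel + pmax(0, 0.15 - xrel)))
    is_in <- seq_along(bnd) %in% ord[seq_len(min(stats$n_inflow, length(bnd) - 1))]
  }
  if (!any(is_in)) is_in[which.max(zrel)] <- TRUE
  if (all(is_in)) is_in[which.min(zrel)] <- FALSE
  boundary <- rep("interior", nrow(pos))
  boundary[bnd[is_in]] <- "inflow"
  boundary[bnd[!is_in]] <- "outflow"

  # vessel lengths: truncated-normal draws bounded below by the chords,
  # moment-corrected by an iterated clamped affine map
  chord <- sqrt(rowSums((pos[edges[, 1], , drop = FALSE] -
                           pos[edges[, 2], , drop = FALSE])^2))
  len <- pmax(chord, rtnorm(n_v, stats$length_mean, stats$length_sd, 3))
  if (stats$length_sd > 0 && n_v >= 5) {
    for (it in 1:60) {
      m <- mean(len); s <- stats::sd(len)
      if (abs(m - stats$length_mean) < 0.004 * stats$length_mean &&
          abs(s - stats$length_sd) < 0.02 * stats$length_sd) break
      a <- stats$length_sd / s
      len <- pmax(chord, a * (len - m) + stats$length_mean)
    }
  }
  centerlines <- purrr::map(seq_len(n_v), function(i) {
    tortuous_polyline(pos[edges[i, 1], ], pos[edges[i, 2], ], len[i])
  })
  diam <- pmax(stats::rnorm(n_v, stats$diameter_mean, stats$diameter_sd),
               stats$diameter_floor)

  # shift the origin to the realized bounding-box corner
  allpts <- do.call(rbind, centerlines)
  origin <- apply(allpts, 2, min)
  centerlines <- purrr::map(centerlines, ~ sweep(.x, 2, origin))
  pos <- sweep(pos, 2, origin)

  nodes <- tibble::tibble(node = seq_len(nrow(pos)), x = pos[, 1],
                          y = pos[, 2], z = pos[, 3], boundary = boundary)
  vessels <- tibble::tibble(vessel = seq_len(n_v), from = edges[, 1],
                            to = edges[, 2], diameter = diam,
                            centerline = centerlines)
  net <- capnet(nodes, vessels)
  net <- derive_radii(net)
  if (!solve_flow) return(net)

  # ground-truth flow: boundary pressures reconstructed so that the speed
  # distribution matches the target mean/SD under the hydraulic constraints
  # (full-coverage synthetic "measurements" drawn from that distribution)
  v_targets <- rtnorm(n_v, stats$v_rbc_mean, stats$v_rbc_sd,
                      lower = 0.05 * stats$v_rbc_mean)
  targets <- tibble::tibble(vessel = vessels$vessel, v_meas = v_targets,
                            noise_sd = stats$pressure_noise *
                              stats$v_rbc_mean)
  net <- reconstruct_flow(net, targets, inflow_ht = stats$inflow_ht)
  # relabel boundary nodes to match the realized flow directions
  de <- directed_ends(net)
  live <- de[!de$zero_flow, ]
  is_b <- net$nodes$boundary != "interior"
  feeds <- net$nodes$node %in% live$tail
  drains <- net$nodes$node %in% live$head
  net$nodes$boundary[is_b & feeds] <- "inflow"
  net$nodes$boundary[is_b & drains & !feeds] <- "outflow"
  if (sum(net$nodes$boundary == "inflow") == 0 ||
      sum(net$nodes$boundary == "outflow") == 0) {
    stop("flow does not percolate between inflow and outflow nodes")
  }
  net
}

#' Sample sparse RBC velocity measurements from a solved network
#'
#' Emulates line-scan velocimetry coverage: a random subset of vessels is
#' selected and the true speeds are perturbed with Gaussian noise.
#'
#' @param net A `capnet` with (ground-truth) flow.
#' @param fraction Fraction of vessels measured, in (0, 1].
#' @param noise_sd Measurement noise SD, um/s.
#' @param seed Integer seed.
#' @return Tibble with columns `vessel`, `v_meas` (um/s, positive) and
#'   `noise_sd`.
#' @export
sample_measurements <- function(net, fraction = 0.3, noise_sd = 0,
                                seed = 1L) {
  stop_if_no_flow(net)
  n <- nrow(net$vessels)
  n_sel <- floor(fraction * n)
  if (n_sel < 1) {
    stop("fraction * n_vessels = ", fraction * n,
         " selects no vessels", call. = FALSE)
  }
  set.seed(seed)
  sel <- sort(sample.int(n, n_sel))
  v <- abs(net$vessels$v_rbc[sel]) + stats::rnorm(n_sel, 0, noise_sd)
  tibble::tibble(vessel = net$vessels$vessel[sel],
                 v_meas = pmax(v, 1), noise_sd = noise_sd)
}

#' Assign inflow hemoglobin saturation boundary values
#'
#' Either a constant saturation at every inflow vessel or an independent
#' uniform draw per inflow vessel.
#'
#' @param net A `capnet`.
#' @param mode `"constant"` or `"uniform"`.
#' @param value Constant saturation (mode `"constant"`).
#' @param range Length-2 interval in `[0, 1]` (mode `"uniform"`).
#' @param seed Integer seed (mode `"uniform"`).
#' @return Tibble with columns `vessel`, `s_a` covering the inflow vessels.
#' @export
assign_inflow_saturation <- function(net, mode = c("constant", "uniform"),
                                     value = 0.6, range = c(0.5, 0.7),
                                     seed = 1L) {
  mode <- match.arg(mode)
  inflow_nodes <- net$nodes$node[net$nodes$boundary == "inflow"]
  if (length(inflow_nodes) == 0) stop("network has no inflow nodes",
                                      call. = FALSE)
  vid <- net$vessels$vessel[net$vessels$from %in% inflow_nodes |
                              net$vessels$to %in% inflow_nodes]
  if (mode == "constant") {
    if (value < 0 || value > 1) stop("saturation must be in [0, 1]",
                                     call. = FALSE)
    return(tibble::tibble(vessel = vid, s_a = value))
  }
  stopifnot(length(range) == 2)
  if (any(range < 0) || any(range > 1) || range[1] > range[2]) {
    stop("saturation range must be within [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  tibble::tibble(vessel = vid,
                 s_a = stats::runif(length(vid), range[1], range[2]))
}
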