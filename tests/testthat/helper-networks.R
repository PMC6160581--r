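# small hand-built fixture networks with fully specified flow states

# straight chain of n vessels along x
make_chain_net <- function(n = 3, length = 50, diameter = 5, p_in = 55,
                           p_out = 45, inflow_ht = 0.25) {
  nodes <- tibble::tibble(
    node = seq_len(n + 1),
    x = (seq_len(n + 1) - 1) * length, y = 0, z = 0,
    boundary = c("inflow", rep("interior", n - 1), "outflow")
  )
  vessels <- tibble::tibble(vessel = seq_len(n), from = seq_len(n),
                            to = seq_len(n) + 1, diameter = diameter)
  net <- derive_radii(capnet(nodes, vessels))
  pb <- stats::setNames(c(p_in, p_out), c(1, n + 1))
  solve_network_flow(net, pb, inflow_ht = inflow_ht)
}

# two parent vessels converging into one child
make_y_net <- function(diameters = c(5, 5, 5), p_in = c(55, 55),
                       p_out = 45, inflow_ht = 0.25) {
  nodes <- tibble::tibble(
    node = 1:4,
    x = c(0, 0, 50, 110), y = c(30, -30, 0, 0), z = 0,
    boundary = c("inflow", "inflow", "interior", "outflow")
  )
  vessels <- tibble::tibble(vessel = 1:3, from = c(1, 2, 3), to = c(3, 3, 4),
                            diameter = diameters)
  net <- derive_radii(capnet(nodes, vessels))
  pb <- stats::setNames(c(p_in, p_out), c(1, 2, 4))
  solve_network_flow(net, pb, inflow_ht = inflow_ht)
}

# one inflow diverging into two branches that reconverge (diamond)
make_diamond_net <- function(branch_d = c(5, 5), p_in = 55, p_out = 45,
                             inflow_ht = 0.25) {
  nodes <- tibble::tibble(
    node = 1:4,
    x = c(0, 50, 110, 160), y = 0, z = 0,
    boundary = c("inflow", "interior", "interior", "outflow")
  )
  nodes$y <- 0
  vessels <- tibble::tibble(
    vessel = 1:4, from = c(1, 2, 2, 3), to = c(2, 3, 3, 4),
    diameter = c(5, branch_d, 5),
    centerline = list(
      rbind(c(0, 0, 0), c(50, 0, 0)),
      rbind(c(50, 0, 0), c(80, 25, 0), c(110, 0, 0)),
      rbind(c(50, 0, 0), c(80, -25, 0), c(110, 0, 0)),
      rbind(c(110, 0, 0), c(160, 0, 0))
    )
  )
  net <- derive_radii(capnet(nodes, vessels))
  pb <- stats::setNames(c(p_in, p_out), c(1, 4))
  solve_network_flow(net, pb, inflow_ht = inflow_ht)
}

# small generator settings for fast stochastic tests
small_stats <- function(n_vessels = 40, ...) {
  scale <- (n_vessels / 92)^(1 / 3)
  network_stats_target(n_vessels = n_vessels,
                       box = c(219, 220, 168) * scale, ...)
}

quiet_generate <- function(...) suppressWarnings(generate_network(...))

# single straight vessel with prescribed flow state, for transport oracles
make_single_vessel <- function(length = 100, diameter = 5, v = 1000,
                               h_t = 0.25) {
  net <- make_chain_net(n = 1, length = length, diameter = diameter)
  # overwrite with the prescribed state (velocity sign along from->to)
  net$vessels$v_rbc <- v
  net$vessels$q <- v * pi * net$vessels$r_p^2
  net$vessels$h_t <- h_t
  net$vessels$mu_ld <- linear_density(h_t, net$vessels$r_p, net$vessels$r_c)
  net$vessels$q_rbc <- h_t * abs(net$vessels$q)
  net
}

# cached expensive study objects shared across acceptance tests
study_cache <- new.env(parent = emptyenv())

cached_study <- function(seed, ...) {
  key <- paste0("study_", seed, "_", rlang::hash(list(...)))
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- suppressWarnings(
      run_cosh_study(seed = seed, ...))
  }
  study_cache[[key]]
}
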