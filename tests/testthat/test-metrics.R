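test_that("weighted statistics use the population convention", {
  expect_equal(weighted_sd(c(0.4, 0.6), c(1, 1)), 0.1)
  expect_equal(weighted_sd(rep(0.5, 5), runif(5) + 0.1), 0)
  # weights {2, 1} on {0.3, 0.6}: mean 0.4, SD sqrt(0.02)
  expect_equal(weighted_mean(c(0.3, 0.6), c(2, 1)), 0.4)
  expect_equal(weighted_sd(c(0.3, 0.6), c(2, 1)), sqrt(0.02))
  expect_error(weighted_sd(c(1, 2), c(0, 0)), "zero")
})

test_that("path enumeration weights are RBC-routing probabilities", {
  chain <- make_chain_net(3)
  p <- enumerate_paths(chain)
  expect_equal(nrow(p), 1)
  expect_equal(p$weight, 1)
  expect_equal(p$tau, sum(chain$vessels$length / abs(chain$vessels$v_rbc)))
  dia <- make_diamond_net()
  pd <- enumerate_paths(dia)
  expect_equal(nrow(pd), 2)
  expect_equal(sort(pd$weight), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("path weights sum to one and match an independent graph
           enumeration on small networks", {
  for (s in c(2, 5)) {
    net <- quiet_generate(small_stats(12), seed = s)
    paths <- enumerate_paths(net)
    expect_equal(sum(paths$weight), 1, tolerance = 1e-12)
    # independent oracle: count simple directed paths with igraph
    de <- directed_ends(net)
    live <- de[!de$zero_flow, ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(live$tail),
                 to = as.character(live$head)))
    bnd <- as.character(net$nodes$node[net$nodes$boundary != "interior"])
    sources <- intersect(bnd, as.character(live$tail))
    sinks <- intersect(bnd, as.character(live$head))
    n_oracle <- 0
    for (src in intersect(sources, igraph::V(g)$name)) {
      for (snk in intersect(sinks, igraph::V(g)$name)) {
        n_oracle <- n_oracle +
          length(igraph::all_simple_paths(g, src, snk, mode = "out"))
      }
    }
    expect_equal(nrow(paths), n_oracle)
  }
})

test_that("the model comparison reductions follow the COSH formula", {
  two_point <- function(sd) tibble::tibble(s = c(0.5 - sd, 0.5 + sd),
                                           w = c(0.5, 0.5))
  same <- compare_models(two_point(0.08), two_point(0.08), two_point(0.08))
  expect_equal(same$reduction_total, 0)
  cmp <- compare_models(two_point(0.0891), two_point(0.0599),
                        two_point(0.0512))
  expect_equal(cmp$table$cosh, c(0.0891, 0.0599, 0.0512))
  expect_equal(cmp$reduction_total, 42.5, tolerance = 1e-2)
  # invariant under a common rescaling of the weights
  a <- two_point(0.0891); a$w <- a$w * 7
  cmp2 <- compare_models(a, two_point(0.0599), two_point(0.0512))
  expect_equal(cmp2$reduction_total, cmp$reduction_total)
})

test_that("the correlation suite reports exact and null relations", {
  paths <- tibble::tibble(
    s_a = 0.6, tau = seq(0.05, 0.5, length.out = 40),
    length = runif(40, 50, 400)
  )
  paths$delta_s <- 0.4 * paths$tau          # deterministic in tau
  paths$s_v <- paths$s_a - paths$delta_s
  paths$weight <- rep(1 / 40, 40)
  hs <- correlation_suite(paths)
  r_tau <- hs$correlations$r[hs$correlations$pair == "delta_s_vs_tau"]
  expect_equal(r_tau, 1, tolerance = 1e-12)
  expect_lt(hs$correlations$p_value[1], 1e-10)
  # independent noise: small correlations, roughly uniform p-values
  set.seed(42)
  ps <- replicate(30, {
    pp <- tibble::tibble(s_a = 0.6, tau = rnorm(100), length = rnorm(100),
                         delta_s = rnorm(100))
    pp$s_v <- 0.5; pp$weight <- 1 / 100
    correlation_suite(pp)$correlations$p_value[1]
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("Eq.-4 determinism: uniform hematocrit and extraction make the
           saturation drop a function of transit time alone", {
  net <- quiet_generate(small_stats(40), seed = 9)
  net$vessels$h_t <- 0.25
  net$vessels$mu_ld <- linear_density(0.25, net$vessels$r_p,
                                      net$vessels$r_c)
  net$vessels$q_rbc <- net$vessels$mu_ld * abs(net$vessels$v_rbc) * pi *
    net$vessels$r_c^2
  net$vessels$r_c <- mean(net$vessels$r_c)   # uniform capacity geometry
  net$vessels$mu_ld <- mean(net$vessels$mu_ld)
  paths <- enumerate_paths(net)
  r_t <- tibble::tibble(vessel = net$vessels$vessel, r_t = 15)
  net$vessels$r_w <- 2.5
  inflow_s <- tibble::tibble(vessel = net$vessels$vessel, s_a = 0.6)
  params <- oxygen_params(m0 = 5e-5)
  out <- path_outflow_ode(net, paths, r_t, inflow_s, params)
  keep <- out$s_v > 0
  expect_gt(sum(keep), 5)
  r <- stats::cor(out$delta_s[keep], out$tau[keep])
  expect_gt(r, 0.999)
})

test_that("the pipeline runs end to end, gates stages and is deterministic", {
  cfg <- list(
    seed = 4,
    network = list(n_vessels = 30, box = c(150, 151, 115)),
    voxel = list(h = 3, bin_width = 5),
    lagrangian = list(t_end = 3, averaging = 1, dt = 1e-3,
                      spacing_cv = 0.5, coupling = TRUE)
  )
  d1 <- file.path(withr::local_tempdir(), "run1")
  d2 <- file.path(withr::local_tempdir(), "run2")
  out1 <- suppressWarnings(run_pipeline(c(cfg, list(out_dir = d1))))
  expect_s3_class(out1$study, "cosh_study")
  expect_lt(out1$study$conservation$discrepancy, 0.25)
  expect_true(file.exists(file.path(d1, "summary.json")))
  out2 <- suppressWarnings(run_pipeline(c(cfg, list(out_dir = d2))))
  for (f in c("territories.csv", "paths_lagrangian.csv", "summary.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # stage gating: flow only
  flow_only <- suppressWarnings(run_pipeline(list(
    seed = 4, stages = c("generate", "flow"),
    network = list(n_vessels = 30, box = c(150, 151, 115)))))
  expect_null(flow_only$study)
  expect_true(all(c("q", "v_rbc") %in% names(flow_only$net$vessels)))
})
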