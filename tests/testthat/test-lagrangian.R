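test_that("renewal injection converges to the target linear density", {
  set.seed(1)
  # periodic arrivals: exact density
  tt <- inject_rbcs(0.3, 1000, 7, spacing_cv = 0, t_total = 10)
  mu_real <- length(tt) * 7 / (1000 * 10)
  expect_lt(abs(mu_real - 0.3) / 0.3, 0.01)
  # stochastic arrivals: density within 5% over a long stream
  tt2 <- inject_rbcs(0.3, 1000, 7, spacing_cv = 0.5, t_total = 10)
  mu2 <- length(tt2) * 7 / (1000 * 10)
  expect_lt(abs(mu2 - 0.3) / 0.3, 0.05)
  # hard-core constraint: arrivals can never overlap, even at density 1
  tt3 <- inject_rbcs(0.999, 1000, 7, spacing_cv = 0.8, t_total = 2)
  expect_gte(min(diff(tt3)), 7 / 1000 - 1e-12)
})

single_vessel_run <- function(spacing_cv, seed = 11, h_t = 0.25,
                              t_end = 4, s_a = 0.6, m0 = 2e-4) {
  net <- make_single_vessel(length = 150, v = 800, h_t = h_t)
  terr <- assign_geometric_territories(net, h = 2, margin = 15)
  inflow_s <- tibble::tibble(vessel = 1L, s_a = s_a)
  params <- oxygen_params(m0 = m0)
  run <- simulate_rbc_transport(net, terr, inflow_s, params = params,
                                t_end = t_end, averaging = 1,
                                spacing_cv = spacing_cv, seed = seed)
  list(net = net, terr = terr, run = run, params = params)
}

test_that("the uniform-spacing limit reproduces the transport equation", {
  res <- single_vessel_run(spacing_cv = 0)
  w <- res$run$exits[res$run$exits$in_window, ]
  jt <- extraction_rate(res$terr$territories$r_t_geo,
                        res$net$vessels$r_w, res$params$m0)
  s_ode <- vessel_forward(0.6, jt, 800, res$net$vessels$mu_ld,
                          res$net$vessels$r_c, res$net$vessels$r_p, 150,
                          res$params)
  expect_lt(abs(mean(w$s_out) - s_ode) / (0.6 - s_ode), 0.02)
  # deterministic injection: negligible outflow spread
  expect_lt(stats::sd(w$s_out), 2e-3)
})

test_that("runs are seed-reproducible", {
  a <- single_vessel_run(spacing_cv = 0.5, seed = 7, t_end = 2)$run
  b <- single_vessel_run(spacing_cv = 0.5, seed = 7, t_end = 2)$run
  expect_identical(a$exits$s_out, b$exits$s_out)
  expect_identical(a$exits$t_exit, b$exits$t_exit)
})

test_that("hematocrit fluctuations grow heterogeneity from a uniform inlet", {
  res <- single_vessel_run(spacing_cv = 0.8, seed = 3, t_end = 6)
  w <- res$run$exits[res$run$exits$in_window, ]
  expect_gt(stats::sd(w$s_out), 1e-3)   # inlet sigma is exactly 0
})

test_that("RBC diffusive interaction shrinks saturation differences", {
  # two inflow vessels with different saturations converging into a child:
  # the child outflow spread is below its inlet spread
  net <- make_y_net(p_in = c(55, 55))
  terr <- assign_geometric_territories(net, h = 2, margin = 15)
  inflow_s <- tibble::tibble(vessel = c(1L, 2L), s_a = c(0.7, 0.5))
  params <- oxygen_params(m0 = 2e-4)
  run <- simulate_rbc_transport(net, terr, inflow_s, params = params,
                                t_end = 6, averaging = 2, spacing_cv = 0.3,
                                seed = 5)
  vs <- run$vessel_stats
  child <- vs[vs$vessel == 3, ]
  expect_gt(child$sigma_a, 0.03)        # mixed parent saturations arrive
  expect_lt(child$sigma_v, child$sigma_a)
})

test_that("the window oxygen budget closes", {
  res <- single_vessel_run(spacing_cv = 0.5, seed = 9, t_end = 4)
  expect_lt(abs(res$run$balance$relative_error), 0.01)
})

test_that("gap-versus-drop correlation detects the constructed signal", {
  set.seed(4)
  n <- 120
  t_in <- cumsum(rexp(n, 50))
  gaps <- c(NA, diff(t_in))
  drop <- 0.05 + 0.4 * ifelse(is.na(gaps), 0.02, gaps) + rnorm(n, 0, 0.004)
  transits <- tibble::tibble(vessel = 1L, rbc = seq_len(n), t_in = t_in,
                             s_in = 0.6, t_out = t_in + 0.05,
                             s_out = 0.6 - drop)
  res <- correlate_gap_vs_drop(transits, n_perm = 500, seed = 1)
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)
  # destroying the pairing kills the correlation
  shuffled <- transits
  shuffled$s_out <- 0.6 - sample(drop)
  res2 <- correlate_gap_vs_drop(shuffled, n_perm = 500, seed = 1)
  expect_gt(res2$p_value, 0.05)
  # constant gaps are degenerate
  const <- transits
  const$t_in <- seq_len(n) * 0.02
  const$s_out <- 0.6 - drop
  res3 <- correlate_gap_vs_drop(const, n_perm = 100, seed = 1)
  expect_true(res3$degenerate)
})
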