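test_that("Hill equilibrium identities hold", {
  expect_equal(hill_peq(0.5, p50 = 47.9), 47.9)
  expect_equal(hill_seq(hill_peq(0.73)), 0.73, tolerance = 1e-12)
  # P_eq(0.8) = P50 * 4^(1/n)
  expect_equal(hill_peq(0.8, 47.9, 2.64), 47.9 * 4^(1 / 2.64),
               tolerance = 1e-12)
  # closed-form derivative against a central difference
  h <- 1e-6
  num <- (hill_peq(0.6 + h) - hill_peq(0.6 - h)) / (2 * h)
  expect_equal(hill_dpeq_ds(0.6), num, tolerance = 1e-6)
})

test_that("convective capacity combines RBC and plasma contributions", {
  p0 <- oxygen_params(alpha_eff = 0, c0 = 0.5)
  q1 <- convective_capacity(0.3, 1000, 0.3906, 1.6, 2, p0)
  q2 <- convective_capacity(0.8, 1000, 0.3906, 1.6, 2, p0)
  expect_equal(q1, q2)                       # S-independent without plasma
  expect_equal(q1, 1570.70, tolerance = 1e-4)
  expect_equal(convective_capacity(0.5, 2000, 0.3906, 1.6, 2, p0), 2 * q1)
  pa <- oxygen_params(alpha_eff = 3e-5)
  expect_gt(convective_capacity(0.5, 1000, 0.3906, 1.6, 2, pa), q1)
})

test_that("extraction rate is the Krogh annulus consumption", {
  expect_equal(extraction_rate(2.5, 2.5, 1), 0)
  expect_equal(extraction_rate(18.8, 2.5, 1), pi * (18.8^2 - 2.5^2))
  expect_equal(extraction_rate(18.8, 2.5, 1), 1090.67, tolerance = 1e-4)
  expect_gt(extraction_rate(20, 2.5, 1), extraction_rate(15, 2.5, 1))
  expect_error(extraction_rate(2, 2.5, 1), "smaller")
})

test_that("the adaptive solve matches the hemoglobin-only closed form", {
  # adaptive ODE forced by a tiny plasma solubility; compared to the exact
  # linear solution of the hemoglobin-only limit
  p_ode <- oxygen_params(alpha_eff = 1e-10)
  p_lin <- oxygen_params(alpha_eff = 0)
  s_in <- c(0.7, 0.55, 0.4)
  jt <- 0.8   # physiological scale: M0 pi (r_t^2 - r_w^2) with r_t ~ 20 um
  ode <- integrate_vessel(s_in, jt, 900, 0.39, 1.6, 2, 80, p_ode,
                          n_out = 11)
  cap <- 900 * 0.39 * pi * 1.6^2 * p_lin$c0
  exact <- outer(ode$x, s_in, function(x, s0) s0 - jt * x / cap)
  expect_equal(ode$s, pmax(exact, 0), tolerance = 1e-8)
  # zero extraction conserves saturation exactly
  cons <- integrate_vessel(0.6, 0, 900, 0.39, 1.6, 2, 80, p_lin)
  expect_equal(cons$s[nrow(cons$s), ], 0.6)
  # strong extraction floors at zero and is flagged
  fl <- integrate_vessel(0.05, 5000, 300, 0.2, 1.6, 2, 80, p_lin)
  expect_equal(fl$s[nrow(fl$s), ], 0)
  expect_true(fl$floored)
})

test_that("atoms sharing an extraction profile never cross", {
  p <- oxygen_params(alpha_eff = 3e-5)
  s_in <- sort(runif(8, 0.2, 0.9))
  out <- integrate_vessel(s_in, 600, 700, 0.3, 1.6, 2, 90, p)
  for (r in seq_len(nrow(out$s))) {
    expect_true(all(diff(out$s[r, ]) >= -1e-10))
  }
})

test_that("converging bifurcations mix distributions by RBC flux", {
  y <- make_y_net()
  # force known RBC fluxes in a 2:1 ratio
  y$vessels$q_rbc <- c(2, 1, 3)
  y$vessels$mu_ld <- rep(0.3, 3)
  inflow_s <- tibble::tibble(vessel = c(1L, 2L), s_a = c(0.6, 0.4))
  r_t <- tibble::tibble(vessel = 1:3, r_t = y$vessels$r_w)  # no extraction
  prop <- propagate_network(y, inflow_s, r_t)
  din <- prop$distributions$inlet[[3]]
  ord <- order(din$s, decreasing = TRUE)
  expect_equal(din$s[ord], c(0.6, 0.4))
  expect_equal(din$w[ord], c(2 / 3, 1 / 3), tolerance = 1e-12)
  # equal fluxes give equal weights
  y$vessels$q_rbc <- c(1, 1, 2)
  prop2 <- propagate_network(y, inflow_s, r_t)
  expect_equal(sort(prop2$distributions$inlet[[3]]$w), c(0.5, 0.5))
})

test_that("a chain with constant inflow carries single-atom distributions", {
  chain <- make_chain_net(3)
  inflow_s <- tibble::tibble(vessel = 1L, s_a = 0.6)
  r_t <- tibble::tibble(vessel = 1:3, r_t = 15)
  prop <- propagate_network(chain, inflow_s, r_t)
  expect_true(all(prop$vessels$n_atoms == 1))
  expect_true(all(diff(prop$vessels$s_v) < 0))  # monotone along the chain
})

test_that("atom weights sum to one and saturation is monotone network-wide", {
  net <- quiet_generate(small_stats(40), seed = 6)
  inflow_s <- assign_inflow_saturation(net, "uniform", seed = 2)
  terr <- assign_geometric_territories(net, h = 4)
  r_t <- dplyr::rename(
    dplyr::select(terr$territories, "vessel", "r_t_geo"), r_t = "r_t_geo")
  prop <- propagate_network(net, inflow_s, r_t)
  for (d in prop$distributions$outlet) {
    if (!is.null(d)) expect_equal(sum(d$w), 1, tolerance = 1e-12)
  }
  expect_equal(sum(prop$outflow$w), 1, tolerance = 1e-12)
  # within every vessel the mean profile is non-increasing
  drop_ok <- prop$profiles |>
    dplyr::group_by(.data$vessel) |>
    dplyr::summarise(mono = all(diff(.data$s_mean) <= 1e-12))
  expect_true(all(drop_ok$mono))
})

test_that("with geometric radii the released oxygen matches the metabolic
           demand of perfused territories", {
  net <- quiet_generate(small_stats(40), seed = 8)
  # moderate demand so that no atom floors
  params <- oxygen_params(m0 = 5e-5)
  inflow_s <- assign_inflow_saturation(net, "constant", 0.6)
  terr <- assign_geometric_territories(net, h = 2)
  r_t <- dplyr::rename(
    dplyr::select(terr$territories, "vessel", "r_t_geo"), r_t = "r_t_geo")
  prop <- propagate_network(net, inflow_s, r_t, params)
  # vessels whose atoms never floor release exactly their territory demand
  ok <- prop$vessels$vessel[!prop$vessels$floored]
  expect_gt(length(ok), 15)
  rel <- oxygen_release(prop, net, params, per_vessel = TRUE)
  vol <- sum(terr$territories$v_geo[terr$territories$vessel %in% ok])
  expect_equal(sum(rel$release[rel$vessel %in% ok]), params$m0 * vol,
               tolerance = 1e-3)
})

test_that("atom merging conserves mass and the first moment", {
  s <- runif(60)
  w <- runif(60); w <- w / sum(w)
  m <- merge_atoms(s, w, cap = 16)
  expect_lte(length(m$s), 16)
  expect_equal(sum(m$w), 1, tolerance = 1e-12)
  expect_equal(sum(m$s * m$w), sum(s * w), tolerance = 1e-12)
})
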