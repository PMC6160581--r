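test_that("generation is seed-reproducible and validates", {
  a <- quiet_generate(small_stats(30), seed = 5)
  b <- quiet_generate(small_stats(30), seed = 5)
  expect_equal(a$vessels$diameter, b$vessels$diameter, tolerance = 0)
  expect_equal(a$vessels$q, b$vessels$q, tolerance = 0)
  c <- quiet_generate(small_stats(30), seed = 6)
  expect_false(isTRUE(all.equal(a$vessels$diameter, c$vessels$diameter)))
  expect_silent(validate_capnet(a))
})

test_that("tiny networks can be generated", {
  net <- quiet_generate(small_stats(6), seed = 2)
  expect_gte(nrow(net$vessels), 3)
  expect_silent(validate_capnet(net))
})

test_that("realized statistics emulate the target network", {
  net <- quiet_generate(network_stats_target(), seed = 1)
  # diameter within 10% of the reference mean (generator contract)
  expect_lt(abs(mean(net$vessels$diameter) - 5.03) / 5.03, 0.10)
  # converging bifurcation count within +/- 30% of the target
  nc <- attr(classify_bifurcations(net), "n_converging")
  expect_gte(nc, 22 * 0.7)
  expect_lte(nc, 22 * 1.3)
  # speeds within the physiological decade
  vbar <- mean(abs(net$vessels$v_rbc)) / 1000
  expect_gt(vbar, 0.1)
  expect_lt(vbar, 10)
})

test_that("diameter and length moments converge to the targets", {
  st <- network_stats_target(n_vessels = 500,
                             box = c(219, 220, 168) * (500 / 92)^(1 / 3))
  net <- quiet_generate(st, seed = 7)
  expect_lt(abs(mean(net$vessels$diameter) - 5.06) / 5.06, 0.05)
  expect_lt(abs(mean(net$vessels$length) - 57.3) / 57.3, 0.05)
  expect_lt(abs(stats::sd(net$vessels$length) - 41.1) / 41.1, 0.05)
})

test_that("measurement sampling behaves like sparse noisy line scans", {
  net <- quiet_generate(small_stats(40), seed = 2)
  full <- sample_measurements(net, fraction = 1, noise_sd = 0, seed = 1)
  expect_equal(full$v_meas,
               abs(net$vessels$v_rbc[match(full$vessel,
                                           net$vessels$vessel)]))
  s1 <- sample_measurements(net, fraction = 0.3, seed = 9)
  s2 <- sample_measurements(net, fraction = 0.3, seed = 9)
  expect_identical(s1$vessel, s2$vessel)
  expect_error(sample_measurements(net, fraction = 0.001), "selects no")
  # empirical residual SD close to the requested noise level
  st <- network_stats_target(n_vessels = 150,
                             box = c(219, 220, 168) * (150 / 92)^(1 / 3))
  big <- quiet_generate(st, seed = 3)
  noisy <- sample_measurements(big, fraction = 1, noise_sd = 100, seed = 4)
  res <- noisy$v_meas - abs(big$vessels$v_rbc[match(noisy$vessel,
                                                    big$vessels$vessel)])
  expect_lt(abs(stats::sd(res) - 100) / 100, 0.3)
})

test_that("inflow saturation assignment covers both boundary modes", {
  net <- make_y_net()
  const <- assign_inflow_saturation(net, "constant", value = 0.6)
  expect_equal(const$s_a, c(0.6, 0.6))
  u1 <- assign_inflow_saturation(net, "uniform", range = c(0.5, 0.7),
                                 seed = 3)
  u2 <- assign_inflow_saturation(net, "uniform", range = c(0.5, 0.7),
                                 seed = 3)
  expect_identical(u1$s_a, u2$s_a)
  expect_true(all(u1$s_a >= 0.5 & u1$s_a <= 0.7))
  deg <- assign_inflow_saturation(net, "uniform", range = c(0.6, 0.6))
  expect_equal(deg$s_a, c(0.6, 0.6))
  expect_error(assign_inflow_saturation(net, "uniform", range = c(0.5, 1.2)),
               "within")
  expect_error(assign_inflow_saturation(net, "constant", value = -0.1),
               "0, 1")
})
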