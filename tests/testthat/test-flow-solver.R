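test_that("vessel resistance follows the Poiseuille scalings", {
  r1 <- vessel_resistance(5, 50, 0.25)
  expect_equal(vessel_resistance(5, 100, 0.25), 2 * r1)
  # halving the diameter multiplies resistance by at least 16
  expect_gte(vessel_resistance(2.5, 50, 0.25) / r1, 16)
  # zero hematocrit reduces to the plasma value with the in-vivo
  # exclusion-layer factor, evaluated from the law directly
  mu_p <- oxygen_params()$mu_plasma
  dd <- (5 / (5 - 1.1))^2
  expect_equal(vessel_resistance(5, 50, 0),
               128 * mu_p * dd * 50 / (pi * 5^4), tolerance = 1e-12)
  expect_gt(vessel_resistance(5, 50, 0.45), vessel_resistance(5, 50, 0.2))
})

test_that("pressure solve matches the Ohm analogy and symmetry", {
  net <- make_chain_net(1)
  R <- vessel_resistance(net$vessels$diameter, net$vessels$length,
                         net$vessels$h_t)
  expect_equal(net$vessels$q * R, 10, tolerance = 1e-10)  # q = dP / R
  y <- make_y_net()
  expect_equal(y$vessels$q[1], y$vessels$q[2], tolerance = 1e-10)
})

test_that("volume and RBC flux are conserved at interior nodes", {
  net <- quiet_generate(small_stats(40), seed = 4)
  cons <- flow_conservation(net)
  expect_lt(max(abs(cons$volume_imbalance)), 1e-10)
  expect_lt(max(abs(cons$rbc_imbalance)), 1e-10)
})

test_that("flows are gauge invariant under a boundary pressure shift", {
  net <- make_diamond_net()
  pb <- stats::setNames(c(55, 45), c(1, 4))
  a <- solve_pressures(net, pb)
  b <- solve_pressures(net, pb + 10)
  expect_equal(a$vessels$q, b$vessels$q, tolerance = 1e-12)
})

test_that("missing boundary pressures and isolated graphs are rejected", {
  net <- make_y_net()
  expect_error(solve_pressures(net, c("1" = 55)), "node")
})

test_that("hematocrit distribution conserves and splits sensibly", {
  chain <- make_chain_net(4)
  expect_equal(chain$vessels$h_t, rep(0.25, 4), tolerance = 1e-12)
  dia <- make_diamond_net()
  # symmetric branches: equal hematocrit
  expect_equal(dia$vessels$h_t[2], dia$vessels$h_t[3], tolerance = 1e-9)
  # global RBC flux conservation
  de <- directed_ends(dia)
  bnd <- dia$nodes$node[dia$nodes$boundary != "interior"]
  q_in <- sum(dia$vessels$q_rbc[de$tail %in% bnd])
  q_out <- sum(dia$vessels$q_rbc[de$head %in% bnd])
  expect_equal(q_in, q_out, tolerance = 1e-10 * q_in)
})

test_that("linear density follows the cylindrical-RBC geometry", {
  expect_equal(linear_density(0.25, 2, 1.6), 0.25 / 0.64)
  expect_equal(linear_density(0, 2, 1.6), 0)
  expect_equal(linear_density(0.64, 2, 1.6), 1)
  expect_warning(linear_density(0.7, 2, 1.6), "clipped")
})

test_that("flow reconstruction recovers ground truth from full coverage", {
  for (s in 1:2) {
    net <- quiet_generate(small_stats(35), seed = s)
    truth <- abs(net$vessels$v_rbc)
    meas <- sample_measurements(net, fraction = 1, noise_sd = 0, seed = 1)
    blank <- net
    blank$vessels <- dplyr::select(blank$vessels, "vessel", "from", "to",
                                   "diameter", "centerline", "length",
                                   "r_p", "r_c", "r_w")
    rec <- reconstruct_flow(blank, meas, inflow_ht = 0.25)
    rms <- sqrt(mean((abs(rec$vessels$v_rbc) - truth)^2)) / mean(truth)
    expect_lt(rms, 0.02)
    cons <- flow_conservation(rec)
    expect_lt(max(abs(cons$volume_imbalance)), 1e-10)
  }
})

test_that("without measurements the pressure-drop constraint prevents the
           zero-flow solution", {
  net <- make_diamond_net()
  blank <- net
  rec <- reconstruct_flow(blank, NULL, inflow_ht = 0.25)
  expect_gt(mean(abs(rec$vessels$q)), 0)
  p <- rec$nodes$pressure
  drop <- mean(p[rec$nodes$boundary == "inflow"]) -
    mean(p[rec$nodes$boundary == "outflow"])
  expect_gt(drop, 0.4)
})

test_that("all-zero measurement weights are rejected", {
  net <- make_diamond_net()
  meas <- sample_measurements(net, fraction = 1, noise_sd = 0, seed = 1)
  meas$noise_sd <- Inf
  expect_error(reconstruct_flow(net, meas), "zero")
})
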