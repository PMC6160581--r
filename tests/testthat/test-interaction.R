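test_that("the capillary interaction coefficient follows its closed form", {
  # log term cancels exactly at r_t = r_w * sqrt(e)
  expect_equal(capillary_interaction_coefficient(1.5, 2000, 3e-5,
                                                 2.5 * exp(0.5), 2.5),
               1.5, tolerance = 1e-12)
  expect_equal(capillary_interaction_coefficient(0, 2000, 3e-5, 18.8, 2.5),
               (log(18.8 / 2.5) - 0.5) / (2 * pi * 0.06), tolerance = 1e-12)
  k1 <- capillary_interaction_coefficient(1, 2000, 3e-5, 15, 2.5)
  k2 <- capillary_interaction_coefficient(1, 2000, 3e-5, 25, 2.5)
  expect_gt(k2, k1)
})

frozen_rate <- function(k, s_bar0, v = 900, mu = 0.39, r_c = 1.6, r_p = 2,
                        params = oxygen_params()) {
  q0 <- convective_capacity(s_bar0, v, mu, r_c, r_p, params)
  hill_dpeq_ds(s_bar0, params$p50, params$hill_n) / (k * q0)
}

test_that("frozen-coefficient decays are exact exponentials", {
  k_ci <- 5
  out <- predict_deltaS_decay(0.1, 0.6, 0.8, k_ci, 900, 0.39, 1.6, 2, 150,
                              frozen = TRUE)
  rate <- frozen_rate(k_ci, 0.6)
  expect_equal(out$delta_s, 0.1 * exp(-rate * out$x), tolerance = 1e-8)
  sig <- predict_sigmaS_decay(0.05, 0.55, 0.8, 4, 900, 0.39, 1.6, 2, 150,
                              frozen = TRUE)
  expect_equal(sig$sigma_s, 0.05 * exp(-frozen_rate(4, 0.55) * sig$x),
               tolerance = 1e-8)
})

test_that("zero initial heterogeneity stays zero and decay is monotone in
           the interaction coefficient", {
  out0 <- predict_deltaS_decay(0, 0.6, 0.8, 5, 900, 0.39, 1.6, 2, 150)
  expect_true(all(out0$delta_s == 0))
  fast <- predict_deltaS_decay(0.1, 0.6, 0.8, 2, 900, 0.39, 1.6, 2, 150)
  slow <- predict_deltaS_decay(0.1, 0.6, 0.8, 10, 900, 0.39, 1.6, 2, 150)
  expect_true(all(slow$delta_s[-1] > fast$delta_s[-1]))
  # the decay slope at the inlet is proportional to the heterogeneity
  a <- predict_sigmaS_decay(0.02, 0.6, 0.8, 4, 900, 0.39, 1.6, 2, 150)
  b <- predict_sigmaS_decay(0.04, 0.6, 0.8, 4, 900, 0.39, 1.6, 2, 150)
  da <- (a$sigma_s[2] - a$sigma_s[1]) / (a$x[2] - a$x[1])
  db <- (b$sigma_s[2] - b$sigma_s[1]) / (b$x[2] - b$x[1])
  expect_lt(da, 0)
  expect_equal(db / da, 2, tolerance = 1e-3)
})

test_that("the paired system conserves the mean saturation solution", {
  prof <- predict_deltaS_decay(0.1, 0.6, 0.8, 5, 900, 0.39, 1.6, 2, 200,
                               params = oxygen_params(alpha_eff = 1e-10))
  single <- integrate_vessel(0.6, 0.8, 900, 0.39, 1.6, 2, 200,
                             oxygen_params(alpha_eff = 1e-10),
                             n_out = nrow(prof))
  expect_equal(prof$s_bar, as.numeric(single$s), tolerance = 1e-6)
  # heterogeneity never increases under the interaction models
  expect_true(all(diff(prof$delta_s) <= 1e-12))
})

test_that("decay-rate fitting recovers known rates", {
  x <- seq(0, 200, by = 5)
  fit <- fit_decay_rate(x, exp(-x / 50))
  expect_equal(fit$rate, 0.02, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  flat <- fit_decay_rate(x, rep(2, length(x)))
  expect_equal(flat$rate, 0, tolerance = 1e-12)
  # rate fitted from the frozen model equals the analytic rate
  k_ri <- 4
  prof <- predict_sigmaS_decay(0.05, 0.55, 0.8, k_ri, 900, 0.39, 1.6, 2,
                               150, frozen = TRUE)
  fit2 <- fit_decay_rate(prof$x, prof$sigma_s)
  expect_equal(fit2$rate, frozen_rate(k_ri, 0.55), tolerance = 1e-6)
  # non-positive tail is trimmed and flagged
  y <- exp(-x / 30); y[30:41] <- 0
  fit3 <- fit_decay_rate(x, y)
  expect_true(fit3$truncated)
  expect_equal(fit3$rate, 1 / 30, tolerance = 1e-6)
})
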