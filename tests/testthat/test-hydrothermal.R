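# Two-branch hydrothermal-time model: cardinal temperatures, branch
# predictions, nested profiled fitting.

test_that("ceiling temperature solves the shifted-threshold equation", {
  p <- truth_htt()
  expect_equal(ceiling_temperature(p, psi = 0, g = 0.5), 27.2,
               tolerance = 1e-9)
  expect_equal(ceiling_temperature(p, psi = -0.2, g = 0.5), 25.2,
               tolerance = 1e-9)
  # warmer percentiles (larger g) hit their ceiling sooner
  g <- seq(0.1, 0.9, by = 0.1)
  tc <- vapply(g, function(gg) ceiling_temperature(p, 0, gg), numeric(1))
  expect_true(all(diff(tc) < 0))
  # no supra-optimal window below the percentile threshold
  expect_error(ceiling_temperature(p, psi = -0.8, g = 0.5),
               "cannot germinate")
  expect_error(ceiling_temperature(p, psi = 0.1), "<= 0")
})

test_that("ceiling identity t_c50 = t_o - psi_b50/k_T holds by construction", {
  p <- truth_htt()
  expect_identical(p$t_c50, p$t_o + (0 - p$psi_b50) / p$k_T)
  expect_true(p$t_b < p$t_o && p$t_o < p$t_c50)
})

test_that("sub-optimal predictions follow the hydrothermal relation", {
  p <- truth_htt()
  expect_equal(predict_htt_time_to_g(p, 15, 0, 0.5),
               43.9 / ((15 - 7) * 0.67), tolerance = 1e-9)
  expect_equal(predict_htt_time_to_g(p, p$t_b, 0, 0.5), Inf)
  # in water at the median ceiling: never (boundary)
  expect_equal(predict_htt_time_to_g(p, p$t_c50, 0, 0.5), Inf)
  expect_equal(predict_htt_time_to_g(p, p$t_c50 + 1, 0, 0.5), Inf)
  # GR linear in T at fixed psi and in psi at fixed T (sub branch)
  temps <- c(10, 12, 14, 16)
  gr_t <- 1 / predict_htt_time_to_g(p, temps, 0, 0.5)
  expect_equal(diff(diff(gr_t) / diff(temps)), c(0, 0), tolerance = 1e-9)
  psis <- c(0, -0.1, -0.2, -0.3)
  gr_p <- 1 / predict_htt_time_to_g(p, 15, psis, 0.5)
  expect_equal(diff(diff(gr_p) / diff(psis)), c(0, 0), tolerance = 1e-9)
})

test_that("sub-optimal branch equals the hydrotime model with theta_H = theta_HT/(T - T_b)", {
  p <- truth_htt()
  for (temp in c(11, 15, 20)) {
    ph <- ht_params(theta_H = p$theta_HT / (temp - p$t_b),
                    psi_b50 = p$psi_b50, sigma_psib = p$sigma_psib,
                    temperature = temp)
    for (g in c(0.2, 0.5, 0.8)) for (psi in c(0, -0.3)) {
      expect_equal(predict_htt_time_to_g(p, temp, psi, g),
                   predict_time_to_g(ph, psi, g), tolerance = 1e-9)
    }
    tt <- c(2, 5, 10, 20)
    expect_equal(predict_htt_fraction_at_time(p, temp, -0.2, tt),
                 predict_fraction_at_time(ph, -0.2, tt),
                 tolerance = 1e-9)
  }
})

test_that("the supra branch is continuous at the optimum and loses its shift as k_T -> 0", {
  p <- truth_htt()
  # continuity: just above the optimum the prediction approaches the
  # sub-optimal prediction at the optimum
  expect_equal(predict_htt_time_to_g(p, p$t_o + 1e-9, -0.1, 0.5),
               predict_htt_time_to_g(p, p$t_o, -0.1, 0.5),
               tolerance = 1e-6)
  # k_T -> 0: the threshold shift vanishes and the supra prediction
  # reduces to the sub-optimal predictor evaluated at the optimum rate
  p_small <- htt_params(p$theta_HT, p$t_b, p$psi_b50, p$sigma_psib,
                        t_o = p$t_o, k_T = 1e-9)
  expect_equal(predict_htt_time_to_g(p_small, 25, -0.1, 0.5),
               predict_htt_time_to_g(p, p$t_o, -0.1, 0.5),
               tolerance = 1e-6)
})

test_that("temperatures classify as sub at or below the optimum", {
  expect_identical(classify_branch(20.5, 20.5), "sub")
  expect_identical(classify_branch(28, 20.5), "supra")
  expect_identical(classify_branch(11, 20.5), "sub")
})

test_that("noiseless model data are recovered within grid resolution", {
  p <- truth_htt()
  nd <- noiseless_htt_data(p, temperatures = c(11, 15, 20, 24, 28),
                           days = 1:40)
  fit <- suppressWarnings(fit_htt(nd))
  expect_lt(abs(fit$t_b - p$t_b), 0.1 + 1e-9)
  expect_lt(abs(fit$theta_HT - p$theta_HT) / p$theta_HT, 0.02)
  expect_lt(abs(fit$psi_b50 - p$psi_b50), 0.01)
  expect_lt(abs(fit$t_o - p$t_o), 0.1 + 1e-9)
  expect_lt(abs(fit$k_T - p$k_T), 0.01 + 1e-9)
  expect_false(fit$match_failure)
  # fitted ceiling identity holds in exact arithmetic
  expect_identical(fit$t_c50, fit$t_o + (0 - fit$psi_b50) / fit$k_T)
})

test_that("single-temperature input is rejected with guidance", {
  d <- noiseless_ht_data(truth_ht20(), days = 1:20, n = 100)
  expect_error(fit_htt_suboptimal(d), "fit_ht")
  expect_error(fit_htt(d), "fit_ht")
})

test_that("supra search reports match failure under impossible tolerances", {
  p <- truth_htt()
  nd <- noiseless_htt_data(p, temperatures = c(11, 15, 20, 24, 28),
                           days = 1:40)
  sub <- suppressWarnings(fit_htt_suboptimal(nd, c(11, 15, 20)))
  sup <- fit_htt_supraoptimal(nd, sub,
                              match_tol = c(psi_b50 = 1e-12,
                                            sigma = 1e-12))
  expect_true(sup$match_failure)
  # with the declared tolerances the same search matches
  sup2 <- fit_htt_supraoptimal(nd, sub)
  expect_false(sup2$match_failure)
  expect_equal(sup2$t_o, p$t_o, tolerance = 0.011)
})

test_that("sub-optimal profiled fit matches the exhaustive grid oracle", {
  # small instance: 2 temperatures x 1 day-pair grid, <= 10 cells
  p <- truth_htt()
  days <- c(4, 8)
  g <- expand.grid(day = days, psi = c(0, -0.3),
                   temperature = c(12, 18))
  set.seed(21)
  n <- 200
  s <- rbinom(nrow(g), n,
              predict_htt_fraction_at_time(p, g$temperature, g$psi,
                                           g$day))
  d <- germination_data(data.frame(
    temperature = g$temperature, psi = g$psi, replicate = 1,
    day = g$day, germinated = s, n_seeds = n))
  fit <- suppressWarnings(
    fit_htt_suboptimal(d, t_b_grid = seq(4, 10, by = 0.5)))
  o <- grid_htt_oracle(g$temperature, g$psi, g$day, s, rep(n, nrow(g)),
                       tb_grid = seq(4, 10, by = 0.5),
                       theta_grid = seq(25, 70, by = 1),
                       a_range = c(1.2, 3.8), b_range = c(1.8, 5.8),
                       ab_step = 0.05)
  expect_lt(abs(fit$t_b - o[["tb"]]), 0.5 + 1e-9)
  expect_lt(abs(fit$theta_HT - o[["theta"]]), 1 + 1e-9)
})
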