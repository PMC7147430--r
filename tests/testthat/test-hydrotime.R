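# Per-temperature hydrotime model: prediction, normalization, profiled
# fitting.

test_that("predicted germination times invert the hydrotime relation", {
  p20 <- truth_ht20()
  expect_equal(predict_time_to_g(p20, psi = 0, g = 0.5), 4.2 / 0.49,
               tolerance = 1e-9)
  # psi exactly at the percentile threshold: never
  expect_equal(predict_time_to_g(p20, psi = p20$psi_b50, g = 0.5), Inf)
  # psi below the median threshold: never
  expect_equal(predict_time_to_g(p20, psi = -0.6, g = 0.5), Inf)
})

test_that("predicted fractions follow the threshold distribution", {
  p20 <- truth_ht20()
  # long-time limit at psi = -0.6 equals the threshold mass below psi
  expect_equal(predict_fraction_at_time(p20, -0.6, 1e9),
               0.3419, tolerance = 1e-3)
  expect_equal(predict_fraction_at_time(p20, p20$psi_b50, 1e9), 0.5,
               tolerance = 1e-6)
  # definitional consistency with predict_time_to_g: at the predicted
  # t50 the predicted fraction is exactly one half
  t50 <- predict_time_to_g(p20, 0, 0.5)
  expect_equal(predict_fraction_at_time(p20, 0, t50), 0.5)
  # monotone in t
  fr <- predict_fraction_at_time(p20, -0.2, seq(1, 40, by = 0.5))
  expect_true(all(diff(fr) >= 0))
  expect_error(predict_fraction_at_time(p20, 0, 0), "positive")
})

test_that("psi_b quantiles are the fitted normal quantiles", {
  p20 <- truth_ht20()
  expect_equal(psi_b_quantile(p20, 0.5), p20$psi_b50)
  expect_equal(psi_b_quantile(p20, 0.975), -0.49 + 0.27 * 1.959964,
               tolerance = 1e-5)
  g <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(psi_b_quantile(p20, g)) > 0))
})

test_that("hydrotime normalization maps times to the water curve", {
  p <- ht_params(theta_H = 4, psi_b50 = -0.4, sigma_psib = 0.2)
  # identity in water
  expect_equal(normalize_time(10, 0, 0.5, p), 10)
  # worked example: psi_b(g) = -0.4, psi = -0.2 halves the driving force
  expect_equal(normalize_time(10, -0.2, 0.5, p), 5)
  # algebraic identity: normalized model-predicted time at any psi
  # equals the model-predicted water time, across the percentile grid
  for (g in seq(0.1, 0.9, by = 0.1)) {
    for (psi in c(-0.1, -0.2, -0.3)) {
      tg <- predict_time_to_g(p, psi, g)
      if (is.finite(tg))
        expect_equal(normalize_time(tg, psi, g, p),
                     predict_time_to_g(p, 0, g), tolerance = 1e-9)
    }
  }
  p0 <- ht_params(theta_H = 4, psi_b50 = 0 - 0.2 * qnorm(0.7),
                  sigma_psib = 0.2)
  expect_error(normalize_time(5, -0.1, 0.7, p0), "undefined")
})

test_that("thermal time accumulates degrees above base", {
  expect_equal(thermal_time_scale(5, 20, 7.0), 65)
  expect_equal(thermal_time_scale(0, 20, 7.0), 0)
  expect_error(thermal_time_scale(5, 7, 7), "exceed")
})

test_that("normalized noiseless time courses collapse onto the water curve", {
  p <- truth_ht20()
  nd <- noiseless_ht_data(p, days = 1:40, n = 100000)
  norm <- normalized_timecourse(nd, p)
  water <- norm[norm$psi == 0, ]
  # linear interpolation of the water curve at the normalized times of
  # the reduced-psi observations
  for (psi in c(-0.2, -0.4)) {
    red <- norm[norm$psi == psi, ]
    keep <- red$normalized_day >= min(water$normalized_day) &
      red$normalized_day <= max(water$normalized_day)
    approxed <- approx(water$normalized_day, water$fraction,
                       xout = red$normalized_day[keep])$y
    expect_lt(max(abs(approxed - red$fraction[keep])), 0.02)
  }
})

test_that("fitted GR50 is linear in psi with slope 1/theta_H", {
  p <- truth_ht20()
  fit <- fit_ht(noiseless_ht_data(p, days = 1:40))
  expect_equal(fit$theta_H, p$theta_H, tolerance = 0.01)
  psis <- c(0, -0.1, -0.2, -0.3)
  gr50 <- 1 / predict_time_to_g(fit, psis, 0.5)
  slopes <- diff(gr50) / diff(psis)
  expect_equal(unname(slopes / slopes[1]), rep(1, length(slopes)),
               tolerance = 1e-9)
  expect_equal(slopes[1], 1 / fit$theta_H, tolerance = 1e-9)
})

test_that("hydrotime fit recovers generating parameters", {
  fits <- lapply(1:5, function(i) {
    sim <- simulate_experiment(sim_config(truth_ht20(),
                                          temperatures = 20,
                                          seed = 100 + i))
    fit_ht(sim)
  })
  theta <- median(vapply(fits, function(f) f$theta_H, numeric(1)))
  psi50 <- median(vapply(fits, function(f) f$psi_b50, numeric(1)))
  expect_lt(abs(theta - 4.2) / 4.2, 0.10)
  expect_lt(abs(psi50 - (-0.49)), 0.05)
  # local optimality of the profiled likelihood
  f <- fits[[1]]
  sim <- simulate_experiment(sim_config(truth_ht20(), temperatures = 20,
                                        seed = 101))
  cells <- hydrotime:::.ht_cells(sim, 20)
  prof <- function(theta)
    hydrotime:::.probit_profile_ll(cells$psi - theta / cells$t,
                                   cells$s, cells$n)
  expect_gte(prof(f$theta_H) + 1e-9, prof(f$theta_H - 0.1))
  expect_gte(prof(f$theta_H) + 1e-9, prof(f$theta_H + 0.1))
})

test_that("degenerate and invalid inputs are rejected", {
  # all psi levels germinate identically and instantly: no psi signal
  d <- germination_data(data.frame(
    temperature = 20, psi = rep(c(0, -0.2), each = 2),
    replicate = 1, day = rep(1:2, 2), germinated = 100, n_seeds = 100))
  expect_error(fit_ht(d), "identifiable")
  # single psi level
  d1 <- germination_data(data.frame(
    temperature = 20, psi = 0, replicate = 1, day = 1:3,
    germinated = c(10, 50, 80), n_seeds = 100))
  expect_error(fit_ht(d1), "water potential levels")
  # no germination anywhere
  d0 <- germination_data(data.frame(
    temperature = 20, psi = rep(c(0, -0.2), each = 3),
    replicate = 1, day = rep(1:3, 2), germinated = 0, n_seeds = 100))
  expect_error(fit_ht(d0), "no germination")
})

test_that("profiled fit matches the exhaustive grid-search oracle", {
  # small instance: 2 psi levels x 4 scoring days
  p <- ht_params(theta_H = 4, psi_b50 = -0.45, sigma_psib = 0.25)
  days <- c(3, 6, 9, 12)
  g <- expand.grid(day = days, psi = c(0, -0.3))
  set.seed(9)
  n <- 80
  s <- rbinom(8, n, pnorm((g$psi - p$theta_H / g$day - p$psi_b50) /
                            p$sigma_psib))
  d <- germination_data(data.frame(
    temperature = 20, psi = g$psi, replicate = 1, day = g$day,
    germinated = s, n_seeds = n))
  fit <- fit_ht(d)
  o <- grid_ht_oracle(g$psi, g$day, s, rep(n, 8),
                      theta_grid = seq(2, 7, by = 0.05),
                      a_range = c(0.5, 3.5), b_range = c(1.5, 7),
                      ab_step = 0.05)
  expect_lt(abs(fit$theta_H - o[["theta"]]), 0.05 + 1e-9)
})
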