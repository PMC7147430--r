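# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no stored data files.

# Reference parameter sets used as generating truth throughout the
# suite: a temperate Allium seed lot.
truth_htt <- function() htt_params(theta_HT = 43.9, t_b = 7.0,
                                   psi_b50 = -0.67, sigma_psib = 0.28,
                                   t_o = 20.5, k_T = 0.1)
truth_ht20 <- function() ht_params(theta_H = 4.2, psi_b50 = -0.49,
                                   sigma_psib = 0.27, temperature = 20)
truth_ht24 <- function() ht_params(theta_H = 3.0, psi_b50 = -0.40,
                                   sigma_psib = 0.28, temperature = 24)

# Noiseless hydrotime counts: expected cumulative fractions rounded to
# counts out of n. With large n the rounding is negligible and the data
# sit exactly on the model.
noiseless_ht_data <- function(params, psis = c(0, -0.2, -0.4, -0.6),
                              days = 1:25, n = 10000) {
  g <- expand.grid(day = days, psi = psis, KEEP.OUT.ATTRS = FALSE)
  frac <- pnorm((g$psi - params$theta_H / g$day - params$psi_b50) /
                  params$sigma_psib)
  germination_data(data.frame(
    temperature = params$temperature, psi = g$psi, replicate = 1,
    day = g$day, germinated = round(n * frac), n_seeds = n))
}

# Noiseless hydrothermal counts over a (T, psi) design.
noiseless_htt_data <- function(params, temperatures, psis = c(0, -0.2,
                                                              -0.4, -0.6),
                               days = 1:30, n = 10000) {
  g <- expand.grid(day = days, psi = psis, temperature = temperatures,
                   KEEP.OUT.ATTRS = FALSE)
  frac <- predict_htt_fraction_at_time(params, g$temperature, g$psi,
                                       g$day)
  germination_data(data.frame(
    temperature = g$temperature, psi = g$psi, replicate = 1,
    day = g$day, germinated = round(n * frac), n_seeds = n))
}

# Brute-force 2-D grid maximization of the binomial probit likelihood,
# independent of the package's fitting path. Returns the argmax over
# the (intercept, slope) grid.
grid_probit_oracle <- function(x, s, n, a_range, b_range, step = 1e-3) {
  a_grid <- seq(a_range[1], a_range[2], by = step)
  b_grid <- seq(b_range[1], b_range[2], by = step)
  ab <- expand.grid(a = a_grid, b = b_grid, KEEP.OUT.ATTRS = FALSE)
  eta <- matrix(ab$a, nrow(ab), length(x)) + outer(ab$b, x)
  p <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
  ll <- as.vector(log(p) %*% s + log1p(-p) %*% (n - s))
  i <- which.max(ll)
  c(a = ab$a[i], b = ab$b[i], ll = ll[i])
}

# Profiled grid oracle for the hydrotime fit: exhaustive search over
# (theta_H, intercept, slope).
grid_ht_oracle <- function(psi, t, s, n, theta_grid, a_range, b_range,
                           ab_step = 0.02) {
  best <- c(theta = NA_real_, ll = -Inf)
  for (theta in theta_grid) {
    o <- grid_probit_oracle(psi - theta / t, s, n, a_range, b_range,
                            step = ab_step)
    if (o["ll"] > best["ll"]) best <- c(theta = theta, ll = o[["ll"]])
  }
  best
}

# Profiled grid oracle for the sub-optimal hydrothermal fit: exhaustive
# search over (t_b, theta_HT, intercept, slope).
grid_htt_oracle <- function(temp, psi, t, s, n, tb_grid, theta_grid,
                            a_range, b_range, ab_step = 0.05) {
  best <- c(tb = NA_real_, theta = NA_real_, ll = -Inf)
  for (tb in tb_grid) for (theta in theta_grid) {
    x <- psi - theta / ((temp - tb) * t)
    o <- grid_probit_oracle(x, s, n, a_range, b_range, step = ab_step)
    if (o["ll"] > best["ll"])
      best <- c(tb = tb, theta = theta, ll = o[["ll"]])
  }
  best
}

# Write a germination CSV from raw column vectors (schema fixture).
write_raw_csv <- function(path, temperature, psi, replicate, day,
                          germinated, n_seeds) {
  df <- data.frame(temperature_C = temperature,
                   water_potential_MPa = psi, replicate = replicate,
                   day = day, germinated = germinated,
                   n_seeds = n_seeds)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
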