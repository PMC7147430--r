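# Per-temperature hydrotime model. The germination time of percentile g
# satisfies theta_H = (psi - psi_b(g)) * t_g, with psi_b(g) normally
# distributed over the seed population: psi_b(g) = psi_b50 +
# sigma_psib * probit(g). Fitting profiles theta_H: for a candidate
# theta_H every scoring cell yields the predictor x = psi - theta_H/t_g
# and a binomial probit regression of cumulative germination on x; the
# returned theta_H maximizes the profiled log-likelihood, and then
# psi_b50 = -intercept/slope, sigma_psib = 1/slope.

#' Hydrotime parameter set
#'
#' Container for hydrotime parameters, either as simulation truth or as
#' a fitted set. Times are in days, water potentials in MPa.
#'
#' @param theta_H hydrotime constant, MPa d (> 0).
#' @param psi_b50 median base water potential, MPa.
#' @param sigma_psib standard deviation of the base water potential over
#'   the seed population, MPa (> 0).
#' @param temperature the incubation temperature the parameters refer
#'   to, degrees C (optional).
#' @return an object of class `"ht_params"`.
#' @examples
#' ht_params(theta_H = 4.2, psi_b50 = -0.49, sigma_psib = 0.27,
#'           temperature = 20)
#' @export
ht_params <- function(theta_H, psi_b50, sigma_psib, temperature = NA_real_) {
  stopifnot(theta_H > 0, sigma_psib > 0)
  structure(list(temperature = temperature, theta_H = theta_H,
                 psi_b50 = psi_b50, sigma_psib = sigma_psib),
            class = "ht_params")
}

# Accept an ht_params, ht_fit, or bare list carrying the three fields.
.as_ht <- function(params) {
  stopifnot(is.list(params),
            all(c("theta_H", "psi_b50", "sigma_psib") %in% names(params)))
  params
}

# Extract observation cells at one temperature: predictor inputs for the
# repeated-probit likelihood. t_g for a cell is the scoring day itself
# (the right endpoint of the censoring interval; counts are scored
# daily). Replicate dishes share the success probability at a given
# (T, psi, day), so they are pooled into a single binomial cell — the
# likelihood is unchanged and the fit is 4x cheaper with 4 replicates.
.pool_cells <- function(d) {
  key <- paste(d$temperature, d$psi, d$day, sep = "\r")
  s <- rowsum(d$germinated, key)
  n <- rowsum(d$n_seeds, key)
  first <- !duplicated(key)
  o <- match(rownames(s), key[first])
  idx <- which(first)[o]
  list(temp = d$temperature[idx], psi = d$psi[idx], t = d$day[idx],
       s = as.vector(s), n = as.vector(n))
}

.ht_cells <- function(data, temperature) {
  d <- as.data.frame(data)
  d <- d[d$temperature == temperature, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no data at temperature ", temperature, " C; available: ",
         paste(sort(unique(as.data.frame(data)$temperature)),
               collapse = ", "), call. = FALSE)
  .pool_cells(d)
}

# Golden-section maximization of f on [lo, hi] to tolerance tol, after a
# coarse bracketing grid (guards against flat shoulders). Ties resolve
# toward the smaller argument.
.golden_max <- function(f, lo, hi, tol, n_grid = 32) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  fg <- vapply(grid, f, numeric(1))
  i <- which.max(fg)                      # which.max takes the first tie
  a <- grid[max(1, i - 1)]; b <- grid[min(n_grid, i + 1)]
  gr <- (sqrt(5) - 1) / 2
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc >= fd) {                       # ties keep the lower interval
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  x <- if (fc >= fd) c else d
  list(x = x, value = max(fc, fd))
}

#' Fit the hydrotime model at one temperature
#'
#' Profiled maximum-likelihood fit: the hydrotime constant `theta_H` is
#' searched by golden-section (after a coarse bracketing grid) on
#' `theta_range`; at each candidate every scoring cell enters a binomial
#' probit regression of cumulative germination on `psi - theta_H / t`.
#' Replicate dishes are pooled as independent binomial cells, the
#' standard repeated-probit layout for these models.
#'
#' @param data a [germination_data()] object covering at least two water
#'   potential levels at `temperature`.
#' @param temperature the temperature (degrees C) to fit; may be omitted
#'   when the data hold a single temperature.
#' @param theta_range search interval for `theta_H`, MPa d.
#' @param tol absolute tolerance of the `theta_H` search, MPa d.
#' @return an object of class `"ht_fit"`: the fitted [ht_params()]
#'   fields plus `fit` (the [fit_probit()] result at the optimum),
#'   `log_lik`, `n_cells`, `identifiable`, and the search settings.
#' @seealso [ht_table()] to fit every temperature, [predict.ht_fit()],
#'   [normalize_time()].
#' @export
fit_ht <- function(data, temperature = NULL, theta_range = c(0.05, 50),
                   tol = 1e-3) {
  d <- as.data.frame(data)
  if (is.null(temperature)) {
    temps <- unique(d$temperature)
    if (length(temps) != 1)
      stop("data hold several temperatures (",
           paste(sort(temps), collapse = ", "),
           "); pass `temperature` explicitly", call. = FALSE)
    temperature <- temps
  }
  cells <- .ht_cells(data, temperature)
  if (length(unique(cells$psi)) < 2)
    stop("hydrotime fit needs >= 2 distinct water potential levels",
         call. = FALSE)
  if (sum(cells$s) == 0)
    stop("no germination at any condition; hydrotime model unfit",
         call. = FALSE)
  frac <- cells$s / cells$n
  if (all(frac %in% c(0, 1)))
    stop("degenerate time courses (every cell fraction is 0 or 1); ",
         "theta_H is not identifiable", call. = FALSE)

  prof <- function(theta)
    .probit_profile_ll(cells$psi - theta / cells$t, cells$s, cells$n)
  opt <- .golden_max(prof, theta_range[1], theta_range[2], tol)
  theta <- opt$x
  fit <- fit_probit(cells$psi - theta / cells$t, cells$s, cells$n)
  if (fit$slope <= 0)
    stop("model misfit: germination not increasing in psi - theta_H/t ",
         "(probit slope <= 0 at the profiled optimum)", call. = FALSE)

  structure(list(
    temperature = temperature,
    theta_H = theta,
    psi_b50 = -fit$intercept / fit$slope,
    sigma_psib = 1 / fit$slope,
    fit = fit,
    log_lik = fit$log_lik,
    n_cells = fit$n_cells,
    identifiable = fit$converged,
    search = list(theta_range = theta_range, tol = tol),
    call = match.call()
  ), class = c("ht_fit", "ht_params"))
}

#' Fit the hydrotime model at every temperature
#'
#' @param data a [germination_data()] object.
#' @param ... passed to [fit_ht()].
#' @return a list of `"ht_fit"` objects, one per temperature in
#'   ascending order, with a `summary` table attribute (one row per
#'   temperature: theta_H, psi_b50, sigma_psib, R^2).
#' @export
ht_table <- function(data, ...) {
  temps <- sort(unique(as.data.frame(data)$temperature))
  fits <- lapply(temps, function(tt) fit_ht(data, tt, ...))
  names(fits) <- as.character(temps)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(temperature = f$temperature, theta_H = f$theta_H,
               psi_b50 = f$psi_b50, sigma_psib = f$sigma_psib,
               r_squared = f$fit$r_squared)))
  rownames(tab) <- NULL
  attr(fits, "summary") <- tab
  fits
}

#' Base water potential of a germination percentile
#'
#' `psi_b(g) = psi_b50 + sigma_psib * probit(g)`: the threshold water
#' potential below which fraction `g` of the population cannot
#' germinate.
#'
#' @param params hydrotime parameters ([ht_params()] or `"ht_fit"`).
#' @param g percentile fraction in (0, 1); vectorized.
#' @return water potential(s) in MPa.
#' @export
psi_b_quantile <- function(params, g) {
  p <- .as_ht(params)
  p$psi_b50 + p$sigma_psib * probit(g)
}

#' Predicted time for percentile g to germinate
#'
#' Inverts the hydrotime relation `theta_H = (psi - psi_b(g)) * t_g`.
#' When the ambient water potential does not exceed the percentile's
#' base threshold the percentile never germinates and `Inf` is returned.
#'
#' @param params hydrotime parameters.
#' @param psi ambient water potential, MPa.
#' @param g percentile fraction in (0, 1).
#' @return time in days, or `Inf` ("never").
#' @examples
#' p20 <- ht_params(4.2, -0.49, 0.27, temperature = 20)
#' predict_time_to_g(p20, psi = 0, g = 0.5)  # 4.2 / 0.49 = 8.57 d
#' @export
predict_time_to_g <- function(params, psi, g) {
  p <- .as_ht(params)
  psib <- psi_b_quantile(p, g)
  ifelse(psi > psib, p$theta_H / (psi - psib), Inf)
}

#' Predicted cumulative germination fraction at a time
#'
#' `Phi((psi - theta_H/t - psi_b50) / sigma_psib)`; non-decreasing in t
#' with limit `Phi((psi - psi_b50) / sigma_psib)` as t grows.
#'
#' @param params hydrotime parameters.
#' @param psi ambient water potential, MPa.
#' @param t time since sowing, days (> 0); vectorized.
#' @return fraction in (0, 1).
#' @export
predict_fraction_at_time <- function(params, psi, t) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  p <- .as_ht(params)
  stats::pnorm((psi - p$theta_H / t - p$psi_b50) / p$sigma_psib)
}

#' Normalize a germination time to its pure-water equivalent
#'
#' Under the hydrotime model, multiplying an observed time by
#' `1 - psi / psi_b(g)` maps it to the time the same percentile would
#' need in distilled water (psi = 0), collapsing time courses across
#' water potentials onto the water curve.
#'
#' @param t_g observed time, days.
#' @param psi ambient water potential of the observation, MPa.
#' @param g the germination fraction reached at `t_g`.
#' @param params hydrotime parameters used for `psi_b(g)`.
#' @return normalized time in days.
#' @export
normalize_time <- function(t_g, psi, g, params) {
  psib <- psi_b_quantile(.as_ht(params), g)
  if (any(psib == 0))
    stop("psi_b(g) = 0: normalization factor undefined", call. = FALSE)
  (1 - psi / psib) * t_g
}

#' Thermal time scale
#'
#' Converts clock time at a constant temperature to thermal time
#' (degree-days above the base temperature).
#'
#' @param t time, days.
#' @param temperature incubation temperature, degrees C; must exceed
#'   `t_b`.
#' @param t_b base temperature, degrees C.
#' @return thermal time, C d.
#' @export
thermal_time_scale <- function(t, temperature, t_b) {
  if (any(temperature <= t_b))
    stop("temperature must exceed the base temperature t_b", call. = FALSE)
  (temperature - t_b) * t
}

#' @export
coef.ht_fit <- function(object, ...) {
  c(theta_H = object$theta_H, psi_b50 = object$psi_b50,
    sigma_psib = object$sigma_psib)
}

#' @export
logLik.ht_fit <- function(object, ...) {
  structure(object$log_lik, df = 3L, class = "logLik")
}

#' @export
print.ht_fit <- function(x, digits = 3, ...) {
  cat("Hydrotime model fit",
      if (!is.na(x$temperature)) sprintf(" at %g C", x$temperature),
      "\n", sep = "")
  cat(sprintf("  theta_H    %8.*f MPa d\n", digits, x$theta_H))
  cat(sprintf("  psi_b(50)  %8.*f MPa\n", digits, x$psi_b50))
  cat(sprintf("  sigma_psib %8.*f MPa\n", digits, x$sigma_psib))
  cat(sprintf("  R^2 %.3f   log-likelihood %.2f   (%d cells)\n",
              x$fit$r_squared, x$log_lik, x$n_cells))
  invisible(x)
}

#' @export
summary.ht_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  predicted t50 in water: %.2f d\n",
              predict_time_to_g(object, 0, 0.5)))
  invisible(object)
}

#' Predict from a hydrotime fit
#'
#' @param object an `"ht_fit"`.
#' @param newdata data.frame with columns `psi` and either `t` (days;
#'   predicts the cumulative fraction) or `g` (fraction; predicts the
#'   time to reach it).
#' @param type `"fraction"` or `"time"`; inferred from `newdata` when
#'   omitted.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ht_fit <- function(object, newdata,
                           type = c("auto", "fraction", "time"), ...) {
  type <- match.arg(type)
  if (type == "auto") type <- if ("t" %in% names(newdata)) "fraction" else "time"
  if (type == "fraction")
    mapply(function(psi, t) predict_fraction_at_time(object, psi, t),
           newdata$psi, newdata$t)
  else
    mapply(function(psi, g) predict_time_to_g(object, psi, g),
           newdata$psi, newdata$g)
}

#' Residuals of a hydrotime fit
#'
#' Observed minus fitted cumulative germination fraction per scoring
#' cell.
#'
#' @param object an `"ht_fit"`.
#' @param data the [germination_data()] the model was fitted to.
#' @param ... unused.
#' @return data.frame of cells with observed, fitted and residual
#'   fractions.
#' @export
residuals.ht_fit <- function(object, data, ...) {
  d <- as.data.frame(data)
  d <- d[d$temperature == object$temperature, , drop = FALSE]
  obs <- d$germinated / d$n_seeds
  fitted <- predict_fraction_at_time(object, d$psi, d$day)
  data.frame(psi = d$psi, replicate = d$replicate, day = d$day,
             observed = obs, fitted = fitted, residual = obs - fitted)
}

#' Plot a hydrotime fit
#'
#' Left panel: observed cumulative germination (points, replicate means)
#' with model-predicted time courses per water potential. Right panel:
#' the fitted normal density of base water potentials.
#'
#' @param x an `"ht_fit"`.
#' @param data optional [germination_data()] to overlay observations.
#' @param ... unused.
#' @export
plot.ht_fit <- function(x, data = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  psis <- if (!is.null(data))
    sort(unique(as.data.frame(data)$psi), decreasing = TRUE)
  else c(0, -0.2, -0.4, -0.6)
  tmax <- if (!is.null(data)) max(as.data.frame(data)$day) else 30
  tt <- seq(0.1, tmax, length.out = 200)
  cols <- grDevices::hcl.colors(length(psis), "Dark 3")
  graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, 1),
                 xlab = "time (d)", ylab = "cumulative fraction",
                 main = sprintf("hydrotime fit, %g C", x$temperature))
  for (i in seq_along(psis)) {
    graphics::lines(tt, predict_fraction_at_time(x, psis[i], tt),
                    col = cols[i])
    if (!is.null(data)) {
      d <- as.data.frame(data)
      d <- d[d$temperature == x$temperature & d$psi == psis[i], ]
      m <- tapply(d$germinated / d$n_seeds, d$day, mean)
      graphics::points(as.numeric(names(m)), m, col = cols[i], pch = 16,
                       cex = 0.6)
    }
  }
  graphics::legend("bottomright", legend = sprintf("%g MPa", psis),
                   col = cols, lty = 1, cex = 0.7, bty = "n")
  pb <- seq(x$psi_b50 - 4 * x$sigma_psib, x$psi_b50 + 4 * x$sigma_psib,
            length.out = 200)
  graphics::plot(pb, stats::dnorm(pb, x$psi_b50, x$sigma_psib), type = "l",
                 xlab = "base water potential (MPa)", ylab = "density",
                 main = "psi_b distribution")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
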