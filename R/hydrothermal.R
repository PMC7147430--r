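# Pooled hydrothermal-time model across temperature and water potential.
# Sub-optimal branch (T <= T_o):
#   theta_HT = (T - T_b) * (psi - psi_b(g)) * t_g,
# fitted as a probit regression on x = psi - theta_HT / ((T - T_b) t)
# with (T_b, theta_HT) profiled (outer T_b grid, inner golden-section).
# Supra-optimal branch (T > T_o): the base water potential distribution
# shifts upward at rate K_T per degree above the optimum,
#   psi_b(g; T) = psi_b(g) + K_T (T - T_o),
# while thermal time accrues at the optimum rate, (T - T_b) held at
# (T_o - T_b). (T_o, K_T) are grid-searched so that the supra-optimal
# probit fit reproduces the sub-optimal psi_b(50) and sigma_psib within
# declared match tolerances. The ceiling temperature follows:
#   T_c(g) = T_o + (psi - psi_b(g)) / K_T.

#' Hydrothermal-time parameter set
#'
#' Container for hydrothermal-time parameters, usable as simulation
#' truth or assembled by [fit_htt()]. The supra-optimal fields may be
#' `NA` for a sub-optimal-only parameterization.
#'
#' @param theta_HT hydrothermal time constant, MPa C d (> 0).
#' @param t_b base temperature, degrees C.
#' @param psi_b50 median base water potential, MPa.
#' @param sigma_psib standard deviation of the base water potential,
#'   MPa (> 0).
#' @param t_o optimum temperature, degrees C (`NA` if unknown).
#' @param k_T upward shift rate of the base water potential per degree
#'   above `t_o`, MPa/C (> 0, `NA` if unknown).
#' @param sigma_psib_supra supra-optimal sigma; defaults to
#'   `sigma_psib`.
#' @return an object of class `"htt_params"`, including the derived
#'   ceiling temperature `t_c50 = t_o - psi_b50 / k_T` when the
#'   supra-optimal fields are present.
#' @examples
#' htt_params(theta_HT = 43.9, t_b = 7.0, psi_b50 = -0.67,
#'            sigma_psib = 0.28, t_o = 20.5, k_T = 0.1)
#' @export
htt_params <- function(theta_HT, t_b, psi_b50, sigma_psib,
                       t_o = NA_real_, k_T = NA_real_,
                       sigma_psib_supra = sigma_psib) {
  stopifnot(theta_HT > 0, sigma_psib > 0)
  if (!is.na(k_T)) stopifnot(k_T > 0)
  t_c50 <- if (!is.na(t_o) && !is.na(k_T)) t_o + (0 - psi_b50) / k_T
           else NA_real_
  structure(list(theta_HT = theta_HT, t_b = t_b, psi_b50 = psi_b50,
                 sigma_psib = sigma_psib,
                 sigma_psib_supra = sigma_psib_supra,
                 t_o = t_o, k_T = k_T, t_c50 = t_c50),
            class = "htt_params")
}

#' Classify a temperature as sub- or supra-optimal
#'
#' Temperatures at or below the optimum belong to the sub-optimal
#' branch (the boundary is assigned sub).
#'
#' @param temperature degrees C; vectorized.
#' @param t_o optimum temperature, degrees C.
#' @return character vector, `"sub"` or `"supra"`.
#' @export
classify_branch <- function(temperature, t_o) {
  ifelse(temperature <= t_o, "sub", "supra")
}

# Observation cells over a temperature subset, replicate-pooled (see
# .pool_cells).
.htt_cells <- function(data, temperatures) {
  d <- as.data.frame(data)
  d <- d[d$temperature %in% temperatures, , drop = FALSE]
  .pool_cells(d)
}

#' Fit the sub-optimal hydrothermal-time branch
#'
#' Nested profiled maximum likelihood: the base temperature `t_b` is
#' scanned on a grid (0 C to 0.5 C below the coolest tested
#' temperature, step 0.1 C); for each candidate, `theta_HT` is profiled
#' by golden-section and every scoring cell enters a binomial probit
#' regression on `psi - theta_HT / ((T - t_b) * t)`. Returns the
#' maximum-likelihood combination.
#'
#' @param data a [germination_data()] object restricted to (or
#'   containing) the sub-optimal temperatures.
#' @param temperatures the sub-optimal temperatures to use; defaults to
#'   all temperatures in `data`.
#' @param t_b_grid candidate base temperatures, degrees C.
#' @param theta_range search interval for `theta_HT`, MPa C d.
#' @param tol absolute tolerance of the inner `theta_HT` search.
#' @return a list with `theta_HT`, `t_b`, `psi_b50`, `sigma_psib`,
#'   `fit` (a [fit_probit()] result), `log_lik`, `boundary` (TRUE when
#'   the best `t_b` sits on a grid end), and the search settings.
#' @export
fit_htt_suboptimal <- function(data, temperatures = NULL,
                               t_b_grid = NULL,
                               theta_range = c(1, 500), tol = 1e-3) {
  d <- as.data.frame(data)
  if (is.null(temperatures)) temperatures <- sort(unique(d$temperature))
  if (length(temperatures) < 2)
    stop("sub-optimal fit needs >= 2 temperatures (T_b and theta_HT are ",
         "confounded at a single temperature; use fit_ht() instead)",
         call. = FALSE)
  cells <- .htt_cells(data, temperatures)
  if (length(cells$psi) == 0) stop("no data at the requested temperatures",
                                   call. = FALSE)
  if (length(unique(cells$psi)) < 2)
    stop("sub-optimal fit needs >= 2 water potential levels", call. = FALSE)
  if (sum(cells$s) == 0)
    stop("no germination at any condition", call. = FALSE)
  if (is.null(t_b_grid))
    t_b_grid <- seq(0, min(temperatures) - 0.5, by = 0.1)

  best <- list(ll = -Inf)
  for (tb in t_b_grid) {
    w <- 1 / ((cells$temp - tb) * cells$t)
    prof <- function(theta)
      .probit_profile_ll(cells$psi - theta * w, cells$s, cells$n)
    opt <- .golden_max(prof, theta_range[1], theta_range[2], tol,
                       n_grid = 16)
    if (opt$value > best$ll)
      best <- list(ll = opt$value, tb = tb, theta = opt$x)
  }
  fit <- fit_probit(cells$psi - best$theta /
                      ((cells$temp - best$tb) * cells$t),
                    cells$s, cells$n)
  if (fit$slope <= 0)
    stop("model misfit: probit slope <= 0 at the profiled optimum",
         call. = FALSE)
  boundary <- best$tb %in% range(t_b_grid)
  if (boundary)
    warning("maximum-likelihood T_b lies on the search-grid boundary (",
            best$tb, " C)", call. = FALSE)
  list(theta_HT = best$theta, t_b = best$tb,
       psi_b50 = -fit$intercept / fit$slope,
       sigma_psib = 1 / fit$slope,
       fit = fit, log_lik = fit$log_lik, boundary = boundary,
       temperatures = temperatures,
       search = list(t_b_grid = range(t_b_grid), t_b_step = 0.1,
                     theta_range = theta_range, tol = tol))
}

#' Fit the supra-optimal hydrothermal-time branch
#'
#' Holds `theta_HT`, `t_b`, `psi_b50` and `sigma_psib` at their
#' sub-optimal values and grid-searches the optimum temperature `t_o`
#' and shift rate `k_T`: for each pair every supra-optimal cell yields
#' the predictor `psi - theta_HT/((T_o - t_b) * t) - k_T * (T - t_o)`
#' (with `supra_thermal = "actual"` the thermal term uses the actual
#' `T - t_b` instead). The selected pair maximizes the supra-optimal
#' likelihood subject to the fitted `psi_b(50)` and `sigma_psib`
#' matching the sub-optimal values within `match_tol`; when no pair
#' satisfies the tolerances the best pair is returned with
#' `match_failure = TRUE`.
#'
#' @param data a [germination_data()] object containing the
#'   supra-optimal temperatures.
#' @param sub_fit result of [fit_htt_suboptimal()].
#' @param temperatures supra-optimal temperatures; defaults to all
#'   temperatures in `data` above the largest sub-optimal one.
#' @param t_o_grid candidate optimum temperatures; defaults to a 0.1 C
#'   grid between the warmest sub-optimal and the coolest supra-optimal
#'   tested temperature (the data only identify `t_o` between them).
#' @param k_T_grid candidate shift rates, MPa/C; default 0.01 to 1 step
#'   0.01.
#' @param match_tol named vector: allowed `|delta psi_b50|` and
#'   `|delta sigma|` against the sub-optimal fit, MPa.
#' @param supra_thermal `"at_topt"` (thermal time accrues at the
#'   optimum rate above `t_o`) or `"actual"`.
#' @return a list with `t_o`, `k_T`, `sigma_psib_supra`, `psi_b50_supra`,
#'   `fit`, `log_lik`, `match_failure`, and the search settings.
#' @export
fit_htt_supraoptimal <- function(data, sub_fit, temperatures = NULL,
                                 t_o_grid = NULL,
                                 k_T_grid = seq(0.01, 1, by = 0.01),
                                 match_tol = c(psi_b50 = 0.02,
                                               sigma = 0.05),
                                 supra_thermal = c("at_topt", "actual")) {
  supra_thermal <- match.arg(supra_thermal)
  d <- as.data.frame(data)
  if (is.null(temperatures))
    temperatures <- sort(unique(d$temperature[d$temperature >
                                                max(sub_fit$temperatures)]))
  if (length(temperatures) < 1)
    stop("no supra-optimal temperatures in the data", call. = FALSE)
  cells <- .htt_cells(data, temperatures)
  if (is.null(t_o_grid))
    t_o_grid <- seq(max(sub_fit$temperatures), min(temperatures), by = 0.1)

  theta <- sub_fit$theta_HT; tb <- sub_fit$t_b
  best <- list(ll = -Inf); best_ok <- list(ll = -Inf)
  for (to in t_o_grid) {
    thermal <- if (supra_thermal == "at_topt") (to - tb)
               else (cells$temp - tb)
    base_x <- cells$psi - theta / (thermal * cells$t)
    for (k in k_T_grid) {
      x <- base_x - k * (cells$temp - to)
      fit <- .probit_mle(x, cells$s, cells$n)
      if (!is.finite(fit$ll) || fit$b <= 0) next
      ll <- fit$ll
      psi50 <- -fit$a / fit$b
      sig <- 1 / fit$b
      cand <- list(ll = ll, to = to, k = k, psi50 = psi50, sig = sig)
      if (ll > best$ll) best <- cand
      ok <- abs(psi50 - sub_fit$psi_b50) <= match_tol[["psi_b50"]] &&
            abs(sig - sub_fit$sigma_psib) <= match_tol[["sigma"]]
      if (ok && ll > best_ok$ll) best_ok <- cand
    }
  }
  if (!is.finite(best$ll))
    stop("supra-optimal search failed: no (T_o, K_T) pair gave a valid ",
         "probit fit", call. = FALSE)
  match_failure <- !is.finite(best_ok$ll)
  sel <- if (match_failure) best else best_ok
  thermal <- if (supra_thermal == "at_topt") (sel$to - tb)
             else (cells$temp - tb)
  sel$fit <- fit_probit(cells$psi - theta / (thermal * cells$t) -
                          sel$k * (cells$temp - sel$to),
                        cells$s, cells$n)
  list(t_o = sel$to, k_T = sel$k, sigma_psib_supra = sel$sig,
       psi_b50_supra = sel$psi50, fit = sel$fit, log_lik = sel$ll,
       match_failure = match_failure, temperatures = temperatures,
       search = list(t_o_grid = range(t_o_grid), t_o_step = 0.1,
                     k_T_grid = range(k_T_grid), k_T_step = 0.01,
                     match_tol = match_tol, supra_thermal = supra_thermal))
}

#' Fit the full hydrothermal-time model
#'
#' Partitions the tested temperatures into sub- and supra-optimal sets
#' using the temperature with the highest mean final germination
#' percentage as the provisional optimum (ties resolve to the warmer
#' temperature; the boundary temperature is assigned sub), fits the
#' sub-optimal branch with [fit_htt_suboptimal()], then — when
#' supra-optimal temperatures exist — locates the optimum temperature
#' and the threshold shift rate with [fit_htt_supraoptimal()].
#'
#' @param data a [germination_data()] object spanning >= 2 temperatures
#'   and >= 2 water potentials.
#' @param t_o_provisional override for the provisional optimum used to
#'   partition the data (degrees C).
#' @param ... passed on to [fit_htt_suboptimal()] and
#'   [fit_htt_supraoptimal()] (`t_b_grid`, `theta_range`, `tol`,
#'   `t_o_grid`, `k_T_grid`, `match_tol`, `supra_thermal`).
#' @return an object of class `"htt_fit"` carrying the [htt_params()]
#'   fields (`theta_HT`, `t_b`, `psi_b50`, `sigma_psib`,
#'   `sigma_psib_supra`, `t_o`, `k_T`, `t_c50`), both branch fits
#'   (`fit_sub`, `fit_supra`), the temperature partition, and flags
#'   (`boundary`, `match_failure`).
#' @seealso [ceiling_temperature()], [predict.htt_fit()],
#'   [simulate.htt_fit()]
#' @export
fit_htt <- function(data, t_o_provisional = NULL, ...) {
  dots <- list(...)
  sub_args <- dots[names(dots) %in% c("t_b_grid", "theta_range", "tol")]
  supra_args <- dots[names(dots) %in% c("t_o_grid", "k_T_grid",
                                        "match_tol", "supra_thermal")]
  d <- as.data.frame(data)
  temps <- sort(unique(d$temperature))
  if (length(temps) < 2)
    stop("hydrothermal fit needs >= 2 temperatures; use fit_ht() for a ",
         "single temperature", call. = FALSE)
  if (is.null(t_o_provisional)) {
    fgp <- .fgp_by_temperature(data)
    mx <- as.numeric(names(fgp))[fgp == max(fgp)]
    t_o_provisional <- max(mx)       # ties resolve to the warmer T
  }
  sub_t <- temps[temps <= t_o_provisional]
  supra_t <- temps[temps > t_o_provisional]
  if (length(sub_t) < 2)
    stop("fewer than two sub-optimal temperatures below the provisional ",
         "optimum (", t_o_provisional, " C)", call. = FALSE)

  sub <- do.call(fit_htt_suboptimal,
                 c(list(data = data, temperatures = sub_t), sub_args))
  supra <- if (length(supra_t) > 0)
    do.call(fit_htt_supraoptimal,
            c(list(data = data, sub_fit = sub, temperatures = supra_t),
              supra_args))
  else NULL

  out <- list(
    theta_HT = sub$theta_HT, t_b = sub$t_b, psi_b50 = sub$psi_b50,
    sigma_psib = sub$sigma_psib,
    sigma_psib_supra = if (is.null(supra)) NA_real_
                       else supra$sigma_psib_supra,
    t_o = if (is.null(supra)) NA_real_ else supra$t_o,
    k_T = if (is.null(supra)) NA_real_ else supra$k_T,
    t_c50 = if (is.null(supra)) NA_real_
            else supra$t_o + (0 - sub$psi_b50) / supra$k_T,
    fit_sub = sub$fit, fit_supra = if (is.null(supra)) NULL else supra$fit,
    sub_temperatures = sub_t, supra_temperatures = supra_t,
    t_o_provisional = t_o_provisional,
    boundary = sub$boundary,
    match_failure = if (is.null(supra)) NA else supra$match_failure,
    search = list(sub = sub$search,
                  supra = if (is.null(supra)) NULL else supra$search),
    call = match.call()
  )
  class(out) <- c("htt_fit", "htt_params")
  out
}

.as_htt <- function(params) {
  stopifnot(is.list(params),
            all(c("theta_HT", "t_b", "psi_b50", "sigma_psib") %in%
                  names(params)))
  if (is.null(params$sigma_psib_supra) || is.na(params$sigma_psib_supra))
    params$sigma_psib_supra <- params$sigma_psib
  params
}

#' Ceiling temperature of a germination percentile
#'
#' The temperature at which the K_T-shifted base water potential of
#' percentile `g` reaches the ambient water potential, so its
#' germination theoretically ceases:
#' `T_c(g) = T_o + (psi - psi_b(g)) / K_T`, with `psi_b(g)` from the
#' sub-optimal threshold distribution.
#'
#' @param params hydrothermal parameters with supra-optimal fields
#'   (`"htt_fit"` or [htt_params()]).
#' @param psi ambient water potential, MPa (<= 0).
#' @param g percentile fraction in (0, 1).
#' @return ceiling temperature, degrees C.
#' @examples
#' p <- htt_params(43.9, 7.0, -0.67, 0.28, t_o = 20.5, k_T = 0.1)
#' ceiling_temperature(p, psi = 0, g = 0.5)  # 20.5 + 0.67/0.1 = 27.2
#' @export
ceiling_temperature <- function(params, psi = 0, g = 0.5) {
  p <- .as_htt(params)
  if (is.na(p$t_o) || is.na(p$k_T))
    stop("supra-optimal parameters (t_o, k_T) are absent", call. = FALSE)
  if (any(psi > 0)) stop("psi must be <= 0 MPa", call. = FALSE)
  psib <- p$psi_b50 + p$sigma_psib * probit(g)
  if (any(psi < psib))
    stop("psi below psi_b(g) = ", signif(psib, 4),
         " MPa: percentile cannot germinate at any temperature, no ",
         "supra-optimal window exists", call. = FALSE)
  p$t_o + (psi - psib) / p$k_T
}

#' Predicted germination time under the hydrothermal-time model
#'
#' Sub-optimal branch (`temperature <= t_o`, or `t_o` absent):
#' `t_g = theta_HT / ((T - t_b) (psi - psi_b(g)))`. Supra-optimal
#' branch: the threshold shifts to `psi_b(g) + k_T (T - t_o)` and
#' thermal time accrues at the optimum rate `(t_o - t_b)`. Returns
#' `Inf` ("never") below the base temperature, at or above the
#' percentile's ceiling temperature, or at or below its threshold
#' water potential.
#'
#' @param params hydrothermal parameters (`"htt_fit"` or
#'   [htt_params()]).
#' @param temperature degrees C.
#' @param psi ambient water potential, MPa.
#' @param g percentile fraction in (0, 1).
#' @return time in days, or `Inf`.
#' @export
predict_htt_time_to_g <- function(params, temperature, psi, g) {
  p <- .as_htt(params)
  psib <- p$psi_b50 + p$sigma_psib * probit(g)
  n <- max(length(temperature), length(psi), length(g))
  temperature <- rep_len(temperature, n); psi <- rep_len(psi, n)
  psib <- rep_len(psib, n)
  out <- rep(Inf, n)
  supra <- !is.na(p$t_o) & temperature > p$t_o
  shift <- ifelse(supra, p$k_T * (temperature - p$t_o), 0)
  thermal <- ifelse(supra, p$t_o - p$t_b, temperature - p$t_b)
  # the margin tolerance keeps the boundary cases (T at the ceiling,
  # psi at the threshold) at "never" despite floating-point residue
  margin <- psi - psib - shift
  ok <- temperature > p$t_b & margin > 1e-12 & thermal > 0
  out[ok] <- p$theta_HT / (thermal[ok] * margin[ok])
  out
}

#' Predicted cumulative germination fraction under the
#' hydrothermal-time model
#'
#' @param params hydrothermal parameters.
#' @param temperature degrees C.
#' @param psi ambient water potential, MPa.
#' @param t time, days (> 0); vectorized.
#' @return fraction in [0, 1); 0 below the base temperature.
#' @export
predict_htt_fraction_at_time <- function(params, temperature, psi, t) {
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  p <- .as_htt(params)
  n <- max(length(temperature), length(psi), length(t))
  temperature <- rep_len(temperature, n); psi <- rep_len(psi, n)
  t <- rep_len(t, n)
  supra <- !is.na(p$t_o) & temperature > p$t_o
  shift <- ifelse(supra, p$k_T * (temperature - p$t_o), 0)
  thermal <- ifelse(supra, p$t_o - p$t_b, temperature - p$t_b)
  sig <- ifelse(supra, p$sigma_psib_supra, p$sigma_psib)
  out <- numeric(n)
  ok <- temperature > p$t_b & thermal > 0
  out[ok] <- stats::pnorm((psi[ok] - shift[ok] -
                             p$theta_HT / (thermal[ok] * t[ok]) -
                             p$psi_b50) / sig[ok])
  out
}

#' @export
coef.htt_fit <- function(object, ...) {
  c(theta_HT = object$theta_HT, t_b = object$t_b,
    psi_b50 = object$psi_b50, sigma_psib = object$sigma_psib,
    sigma_psib_supra = object$sigma_psib_supra,
    t_o = object$t_o, k_T = object$k_T, t_c50 = object$t_c50)
}

#' @export
logLik.htt_fit <- function(object, ...) {
  ll <- object$fit_sub$log_lik +
    if (!is.null(object$fit_supra)) object$fit_supra$log_lik else 0
  structure(ll, df = if (is.null(object$fit_supra)) 4L else 6L,
            class = "logLik")
}

#' @export
print.htt_fit <- function(x, digits = 3, ...) {
  cat("Hydrothermal-time model fit\n")
  cat(sprintf("  sub-optimal  (T: %s C)\n",
              paste(x$sub_temperatures, collapse = ", ")))
  cat(sprintf("    theta_HT   %8.*f MPa C d\n", digits, x$theta_HT))
  cat(sprintf("    T_b        %8.*f C\n", digits, x$t_b))
  cat(sprintf("    psi_b(50)  %8.*f MPa\n", digits, x$psi_b50))
  cat(sprintf("    sigma_psib %8.*f MPa   R^2 %.3f\n", digits,
              x$sigma_psib, x$fit_sub$r_squared))
  if (x$boundary) cat("    [T_b on search-grid boundary]\n")
  if (!is.null(x$fit_supra)) {
    cat(sprintf("  supra-optimal (T: %s C)\n",
                paste(x$supra_temperatures, collapse = ", ")))
    cat(sprintf("    T_o        %8.*f C\n", digits, x$t_o))
    cat(sprintf("    K_T        %8.*f MPa/C\n", digits, x$k_T))
    cat(sprintf("    T_c(50)    %8.*f C\n", digits, x$t_c50))
    cat(sprintf("    sigma_psib %8.*f MPa   R^2 %.3f\n", digits,
                x$sigma_psib_supra, x$fit_supra$r_squared))
    if (isTRUE(x$match_failure))
      cat("    [no (T_o, K_T) met the branch-match tolerances]\n")
  } else {
    cat("  supra-optimal: absent (no temperatures above the provisional ",
        "optimum)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.htt_fit <- function(object, ...) {
  print(object)
  if (!is.na(object$t_c50))
    cat(sprintf("  cardinal temperatures: T_b %.1f C < T_o %.1f C < ",
                object$t_b, object$t_o),
        sprintf("T_c(50) %.1f C\n", object$t_c50), sep = "")
  invisible(object)
}

#' Predict from a hydrothermal-time fit
#'
#' @param object an `"htt_fit"` (or [htt_params()]).
#' @param newdata data.frame with columns `temperature`, `psi` and
#'   either `t` (days; predicts the cumulative fraction) or `g`
#'   (fraction; predicts the time to reach it).
#' @param type `"fraction"` or `"time"`; inferred from `newdata` when
#'   omitted.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.htt_fit <- function(object, newdata,
                            type = c("auto", "fraction", "time"), ...) {
  type <- match.arg(type)
  if (type == "auto") type <- if ("t" %in% names(newdata)) "fraction" else "time"
  if (type == "fraction")
    predict_htt_fraction_at_time(object, newdata$temperature, newdata$psi,
                                 newdata$t)
  else
    predict_htt_time_to_g(object, newdata$temperature, newdata$psi,
                          newdata$g)
}

#' Residuals of a hydrothermal-time fit
#'
#' Observed minus predicted cumulative germination fraction per scoring
#' cell, across both branches.
#'
#' @param object an `"htt_fit"`.
#' @param data the [germination_data()] the model was fitted to.
#' @param ... unused.
#' @return data.frame with one row per cell.
#' @export
residuals.htt_fit <- function(object, data, ...) {
  d <- as.data.frame(data)
  obs <- d$germinated / d$n_seeds
  fitted <- predict_htt_fraction_at_time(object, d$temperature, d$psi,
                                         d$day)
  data.frame(temperature = d$temperature, psi = d$psi, day = d$day,
             observed = obs, fitted = fitted, residual = obs - fitted)
}

#' Plot a hydrothermal-time fit
#'
#' One panel per temperature: observed replicate-mean cumulative
#' germination with the model-predicted time courses per water
#' potential.
#'
#' @param x an `"htt_fit"`.
#' @param data optional [germination_data()] to overlay observations.
#' @param ... unused.
#' @export
plot.htt_fit <- function(x, data = NULL, ...) {
  temps <- sort(unique(c(x$sub_temperatures, x$supra_temperatures)))
  nc <- ceiling(sqrt(length(temps)))
  op <- graphics::par(mfrow = c(ceiling(length(temps) / nc), nc),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  psis <- if (!is.null(data))
    sort(unique(as.data.frame(data)$psi), decreasing = TRUE)
  else c(0, -0.2, -0.4, -0.6)
  tmax <- if (!is.null(data)) max(as.data.frame(data)$day) else 40
  tt <- seq(0.1, tmax, length.out = 200)
  cols <- grDevices::hcl.colors(length(psis), "Dark 3")
  for (temp in temps) {
    graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, 1),
                   xlab = "time (d)", ylab = "cumulative fraction",
                   main = sprintf("%g C", temp))
    for (i in seq_along(psis)) {
      graphics::lines(tt, predict_htt_fraction_at_time(x, temp, psis[i],
                                                       tt), col = cols[i])
      if (!is.null(data)) {
        d <- as.data.frame(data)
        d <- d[d$temperature == temp & d$psi == psis[i], ]
        if (nrow(d)) {
          m <- tapply(d$germinated / d$n_seeds, d$day, mean)
          graphics::points(as.numeric(names(m)), m, col = cols[i],
                           pch = 16, cex = 0.5)
        }
      }
    }
  }
  invisible(x)
}
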