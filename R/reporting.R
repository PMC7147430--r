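# Machine-readable fit reports and table/figure-style outputs:
# JSON reports carrying parameters, search settings and residuals, and
# CSV-able tables of predicted and normalized time courses.

#' Write a JSON fit report
#'
#' Serializes a fitted model — parameters, search grids and tolerances,
#' goodness of fit, package version, and (when the data are supplied)
#' per-cell residuals — so a run can be audited and regenerated.
#'
#' @param fit an `"ht_fit"` or `"htt_fit"`.
#' @param path output JSON path.
#' @param data optional [germination_data()] the model was fitted to;
#'   adds per-cell residuals.
#' @param run_config optional named list of resolved run options
#'   (input paths, seeds, conventions) recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, data = NULL, run_config = NULL) {
  stopifnot(inherits(fit, "ht_fit") || inherits(fit, "htt_fit"))
  pf <- function(f) if (is.null(f)) NULL else
    list(intercept = f$intercept, slope = f$slope, log_lik = f$log_lik,
         r_squared = f$r_squared, n_cells = f$n_cells,
         converged = f$converged)
  rep <- list(
    model = if (inherits(fit, "htt_fit")) "hydrothermal_time"
            else "hydrotime",
    package_version = as.character(utils::packageVersion("hydrotime")),
    parameters = as.list(coef(fit)),
    search = fit$search,
    interpolation = "piecewise linear on cumulative fraction vs day",
    run_config = run_config
  )
  if (inherits(fit, "htt_fit")) {
    rep$fit_sub <- pf(fit$fit_sub)
    rep$fit_supra <- pf(fit$fit_supra)
    rep$sub_temperatures <- fit$sub_temperatures
    rep$supra_temperatures <- fit$supra_temperatures
    rep$flags <- list(t_b_boundary = fit$boundary,
                      match_failure = fit$match_failure)
  } else {
    rep$temperature <- fit$temperature
    rep$fit <- pf(fit$fit)
  }
  if (!is.null(data))
    rep$residuals <- residuals(fit, data)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read model parameters back from a JSON fit report
#'
#' Reconstructs an [ht_params()] or [htt_params()] object from a report
#' written by [write_fit_report()], for prediction and normalization on
#' new grids.
#'
#' @param path path to a report JSON.
#' @return an `"ht_params"` or `"htt_params"` object.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::fromJSON(path)
  p <- rep$parameters
  if (identical(rep$model, "hydrothermal_time"))
    htt_params(theta_HT = p$theta_HT, t_b = p$t_b, psi_b50 = p$psi_b50,
               sigma_psib = p$sigma_psib,
               t_o = if (is.null(p$t_o)) NA_real_ else p$t_o,
               k_T = if (is.null(p$k_T)) NA_real_ else p$k_T,
               sigma_psib_supra = if (is.null(p$sigma_psib_supra))
                 p$sigma_psib else p$sigma_psib_supra)
  else
    ht_params(theta_H = p$theta_H, psi_b50 = p$psi_b50,
              sigma_psib = p$sigma_psib,
              temperature = if (is.null(rep$temperature)) NA_real_
                            else rep$temperature)
}

#' Table of model-predicted time courses
#'
#' Evaluates the fitted model on a user grid, producing the data behind
#' predicted-time-course figures. Within each (temperature, psi) group
#' the predicted fraction is non-decreasing in day.
#'
#' @param params an `"ht_fit"`/[ht_params()] or
#'   `"htt_fit"`/[htt_params()].
#' @param water_potentials psi grid, MPa.
#' @param days day grid (> 0).
#' @param temperatures temperature grid (hydrothermal parameters only;
#'   for hydrotime parameters the fit's own temperature is used).
#' @return data.frame with columns `temperature`, `psi`, `day`,
#'   `predicted_fraction`.
#' @export
predicted_timecourse_table <- function(params,
                                       water_potentials = c(0, -0.2,
                                                            -0.4, -0.6),
                                       days = 1:30,
                                       temperatures = NULL) {
  stopifnot(all(days > 0))
  if (!is.null(params$theta_HT)) {
    if (is.null(temperatures))
      stop("temperatures must be given for hydrothermal parameters",
           call. = FALSE)
    g <- expand.grid(day = days, psi = water_potentials,
                     temperature = temperatures, KEEP.OUT.ATTRS = FALSE)
    g$predicted_fraction <- predict_htt_fraction_at_time(
      params, g$temperature, g$psi, g$day)
  } else {
    g <- expand.grid(day = days, psi = water_potentials,
                     KEEP.OUT.ATTRS = FALSE)
    g$temperature <- if (!is.null(params$temperature)) params$temperature
                     else NA_real_
    g$predicted_fraction <- mapply(
      function(psi, t) predict_fraction_at_time(params, psi, t),
      g$psi, g$day)
  }
  g[, c("temperature", "psi", "day", "predicted_fraction")]
}

#' Normalize observed time courses to the water curve
#'
#' Applies the hydrotime normalization `(1 - psi / psi_b(g)) * t` to
#' every observed point with cumulative fraction strictly inside
#' (0, 1), using the observed fraction as the percentile g. With a base
#' temperature the normalized times are additionally expressed on the
#' thermal time scale `(T - t_b) * t_norm`, putting all temperatures on
#' one axis.
#'
#' @param data a [germination_data()] object.
#' @param params hydrotime or hydrothermal parameters supplying
#'   `psi_b(g)`.
#' @param t_b optional base temperature for the thermal-time column;
#'   defaults to `params$t_b` when present.
#' @return data.frame with columns `temperature`, `psi`, `replicate`,
#'   `day`, `fraction`, `normalized_day`, and `thermal_time` when a
#'   base temperature is available. Points with fraction 0 or 1 are
#'   dropped (the probit percentile is undefined there).
#' @export
normalized_timecourse <- function(data, params, t_b = NULL) {
  d <- as.data.frame(data)
  frac <- d$germinated / d$n_seeds
  keep <- frac > 0 & frac < 1
  d <- d[keep, , drop = FALSE]; frac <- frac[keep]
  psib <- params$psi_b50 + params$sigma_psib * stats::qnorm(frac)
  if (any(psib == 0))
    stop("psi_b(g) = 0 for an observed fraction; normalization ",
         "undefined", call. = FALSE)
  out <- data.frame(temperature = d$temperature, psi = d$psi,
                    replicate = d$replicate, day = d$day,
                    fraction = frac,
                    normalized_day = (1 - d$psi / psib) * d$day)
  if (is.null(t_b) && !is.null(params$t_b)) t_b <- params$t_b
  if (!is.null(t_b) && !is.na(t_b))
    out$thermal_time <- (out$temperature - t_b) * out$normalized_day
  out
}
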