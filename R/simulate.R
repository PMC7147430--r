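# Forward simulator of interval-censored germination experiments under
# the hydrotime / hydrothermal-time threshold model, emulating the lab
# protocol: dishes of seeds scored daily for radicle protrusion,
# germinated seeds removed, a dish terminated after a run of
# consecutive zero-count scoring days.
#
# Each seed draws its base water potential psi_b ~ N(psi_b50,
# sigma_psib); its latent germination time is the deterministic
# threshold-model time (no extra timing noise), so interval censoring
# at the scoring days is the only discretization and the generator is
# the exact forward model of the fitted likelihood.

#' Simulation configuration
#'
#' Describes a germination experiment to simulate: generating truth,
#' design grid, dish size, scoring and termination rules, RNG seed.
#' Defaults mirror the laboratory protocol the models target: 4
#' replicate dishes of 100 seeds, daily scoring, termination after 3
#' consecutive days without a new germination, a 60-day cap.
#'
#' @param truth generating parameters: an [ht_params()]/`"ht_fit"` or
#'   [htt_params()]/`"htt_fit"` object.
#' @param temperatures,water_potentials the factorial design levels
#'   (degrees C; MPa, non-positive). Alternatively pass `design`.
#' @param design optional data.frame with columns `temperature` and
#'   `psi`, overriding the factorial crossing.
#' @param replicates dishes per condition.
#' @param n_seeds seeds per dish.
#' @param scoring_interval days between scorings.
#' @param termination_zero_days consecutive zero-count scorings that
#'   terminate a dish; `Inf` disables the rule (the series then ends at
#'   the last germination, which leaves the final counts uncensored).
#' @param max_days hard cap on the scoring horizon, days.
#' @param align_final_day if TRUE, all dishes are scored to the latest
#'   termination day of the experiment (tidy factorial output).
#' @param seed integer RNG seed; each dish uses an independent stream
#'   derived from it and the (condition, replicate) index, so the
#'   output is reproducible and independent of simulation order.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(truth, temperatures = c(11, 15, 20, 24, 28),
                       water_potentials = c(0, -0.2, -0.4, -0.6),
                       design = NULL, replicates = 4, n_seeds = 100,
                       scoring_interval = 1, termination_zero_days = 3,
                       max_days = 60, align_final_day = FALSE,
                       seed = 1L) {
  if (is.null(design))
    design <- expand.grid(temperature = temperatures,
                          psi = water_potentials,
                          KEEP.OUT.ATTRS = FALSE)
  stopifnot(all(c("temperature", "psi") %in% names(design)),
            all(design$psi <= 0),
            n_seeds >= 1, replicates >= 1, scoring_interval > 0,
            max_days >= scoring_interval)
  structure(list(truth = truth, design = as.data.frame(design),
                 replicates = as.integer(replicates),
                 n_seeds = as.integer(n_seeds),
                 scoring_interval = scoring_interval,
                 termination_zero_days = termination_zero_days,
                 max_days = max_days, align_final_day = align_final_day,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-dish seed below 2^31, keyed by experiment seed,
# condition index and replicate.
.dish_seed <- function(seed, cond_index, replicate) {
  as.integer((as.double(seed) * 48271 + cond_index * 1009 +
                replicate * 31) %% 2147483647)
}

# Latent germination times for one dish: deterministic threshold-model
# time given each seed's psi_b draw; Inf for seeds whose threshold the
# ambient conditions never exceed.
.latent_times <- function(truth, temperature, psi, psi_b) {
  if (inherits(truth, "htt_params") || !is.null(truth$theta_HT)) {
    p <- .as_htt(truth)
    if (temperature <= p$t_b) return(rep(Inf, length(psi_b)))
    supra <- !is.na(p$t_o) && temperature > p$t_o
    shift <- if (supra) p$k_T * (temperature - p$t_o) else 0
    thermal <- if (supra) p$t_o - p$t_b else temperature - p$t_b
    thr <- psi_b + shift
    ifelse(psi > thr, p$theta_HT / (thermal * (psi - thr)), Inf)
  } else {
    p <- .as_ht(truth)
    ifelse(psi > psi_b, p$theta_H / (psi - psi_b), Inf)
  }
}

#' Simulate one Petri dish
#'
#' Draws per-seed base water potentials, computes latent germination
#' times under the threshold model, and scores cumulative counts at the
#' configured scoring days (a seed with latent time in `(d - interval,
#' d]` is scored on day `d`). The series ends at the termination rule
#' or the day cap.
#'
#' @param config a [sim_config()].
#' @param temperature,psi the condition (must appear in the design).
#' @param replicate replicate index (1-based).
#' @return one time-course series as a data.frame with columns
#'   `temperature`, `psi`, `replicate`, `day`, `germinated`
#'   (cumulative), `n_seeds`.
#' @export
simulate_dish <- function(config, temperature, psi, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  ci <- which(config$design$temperature == temperature &
                config$design$psi == psi)
  if (length(ci) != 1)
    stop("condition (", temperature, " C, ", psi,
         " MPa) not in the design", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.dish_seed(config$seed, ci, replicate))

  p <- config$truth
  psi_b <- stats::rnorm(config$n_seeds, p$psi_b50, p$sigma_psib)
  lat <- .latent_times(p, temperature, psi, psi_b)

  dt <- config$scoring_interval
  days <- seq(dt, config$max_days, by = dt)
  cum <- vapply(days, function(d) sum(lat <= d), integer(1))

  if (is.finite(config$termination_zero_days)) {
    # the zero-count run only starts once germination has begun: a dish
    # is not abandoned before its first radicle appears
    inc <- diff(c(0L, cum))
    run <- 0L; stop_at <- length(days)
    for (i in seq_along(days)) {
      if (cum[i] == 0L) next
      run <- if (inc[i] == 0L) run + 1L else 0L
      if (run >= config$termination_zero_days) { stop_at <- i; break }
    }
    days <- days[seq_len(stop_at)]; cum <- cum[seq_len(stop_at)]
  } else {
    # uncensored mode: keep through the last germination event
    last <- max(1L, which(cum == max(cum))[1])
    days <- days[seq_len(last)]; cum <- cum[seq_len(last)]
  }
  data.frame(temperature = temperature, psi = psi,
             replicate = replicate, day = days, germinated = cum,
             n_seeds = config$n_seeds)
}

#' Simulate a full germination experiment
#'
#' One dish per (condition, replicate) of the design. Dish RNG streams
#' are independent and keyed by (condition, replicate), so the result
#' is reproducible for a given config and seed regardless of order.
#'
#' @param config a [sim_config()].
#' @return a [germination_data()] object with a `truth` attribute (the
#'   generating parameters, design and seed — the simulation manifest).
#' @examples
#' truth <- htt_params(43.9, 7.0, -0.67, 0.28, t_o = 20.5, k_T = 0.1)
#' cfg <- sim_config(truth, temperatures = c(15, 20), seed = 42)
#' sim <- simulate_experiment(cfg)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- vector("list", nrow(config$design) * config$replicates)
  k <- 0L
  for (ci in seq_len(nrow(config$design))) {
    for (r in seq_len(config$replicates)) {
      k <- k + 1L
      rows[[k]] <- simulate_dish(config, config$design$temperature[ci],
                                 config$design$psi[ci], r)
    }
  }
  out <- do.call(rbind, rows)
  if (config$align_final_day) {
    final <- max(out$day)
    dt <- config$scoring_interval
    ext <- lapply(split(out, interaction(out$temperature, out$psi,
                                         out$replicate, drop = TRUE)),
                  function(s) {
                    if (max(s$day) >= final) return(s)
                    add <- seq(max(s$day) + dt, final, by = dt)
                    if (length(add) == 0) return(s)
                    rbind(s, data.frame(
                      temperature = s$temperature[1], psi = s$psi[1],
                      replicate = s$replicate[1], day = add,
                      germinated = s$germinated[nrow(s)],
                      n_seeds = s$n_seeds[1]))
                  })
    out <- do.call(rbind, ext)
  }
  gd <- germination_data(out)
  attr(gd, "truth") <- list(
    params = unclass(config$truth)[!vapply(config$truth, is.list,
                                           logical(1))],
    design = config$design, replicates = config$replicates,
    n_seeds = config$n_seeds,
    scoring_interval = config$scoring_interval,
    termination_zero_days = config$termination_zero_days,
    max_days = config$max_days, seed = config$seed)
  gd
}

#' Write a simulated experiment with its truth manifest
#'
#' Writes the germination CSV schema plus a JSON manifest recording the
#' generating parameters and RNG seed alongside it.
#'
#' @param sim result of [simulate_experiment()].
#' @param path output CSV path; the manifest goes to
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_timecourses(sim, path)
  manifest <- attr(sim, "truth")
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate germination experiments from a fitted hydrotime model
#'
#' Parametric simulation: generates new experiments using the fitted
#' parameters as truth, over the fitted temperature and a default
#' water-potential design.
#'
#' @param object an `"ht_fit"`.
#' @param nsim number of simulated experiments.
#' @param seed RNG seed for the first experiment; subsequent ones use
#'   `seed + 1, ...`.
#' @param water_potentials,replicates,n_seeds,... design settings
#'   passed to [sim_config()].
#' @return a list of `nsim` [germination_data()] objects (a single
#'   object when `nsim = 1`).
#' @export
simulate.ht_fit <- function(object, nsim = 1, seed = 1L,
                            water_potentials = c(0, -0.2, -0.4, -0.6),
                            replicates = 4, n_seeds = 100, ...) {
  sims <- lapply(seq_len(nsim) - 1L, function(i) {
    cfg <- sim_config(object, temperatures = object$temperature,
                      water_potentials = water_potentials,
                      replicates = replicates, n_seeds = n_seeds,
                      seed = seed + i, ...)
    simulate_experiment(cfg)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Simulate germination experiments from a fitted hydrothermal-time
#' model
#'
#' @param object an `"htt_fit"`.
#' @param nsim number of simulated experiments.
#' @param seed RNG seed for the first experiment.
#' @param temperatures,water_potentials,replicates,n_seeds,... design
#'   settings passed to [sim_config()]; temperatures default to the
#'   fitted partition.
#' @return a list of `nsim` [germination_data()] objects (a single
#'   object when `nsim = 1`).
#' @export
simulate.htt_fit <- function(object, nsim = 1, seed = 1L,
                             temperatures = NULL,
                             water_potentials = c(0, -0.2, -0.4, -0.6),
                             replicates = 4, n_seeds = 100, ...) {
  if (is.null(temperatures))
    temperatures <- sort(unique(c(object$sub_temperatures,
                                  object$supra_temperatures)))
  sims <- lapply(seq_len(nsim) - 1L, function(i) {
    cfg <- sim_config(object, temperatures = temperatures,
                      water_potentials = water_potentials,
                      replicates = replicates, n_seeds = n_seeds,
                      seed = seed + i, ...)
    simulate_experiment(cfg)
  })
  if (nsim == 1) sims[[1]] else sims
}
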