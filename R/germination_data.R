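# Data model, CSV I/O and descriptive statistics for germination time
# courses. The canonical in-memory form is a long data.frame of class
# "germination_data": one row per (temperature, water potential,
# replicate, scoring day) holding the cumulative germinated count and the
# number of seeds sown.

.gd_csv_cols <- c("temperature_C", "water_potential_MPa", "replicate",
                  "day", "germinated", "n_seeds")

#' Build a validated germination data set
#'
#' Validates and classes a long table of germination counts. Counts must
#' be cumulative; use `counts = "increment"` in [read_timecourses()] for
#' lab sheets recording per-day increments (germinated seeds are removed
#' after counting, so raw sheets are often incremental).
#'
#' @param df data.frame with columns `temperature` (degrees C),
#'   `psi` (water potential, MPa, non-positive), `replicate`, `day`
#'   (days since sowing, positive), `germinated` (cumulative count) and
#'   `n_seeds` (seeds sown).
#' @return the data.frame, ordered by condition and day, with class
#'   `"germination_data"`.
#' @export
germination_data <- function(df) {
  need <- c("temperature", "psi", "replicate", "day", "germinated", "n_seeds")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  if (nrow(df) == 0) {
    warning("empty germination data set", call. = FALSE)
    class(df) <- c("germination_data", "data.frame")
    return(df)
  }
  if (any(df$psi > 0))
    stop("water potential must be <= 0 MPa", call. = FALSE)
  if (any(df$day <= 0))
    stop("scoring days must be positive", call. = FALSE)
  bad <- which(df$germinated < 0 | df$germinated > df$n_seeds)
  if (length(bad))
    stop("germinated count outside [0, n_seeds] at row ", bad[1],
         " (germinated = ", df$germinated[bad[1]],
         ", n_seeds = ", df$n_seeds[bad[1]], ")", call. = FALSE)

  key <- interaction(df$temperature, df$psi, df$replicate, drop = TRUE)
  df <- df[order(key, df$day), , drop = FALSE]
  rownames(df) <- NULL
  for (idx in split(seq_len(nrow(df)), interaction(df$temperature, df$psi,
                                                   df$replicate, drop = TRUE))) {
    d <- df$day[idx]
    if (any(diff(d) <= 0))
      stop("duplicate or non-increasing scoring days within series (",
           "T = ", df$temperature[idx[1]], ", psi = ", df$psi[idx[1]],
           ", rep = ", df$replicate[idx[1]], ")", call. = FALSE)
    g <- df$germinated[idx]
    if (any(diff(g) < 0)) {
      at <- idx[which(diff(g) < 0)[1] + 1]
      stop("cumulative germinated count decreases at row ", at,
           " (T = ", df$temperature[at], ", psi = ", df$psi[at],
           ", rep = ", df$replicate[at], ", day = ", df$day[at], ")",
           call. = FALSE)
    }
    if (length(unique(df$n_seeds[idx])) != 1)
      stop("n_seeds varies within one series", call. = FALSE)
  }
  class(df) <- c("germination_data", "data.frame")
  df
}

#' Read germination time courses from CSV
#'
#' Reads the long CSV schema
#' `temperature_C,water_potential_MPa,replicate,day,germinated,n_seeds`
#' (UTF-8, header row). The `counts` flag declares whether `germinated`
#' holds cumulative totals (default) or per-day increments; increments
#' are accumulated to cumulative form within each series.
#'
#' @param path path to a CSV file.
#' @param counts `"cumulative"` or `"increment"`.
#' @return a [germination_data()] object.
#' @export
read_timecourses <- function(path, counts = c("cumulative", "increment")) {
  counts <- match.arg(counts)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.gd_csv_cols, names(df))
  if (length(miss))
    stop("CSV schema error, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  names(df)[match(.gd_csv_cols, names(df))] <-
    c("temperature", "psi", "replicate", "day", "germinated", "n_seeds")
  if (nrow(df) > 0 && counts == "increment") {
    key <- interaction(df$temperature, df$psi, df$replicate, drop = TRUE)
    df <- df[order(key, df$day), , drop = FALSE]
    for (idx in split(seq_len(nrow(df)),
                      interaction(df$temperature, df$psi, df$replicate,
                                  drop = TRUE)))
      df$germinated[idx] <- cumsum(df$germinated[idx])
  }
  germination_data(df)
}

#' Write germination time courses to CSV
#'
#' Inverse of [read_timecourses()]: writes the documented cumulative CSV
#' schema so that a write/read round trip reproduces the data exactly.
#'
#' @param data a [germination_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(data, path) {
  stopifnot(inherits(data, "germination_data"))
  out <- data.frame(
    temperature_C = data$temperature,
    water_potential_MPa = data$psi,
    replicate = data$replicate,
    day = data$day,
    germinated = data$germinated,
    n_seeds = data$n_seeds
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.germination_data <- function(x, ...) {
  n_series <- if (nrow(x) == 0) 0L else
    length(unique(interaction(x$temperature, x$psi, x$replicate, drop = TRUE)))
  cat("Germination time courses: ", n_series, " series, ",
      nrow(x), " scoring rows\n", sep = "")
  if (nrow(x) > 0) {
    cat("  temperatures (C): ", paste(sort(unique(x$temperature)),
                                      collapse = ", "), "\n", sep = "")
    cat("  water potentials (MPa): ", paste(sort(unique(x$psi)),
                                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Split into per-series data.frames, named "T<temp>_psi<psi>_rep<rep>".
.gd_split <- function(data) {
  split(as.data.frame(data),
        interaction(data$temperature, data$psi, data$replicate, drop = TRUE))
}

#' Germination rate
#'
#' The germination rate of percentile g is the reciprocal of the time
#' taken to reach it: `GR_g = 1 / t_g` (per day).
#'
#' @param t_g time to reach the percentile, in days; must be positive.
#' @return rate in 1/day.
#' @examples
#' germination_rate(5)  # 0.2 per day
#' @export
germination_rate <- function(t_g) {
  if (any(!is.finite(t_g)) || any(t_g <= 0))
    stop("t_g must be positive and finite", call. = FALSE)
  1 / t_g
}

#' Interpolated time to reach a germination fraction
#'
#' Linear interpolation of the cumulative germination fraction against
#' the scoring day, with sowing (day 0, fraction 0) as an implicit first
#' observation. Returns the first day at which the cumulative fraction
#' reaches `g`, or `NA` when the series never reaches it.
#'
#' @param tc one time-course series: a data.frame with columns `day`,
#'   `germinated` (cumulative) and `n_seeds`.
#' @param g target fraction, strictly inside (0, 1).
#' @return interpolated time in days, or `NA_real_` if unreached.
#' @export
time_to_fraction <- function(tc, g) {
  if (length(g) != 1 || !is.finite(g) || g <= 0 || g >= 1)
    stop("g must be a single fraction strictly inside (0, 1)", call. = FALSE)
  if (nrow(tc) == 0) stop("empty time course", call. = FALSE)
  tc <- tc[order(tc$day), , drop = FALSE]
  day <- c(0, tc$day)
  frac <- c(0, tc$germinated / tc$n_seeds)
  if (max(frac) < g) return(NA_real_)
  i <- which(frac >= g)[1]
  if (frac[i] == g) return(day[i])
  # first crossing lies between i-1 and i; frac[i-1] < g <= frac[i]
  day[i - 1] + (g - frac[i - 1]) / (frac[i] - frac[i - 1]) *
    (day[i] - day[i - 1])
}

#' Final germination percentage
#'
#' 100 times the last cumulative fraction of a time course; the plateau
#' of the cumulative curve. The denominator is seeds sown.
#'
#' @param tc one time-course series (columns `day`, `germinated`,
#'   `n_seeds`).
#' @return percentage in [0, 100].
#' @export
final_germination_percentage <- function(tc) {
  if (nrow(tc) == 0) stop("empty time course", call. = FALSE)
  tc <- tc[order(tc$day), , drop = FALSE]
  100 * tc$germinated[nrow(tc)] / tc$n_seeds[nrow(tc)]
}

# Mean FGP per temperature (over psi levels and replicates); used for the
# provisional optimum-temperature partition of the hydrothermal fit.
.fgp_by_temperature <- function(data) {
  fgp <- vapply(.gd_split(data), final_germination_percentage, numeric(1))
  temp <- vapply(.gd_split(data), function(s) s$temperature[1], numeric(1))
  tapply(fgp, temp, mean)
}
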