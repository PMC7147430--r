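# Maximum-likelihood binomial probit regression used by both threshold
# models. Each observation cell is (predictor x, germinated count, seeds
# sown); the success probability is Phi(intercept + slope * x).

#' Probit transform
#'
#' The probit is the standard normal quantile function, mapping a
#' germination fraction in (0, 1) to a z-score.
#'
#' @param p numeric vector of fractions, strictly between 0 and 1.
#' @return numeric vector of probit units, `qnorm(p)`.
#' @seealso [inverse_probit()]
#' @examples
#' probit(0.5)    # 0
#' probit(0.975)  # 1.96
#' @export
probit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probit() requires fractions strictly inside (0, 1)", call. = FALSE)
  stats::qnorm(p)
}

#' Inverse probit transform
#'
#' @param z numeric vector of probit units.
#' @return fractions `pnorm(z)` in (0, 1).
#' @export
inverse_probit <- function(z) stats::pnorm(z)

# binomial family object built once; glm.fit is called many times inside
# the profiled searches and family construction is not free
.probit_family <- stats::binomial(link = "probit")

# Binomial log-likelihood of counts s out of n at success prob p.
.binom_loglik <- function(s, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(stats::dbinom(s, n, p, log = TRUE))
}

# Lean two-parameter probit MLE by Fisher scoring (the IRLS normal
# equations solved in closed 2x2 form). Equivalent to glm.fit with a
# probit link but without its per-call overhead; the profiled searches
# call this thousands of times. Convergence: log-likelihood change
# below 1e-8.
.probit_mle <- function(x, s, n, max_iter = 50L) {
  y <- s / n
  # start from unweighted least squares on shrunken empirical probits
  z0 <- stats::qnorm((s + 0.5) / (n + 1))
  mx <- mean(x); mz <- mean(z0)
  vb <- sum((x - mx) * (z0 - mz)) / sum((x - mx)^2)
  if (!is.finite(vb)) vb <- 1
  a <- mz - vb * mx; b <- vb
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- a + b * x
    p <- stats::pnorm(eta)
    phi <- stats::dnorm(eta)
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(s * log(pc) + (n - s) * log1p(-pc))
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8) {
      return(list(a = a, b = b, ll = ll, converged = TRUE, iter = it))
    }
    ll_old <- ll
    w <- n * phi^2 / (pc * (1 - pc))
    zz <- eta + (y - p) / pmax(phi, 1e-300)
    sw <- sum(w); swx <- sum(w * x); swx2 <- sum(w * x^2)
    swz <- sum(w * zz); swxz <- sum(w * x * zz)
    det <- sw * swx2 - swx^2
    if (!is.finite(det) || det <= 0) break
    a_new <- (swx2 * swz - swx * swxz) / det
    b_new <- (sw * swxz - swx * swz) / det
    if (!is.finite(a_new) || !is.finite(b_new) ||
        abs(b_new) > 1e4 || abs(a_new) > 1e6) break
    a <- a_new; b <- b_new
  }
  list(a = a, b = b, ll = ll_old, converged = FALSE, iter = max_iter)
}

#' Fit a binomial probit regression by maximum likelihood
#'
#' Fits `P(germinated) = Phi(intercept + slope * x)` to binomial count
#' cells by iteratively reweighted least squares (Fisher scoring, the
#' maximum-likelihood weighted regression for a probit link). Cells with
#' observed fraction exactly 0 or 1 contribute to the likelihood but are
#' excluded from the reported R-squared, which is the squared Pearson
#' correlation between observed and fitted values on the probit scale.
#'
#' @param x numeric predictor, one value per cell.
#' @param successes integer counts of germinated seeds per cell.
#' @param trials integer counts of seeds sown per cell.
#' @return an object of class `"probit_fit"`: a list with elements
#'   `intercept`, `slope`, `log_lik` (nats), `r_squared` (`NA` when fewer
#'   than two cells have fraction strictly inside (0, 1)), `n_cells`,
#'   `converged`, and `fitted` (fitted probabilities per cell). Complete
#'   separation is reported via `converged = FALSE`, not an error.
#' @examples
#' x <- c(-2, -1, 0, 1, 2)
#' s <- round(1000 * pnorm(0.5 * x))
#' fit_probit(x, s, rep(1000, 5))
#' @export
fit_probit <- function(x, successes, trials) {
  if (length(x) != length(successes) || length(x) != length(trials))
    stop("x, successes and trials must have equal length", call. = FALSE)
  if (any(successes < 0) || any(successes > trials))
    stop("successes must satisfy 0 <= successes <= trials", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("at least two distinct predictor values are required", call. = FALSE)

  keep <- trials > 0
  xk <- x[keep]; sk <- successes[keep]; nk <- trials[keep]

  fit <- .probit_mle(xk, sk, nk)
  fit$ll <- .binom_loglik(sk, nk, stats::pnorm(fit$a + fit$b * xk))
  if (!fit$converged) {
    # fall back to glm's IRLS (step-halving etc.) before flagging
    g <- try(suppressWarnings(stats::glm.fit(
      x = cbind(1, xk), y = sk / nk, weights = nk,
      family = .probit_family, control = stats::glm.control(maxit = 100)
    )), silent = TRUE)
    if (!inherits(g, "try-error") && all(is.finite(g$coefficients))) {
      ga <- unname(g$coefficients[1]); gb <- unname(g$coefficients[2])
      gll <- .binom_loglik(sk, nk, stats::pnorm(ga + gb * xk))
      if (gll >= fit$ll || !is.finite(fit$ll))
        fit <- list(a = ga, b = gb, ll = gll,
                    converged = isTRUE(g$converged))
    }
  }
  a <- fit$a; b <- fit$b
  converged <- isTRUE(fit$converged) && is.finite(a) && is.finite(b) &&
    abs(b) < 1e3
  p_hat <- stats::pnorm(a + b * xk)
  ll <- .binom_loglik(sk, nk, p_hat)

  # complete separation: every observed fraction is 0 or 1 and the fit
  # reproduces them essentially exactly — the ML optimum is at infinity,
  # so flag the fit rather than trusting the step-limited coefficients
  frac0 <- sk / nk
  if (b != 0 && all(frac0 %in% c(0, 1)) &&
      ll > -0.01 * length(xk)) converged <- FALSE

  # probit-scale R^2 over cells with fraction strictly in (0,1)
  frac <- sk / nk
  ok <- frac > 0 & frac < 1
  r2 <- if (sum(ok) >= 2 && stats::sd(xk[ok]) > 0) {
    obs <- stats::qnorm(frac[ok])
    pred <- a + b * xk[ok]
    if (stats::sd(pred) > 0) stats::cor(obs, pred)^2 else NA_real_
  } else NA_real_

  structure(list(
    intercept = a, slope = b, log_lik = ll, r_squared = r2,
    n_cells = length(xk), converged = converged, fitted = p_hat
  ), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Binomial probit fit (", x$n_cells, " cells)\n", sep = "")
  cat(sprintf("  intercept %.4f  slope %.4f\n", x$intercept, x$slope))
  cat(sprintf("  log-likelihood %.3f  R^2 %s%s\n", x$log_lik,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

# Profiled-likelihood helper: log-likelihood of the best probit fit for a
# given predictor vector; -Inf when the fit is degenerate. Used by the
# hydrotime and hydrothermal profiling loops.
.probit_profile_ll <- function(x, successes, trials) {
  if (any(!is.finite(x)) || length(unique(x)) < 2) return(-Inf)
  fit <- .probit_mle(x, successes, trials)
  if (!is.finite(fit$ll)) return(-Inf)
  fit$ll
}
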