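---
title: "Hydrotime and hydrothermal-time models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrotime and hydrothermal-time models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotime)
```

## The population-based threshold model

Germination of a seed lot is modelled as a population of thresholds.
Seed *i* carries a base water potential $\psi_{b,i}$ drawn from
$\mathcal{N}(\psi_{b}(50), \sigma_{\psi b}^2)$; at ambient water
potential $\psi$ (MPa) and constant temperature $T$ (°C) it germinates
once its accumulated dose reaches the population constant. At a single
temperature the dose is hydrotime, $\theta_H = (\psi - \psi_{b,i})\,
t$ (MPa d); across sub-optimal temperatures it is hydrothermal time,
$\theta_{HT} = (T - T_b)(\psi - \psi_{b,i})\, t$ (MPa °C d), with
$T_b$ the base temperature below which thermal time does not
accumulate.

Writing $g$ for the population fraction, the cumulative germination
fraction at time $t$ is

$$\Pr(\text{germinated by } t) =
  \Phi\!\left(\frac{\psi - \theta_{HT}/[(T - T_b)t] -
  \psi_b(50)}{\sigma_{\psi b}}\right),$$

a probit regression on the composite predictor
$x = \psi - \theta_{HT}/[(T - T_b)t]$. Above the optimum temperature
$T_o$ the threshold distribution is displaced upward at rate $K_T$
(MPa °C⁻¹): $\psi_b(g; T) = \psi_b(g) + K_T (T - T_o)$. The displaced
median reaches $\psi = 0$ at the ceiling temperature
$T_c(50) = T_o - \psi_b(50)/K_T$; more generally
$T_c(g) = T_o + [\psi - \psi_b(g)]/K_T$, so warmer-threshold
percentiles stop germinating first and final germination declines with
temperature above the optimum.

### The supra-optimal thermal term

Printed formulations of the supra-optimal model are ambiguous about
whether thermal time above the optimum accrues at the actual rate
$(T - T_b)$ or is held at the optimum rate $(T_o - T_b)$. This package
defaults to holding it at $(T_o - T_b)$ — the reading under which
germination *rate* stays at its optimum value just above $T_o$ and the
decline in final germination is carried entirely by the threshold
shift $K_T(T - T_o)$, which is how the two-branch model is normally
interpreted. The alternative reading is available as
`supra_thermal = "actual"` in `fit_htt()` / `fit_htt_supraoptimal()`;
the forward simulator and the predictors follow the default
convention, keeping generator and likelihood exactly matched.

## Fitting: profiled maximum-likelihood probit regression

Every scoring cell — one dish at one scoring day — contributes a
binomial observation: `germinated` cumulative successes out of
`n_seeds`, with success probability $\Phi(a + b x)$. The time entering
the predictor is the scoring day itself (the right endpoint of the
censoring interval), which matches the forward model exactly: a seed
whose latent time falls in $(d-1, d]$ is counted on day $d$, so the
cumulative count at day $d$ is binomial with probability evaluated at
$t = d$. Replicate dishes are pooled (not averaged); dishes scored on
the same day at the same condition are merged into one binomial cell,
which leaves the likelihood unchanged. Cells with zero cumulative
germination are retained — they carry information about the
thresholds. Fractions of exactly 0 or 1 enter the likelihood but are
excluded from the reported $R^2$, the squared Pearson correlation
between observed and fitted values on the probit scale; because the
$R^2$ convention of legacy probit software varies, $R^2$ is a
diagnostic here, never a fitted quantity.

The inner probit fit is Fisher scoring (IRLS) with the 2×2 normal
equations solved in closed form, converged when the log-likelihood
changes by less than $10^{-8}$; `stats::glm.fit` is the fallback when
scoring diverges. Complete separation is reported via a
`converged = FALSE` flag rather than an error. Around this core:

* **Hydrotime** (`fit_ht`): $\theta_H$ is profiled by golden-section
  search on [0.05, 50] MPa d (after a 32-point log-spaced bracketing
  grid) to an absolute tolerance of $10^{-3}$, ties resolving toward
  the smaller constant. Then $\psi_b(50) = -a/b$ and
  $\sigma_{\psi b} = 1/b$.
* **Sub-optimal HTT** (`fit_htt_suboptimal`): nested profiling — an
  outer grid on $T_b$ from 0 °C to 0.5 °C below the coolest tested
  temperature in 0.1 °C steps, an inner golden-section on
  $\theta_{HT}$ over [1, 500] MPa °C d. A maximum on the grid
  boundary raises a warning flag. A non-positive probit slope at the
  optimum (germination not increasing in the predictor) is a model
  misfit and errors.
* **Supra-optimal HTT** (`fit_htt_supraoptimal`): $\theta_{HT}$,
  $T_b$, $\psi_b(50)$, $\sigma_{\psi b}$ are held at their
  sub-optimal values; $(T_o, K_T)$ are grid-searched — $T_o$ in
  0.1 °C steps between the warmest sub-optimal and the coolest
  supra-optimal tested temperature (outside that interval the data
  cannot identify it), $K_T$ in 0.01 MPa °C⁻¹ steps over (0, 1]. The
  selected pair maximizes the supra-optimal likelihood subject to the
  re-fitted $\psi_b(50)$ and $\sigma_{\psi b}$ matching the
  sub-optimal values within $|\Delta\psi_b(50)| \le 0.02$ MPa and
  $|\Delta\sigma| \le 0.05$ MPa; if no pair qualifies, the
  unconstrained optimum is returned with `match_failure = TRUE`. The
  match tolerances are deliberately loose on $\sigma$: the two
  branches of a real fit rarely agree exactly.

The provisional sub/supra partition takes the tested temperature with
the highest mean final germination percentage as the boundary (ties to
the warmer temperature; the boundary temperature itself is assigned
sub-optimal); the final $T_o$ comes from the supra-optimal search.
With at least two temperatures the base temperature is estimated
jointly from the sub-optimal profile; a single temperature cannot
separate $T_b$ from $\theta_{HT}$, and `fit_htt` directs the user to
`fit_ht` instead.

## Normalization and thermal time

`normalize_time()` multiplies an observed time by
$1 - \psi/\psi_b(g)$, mapping it to the time the same percentile would
need in pure water; under the model this is an exact algebraic
collapse onto the water curve. `normalized_timecourse()` applies it to
every observed point, using the observed cumulative fraction as $g$
(points at fraction 0 or 1 are dropped — their probit percentile is
undefined), and adds the thermal-time axis $(T - T_b)\,t$ when a base
temperature is available, putting all temperatures on one scale.
`psi_b(g) = 0` makes the factor undefined and errors; this occurs only
for percentiles whose threshold sits exactly at pure water.

## The forward simulator

`simulate_experiment()` is the exact forward model of the fitted
likelihood. Per seed: draw $\psi_{b,i}$, shift it by
$K_T \max(0, T - T_o)$, compute the deterministic latent time
$\theta / [\text{thermal} \times (\psi - \text{threshold})]$ (no extra
timing noise — interval censoring at the scoring days is the only
discretization, which keeps parameter recovery a clean test of the
fitting machinery); accumulate counts at scoring days. The default
design mirrors the laboratory protocol the models target: 5
temperatures (11–28 °C) × 4 water potentials (0 to −0.6 MPa) × 4
replicate dishes × 100 seeds, daily scoring, a dish terminated after
3 consecutive zero-count days, a 60-day cap. Two refinements:

* the zero-count run starts only after the dish's first germination —
  a strict reading would abandon every slow dish on day 3, before
  anything had germinated, which no laboratory does;
* `termination_zero_days = Inf` disables the rule and truncates at the
  last germination event, giving uncensored final counts for
  envelope checks without scoring thousands of empty days.

Each dish draws from an independent RNG stream keyed by the experiment
seed and the (condition, replicate) index, so output is reproducible
and independent of simulation order. What the simulator does *not*
emulate: seed mortality and fungal loss, secondary dormancy induction
at supra-optimal temperatures, photoperiod effects, between-replicate
heterogeneity beyond binomial sampling, and timing noise around the
threshold model. Passing recovery tests therefore show that the
fitting machinery inverts the model faithfully under the study design
— not that real germination data satisfy the model.

## Numerical choices and degenerate inputs

Golden-section profiling assumes a unimodal profile likelihood, which
holds in practice for these models; the coarse bracketing grid guards
against flat shoulders. Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ inside likelihoods. Boundary predictions
(temperature at the ceiling, $\psi$ at the threshold) return `Inf`
("never") with a $10^{-12}$ margin against floating-point residue.
Degenerate data — no germination anywhere, or every cell at fraction
0/1 (no $\psi$ signal, $\theta_H$ unidentifiable) — error with
diagnostics. Interpolated times (`time_to_fraction`) are
piecewise-linear on cumulative fraction vs day with sowing (day 0,
fraction 0) as an implicit anchor; linear interpolation is the minimal
reproducible choice and is recorded in fit-report metadata.

## Problem sizes in the checks

Recovery checks simulate the reference factorial (4 dishes × 100
seeds per condition, daily scoring) and report medians over 20
independently seeded experiments; with ~400 seeds per condition the
median estimates sit well within ±10% for the time constants, ±1 °C
for $T_b$ and $T_o$, and ±0.05 MPa for $\psi_b(50)$. Grid-search
oracle comparisons use small instances (≤ 10 binomial cells) so the
exhaustive 3- and 4-parameter grids stay tractable.

## Known limitations

* $T_o$ is only identified between the warmest sub-optimal and
  coolest supra-optimal *tested* temperatures; with sparse temperature
  grids the reported optimum inherits that coarseness.
* The two-branch fit is sequential (sub-optimal first, supra-optimal
  conditional on it), matching standard practice; a joint fit of both
  branches would weigh the branches differently.
* Repeated cumulative counts from one dish are treated as independent
  binomials — the standard repeated-probit convention for these
  models. Standard errors from the probit fit are therefore
  optimistic; the package reports point estimates and likelihoods,
  not Wald intervals.
* No dormancy-loss or priming extensions (time-varying
  $\psi_b(50)$); no thermal-time-only model.
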