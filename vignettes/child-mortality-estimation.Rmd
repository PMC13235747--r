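---
title: "Estimating and projecting under-5, infant, and neonatal mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and projecting under-5, infant, and neonatal mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(childmort)
```

## The estimation problem

National child-mortality indicators — the under-5 mortality rate (U5MR),
infant mortality rate (IMR), and neonatal mortality rate (NMR), all
cumulative probabilities of death expressed per 1000 live births — must be
estimated for every country from heterogeneous data: continuous vital
registration (VR), sample registration (SVR), censuses, and retrospective
survey birth histories (full, FBH, or summary, SBH).  Sources disagree
systematically: each carries its own sampling error, non-sampling error,
and average bias.  `childmort` implements a full estimation and projection
pipeline for this problem: a bias-adjusted Bayesian penalized B-spline
model for the rate trends, a ratio model for neonatal mortality, additive
crisis and HIV adjustments, a weekly-cohort deaths engine, pace-of-decline
metrics, and scenario projections to 2030 — together with a synthetic-data
generator so that every stage can be tested end to end without any
external database.

## The trend model

For one country and indicator, write $f(t)$ for the unknown true rate (per
1000) at time $t$.  Observations are conceptualised as the true rate times
an error multiplier; on the log scale,

$$\log y_i = \log f(t_i) + b_{s(i)} + \varepsilon_i, \qquad
  \varepsilon_i \sim \mathcal N\!\big(0,\; v_i + \sigma^2_{s(i)}\big),$$

where $s(i)$ is the source type of observation $i$, $b_s$ is the average
systematic bias of that source type, $v_i$ is the observation's sampling
variance on the log scale (delta method from its reported rate-scale
standard error), and $\sigma^2_s$ is the source type's non-sampling
variance.  No covariates enter the mean.  The log trend is a penalized
B-spline,

$$\log f(t) = \sum_j \alpha_j B_j(t),$$

with cubic basis functions on equally spaced knots (default spacing 2.5
years) and a second-order difference penalty on the coefficients —
equivalently a random-walk prior with smoothing variance $\tau^2$.  One
source type is designated the reference (high-coverage VR by default) and
its bias is fixed at zero; this identifies the remaining biases, which get
zero-centred normal priors (SD 0.2 on the log scale).  Non-sampling SDs
get half-normal priors (scale 0.1) and $\tau^2$ a weakly informative
inverse-gamma prior.

Posterior sampling is by blocked Gibbs: the spline coefficients and the
biases are conditionally Gaussian, $\tau^2$ is conjugate inverse-gamma,
and the non-sampling SDs are updated by random-walk Metropolis on
$\log\sigma_s$.  Two chains are run by default and convergence is gated on
a split-chain potential scale reduction factor below 1.05 for the log
trend at a spread of years and for $\log\tau$; a failed gate attaches a
warning to the fit.  For validation, `b3_config()` can pin $\tau$,
$\sigma_s$, or the biases, in which case the model is a Gaussian linear
model whose posterior is available in closed form — the test suite checks
the sampler against that analytic posterior.

**Timing convention.**  An annual estimate for calendar year $t$ refers to
mid-year, $t + 0.5$, matching the decimal reference-year convention of the
observations (a survey observation is referenced to the midpoint of its
recall window).  The fitted spline is therefore evaluated at $t + 0.5$
when the annual trajectory is extracted.  Ignoring this half-year offset
biases every estimate by about half the annual rate of reduction, which is
material when precise VR data make the uncertainty band narrow.

## Extrapolation

Trajectories are extended from the last included observation to a common
reference year (2024) by declining each posterior draw log-linearly at an
equally weighted combination of that draw's own recent trend — its annual
rate of reduction over the trailing 10 years — and the global trend,
computed from the birth-weighted global rate series.  Countries whose data
reach the reference year are left untouched.  The trailing window and the
equal weights are configuration, not estimates.

## Neonatal mortality

NMR is not fitted independently.  The modelled quantity is the ratio

$$R(t) = \frac{\mathrm{NMR}(t)}{\mathrm{U5MR}(t) - \mathrm{NMR}(t)}
       = \mathbb E[R \mid \mathrm{U5MR}(t)] \times m(t),$$

an expected ratio — a global relation, here $\log R$ linear in
$\log \mathrm{U5MR}$ above a low-mortality plateau (below U5MR 10 per
1000 the ratio is held constant) — times a country multiplier $m(t)$ whose
log follows a first-order random walk centred at zero, fitted to the
country's neonatal observations.  The default curve parameters
(intercept 0.947, slope −0.306) are calibrated so the curve passes through
the published global (U5MR, NMR) pairs for 1990 and 2024;
`fit_expected_ratio()` recalibrates them from any set of (U5MR, ratio)
pairs.  With no neonatal data the multiplier is identically one and the
country inherits the expected-ratio curve.  Inverting the ratio,
$\mathrm{NMR} = \mathrm{U5MR}\, R / (1 + R)$, guarantees
$0 < \mathrm{NMR} < \mathrm{U5MR}$ in every posterior draw; no separate
extrapolation is needed because the expected ratio is evaluated on the
already-extrapolated U5MR.  IMR is fitted by the same spline machinery and
kept consistent by per-draw truncation (IMR capped at U5MR, floored at
NMR); where no infant data exist the IMR is interpolated geometrically
between NMR and U5MR.

## Crisis and HIV adjustments

Fits use crisis-free data; deaths from qualifying crisis events are added
back afterwards.  An event's total excess deaths are allocated to age
groups by its age pattern (or taken verbatim from VR where age-specific
counts were recorded), converted to an additive rate — under-5 crisis
deaths divided by live births times 1000, allocated consistently to NMR,
IMR, and U5MR — and added to every posterior draw in the event years.
The adjustment is additive, order-independent across events, and
invertible given the event table; because the age allocation is nested,
the rate ordering is preserved.  Inclusion criteria for events (minimum
excess deaths, minimum share of expected deaths) are configuration
thresholds in `filter_crisis_events()`.  HIV adjustments follow the same
additive mechanism from a per-year table.

## From rates to deaths

Death counts are computed by cohort exposure: each annual birth cohort is
split into 52 equal birth-week cohorts entering at week midpoints
$(k - 0.5)/52$; each cohort is exposed over its first five years to
piecewise-constant hazards on the age segments $[0, 28\mathrm{d})$,
$[28\mathrm{d}, 1\mathrm{y})$, $[1\mathrm{y}, 5\mathrm{y})$, derived from
that calendar year's NMR/IMR/U5MR via the conditional probabilities

$$q_1 = \frac{\mathrm{NMR}}{1000},\quad
  q_2 = 1 - \frac{1 - \mathrm{IMR}/1000}{1 - q_1},\quad
  q_3 = 1 - \frac{1 - \mathrm{U5MR}/1000}{1 - \mathrm{IMR}/1000},$$

each converted to a constant hazard $h = -\log(1 - q)/\Delta t$ on its
segment (widths $28/365.25$, $(365.25-28)/365.25$, and 4 years).  Cohorts
switch to the new year's hazards at each calendar boundary, and deaths are
allocated to the year in which they occur and the age group at death.
The constant-hazard choice makes the survival product reconstruct
$1 - \mathrm{U5MR}/1000$ exactly and the whole calculation piecewise
analytic: in a stationary regime annual under-5 deaths equal births times
U5MR/1000 to numerical precision, cohort deaths plus survivors equal the
cohort exactly, and a daily-resolution microsimulation agrees within a
fraction of a percent.  Deaths are computed per posterior draw; intervals
are percentiles across draws with live births treated as fixed, so death
uncertainty reflects rate uncertainty only.

## Metrics

The annual rate of reduction over $[t_1, t_2]$ is
$\log(\text{rate}_{t_1}/\text{rate}_{t_2})/(t_2 - t_1)$, positive for
declines and additive with duration weights.  Its uncertainty is the
distribution of per-draw ARRs.  Percent declines, neonatal shares of
under-5 mortality, and death shares are ratios of the corresponding
quantities; 90% intervals are 5th/95th percentiles throughout.

## Scenario projections

For internal consistency the rates are first decomposed into component
conditional probabilities — neonatal, post-neonatal (28 days–11 months),
and child (1–4 years) — projected per scenario, and recombined.  The four
scenarios: **constant** freezes 2024 rates; **current trends** declines
each component log-linearly at its crisis-free 2015–24 ARR (median, or the
5th/95th-percentile bounds for the slower/faster variants), with negative
ARRs clamped to zero and absorbing per-1000 floors of 0.7 (neonatal), 0.1
(post-neonatal) and 0.3 (child) — the lowest 2024 values among countries
with at least 10 000 live births, recomputable from any synthetic world
with `compute_floors()`; **sdg_target** sends countries whose
current-trends 2030 U5MR/NMR exceed 25/12 per 1000 along log-linear paths
hitting those targets exactly in 2030; **high_income** does the same with
thresholds 5.1/2.8 per 1000 for every country above them.  Where both the
NMR and U5MR targets bind, the NMR path is fixed first and the
post-neonatal and child components are scaled proportionally on the
log-survival scale so the U5MR path is met exactly while consistency is
preserved — one of several defensible reconciliations; it is isolated in
`project_rates()` and swappable.  "On track" is judged on the median
current-trends projection.  Projected deaths re-use the deaths engine with
projected births, counting deaths allocated to 2025–30 from all cohorts
alive in that window (including those born 2020–24).

## The synthetic-data generator

`sim_config()` defines a world: true log-U5MR trajectories are piecewise
log-linear with a random walk on the yearly decline (matching the spline
model's prior structure), NMR is placed by the expected-ratio curve with a
country multiplier, IMR sits between NMR and U5MR, and crises add
one-or-two-year spikes on the rate scale.  Observation series are drawn
per source type with the error hierarchy VR < SVR < census ≈ FBH < SBH in
both bias magnitude and error SDs — a deliberate placeholder ordering
reflecting the field's data-quality hierarchy, not estimates of any real
survey programme — and SBH series never cover NMR, since neonatal rates
cannot be estimated from summary birth histories.  Births follow
geometric growth from a log-normal level.  A fixed seed determines the
world completely.

What the generator does *not* emulate: recall and displacement errors
specific to real questionnaires, HIV-driven selection bias in birth
histories, subnational heterogeneity, and correlated errors across series.
Tests passing on these worlds therefore demonstrate the correctness and
calibration of the machinery under the model's own assumptions, not the
accuracy of any real country's published estimate.

## Numerical choices and problem sizes

Default MCMC settings (2 chains × 1500 iterations, 500 warmup) give 2000
saved draws; the validation studies in the test suite and acceptance
script use 100 synthetic countries at these settings, which fit
comfortably on one CPU.  Observation sampling variances are floored at
1e-8; the smoothing variance is clipped to [1e-8, 1e4]; floors and
thresholds are treated as absorbing exactly.  Ties and degenerate cases
are handled explicitly: knot spacing wider than the span gives a single
polynomial segment, zero-variance generators give exactly log-linear
paths, and a country whose rates already sit below a scenario threshold
keeps its current-trends path.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_countries = 4, seed = 11)
world <- generate_world(cfg)
dir <- tempfile()
write_dataset(world, dir)
dataset <- apply_inclusion_rules(read_dataset(dir))

fit <- b3_fit(country_observations(dataset, "C001", "U5MR"),
              b3_config(chains = 2, iter = 1500, warmup = 500, seed = 7))
summary(fit)
plot(fit)

pipeline <- run_pipeline(dataset)
rates <- aggregate_rates(lapply(pipeline, `[[`, "u5mr"),
                         lapply(pipeline, `[[`, "births"),
                         attr(pipeline, "region_map"))
render_report(rates)$rates
```

## Known limitations

The global expected-ratio curve is calibrated to two published global
pairs rather than fitted to a country-level ratio database; regional
intervals aggregate independent country draws, whereas production systems
may carry cross-country correlation; the crisis inclusion criteria and
age patterns are configuration inputs, not estimates; and reproducing any
specific country's published estimate is out of scope — it would require
the full observation database and official births series.
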