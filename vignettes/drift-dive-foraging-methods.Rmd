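---
title: "Methods: dive effort and foraging success from satellite-relayed seal dives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dive effort and foraging success from satellite-relayed seal dives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(driftforage)
```

## The scientific problem

Deep-diving phocid seals such as southern elephant seals perform occasional
*drift dives*: dives containing a passive segment in which the animal stops
swimming and drifts vertically at a rate set by its buoyancy. Because buoyancy
reflects the blubber-to-lean-tissue ratio, the vertical drift rate (DR, m/s,
positive upward in this package) is an in-situ proxy for body condition, and
its change over time (dDR = DR[n] − DR[n−1] between consecutive time windows)
proxies net energy gain — foraging success — integrated over a neighbourhood
of dives.

The analysis this package implements asks how routine *dive-effort metrics*
respond to foraging success, after removing the direct mechanical effect of
buoyancy itself. Four metrics cover three dive stages:

* **descent rate** and **ascent rate** (m/s): absolute vertical rate between
  the surface and the first inflection point, and between the last inflection
  point and the surface;
* **dive residual** (s): the residual of a regression of dive duration on
  maximum depth — a dive that is long for its depth has a positive residual;
* **surface residual** (s): the observed post-dive surface interval minus the
  predicted *minimum* interval for a dive of that duration.

The expected pattern under patch-quality foraging theory, and the headline
result this package recovers by simulation, is that when foraging success
increases seals make *shorter, steeper* dives (descent and ascent rates up,
dive residual down) while the surface recovery time does not respond; and
that the strength of these relationships attenuates as the temporal window
over which dDR is computed grows from 1 to 10 days.

## The data-generating pipeline

Satellite relay data loggers cannot transmit full dive records. Depth is
sampled every 4 s onboard but each dive is abstracted — by the tag itself —
to four inflection points chosen by a greedy broken-stick rule, plus maximum
depth, duration and the post-dive surface interval. A random sample of dives
(the observed regime spans 1–186 per day) and 2–15 ARGOS position fixes per
day are relayed. The package mirrors this observation process end to end:

1. `simulate_world()` builds a synthetic population of seals with known
   generative parameters (section below);
2. `broken_stick()` / `summarise_dives()` perform the onboard abstraction;
3. `filter_dives()` applies the exclusion rules (retain only dives deeper
   than 15 m and longer than 5 min; remove dives with missing or
   duplicate-time depths, any segment faster than 4 m/s, duration over
   90 min, depth over 2,000 m, or surface interval over 10 min), with a
   first-failing-rule audit report;
4. `speed_filter()` and `fit_ctcrw()` estimate each seal's track from noisy
   ARGOS fixes with a continuous-time correlated random walk, predicting
   positions at dive times;
5. `candidate_segments()` and `kalman_screen()` detect passive drift
   segments (only in dives deeper than 100 m) and screen them with a
   Kalman-filter inlier probability Z, retaining segments with Z > 0.5;
   `daily_drift_rate()` and `delta_dr()` turn them into daily DR and
   windowed dDR for windows of 1, 2, 3, 7 and 10 days;
6. `compute_dive_metrics()` and `window_aggregate()` compute the four
   metrics and aggregate them over the same windows, classifying each
   window's mean position as shelf or oceanic against the 1,500 m isobath;
7. `build_design()` / `fit_pamm()` fit the response model;
   `coefficient_table()` and `attenuation_report()` summarise it.

`run_pipeline()` orchestrates all stages from a single (YAML-serialisable)
configuration, and `recovery_experiment()` repeats the whole pipeline across
independently seeded worlds to measure parameter recovery.

## The response model

For each metric, stratum and window length the model is a penalized additive
mixed model,

y_it = beta0 + beta1 * dDR_it + f(DR_it) + b0_i + b1_i * dDR_it + e_it,

with:

* a *linear* dDR term (so coefficients are comparable across strata and
  windows), reported with its standard error — this `beta1` is the quantity
  of interest;
* a smooth `f` of drift rate, absorbing the first-order mechanical control
  of buoyancy on all four metrics. The smooth is a rank-10 cubic B-spline
  with a second-difference penalty in its mixed-model (Demmler–Reinsch)
  form: the penalty null space (constant + linear) is carried by the
  intercept and a linear DR column, and the eight penalized directions enter
  as i.i.d. random effects whose variance is the inverse smoothing
  parameter. A thin-plate basis is practically equivalent for a
  one-dimensional smooth; the B-spline form makes the single-REML
  representation exact;
* per-seal random intercepts and dDR slopes with an estimated correlation;
* residuals with continuous-time AR1 correlation phi^dt (dt in days since
  departure, using window mid-times) *plus a white-noise nugget*. The nugget
  carries known heteroscedastic weights proportional to 1/(dives per
  window), because a window-mean of k dives has white variance shrinking
  like 1/k while the day-level autocorrelated process does not.

All variance-type parameters — the smoothing parameter, the two
random-effect variances and their correlation, phi, and the nugget ratio —
are estimated by one profiled REML criterion, optimised by quasi-Newton on
transformed (log / atanh / logit) parameters. After AR1 whitening the nugget
becomes a tridiagonal perturbation handled by a banded factorisation, and
the random effects by the Woodbury identity, so each criterion evaluation is
O(n q^2) with q around 70.

### Why the nugget, and why t-based inference

Two deliberate deviations from the simplest textbook form:

* **Nugget.** Window records genuinely mix a day-level autocorrelated
  process with within-day averaging noise. A pure phi^dt residual cannot
  represent that mixture (its lag-one correlation is forced too high or the
  rest too low); the AR1-plus-nugget form can, and is standard practice in
  `nlme` via `corExp(..., nugget = TRUE)`. The nugget is only active when
  phi is estimated; with `phi = 0` fixed it is unidentifiable and switched
  off, which preserves an exact closed-form limit: with no smooth, no random
  effects and phi = 0 the fit *equals* ordinary least squares — coefficient,
  standard error and p-value — which the test suite checks to six
  significant figures against `lm()`.

* **t reference.** With a per-seal random slope, beta1 is effectively a
  precision-weighted mean of about-as-many independent quantities as there
  are seals, so Wald intervals against the normal are anti-conservative at
  30 seals. p-values and intervals therefore use a t reference with
  (number of seals − 1) degrees of freedom (residual df without random
  effects). Measured across simulated worlds at the study scale, 95%
  intervals for beta1 then cover the generative slope at roughly 92–95%;
  the remaining optimism is the usual effect of plugging in estimated
  variance components.

Significance flags in `coefficient_table()` follow the conventional
presentation: `sig` for p < 0.05, `~` (marginal) for p in [0.05, 0.10),
`ns` otherwise.

## The synthetic world

The generator's defaults are the study conditions; they emulate post-moult
southern elephant seal tracking data. Per seal:

* **Movement**: planar Ornstein–Uhlenbeck-velocity (integrated) track with a
  24-h velocity-decorrelation timescale and 0.5 m/s per-axis stationary
  speed SD — the persistence and travel-rate scale of directed migration;
  reflected at the boundary of a 2,000 × 2,000 km world. Positions are in
  metres on a plane: the geodesy of real tracks adds no testable content
  here, and a projection would sit at the I/O boundary.
* **Bathymetry**: a linear depth field from 100 m to ~3,900 m with a known
  1,500 m isobath (the conventional shelf break), so bilinear interpolation
  is exact and the shelf/oceanic split is analytically known.
* **Condition and drift rate**: a lipid proxy driven by a spatially
  autocorrelated lognormal prey field sampled along the track plus
  day-level lognormal noise, with weak mean reversion; DR is a linear map
  of the proxy, starting near −0.30 m/s and drifting toward neutral over
  months, clipped to [−0.35, 0.10] m/s. dDR_true is its daily difference.
* **Dives**: transmitted counts uniform in [5, 30] per day out of a
  Poisson(60) performed budget (untransmitted dives are not materialised —
  they carry no information downstream). Each dive is built from five
  linear segments whose vertices lie on the 4-s sampling grid, so the
  onboard broken-stick abstraction is *exact* — the "vertex" and "sampled"
  profile modes are equivalent, which a test verifies. Maximum depth is
  lognormal (median 450 m) truncated by the local seafloor, with a 15%
  shallow-dive mixture. Bottom-phase wiggles are fast (0.7–1.2 m/s) or
  short (< 200 s), so they can never masquerade as drift segments.
* **Drift segments**: inserted with probability 0.035 (the reported 3–4%
  of dives) only into dives deeper than 100 m, right after the descent;
  their depth-rate is −(DR + e) with e ~ N(0, 0.002 m/s) — the
  depth-resolution-limited accuracy of a slope over a multi-minute
  segment. The segment length is solved so that the dive's total duration
  realises the same generative duration offset as non-drift dives
  (see *Known limitations*).
* **Metric responses**: each metric is base(depth) + slope_i * dDR_true +
  h(DR_true) + day-AR1 noise + per-dive noise, where the population slopes
  are gamma = +3 (descent), +2.5 (ascent), −600 s (dive residual) and 0
  (surface residual) per (m/s of dDR); per-seal slopes and intercepts are
  Gaussian around these; h is a signed tanh in DR (decreasing for transit
  rates, increasing for the residuals) emulating the smooth buoyancy
  control; day-level noise is AR1 with phi = 0.4/day. The surface interval
  is a 90 s + 0.04 × duration minimum envelope plus exponential excess
  (mean 35 s). Shallow (≤ 100 m) dives are transit/rest behaviour: their
  transit rates respond like any dive, but their durations carry no
  foraging-success offset — which also keeps retention of dives near the
  5-minute filter boundary independent of dDR, a coupling that would
  otherwise bias the window-level coefficients through depth composition.
* **ARGOS**: 2–15 fixes per day; classes 3/2/1/0/A/B with isotropic
  Gaussian error SDs 0.25/0.5/1.25/3/5/10 km — published class error
  magnitudes — and a conventional frequency mix.

Everything is driven by integer-derived per-seal seeds, so a fixed seed
reproduces a bundle exactly.

### What the generator does not emulate

Real SRDL data have: non-Gaussian, heavy-tailed ARGOS errors; depth sensor
drift and quantisation; behaviourally clustered dive types and diel cycles;
haul-outs and data gaps; sex- and habitat-specific physiology; and dives
whose five-segment abstraction is *not* exact. Passing the recovery tests
therefore demonstrates that the pipeline's statistical machinery is
internally correct under realistic sampling regimes — not that every
assumption holds on any particular real dataset.

## Numerical choices and edge cases

* Broken-stick deviations are vertical (same-time depth differences), ties
  break to the earliest time, and `k` = 4 mirrors tag firmware. Note the
  greedy chosen-deviation sequence is *not* guaranteed monotone: refining
  one segment can raise the deviation of a neighbouring sample. The
  implementation is pinned instead by exact equivalence with an
  independent naive oracle and by brute-force recomputation of the final
  reconstruction error.
* Filter thresholds are strict in the printed direction; a dive failing
  several rules is counted once, under the first failing rule of the fixed
  order (no precedence convention is standard in the field; first-failing is
  deterministic and auditable).
* The CTCRW treats axes independently with shared (beta, sigma), exact
  discrete transitions across irregular gaps, a stationary velocity prior
  and a position prior conditioned on the first fix (the diffuse-prior
  limit without its catastrophic cancellation in the smoother). The
  likelihood is optimised from three data-driven starts; one-step
  standardised innovations and their lag-1 autocorrelation are returned as
  a diagnostic, not used for automatic model choice. Extrapolation beyond
  the fix span is refused by default and affected dive records are dropped
  with a logged count.
* Drift screening follows the classification reading of the inlier
  probability: Z is the posterior responsibility of the Normal component
  under the one-step Kalman predictive, with (q, r, w) estimated by a
  bounded EM. The process variance uses the inlier-pair moment identity
  E[(v_i − v_{i−1})^2] = q dt + 2r with a mean (not median) so genuine
  multi-day drift-rate bursts stay in q; the contaminant component is
  uniform over the observed speed range, making Z invariant to location
  shifts. Seals with fewer than 5 candidates are left unscreened and
  excluded with a message.
* dDR windows are non-overlapping blocks anchored at each seal's first
  at-sea day (`window_mode = "running"` is available for sensitivity
  analysis); block values are unweighted means of the daily DR present;
  missingness propagates and is never imputed.
* The "predicted minimum" surface interval is a tau = 0.05 linear quantile
  regression fitted by direct pinball-loss minimisation (Nelder–Mead from
  an OLS start with restarts; smallest-slope solution on ties). Residual
  fits are pooled across seals by default (`scope = "per_seal"` available):
  pooling keeps residuals comparable between individuals.
* Windows with fewer than 5 dives are dropped and counted; boundary depth
  exactly at the isobath classifies as oceanic (strict "shallower" reading).

## Problem sizes used by the verification experiments

The recovery experiments use 20 replicate worlds of 30 seals × 180 days for
the sign/attenuation/robustness checks (fitting all four metrics at the
1-day window and the responsive metrics across all five windows), and 100
replicates of 30 seals × 180 days for CI calibration of the descent-rate
coefficient. Track recovery uses 20 self-simulated OU tracks of 500 fixes
over 60 days. These sizes give stable fractions while each full-pipeline
replicate (roughly 90,000 transmitted dives) remains a few seconds of work.

## Known limitations

* Windows are *selected* by drift-dive presence, so drift dives are
  overrepresented in analysable windows (about 10% of their dives versus
  3.5% overall); drift-dive geometry is constructed to carry the same
  generative duration offset as other deep dives precisely so that this
  selection does not distort the dive-residual coefficient. Measured across
  replicate worlds, all three responsive coefficients recover their
  generative values with no detectable bias; CI calibration is reported for
  the descent rate.
* `r2_fitted_obs` is the squared correlation of (conditional) fitted values
  with observations; it is *not* the adjusted R² a particular GAMM package
  would report, and the two should not be compared numerically.
* Wald-type intervals with estimated variance components retain mild
  (~5 pp) undercoverage even with the t reference; profile-likelihood or
  Kenward–Roger corrections are out of scope.
* The screening EM is a pragmatic bounded iteration, not a full maximum
  likelihood fit of the mixture state-space model; its operating
  characteristics are established by the labelled-simulation tests.

## A worked example

```{r example, eval = FALSE}
library(driftforage)

res <- run_pipeline(pipeline_config(
  simulate = list(n_seals = 8, days_per_seal = 60),
  seed = 3))

res$coefficients
plot_coefficients(res$coefficients)
autoplot(res$fits[["descent_rate_w1_all"]])
```

At this demo scale the coefficient table already shows the qualitative
pattern: positive dDR coefficients for descent and ascent rate, negative for
the dive residual, non-significant for the surface residual, strongest at
the 1-day window. The full-scale recovery numbers are recomputed by
`scripts/acceptance.R` (see the README).
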