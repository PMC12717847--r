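# driftforage

Linking dive-effort metrics of deep-diving seals to an in-situ
foraging-success proxy: the windowed change in drift rate.

Elephant seals perform occasional *drift dives* — dives with a passive
segment in which the animal drifts vertically at a rate set by its buoyancy.
The drift rate (DR, m/s, positive upward) tracks body condition, and its
change between consecutive time windows (dDR = DR[n] − DR[n−1]) proxies net
energy gain. This package provides a complete, tested pipeline from
satellite-relay data logger (SRDL) style inputs to fitted response models:

* a **synthetic seal simulator** with known generative parameters (movement,
  bathymetry, condition trajectories, drift dives, transmitted-dive and
  ARGOS sampling regimes), so every downstream stage is testable without any
  data download;
* **broken-stick abstraction** of 4-s dive profiles to the 4 inflection
  points tags transmit, with an exhaustive-search oracle in the tests;
* the **dive exclusion rules** (depth > 15 m, duration > 5 min, no
  missing/duplicate depths, segment rates ≤ 4 m/s, duration ≤ 90 min, depth
  ≤ 2,000 m, surface interval ≤ 10 min) with an auditable per-rule report;
* a **continuous-time correlated random walk** state-space model (Kalman
  filter + RTS smoother, Rcpp) for ARGOS tracks with a 4 m/s speed
  pre-filter, predicting positions with uncertainty at dive times;
* **drift-segment screening** via a Kalman-filter inlier probability
  (retain Z > 0.5), daily drift rates, and windowed dDR over 1/2/3/7/10-day
  blocks;
* the four **dive metrics** (descent rate, ascent rate, dive residual,
  surface residual — the latter against a tau = 0.05 quantile-regression
  minimum envelope), window aggregation, and shelf/oceanic classification
  at the 1,500 m isobath;
* a **penalized additive mixed model** fitted by a single REML criterion:

  `metric ~ beta1 * dDR + s(DR) + (1 + dDR | seal)`, residuals
  continuous-AR1 (phi^dt) plus a white-noise nugget —

  i.e. a linear foraging-success effect, a penalized spline absorbing the
  mechanical buoyancy effect, per-seal random intercepts and slopes, and
  serially correlated errors, with broom-style `tidy()`/`glance()` and
  `autoplot()` methods.

Everything is tibble-in / tibble-out and pipes end to end;
`run_pipeline()` orchestrates all stages from one (YAML-serialisable)
configuration and `recovery_experiment()` measures parameter recovery
across replicate simulated worlds.

## Worked example

```r
library(driftforage)

res <- run_pipeline(pipeline_config(
  simulate = list(n_seals = 8, days_per_seal = 60),
  seed = 3))

res$coefficients |> dplyr::filter(window_days == 1)
#>   metric           window_days   beta1      se        p flag
#> 1 descent_rate               1    3.03   0.442 0.000479 sig
#> 2 ascent_rate                1    2.49   0.408 0.000881 sig
#> 3 dive_residual              1 -819.   226.    0.0111   sig
#> 4 surface_residual           1   34.1   87.0   0.709    ns
```

Each row is the fitted linear dDR coefficient for one metric at the 1-day
window: even at this small demo scale the headline pattern appears —
transit rates respond *positively* to foraging success (seals descend and
ascend faster; generative values 3 and 2.5), the dive residual responds
*negatively* (shorter dives for their depth; generative −600 s per m/s),
and the surface residual does not respond (generative 0). `flag` marks
Wald-t significance at 0.05 (`~` = marginal, p in [0.05, 0.10)). Across
windows of 1, 2, 3, 7 and 10 days the coefficients shrink toward zero
(`attenuation_report()` summarises this with a Kendall tau per metric), and

```r
autoplot(res$fits[["descent_rate_w1_all"]])   # linear effect + DR smooth
plot_coefficients(res$coefficients)           # forest plot across windows
```

visualise the fits. See the methods vignette
(`vignettes/drift-dive-foraging-methods.Rmd`) for the model, the generator,
and every numerical convention.

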