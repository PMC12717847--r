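#' Simulation configuration for the synthetic seal world
#'
#' Bundles every generative parameter of the simulator: sampling regimes of the
#' satellite relay data logger (transmitted dive counts, ARGOS fix counts and
#' error classes, 4-s depth sampling), the body-condition process that drives
#' drift rate, the per-metric generative linear effects of foraging success
#' (`gamma`, in metric units per m/s of drift-rate change), smooth buoyancy
#' effects, per-seal random intercepts/slopes, day-level AR1 noise, and the
#' movement model. Defaults reflect the observed tag regimes (2-15 ARGOS fixes
#' per day, transmitted dive counts within the reported 1-186 range, ~3-4% of
#' dives carrying a passive drift segment) and post-moult southern elephant
#' seal biology (drift rates from about -0.35 m/s toward neutral over months).
#'
#' @param n_seals Number of seals.
#' @param days_per_seal Track length in days.
#' @param dives_per_day_mean Mean number of dives performed per day (Poisson);
#'   only a transmitted random sample is materialised.
#' @param transmitted_dives_range Integer range `[min, max]` of dives
#'   transmitted per day (uniform); must lie within `[1, 186]`.
#' @param argos_fixes_per_day_range Integer range of ARGOS fixes per day;
#'   must lie within `[1, 50]` (default matches the observed 2-15).
#' @param drift_dive_prob Probability that a dive deeper than 100 m carries a
#'   passive drift segment.
#' @param sampling_interval Depth sampling interval in seconds (tag firmware:
#'   4 s). All dive vertex times fall on this grid.
#' @param gamma Named list of generative linear coefficients of the windowed
#'   drift-rate change on each metric: `descent`, `ascent` (m/s per m/s),
#'   `dive_residual`, `surface_residual` (s per m/s).
#' @param re_slope_sd,re_intercept_sd Named lists: per-seal SDs of the random
#'   slope on the foraging-success effect and of the random intercept.
#' @param noise_sds Named list of per-dive observation noise SDs.
#' @param day_noise_sd Named list of day-level AR1 noise SDs (shared by all
#'   dives within a seal-day).
#' @param phi_day AR1 correlation of the day-level noise at lag one day, in
#'   `[0, 1)`.
#' @param buoyancy_amplitude Named list of signed amplitudes of the smooth
#'   buoyancy effect `h(DR) = amplitude * tanh((DR + 0.125) / 0.12)`
#'   (decreasing in DR for transit rates, increasing for the residuals).
#' @param drift_speed_sd Observation SD of a drift segment's vertical speed
#'   (m/s); depth-resolution-limited slope estimation over a multi-minute
#'   segment motivates the small default.
#' @param dr_range Admissible drift-rate range (m/s, positive upward).
#' @param dr_start_mean,dr_start_sd Initial drift rate distribution.
#' @param dr_target,dr_revert Long-run drift-rate target and daily
#'   mean-reversion rate of the condition process.
#' @param gain_scale Scale converting daily foraging gain to drift-rate change.
#' @param forage_noise_sd Lognormal day-to-day noise SD on realised foraging
#'   gain (drives daily-scale drift-rate variance).
#' @param surface_base,surface_per_duration Minimum surface-interval envelope:
#'   `surface_base + surface_per_duration * duration` seconds.
#' @param surface_exp_mean Mean of the exponential excess surface time (s).
#' @param argos_classes Tibble with `class`, `sd` (m), `prob` columns; see
#'   [argos_class_defaults()].
#' @param move_beta Velocity autocorrelation decay of the
#'   Ornstein-Uhlenbeck movement model (1/s; default timescale 24 h, the
#'   persistence scale of directed post-moult migration).
#' @param move_speed_sd Stationary per-axis speed SD (m/s).
#' @param profile_mode `"vertex"` (emit exact 5-segment dive vertices directly;
#'   fast) or `"sampled"` (emit the 4-s depth series, to be summarised through
#'   the broken-stick stage). The two are equivalent for these piecewise-linear
#'   dives, which is itself verified by a test.
#' @param bathymetry_spec Passed to [make_bathymetry()].
#' @param seed Integer RNG seed; a fixed seed gives identical bundles.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_seals = 10,
    days_per_seal = 60,
    dives_per_day_mean = 60,
    transmitted_dives_range = c(5L, 30L),
    argos_fixes_per_day_range = c(2L, 15L),
    drift_dive_prob = 0.035,
    sampling_interval = 4,
    gamma = list(descent = 3, ascent = 2.5,
                 dive_residual = -600, surface_residual = 0),
    re_slope_sd = list(descent = 0.5, ascent = 0.4,
                       dive_residual = 100, surface_residual = 5),
    re_intercept_sd = list(descent = 0.06, ascent = 0.06,
                           dive_residual = 30, surface_residual = 8),
    noise_sds = list(descent = 0.15, ascent = 0.15,
                     dive_residual = 60, surface_residual = 4),
    day_noise_sd = list(descent = 0.05, ascent = 0.05,
                        dive_residual = 25, surface_residual = 8),
    phi_day = 0.4,
    buoyancy_amplitude = list(descent = -0.30, ascent = -0.25,
                              dive_residual = 60, surface_residual = 10),
    drift_speed_sd = 0.002,
    dr_range = c(-0.35, 0.10),
    dr_start_mean = -0.30, dr_start_sd = 0.03,
    dr_target = -0.05, dr_revert = 0.02,
    gain_scale = 0.05, forage_noise_sd = 0.5,
    surface_base = 90, surface_per_duration = 0.04, surface_exp_mean = 35,
    argos_classes = argos_class_defaults(),
    move_beta = 1 / 86400, move_speed_sd = 0.5,
    profile_mode = c("vertex", "sampled"),
    bathymetry_spec = driftforage::bathymetry_spec(),
    seed = 1L) {
  profile_mode <- match.arg(profile_mode)
  cfg <- list(
    n_seals = n_seals, days_per_seal = days_per_seal,
    dives_per_day_mean = dives_per_day_mean,
    transmitted_dives_range = as.integer(transmitted_dives_range),
    argos_fixes_per_day_range = as.integer(argos_fixes_per_day_range),
    drift_dive_prob = drift_dive_prob,
    sampling_interval = sampling_interval,
    gamma = gamma, re_slope_sd = re_slope_sd,
    re_intercept_sd = re_intercept_sd,
    noise_sds = noise_sds, day_noise_sd = day_noise_sd, phi_day = phi_day,
    buoyancy_amplitude = buoyancy_amplitude,
    drift_speed_sd = drift_speed_sd,
    dr_range = dr_range, dr_start_mean = dr_start_mean,
    dr_start_sd = dr_start_sd, dr_target = dr_target, dr_revert = dr_revert,
    gain_scale = gain_scale, forage_noise_sd = forage_noise_sd,
    surface_base = surface_base, surface_per_duration = surface_per_duration,
    surface_exp_mean = surface_exp_mean,
    argos_classes = argos_classes,
    move_beta = move_beta, move_speed_sd = move_speed_sd,
    profile_mode = profile_mode,
    bathymetry_spec = bathymetry_spec,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- c("n_seals", "days_per_seal", "dives_per_day_mean",
                  "drift_dive_prob", "sampling_interval", "phi_day",
                  "drift_speed_sd", "dr_start_mean", "dr_start_sd",
                  "dr_target", "dr_revert", "gain_scale", "forage_noise_sd",
                  "surface_base", "surface_per_duration", "surface_exp_mean",
                  "move_beta", "move_speed_sd", "seed")
  for (f in num_fields) assert_scalar_num(cfg[[f]], f)
  for (f in c("gamma", "re_slope_sd", "re_intercept_sd", "noise_sds",
              "day_noise_sd", "buoyancy_amplitude")) {
    vals <- unlist(cfg[[f]])
    if (!all(is.finite(vals))) abort(sprintf("non-finite values in `%s`", f))
    missing <- setdiff(metric_names(), names(cfg[[f]]))
    if (length(missing)) {
      abort(sprintf("`%s` lacks entries for: %s", f,
                    paste(missing, collapse = ", ")))
    }
  }
  if (cfg$drift_dive_prob < 0 || cfg$drift_dive_prob > 1) {
    abort("`drift_dive_prob` must be a probability in [0, 1]")
  }
  if (cfg$phi_day < 0 || cfg$phi_day >= 1) abort("`phi_day` must be in [0, 1)")
  if (cfg$n_seals < 1 || cfg$days_per_seal < 1 || cfg$dives_per_day_mean <= 0) {
    abort("counts must be positive")
  }
  tr <- cfg$transmitted_dives_range
  if (length(tr) != 2 || any(!is.finite(tr)) || tr[1] > tr[2] ||
      tr[1] < 1 || tr[2] > 186) {
    abort("`transmitted_dives_range` must lie within [1, 186]")
  }
  ar <- cfg$argos_fixes_per_day_range
  if (length(ar) != 2 || any(!is.finite(ar)) || ar[1] > ar[2] ||
      ar[1] < 1 || ar[2] > 50) {
    abort("`argos_fixes_per_day_range` must lie within [1, 50]")
  }
  if (diff(cfg$dr_range) <= 0) abort("`dr_range` must be increasing")
  invisible(cfg)
}

metric_names <- function() {
  c("descent", "ascent", "dive_residual", "surface_residual")
}

#' Conventional ARGOS location-class error model
#'
#' Isotropic per-axis positional error SDs by location class, with a typical
#' class frequency mix. The tracking literature does not fix these values;
#' they are user-configurable via [sim_config()] and [fit_ctcrw()].
#'
#' @return Tibble with columns `class`, `sd` (metres), `prob`.
#' @export
argos_class_defaults <- function() {
  tibble::tibble(
    class = c("3", "2", "1", "0", "A", "B"),
    sd = c(250, 500, 1250, 3000, 5000, 10000),
    prob = c(0.08, 0.12, 0.18, 0.16, 0.22, 0.24)
  )
}

# Smooth buoyancy effect on a metric: signed, monotone in drift rate over the
# realistic range [-0.35, 0.10] m/s.
buoyancy_effect <- function(amplitude, dr) {
  amplitude * tanh((dr + 0.125) / 0.12)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d seals x %d days, ~%g dives/day (transmit %d-%d/day), ",
    "drift-dive prob %.3f, seed %d\n"),
    x$n_seals, x$days_per_seal, x$dives_per_day_mean,
    x$transmitted_dives_range[1], x$transmitted_dives_range[2],
    x$drift_dive_prob, x$seed))
  invisible(x)
}
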