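# Synthetic world generation: movement, condition/drift-rate trajectories,
# transmitted dives, ARGOS fixes. All vertex times lie on the tag's sampling
# grid, and every dive is piecewise linear over its five segments, so the
# onboard broken-stick abstraction is exact by construction.

#' Simulate a complete synthetic seal tracking dataset
#'
#' Generates, for each seal: a continuous Ornstein-Uhlenbeck-velocity movement
#' path over a planar world with synthetic bathymetry; a body-condition
#' (lipid) trajectory driven by a spatially autocorrelated prey field, mapped
#' linearly to a true drift rate `DR_true` (m/s, positive upward) that starts
#' negative and trends toward neutral; transmitted summarised dives whose
#' metrics respond linearly to the daily drift-rate change and smoothly to
#' buoyancy; passive drift segments inserted (only in dives deeper than 100 m)
#' with probability `drift_dive_prob`; and noisy ARGOS fixes in the configured
#' class mix.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle` with elements `truth` (per seal-day
#'   tibble: position, lipid proxy, `dr_true`, `ddr_true`, `gain_true`),
#'   `seals` (per-seal random effects and sex), `dives` (observable
#'   summarised-dive tibble), `dive_truth` (per-dive generative terms),
#'   `profiles` (4-s depth series; only in `profile_mode = "sampled"`),
#'   `fixes` (noisy ARGOS fixes), `fix_truth` (true positions at fix times),
#'   `bathy`, `truth_params` (echo of all generative coefficients) and
#'   `config`.
#' @examples
#' b <- simulate_world(sim_config(n_seals = 2, days_per_seal = 10))
#' head(b$dives)
#' @export
simulate_world <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  bathy <- make_bathymetry(config$bathymetry_spec)
  prey <- with_seed(child_seed(config$seed, 0L), make_prey_field(bathy))

  per_seal <- purrr::map(seq_len(config$n_seals), function(i) {
    with_seed(child_seed(config$seed, i), simulate_seal(i, config, bathy, prey))
  })

  dives <- dplyr::bind_rows(purrr::map(per_seal, "dives"))
  bundle <- structure(list(
    truth = dplyr::bind_rows(purrr::map(per_seal, "truth")),
    seals = dplyr::bind_rows(purrr::map(per_seal, "seal")),
    dives = dives[observable_dive_cols(dives)],
    dive_truth = dplyr::bind_rows(purrr::map(per_seal, "dive_truth")),
    fixes = dplyr::bind_rows(purrr::map(per_seal, "fixes")),
    fix_truth = dplyr::bind_rows(purrr::map(per_seal, "fix_truth")),
    bathy = bathy,
    truth_params = list(
      gamma = config$gamma,
      buoyancy_amplitude = config$buoyancy_amplitude,
      re_slope_sd = config$re_slope_sd,
      re_intercept_sd = config$re_intercept_sd,
      phi_day = config$phi_day,
      drift_dive_prob = config$drift_dive_prob,
      drift_speed_sd = config$drift_speed_sd,
      move_beta = config$move_beta,
      move_sigma = sqrt(2 * config$move_beta) * config$move_speed_sd
    ),
    config = config
  ), class = "sim_bundle")

  if (config$profile_mode == "sampled") {
    bundle$profiles <- expand_profiles(dives, config$sampling_interval)
  }
  bundle
}

observable_dive_cols <- function(dives) {
  intersect(c("seal_id", "dive_id", "start_time", "t1", "t2", "t3", "t4",
              "d1", "d2", "d3", "d4", "max_depth", "duration",
              "surface_interval"), names(dives))
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d seals, %d seal-days, %d dives, %d ARGOS fixes\n",
              nrow(x$seals), nrow(x$truth), nrow(x$dives), nrow(x$fixes)))
  invisible(x)
}

# ---- internals --------------------------------------------------------------

# Spatially autocorrelated lognormal prey-quality lattice (mean 1).
make_prey_field <- function(bathy, n = 64L, sdlog = 0.4, smooth_cells = 2L) {
  z <- matrix(rnorm(n * n), n, n)
  k <- stats::dnorm(seq(-2, 2, length.out = 2 * smooth_cells + 1))
  k <- k / sum(k)
  sm <- apply(z, 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
  sm <- t(apply(sm, 1, function(row) as.numeric(stats::filter(row, k, circular = TRUE))))
  sm <- sm / sd(sm)
  q <- exp(sdlog * sm)
  q <- q / mean(q)
  list(q = q,
       x0 = min(bathy$x), y0 = min(bathy$y),
       dx = diff(range(bathy$x)) / n, dy = diff(range(bathy$y)) / n)
}

prey_at <- function(prey, x, y) {
  n <- nrow(prey$q)
  ix <- pmin(pmax(floor((x - prey$x0) / prey$dx) + 1L, 1L), n)
  iy <- pmin(pmax(floor((y - prey$y0) / prey$dy) + 1L, 1L), n)
  prey$q[cbind(ix, iy)]
}

# Exact OU-velocity (integrated) track simulation at arbitrary sorted times.
# One axis; returns positions and velocities.
sim_ou_axis <- function(times, beta, sigma, x0, v0) {
  n <- length(times)
  dt <- diff(times)
  a <- exp(-beta * dt)
  vv <- sigma^2 * (1 - a^2) / (2 * beta)
  vx <- sigma^2 / beta^2 * (dt - 2 * (1 - a) / beta + (1 - a^2) / (2 * beta))
  cxv <- sigma^2 * (1 - a)^2 / (2 * beta^2)
  # joint (x, v) innovation via 2x2 Cholesky
  c11 <- sqrt(pmax(vx, 0))
  c21 <- ifelse(c11 > 0, cxv / c11, 0)
  c22 <- sqrt(pmax(vv - c21^2, 0))
  z1 <- rnorm(n - 1); z2 <- rnorm(n - 1)
  x <- numeric(n); v <- numeric(n)
  x[1] <- x0; v[1] <- v0
  for (k in seq_len(n - 1)) {
    x[k + 1] <- x[k] + v[k] * (1 - a[k]) / beta + c11[k] * z1[k]
    v[k + 1] <- a[k] * v[k] + c21[k] * z1[k] + c22[k] * z2[k]
  }
  list(x = x, v = v)
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

simulate_seal <- function(i, config, bathy, prey) {
  seal_id <- sprintf("seal%03d", i)
  D <- config$days_per_seal
  day_len <- 86400

  sex <- if (runif(1) < 0.5) "F" else "M"

  # per-seal random effects (intercept; slope on the foraging-success effect)
  re <- purrr::map(metric_names(), function(m) {
    list(intercept = rnorm(1, 0, config$re_intercept_sd[[m]]),
         slope = rnorm(1, config$gamma[[m]], config$re_slope_sd[[m]]))
  })
  names(re) <- metric_names()

  # day-level AR1 noise per metric
  phi <- config$phi_day
  eta <- purrr::map(metric_names(), function(m) {
    s <- config$day_noise_sd[[m]]
    e <- numeric(D)
    e[1] <- rnorm(1, 0, s)
    if (D > 1) for (d in 2:D) e[d] <- phi * e[d - 1] + rnorm(1, 0, s * sqrt(1 - phi^2))
    e
  })
  names(eta) <- metric_names()

  # transmitted dive schedule
  tr <- config$transmitted_dives_range
  n_perf <- rpois(D, config$dives_per_day_mean)
  n_trans <- pmin(n_perf, tr[1] + floor(runif(D) * (tr[2] - tr[1] + 1L)))
  n_trans <- pmax(n_trans, 0L)
  dive_day <- rep(seq_len(D), n_trans)
  dive_times <- sort((dive_day - 1) * day_len + runif(sum(n_trans)) * (day_len - 4000))

  # ARGOS schedule
  ar <- config$argos_fixes_per_day_range
  n_fix <- ar[1] + floor(runif(D) * (ar[2] - ar[1] + 1L))
  fix_day <- rep(seq_len(D), n_fix)
  fix_times <- sort((fix_day - 1) * day_len + runif(sum(n_fix)) * day_len)
  cls_idx <- sample.int(nrow(config$argos_classes), sum(n_fix), replace = TRUE,
                        prob = config$argos_classes$prob)

  # movement over the union of needed times
  day_mid <- (seq_len(D) - 0.5) * day_len
  all_times <- sort(unique(c(0, day_mid, fix_times, dive_times)))
  x0 <- runif(1, 0.3, 0.7) * diff(range(bathy$x)) + min(bathy$x)
  y0 <- runif(1, 0.15, 0.7) * diff(range(bathy$y)) + min(bathy$y)
  beta_m <- config$move_beta
  sigma_m <- sqrt(2 * beta_m) * config$move_speed_sd
  axx <- sim_ou_axis(all_times, beta_m, sigma_m, x0, rnorm(1, 0, config$move_speed_sd))
  axy <- sim_ou_axis(all_times, beta_m, sigma_m, y0, rnorm(1, 0, config$move_speed_sd))
  px <- reflect_into(axx$x, min(bathy$x), max(bathy$x))
  py <- reflect_into(axy$x, min(bathy$y), max(bathy$y))
  pos_at <- function(tt) {
    j <- match(tt, all_times)
    cbind(px[j], py[j])
  }

  # daily condition / drift-rate trajectory
  pd <- pos_at(day_mid)
  forage <- prey_at(prey, pd[, 1], pd[, 2]) * exp(rnorm(D, 0, config$forage_noise_sd))
  gain <- config$gain_scale * (forage - exp(config$forage_noise_sd^2 / 2))
  dr <- numeric(D)
  dr[1] <- min(max(rnorm(1, config$dr_start_mean, config$dr_start_sd),
                   config$dr_range[1]), config$dr_range[2])
  if (D > 1) {
    for (d in 2:D) {
      step <- config$dr_revert * (config$dr_target - dr[d - 1]) + gain[d - 1]
      dr[d] <- min(max(dr[d - 1] + step, config$dr_range[1]), config$dr_range[2])
    }
  }
  ddr <- c(0, diff(dr))
  seafloor_day <- bathy_depth(bathy, pd[, 1], pd[, 2])

  truth <- tibble::tibble(
    seal_id = seal_id, sex = sex, day = seq_len(D),
    x = pd[, 1], y = pd[, 2],
    lipid = dr / 0.6 + 0.6,
    dr_true = dr, ddr_true = ddr, gain_true = gain,
    seafloor = seafloor_day,
    n_dives_performed = n_perf, n_dives_transmitted = n_trans
  )

  # dives
  nd <- length(dive_times)
  dive_df <- tibble::tibble(
    seal_id = seal_id,
    dive_id = sprintf("%s_d%05d", seal_id, seq_len(nd)),
    day = dive_day,
    start_time = dive_times,
    dr = dr[dive_day], ddr = ddr[dive_day],
    seafloor = seafloor_day[dive_day],
    eta_descent = eta$descent[dive_day],
    eta_ascent = eta$ascent[dive_day],
    eta_dive_residual = eta$dive_residual[dive_day],
    eta_surface_residual = eta$surface_residual[dive_day]
  )
  geom <- build_dive_geometry(dive_df, config, re)

  dives <- dplyr::bind_cols(
    dive_df[c("seal_id", "dive_id", "start_time")],
    geom$obs
  )
  dive_truth <- dplyr::bind_cols(
    dive_df[c("seal_id", "dive_id", "day")],
    tibble::tibble(dr_true = dive_df$dr, ddr_true = dive_df$ddr,
                   seafloor = dive_df$seafloor),
    geom$truth
  )

  # ARGOS fixes
  pf <- pos_at(fix_times)
  cls <- config$argos_classes[cls_idx, ]
  fix_truth <- tibble::tibble(seal_id = seal_id, time = fix_times,
                              x = pf[, 1], y = pf[, 2], class = cls$class)
  fixes <- add_argos_noise(fix_truth, config$argos_classes)

  list(seal = tibble::tibble(
         seal_id = seal_id, sex = sex,
         slope_descent = re$descent$slope,
         slope_ascent = re$ascent$slope,
         slope_dive_residual = re$dive_residual$slope,
         slope_surface_residual = re$surface_residual$slope,
         intercept_descent = re$descent$intercept,
         intercept_ascent = re$ascent$intercept,
         intercept_dive_residual = re$dive_residual$intercept,
         intercept_surface_residual = re$surface_residual$intercept
       ),
       truth = truth, dives = dives, dive_truth = dive_truth,
       fixes = fixes, fix_truth = fix_truth)
}

# Vectorised construction of five-segment dive geometry. `df` carries one row
# per dive with dr, ddr, seafloor and day-level noise; `re` the seal's random
# effects. Returns observable summarised-dive columns and generative truth.
build_dive_geometry <- function(df, config, re,
                                depth_target = NULL, force_drift = NULL,
                                drift_duration = NULL, drift_speed = NULL) {
  n <- nrow(df)
  snap <- function(t) snap_time(t, config$sampling_interval)
  A <- config$buoyancy_amplitude
  ns <- config$noise_sds

  shallow_floor <- df$seafloor < 15

  # target maximum depth
  if (is.null(depth_target)) {
    deep <- runif(n) < 0.85
    depth <- ifelse(deep,
                    pmin(pmax(rlnorm(n, log(450), 0.35), 120), 1900),
                    runif(n, 20, 100))
  } else {
    depth <- rep_len(depth_target, n)
  }
  depth <- pmin(depth, pmax(df$seafloor - 10, 3))

  # drift-dive assignment: only dives deeper than 100 m are eligible
  if (is.null(force_drift)) {
    is_drift <- depth > 100 & runif(n) < config$drift_dive_prob
  } else {
    is_drift <- rep_len(force_drift, n) & depth > 100
  }
  # drift dives leave headroom for the passive sinking segment
  depth <- ifelse(is_drift, pmin(depth, df$seafloor - 240, 1650), depth)
  is_drift <- is_drift & depth > 100

  # realized transit rates: base(depth) + foraging-success effect + buoyancy
  r_d <- 1.1 + 6e-4 * depth +
    re$descent$slope * df$ddr + buoyancy_effect(A$descent, df$dr) +
    re$descent$intercept + df$eta_descent + rnorm(n, 0, ns$descent)
  r_d <- pmin(pmax(r_d, 0.4), 3.5)
  r_a <- 1.0 + 5e-4 * depth +
    re$ascent$slope * df$ddr + buoyancy_effect(A$ascent, df$dr) +
    re$ascent$intercept + df$eta_ascent + rnorm(n, 0, ns$ascent)
  r_a <- pmin(pmax(r_a, 0.4), 3.5)

  dres_term <- re$dive_residual$slope * df$ddr +
    buoyancy_effect(A$dive_residual, df$dr) +
    re$dive_residual$intercept + df$eta_dive_residual +
    rnorm(n, 0, ns$dive_residual)
  # shallow (<= 100 m) dives are transit/rest behaviour, not foraging: their
  # durations do not carry the foraging-success offset (this also keeps
  # retention of dives near the 5-min filter boundary independent of dDR)
  dres_eff <- ifelse(depth > 100, dres_term, rnorm(n, 0, 30))

  t1 <- snap(depth / r_d)
  d1 <- depth

  # --- non-drift geometry: W-shaped bottom phase with steep, short wiggles ---
  dur_target <- 150 + 1.9 * depth + dres_eff
  r3 <- runif(n, 0.7, 1.2)
  # solve bottom length so realised duration matches the target
  B <- (dur_target - t1 - depth / r_a) / pmax(1 - 0.4 * r3 / r_a, 0.5)
  B <- pmax(B, 56)
  s1 <- snap(0.3 * B); s2 <- snap(0.3 * B)
  s3 <- pmax(snap(B - s1 - s2), config$sampling_interval)
  # amplitude cap leaves the wiggle rates >= 0.7 m/s whenever a bottom
  # segment is long enough (>= 200 s) to qualify as a drift candidate
  r1 <- runif(n, 0.7, 1.2)
  a_amp <- pmin(r1 * s1, 0.75 * depth)
  c_amp <- pmin(r3 * s3, 0.75 * depth)
  nt2 <- t1 + s1; nd2 <- depth - a_amp
  nt3 <- nt2 + s2; nd3 <- depth
  nt4 <- nt3 + s3; nd4 <- depth - c_amp
  n_tasc <- snap(nd4 / r_a)

  # --- drift geometry: passive segment right after descent ------------------
  # the drift-segment length is solved so that total dive duration realises
  # the same duration-offset response as non-drift dives (drift dives are
  # ~250 s longer at baseline, reflecting the passive phase)
  if (is.null(drift_speed)) {
    dspeed <- df$dr + rnorm(n, 0, config$drift_speed_sd)  # upward positive
  } else {
    dspeed <- rep_len(drift_speed, n)
  }
  if (is.null(drift_duration)) {
    dur_t_drift <- 150 + 1.9 * depth + 250 + dres_term
    ddur <- (dur_t_drift - t1 - 96 - depth / r_a) / (1 - dspeed / r_a)
    ddur <- snap(pmin(pmax(ddur, 240), 640))
  } else {
    ddur <- snap(rep_len(drift_duration, n))
  }
  gt2 <- t1 + ddur
  gd2 <- pmin(pmax(d1 - ddur * dspeed, 5), pmax(df$seafloor - 5, 6))
  rw <- runif(n, 0.7, 1.2)
  gt3 <- gt2 + 48; gd3 <- pmax(gd2 - 48 * rw, 2)
  gt4 <- gt3 + 48; gd4 <- gd2
  g_tasc <- snap(gd4 / r_a)

  t2 <- ifelse(is_drift, gt2, nt2); d2 <- ifelse(is_drift, gd2, nd2)
  t3 <- ifelse(is_drift, gt3, nt3); d3 <- ifelse(is_drift, gd3, nd3)
  t4 <- ifelse(is_drift, gt4, nt4); d4 <- ifelse(is_drift, gd4, nd4)
  duration <- t4 + ifelse(is_drift, g_tasc, n_tasc)
  max_depth <- pmax(d1, d2, d3, d4)

  surf_extra <- rexp(n, 1 / config$surface_exp_mean) +
    pmax(rnorm(n, 0, ns$surface_residual), 0)
  surf_term <- re$surface_residual$slope * df$ddr +
    buoyancy_effect(A$surface_residual, df$dr) +
    re$surface_residual$intercept + df$eta_surface_residual
  surface_interval <- pmin(pmax(
    config$surface_base + config$surface_per_duration * duration +
      surf_term + surf_extra, 20), 595)

  list(
    obs = tibble::tibble(
      t1 = t1, t2 = t2, t3 = t3, t4 = t4,
      d1 = d1, d2 = d2, d3 = d3, d4 = d4,
      max_depth = max_depth, duration = duration,
      surface_interval = surface_interval
    ),
    truth = tibble::tibble(
      is_drift = is_drift,
      drift_duration = ifelse(is_drift, ddur, NA_real_),
      drift_speed_true = ifelse(is_drift, dspeed, NA_real_),
      descent_rate_true = d1 / t1,
      ascent_rate_true = d4 / (duration - t4),
      dres_term = ifelse(is_drift | depth <= 100, NA_real_, dres_term),
      surf_term = surf_term,
      shallow_seafloor = shallow_floor
    )
  )
}

# Expand summarised vertex dives into 4-s sampled depth profiles.
expand_profiles <- function(dives, sampling_interval = 4) {
  purrr::pmap_dfr(
    dives[c("seal_id", "dive_id", "start_time", "t1", "t2", "t3", "t4",
            "d1", "d2", "d3", "d4", "duration", "surface_interval")],
    function(seal_id, dive_id, start_time, t1, t2, t3, t4,
             d1, d2, d3, d4, duration, surface_interval) {
      tt <- seq(0, duration, by = sampling_interval)
      dd <- approx(c(0, t1, t2, t3, t4, duration),
                   c(0, d1, d2, d3, d4, 0), xout = tt, ties = "ordered")$y
      tibble::tibble(seal_id = seal_id, dive_id = dive_id,
                     start_time = start_time, time = tt, depth = dd,
                     surface_interval = surface_interval)
    })
}

#' Simulate a single dive profile
#'
#' Generates one V/U-shaped (or drift) dive for a given day state: the seal's
#' current drift rate, drift-rate change, and local seafloor depth. The dive
#' is built from five linear segments whose vertices lie on the tag's sampling
#' grid; transit limb slopes realise the generated transit rates, the maximum
#' depth never exceeds the local seafloor, and a requested drift segment is
#' inserted immediately after the descent. A seafloor shallower than 15 m
#' yields a short flagged dive that downstream filtering removes.
#'
#' @param day_state A list with elements `dr` (drift rate, m/s, positive
#'   upward), `ddr` (daily drift-rate change, default 0), `seafloor` (m),
#'   and optionally `depth` (target maximum depth, m), `drift` (`TRUE`, or a
#'   list with `duration` (s) and `speed` (m/s, upward-positive vertical
#'   speed) to request a specific passive segment), `seal_id`, `day`.
#' @param config A [sim_config()]; `noise_sds` and random effects do not apply
#'   here (single-dive generation is conditional on the day state only).
#' @param seed Optional seed for reproducibility.
#' @return A `DiveProfile` tibble with columns `seal_id`, `dive_id`,
#'   `start_time`, `time` (s, 4-s grid), `depth` (m, surface at both ends),
#'   `surface_interval`, with attributes `vertices` (the five-segment
#'   geometry) and `drift_segment` (`NULL`, or list with `start_idx`,
#'   `end_idx`, `speed`).
#' @examples
#' p <- simulate_dive(list(dr = -0.25, seafloor = 2000,
#'                         drift = list(duration = 300, speed = -0.25)),
#'                    seed = 1)
#' max(p$depth)
#' @export
simulate_dive <- function(day_state, config = sim_config(), seed = NULL) {
  stopifnot(is.list(day_state), !is.null(day_state$dr), !is.null(day_state$seafloor))
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_dive(day_state, config)))
  }
  drift <- day_state$drift %||% FALSE
  drift_req <- is.list(drift) || isTRUE(drift)
  re0 <- purrr::map(metric_names(), function(m) {
    list(intercept = 0, slope = config$gamma[[m]])
  })
  names(re0) <- metric_names()
  df <- tibble::tibble(
    seal_id = day_state$seal_id %||% "seal001",
    dive_id = "dive1",
    day = day_state$day %||% 1L,
    start_time = 0,
    dr = day_state$dr, ddr = day_state$ddr %||% 0,
    seafloor = day_state$seafloor,
    eta_descent = 0, eta_ascent = 0,
    eta_dive_residual = 0, eta_surface_residual = 0
  )
  geom <- build_dive_geometry(
    df, config, re0,
    depth_target = day_state$depth %||% NULL,
    force_drift = drift_req,
    drift_duration = if (is.list(drift)) drift$duration else NULL,
    drift_speed = if (is.list(drift)) drift$speed else NULL
  )
  dives <- dplyr::bind_cols(df[c("seal_id", "dive_id", "start_time")], geom$obs)
  prof <- expand_profiles(dives, config$sampling_interval)
  attr(prof, "vertices") <- geom$obs
  if (isTRUE(geom$truth$is_drift[1])) {
    i1 <- which.min(abs(prof$time - dives$t1)); i2 <- which.min(abs(prof$time - dives$t2))
    attr(prof, "drift_segment") <- list(start_idx = i1, end_idx = i2,
                                        speed = geom$truth$drift_speed_true[1])
  }
  prof
}

#' Write a simulation bundle to plain-text files
#'
#' Emits the observable tables (summarised-dive CSV, ARGOS fix CSV, and the
#' 4-s profile CSV when present), the bathymetry grid, and the generative
#' truth (per-seal-day truth CSV and the truth-parameter JSON) into a
#' directory.
#'
#' @param bundle A `sim_bundle` from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dive_table(bundle$dives, file.path(dir, "dives.csv"))
  readr::write_csv(bundle$fixes, file.path(dir, "fixes.csv"), progress = FALSE)
  readr::write_csv(bundle$truth, file.path(dir, "truth.csv"), progress = FALSE)
  if (!is.null(bundle$profiles)) {
    readr::write_csv(bundle$profiles, file.path(dir, "profiles.csv"),
                     progress = FALSE)
  }
  write_bathymetry(bundle$bathy, file.path(dir, "bathymetry.grid"))
  jsonlite::write_json(bundle$truth_params,
                       file.path(dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Add class-dependent ARGOS noise to true positions
#'
#' Adds isotropic Gaussian positional error, with SD given by each fix's
#' location class, to a table of true positions. An empty input yields an
#' empty output.
#'
#' @param fix_truth Tibble with `seal_id`, `time`, `x`, `y`, `class`.
#' @param classes Class error model tibble (`class`, `sd`); see
#'   [argos_class_defaults()].
#' @param seed Optional seed.
#' @return Tibble like `fix_truth` with noisy `x`, `y` and an `sd` column.
#' @export
add_argos_noise <- function(fix_truth, classes = argos_class_defaults(),
                            seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, add_argos_noise(fix_truth, classes)))
  assert_cols(fix_truth, c("seal_id", "time", "x", "y", "class"))
  n <- nrow(fix_truth)
  if (n == 0) {
    return(dplyr::mutate(fix_truth, sd = numeric(0)))
  }
  sd_map <- setNames(classes$sd, classes$class)
  s <- unname(sd_map[as.character(fix_truth$class)])
  if (any(is.na(s))) abort("unknown ARGOS class in `fix_truth`")
  dplyr::mutate(fix_truth,
                x = .data$x + rnorm(n, 0, s),
                y = .data$y + rnorm(n, 0, s),
                sd = s)
}
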