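# The four dive-effort metrics (descent rate, ascent rate, dive residual,
# surface residual), temporal-window aggregation, and habitat classification.

#' Transit rates from a summarised dive
#'
#' Descent rate is the absolute vertical rate between the surface and the
#' first inflection point (`d1 / t1`); ascent rate between the last
#' inflection point and the surface (`d4 / (duration - t4)`). Dives with a
#' zero-length transit interval are dropped with a message.
#'
#' @param dives Filtered summarised-dive tibble.
#' @return The input with `descent_rate` and `ascent_rate` columns (m/s);
#'   degenerate rows removed.
#' @export
transit_rates <- function(dives) {
  assert_cols(dives, c("t1", "t4", "d1", "d4", "duration"))
  out <- dives |>
    dplyr::mutate(descent_rate = abs(.data$d1) / .data$t1,
                  ascent_rate = abs(.data$d4) / (.data$duration - .data$t4))
  bad <- !is.finite(out$descent_rate) | !is.finite(out$ascent_rate)
  if (any(bad)) {
    inform(sprintf("transit_rates: dropped %d dive(s) with zero-length transit",
                   sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Dive residual: relative dive duration given maximum depth
#'
#' Ordinary least-squares regression of dive duration on maximum depth over
#' the fitting scope (all retained dives pooled across seals by default, or
#' per seal); the dive residual is observed minus fitted duration (s),
#' positive for dives relatively long for their depth.
#'
#' @param dives Filtered summarised-dive tibble (needs `max_depth`,
#'   `duration`, and `seal_id` for the per-seal scope).
#' @param scope `"pooled"` (default) or `"per_seal"`.
#' @return The input with a `dive_residual` column (s).
#' @export
dive_residual <- function(dives, scope = c("pooled", "per_seal")) {
  scope <- match.arg(scope)
  assert_cols(dives, c("max_depth", "duration"))
  fit_scope <- function(df) {
    if (nrow(df) < 30) abort("dive_residual needs at least 30 dives in scope")
    if (sd(df$max_depth) < 1e-8) {
      abort("degenerate maximum-depth variance; cannot fit depth-duration regression")
    }
    f <- lm(duration ~ max_depth, data = df)
    df$dive_residual <- unname(stats::resid(f))
    df
  }
  if (scope == "pooled") return(fit_scope(dives))
  assert_cols(dives, "seal_id")
  dives |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(~ fit_scope(.x)) |>
    dplyr::ungroup()
}

#' Surface residual: excess post-dive surface interval
#'
#' The predicted minimum surface recovery interval for a dive of a given
#' duration is the `tau` quantile (default 0.05) of a linear quantile
#' regression of surface interval on dive duration; the surface residual is
#' the observed interval minus this predicted minimum (s). By construction
#' about a fraction `tau` of residuals is negative.
#'
#' @param dives Filtered summarised-dive tibble (needs `surface_interval`,
#'   `duration`).
#' @param tau Quantile defining the minimum envelope, default 0.05.
#' @param scope `"pooled"` (default) or `"per_seal"`.
#' @return The input with a `surface_residual` column (s).
#' @export
surface_residual <- function(dives, tau = 0.05, scope = c("pooled", "per_seal")) {
  scope <- match.arg(scope)
  assert_cols(dives, c("surface_interval", "duration"))
  fit_scope <- function(df) {
    if (nrow(df) < 100) abort("surface_residual needs at least 100 dives in scope")
    qf <- quantile_line(df$duration, df$surface_interval, tau = tau)
    df$surface_residual <- df$surface_interval -
      (qf$intercept + qf$slope * df$duration)
    df
  }
  if (scope == "pooled") return(fit_scope(dives))
  assert_cols(dives, "seal_id")
  dives |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(~ fit_scope(.x)) |>
    dplyr::ungroup()
}

#' Linear quantile regression by pinball-loss minimisation
#'
#' Fits `y ~ a + b x` at quantile `tau` by direct minimisation of the check
#' (pinball) loss, starting from the OLS line shifted to the `tau` residual
#' quantile, with Nelder-Mead polish from multiple starts. Where the optimum
#' is non-unique (flat loss), the smallest-slope solution found is returned.
#'
#' @param x,y Numeric vectors.
#' @param tau Target quantile in (0, 1).
#' @return List with `intercept`, `slope`, `loss`.
#' @export
quantile_line <- function(x, y, tau = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 2, tau > 0, tau < 1)
  loss <- function(par) {
    r <- y - par[1] - par[2] * x
    sum(r * (tau - (r < 0)))
  }
  ols <- lm(y ~ x)
  r0 <- unname(quantile(stats::resid(ols), tau))
  starts <- list(
    c(coef(ols)[1] + r0, coef(ols)[2]),
    c(coef(ols)[1] + r0, 0.8 * coef(ols)[2]),
    c(coef(ols)[1] + r0, 1.2 * coef(ols)[2])
  )
  best <- NULL
  for (s in starts) {
    o <- optim(s, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
    o <- optim(o$par, loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    better <- is.null(best) || o$value < best$value - 1e-9 ||
      (abs(o$value - best$value) <= 1e-9 && abs(o$par[2]) < abs(best$par[2]))
    if (better) best <- o
  }
  list(intercept = unname(best$par[1]), slope = unname(best$par[2]),
       loss = best$value)
}

#' Compute all four dive metrics
#'
#' Convenience wrapper: [transit_rates()], [dive_residual()] and
#' [surface_residual()] applied in sequence, plus a `day` column derived
#' from `start_time`.
#'
#' @inheritParams dive_residual
#' @param tau Quantile for the surface-interval minimum envelope.
#' @return The input with `descent_rate`, `ascent_rate`, `dive_residual`,
#'   `surface_residual`, `day` columns.
#' @export
compute_dive_metrics <- function(dives, scope = c("pooled", "per_seal"),
                                 tau = 0.05) {
  scope <- match.arg(scope)
  dives |>
    transit_rates() |>
    dive_residual(scope = scope) |>
    surface_residual(tau = tau, scope = scope) |>
    dplyr::mutate(day = floor(.data$start_time / 86400) + 1L)
}

#' Aggregate dive metrics over the drift-rate windows
#'
#' Joins per-dive metrics (and, optionally, per-dive positions) onto the
#' windows defined by [delta_dr()]: per seal-window unweighted means of each
#' metric and of position, the dive count, and — when a bathymetry grid is
#' supplied — the shelf/oceanic habitat class of the mean position relative
#' to the 1,500 m isobath. Windows with fewer than `min_dives` dives are
#' dropped and counted; records whose mean position falls outside the grid
#' are dropped with a message.
#'
#' @param metrics Output of [compute_dive_metrics()] (must carry `seal_id`,
#'   `day`, the four metric columns and `dive_id`).
#' @param drift_windows Output of [delta_dr()] for one window length.
#' @param positions Optional tibble `seal_id, dive_id, x, y` of per-dive
#'   (predicted) positions.
#' @param bathy Optional `bathy_grid` for habitat classification.
#' @param min_dives Minimum dives per window (default 5).
#' @param isobath Habitat threshold depth (m), default 1500.
#' @return Tibble of window records: `seal_id`, `window_days`, `block`,
#'   `mid_day`, metric means (same column names), `n_dives`, `dr_window`,
#'   `ddr`, and (with positions) `x`, `y`, (with bathymetry) `habitat`.
#'   The attribute `n_dropped_sparse` counts windows dropped for sparsity.
#' @export
window_aggregate <- function(metrics, drift_windows, positions = NULL,
                             bathy = NULL, min_dives = 5, isobath = 1500) {
  assert_cols(metrics, c("seal_id", "day", "descent_rate", "ascent_rate",
                         "dive_residual", "surface_residual"))
  assert_cols(drift_windows, c("seal_id", "window_days", "block", "day_start",
                               "day_end", "mid_day", "dr_window", "ddr"))
  if (dplyr::n_distinct(drift_windows$window_days) > 1) {
    abort("window_aggregate expects windows of a single length; split by window_days first")
  }
  if (!is.null(positions)) {
    assert_cols(positions, c("seal_id", "dive_id", "x", "y"))
    metrics <- dplyr::left_join(metrics,
                                positions[c("seal_id", "dive_id", "x", "y")],
                                by = c("seal_id", "dive_id"))
  }
  has_pos <- "x" %in% names(metrics)
  win <- drift_windows[c("seal_id", "window_days", "block", "day_start",
                         "day_end", "mid_day", "dr_window", "ddr")]
  joined <- dplyr::inner_join(
    win, metrics,
    by = dplyr::join_by("seal_id", between(y$day, x$day_start, x$day_end)))
  out <- joined |>
    dplyr::group_by(.data$seal_id, .data$window_days, .data$block,
                    .data$mid_day, .data$dr_window, .data$ddr) |>
    dplyr::summarise(
      descent_rate = mean(.data$descent_rate),
      ascent_rate = mean(.data$ascent_rate),
      dive_residual = mean(.data$dive_residual),
      surface_residual = mean(.data$surface_residual),
      x = if (has_pos) mean(.data$x, na.rm = TRUE) else NA_real_,
      y = if (has_pos) mean(.data$y, na.rm = TRUE) else NA_real_,
      n_dives = dplyr::n(),
      .groups = "drop"
    )
  n_sparse <- sum(out$n_dives < min_dives)
  out <- out[out$n_dives >= min_dives, , drop = FALSE]

  if (!is.null(bathy)) {
    stopifnot(inherits(bathy, "bathy_grid"))
    out$habitat <- classify_habitat(bathy, out$x, out$y, isobath = isobath)
    n_out <- sum(is.na(out$habitat) & !is.na(out$x))
    if (n_out > 0) {
      inform(sprintf("window_aggregate: dropped %d record(s) outside the bathymetry grid", n_out))
      out <- out[!(is.na(out$habitat) & !is.na(out$x)), , drop = FALSE]
    }
  }
  attr(out, "n_dropped_sparse") <- n_sparse
  out
}
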