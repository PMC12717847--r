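# Foraging-success proxy: drift-segment candidates, Kalman-filter screening
# with an inlier probability Z, daily drift rates, and windowed drift-rate
# change (dDR).

#' Extract candidate drift segments from summarised dives
#'
#' Candidate passive drift segments are interior segments (segments 2-4 of
#' the five-segment summarised profile) that are long and slow: duration at
#' least `min_duration` seconds and absolute vertical rate at most `max_rate`
#' m/s, taken only from dives deeper than `min_depth` metres (residual lung
#' air biases drift rates in shallower dives). Vertical speed is reported
#' positive upward (`-d(depth)/dt`).
#'
#' @param dives Filtered summarised-dive tibble.
#' @param min_depth Minimum dive maximum depth (m), default 100.
#' @param min_duration Minimum segment duration (s), default 200.
#' @param max_rate Maximum absolute vertical rate (m/s), default 0.6.
#' @return Tibble of candidates: `seal_id`, `dive_id`, `segment` (2-4),
#'   `time` (segment midpoint, epoch s), `speed` (m/s, positive upward),
#'   `seg_duration` (s), `max_depth` (m).
#' @export
candidate_segments <- function(dives, min_depth = 100, min_duration = 200,
                               max_rate = 0.6) {
  assert_cols(dives, c("seal_id", "dive_id", "start_time", "t1", "t2", "t3",
                       "t4", "d1", "d2", "d3", "d4", "max_depth"))
  deep <- dives[dives$max_depth > min_depth, , drop = FALSE]
  if (nrow(deep) == 0) return(empty_candidates())
  segs <- purrr::map_dfr(2:4, function(s) {
    ta <- deep[[paste0("t", s - 1)]]; tb <- deep[[paste0("t", s)]]
    da <- deep[[paste0("d", s - 1)]]; db <- deep[[paste0("d", s)]]
    tibble::tibble(
      seal_id = deep$seal_id, dive_id = deep$dive_id, segment = s,
      time = deep$start_time + (ta + tb) / 2,
      speed = -(db - da) / (tb - ta),
      seg_duration = tb - ta,
      max_depth = deep$max_depth
    )
  })
  out <- segs[is.finite(segs$speed) &
                segs$seg_duration >= min_duration &
                abs(segs$speed) <= max_rate, , drop = FALSE]
  dplyr::arrange(out, .data$seal_id, .data$time)
}

empty_candidates <- function() {
  tibble::tibble(seal_id = character(0), dive_id = character(0),
                 segment = integer(0), time = numeric(0), speed = numeric(0),
                 seg_duration = numeric(0), max_depth = numeric(0))
}

#' Screen drift-rate candidates with a Kalman-filter inlier probability
#'
#' Models each seal's drift-rate series as a slow random walk (variance
#' `q * dt`, dt in days) observed through a two-component mixture: an inlier
#' Normal around the trajectory (variance `r`) and a uniform contaminant
#' component over the observed speed range (active-swimming segments
#' masquerading as drift). For each candidate, `Z` is the posterior
#' probability that the observation belongs to the Normal component given the
#' one-step Kalman predictive distribution; candidates with `Z > 0.5` are
#' retained. The parameters `(q, r, w)` (process variance, observation
#' variance, inlier weight) are estimated by a bounded EM iteration on each
#' seal's series. Seals with fewer than `min_candidates` candidates cannot be
#' screened: their candidates are returned with `Z = NA`, not retained, and a
#' message is emitted.
#'
#' @param candidates Output of [candidate_segments()] (any extra columns are
#'   carried through).
#' @param max_iter Maximum EM iterations (default 15).
#' @param min_candidates Minimum series length to screen (default 5).
#' @return The input tibble plus `z` (inlier probability) and `retained`
#'   (`z > 0.5`).
#' @export
kalman_screen <- function(candidates, max_iter = 15, min_candidates = 5) {
  assert_cols(candidates, c("seal_id", "time", "speed"))
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, z = numeric(0), retained = logical(0)))
  }
  out <- candidates |>
    dplyr::group_by(.data$seal_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time)
      if (nrow(df) < min_candidates) {
        inform(sprintf("kalman_screen: seal %s has %d candidate(s) (< %d); left unscreened",
                       key$seal_id, nrow(df), min_candidates))
        df$z <- NA_real_
        df$retained <- FALSE
        return(df)
      }
      zs <- screen_series(df$speed, df$time / 86400, max_iter)
      df$z <- zs
      df$retained <- zs > 0.5
      df
    }) |>
    dplyr::ungroup()
  out
}

# Robust-Kalman EM on one speed series; times in days. Returns Z.
screen_series <- function(v, t_days, max_iter) {
  n <- length(v)
  u_dens <- 1 / (diff(range(v)) + 0.2)  # contaminant density (location-free)
  # robust initialisation: observation noise from the running-median
  # residuals, process variance from raw squared increments (the median is
  # robust to contaminant jumps)
  k <- min(9L, n)
  run_med <- stats::runmed(v, k = if (k %% 2 == 0) k - 1 else k)
  r <- max(mad(v - run_med)^2, 1e-8)
  dt <- pmax(diff(t_days), 1 / 24)
  q <- max(stats::median(diff(v)^2 / dt), 1e-7)
  w <- 0.8

  z <- rep(0.5, n)
  for (iter in seq_len(max_iter)) {
    m <- run_med[1]; P <- r + q
    mf <- numeric(n)
    for (i in seq_len(n)) {
      if (i > 1) P <- P + q * max(t_days[i] - t_days[i - 1], 1 / 24)
      S <- P + r
      e <- v[i] - m
      num <- w * dnorm(v[i], m, sqrt(S))
      z[i] <- num / (num + (1 - w) * u_dens)
      K <- P / S
      m <- m + z[i] * K * e
      P <- (1 - z[i] * K) * P
      mf[i] <- m
    }
    w_new <- min(max(mean(z), 0.5), 0.99)
    r_new <- max(sum(z * (v - mf)^2) / max(sum(z), 1e-8), 1e-8)
    # inlier increments satisfy E[(v_i - v_{i-1})^2] = q dt + 2 r; the mean
    # (not median) keeps genuine multi-day drift-rate bursts in q
    pair_in <- z[-1] > 0.5 & z[-n] > 0.5
    q_new <- if (sum(pair_in) >= 3) {
      max(mean(((diff(v)^2 - 2 * r_new) / dt)[pair_in]), 1e-8)
    } else q
    if (abs(w_new - w) < 1e-4 && abs(log(r_new / r)) < 1e-3 &&
        abs(log(q_new / q)) < 1e-3) {
      w <- w_new; r <- r_new; q <- q_new
      break
    }
    w <- w_new; r <- r_new; q <- q_new
  }
  z
}

#' Daily drift rate from retained drift estimates
#'
#' Per seal-day unweighted arithmetic mean of retained drift-segment speeds.
#' Days without retained segments are absent from the output (missing, never
#' zero).
#'
#' @param estimates Output of [kalman_screen()]; only rows with
#'   `retained == TRUE` contribute.
#' @return Tibble `seal_id, day, dr, n_segments` (day 1 starts at epoch 0).
#' @export
daily_drift_rate <- function(estimates) {
  assert_cols(estimates, c("seal_id", "time", "speed", "retained"))
  estimates |>
    dplyr::filter(.data$retained) |>
    dplyr::mutate(day = floor(.data$time / 86400) + 1L) |>
    dplyr::group_by(.data$seal_id, .data$day) |>
    dplyr::summarise(dr = mean(.data$speed), n_segments = dplyr::n(),
                     .groups = "drop")
}

#' Windowed drift rate and drift-rate change (foraging success)
#'
#' Aggregates daily drift rates into consecutive non-overlapping blocks of
#' `window_days` days anchored at each seal's first at-sea day (block mode,
#' the default), or into trailing running windows sampled daily. The window
#' value is the unweighted mean of the daily drift rates present in the
#' window; the foraging-success proxy is the difference between consecutive
#' windows, `ddr = dr[n] - dr[n-1]`, defined only when both windows contain
#' at least `min_segments` retained segments (missing propagates, never
#' imputed).
#'
#' @param daily Output of [daily_drift_rate()].
#' @param window_days Window length in days (the analysis uses 1, 2, 3, 7
#'   and 10).
#' @param min_segments Minimum retained segments per window (default 1).
#' @param mode `"block"` (non-overlapping consecutive blocks) or `"running"`
#'   (trailing windows ending at each day, differenced at lag
#'   `window_days`).
#' @return Tibble `seal_id, window_days, block, day_start, day_end, mid_day,
#'   n_days, n_segments, dr_window, ddr` (one row per window with data;
#'   `ddr` is `NA` when the preceding window is missing or under-populated).
#' @export
delta_dr <- function(daily, window_days, min_segments = 1,
                     mode = c("block", "running")) {
  mode <- match.arg(mode)
  assert_cols(daily, c("seal_id", "day", "dr", "n_segments"))
  assert_scalar_num(window_days, "window_days", lo = 1)
  w <- as.integer(window_days)

  if (mode == "block") {
    agg <- daily |>
      dplyr::group_by(.data$seal_id) |>
      dplyr::mutate(block = (as.integer(.data$day) - 1L) %/% w) |>
      dplyr::group_by(.data$seal_id, .data$block) |>
      dplyr::summarise(
        dr_window = mean(.data$dr),
        n_days = dplyr::n(),
        n_segments = sum(.data$n_segments),
        .groups = "drop_last"
      ) |>
      dplyr::mutate(
        window_days = w,
        day_start = .data$block * w + 1L,
        day_end = .data$block * w + w,
        mid_day = .data$block * w + (w + 1) / 2
      ) |>
      dplyr::filter(.data$n_segments >= min_segments) |>
      dplyr::arrange(.data$block) |>
      dplyr::mutate(
        ddr = ifelse(.data$block - dplyr::lag(.data$block) == 1L,
                     .data$dr_window - dplyr::lag(.data$dr_window), NA_real_)
      ) |>
      dplyr::ungroup()
  } else {
    agg <- daily |>
      dplyr::group_by(.data$seal_id) |>
      dplyr::reframe(running_windows(dplyr::pick(dplyr::everything()), w)) |>
      dplyr::filter(.data$n_segments >= min_segments) |>
      dplyr::group_by(.data$seal_id) |>
      dplyr::arrange(.data$day_end, .by_group = TRUE) |>
      dplyr::mutate(
        prev_end = .data$day_end - w,
        ddr = .data$dr_window -
          .data$dr_window[match(.data$prev_end, .data$day_end)]
      ) |>
      dplyr::select(-"prev_end") |>
      dplyr::ungroup()
  }
  dplyr::select(agg, "seal_id", "window_days", "block", "day_start",
                "day_end", "mid_day", "n_days", "n_segments", "dr_window",
                "ddr")
}

running_windows <- function(df, w) {
  days <- seq(min(df$day), max(df$day))
  purrr::map_dfr(days, function(d) {
    in_win <- df$day > d - w & df$day <= d
    if (!any(in_win)) return(NULL)
    tibble::tibble(
      window_days = w, block = as.integer(d),
      day_start = as.integer(d - w + 1L), day_end = as.integer(d),
      mid_day = d - (w - 1) / 2,
      n_days = sum(in_win), n_segments = sum(df$n_segments[in_win]),
      dr_window = mean(df$dr[in_win])
    )
  })
}
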