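#' Broken-stick abstraction of a high-resolution dive profile
#'
#' Summarises a sampled time-depth profile to `k` interior inflection points
#' using the iterative greedy broken-stick rule that satellite relay data
#' loggers apply onboard: starting from the two surface endpoints, each
#' iteration adds the sample with the largest absolute vertical deviation from
#' the current piecewise-linear reconstruction. Ties are broken by earliest
#' time. Deviation is measured vertically (same-time depth difference), not as
#' perpendicular distance.
#'
#' @param time Numeric vector of sample times (seconds from dive start,
#'   strictly increasing; first and last samples are the surface endpoints).
#' @param depth Numeric vector of depths (metres, positive down), same length.
#' @param k Number of interior inflection points to select (default 4, the
#'   SRDL firmware value).
#' @param dive_id Optional identifier used in error messages.
#' @return An object of class `broken_stick`: a list with
#'   \describe{
#'     \item{points}{tibble of the `k` selected interior points
#'       (`time`, `depth`), sorted by time, plus the endpoints flagging column
#'       `iteration` (order of selection; 0 for endpoints).}
#'     \item{max_error}{final maximum absolute reconstruction error (m).}
#'     \item{trace}{tibble with per-iteration `chosen_time` and `deviation`.}
#'   }
#' @examples
#' t <- seq(0, 400, by = 4)
#' d <- approx(c(0, 200, 400), c(0, 300, 0), xout = t)$y
#' bs <- broken_stick(t, d)
#' bs$max_error  # 0: a V-dive is exactly representable
#' @export
broken_stick <- function(time, depth, k = 4, dive_id = NULL) {
  n <- length(time)
  if (length(depth) != n) abort("`time` and `depth` must have equal length")
  if (n < k + 2) {
    abort(sprintf("profile%s has %d samples; need at least k + 2 = %d",
                  if (is.null(dive_id)) "" else paste0(" '", dive_id, "'"),
                  n, k + 2L))
  }
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing")
  res <- .broken_stick_cpp(as.numeric(time), as.numeric(depth), as.integer(k))
  idx <- res$chosen
  ord <- order(time[idx])
  pts <- tibble::tibble(
    time = c(time[1], time[idx][ord], time[n]),
    depth = c(depth[1], depth[idx][ord], depth[n]),
    iteration = c(0L, seq_len(k)[ord], 0L)
  )
  structure(
    list(points = pts, max_error = res$max_error,
         trace = tibble::tibble(chosen_time = time[idx], deviation = res$deviation)),
    class = "broken_stick"
  )
}

#' Reconstruct depths from a broken-stick summary
#'
#' Linear interpolation between the selected points (including the surface
#' endpoints); exact at every selected point.
#'
#' @param result A `broken_stick` object, or any data frame with `time` and
#'   `depth` columns describing the selected points (endpoints included).
#' @param query_times Times (seconds from dive start) at which to evaluate;
#'   must lie within the dive span.
#' @return Numeric vector of reconstructed depths (m).
#' @export
reconstruct <- function(result, query_times) {
  pts <- if (inherits(result, "broken_stick")) result$points else result
  assert_cols(pts, c("time", "depth"), "result")
  lo <- min(pts$time); hi <- max(pts$time)
  if (any(query_times < lo | query_times > hi)) {
    abort(sprintf("query times outside dive span [%g, %g]", lo, hi))
  }
  approx(pts$time, pts$depth, xout = query_times, ties = "ordered")$y
}

#' @export
print.broken_stick <- function(x, ...) {
  cat(sprintf("<broken_stick> %d interior points, max reconstruction error %.3f m\n",
              sum(x$points$iteration > 0), x$max_error))
  print(x$points)
  invisible(x)
}

#' Summarise high-resolution dive profiles to SRDL-style records
#'
#' Applies [broken_stick()] to every dive in a long profile table and emits the
#' summarised-dive table used by all downstream stages (4 interior inflection
#' points, maximum depth, duration, post-dive surface interval).
#'
#' @param profiles Tibble with columns `seal_id`, `dive_id`, `start_time`
#'   (epoch seconds, UTC convention), `time` (s from dive start), `depth` (m),
#'   and per-dive `surface_interval` (s, constant within dive).
#' @param k Number of interior points (default 4).
#' @return A summarised-dive tibble with columns `seal_id`, `dive_id`,
#'   `start_time`, `t1..t4`, `d1..d4`, `max_depth`, `duration`,
#'   `surface_interval`.
#' @export
summarise_dives <- function(profiles, k = 4) {
  assert_cols(profiles, c("seal_id", "dive_id", "start_time", "time", "depth",
                          "surface_interval"))
  profiles |>
    dplyr::group_by(.data$seal_id, .data$dive_id) |>
    dplyr::group_modify(function(df, key) {
      bs <- broken_stick(df$time, df$depth, k = k, dive_id = key$dive_id)
      interior <- bs$points[bs$points$iteration > 0, ]
      out <- tibble::tibble(
        start_time = df$start_time[1],
        max_depth = max(df$depth),
        duration = max(df$time),
        surface_interval = df$surface_interval[1]
      )
      for (j in seq_len(k)) {
        out[[paste0("t", j)]] <- interior$time[j]
        out[[paste0("d", j)]] <- interior$depth[j]
      }
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select("seal_id", "dive_id", "start_time",
                  dplyr::all_of(paste0("t", seq_len(k))),
                  dplyr::all_of(paste0("d", seq_len(k))),
                  "max_depth", "duration", "surface_interval")
}
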