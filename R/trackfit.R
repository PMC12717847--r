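# Track estimation: ARGOS speed filtering and a continuous-time correlated
# random walk (CTCRW) state-space model fitted by maximum likelihood, with
# smoother-based position prediction at arbitrary times.

#' Speed-filter ARGOS fixes
#'
#' Iteratively removes fixes whose implied straight-line speed to both
#' temporal neighbours (among currently retained fixes) exceeds `vmax`, until
#' none remain. The first and last fixes are removed only when the speeds to
#' their nearest two retained neighbours both exceed `vmax`. Operates per
#' seal when a `seal_id` column is present.
#'
#' @param fixes Tibble with `time` (s), `x`, `y` (m), optionally `seal_id`.
#' @param vmax Maximum plausible horizontal speed (m/s), default 4.
#' @return The retained fixes (same columns, original order).
#' @export
speed_filter <- function(fixes, vmax = 4) {
  assert_cols(fixes, c("time", "x", "y"))
  if ("seal_id" %in% names(fixes) && dplyr::n_distinct(fixes$seal_id) > 1) {
    return(fixes |>
             dplyr::group_by(.data$seal_id) |>
             dplyr::group_modify(~ speed_filter_one(.x, vmax)) |>
             dplyr::ungroup())
  }
  speed_filter_one(fixes, vmax)
}

speed_filter_one <- function(fixes, vmax) {
  if (nrow(fixes) < 2) abort("speed filter needs at least 2 fixes")
  ord <- order(fixes$time)
  keep <- ord
  repeat {
    n <- length(keep)
    if (n < 3) break
    tt <- fixes$time[keep]; xx <- fixes$x[keep]; yy <- fixes$y[keep]
    sp <- sqrt(diff(xx)^2 + diff(yy)^2) / pmax(diff(tt), 1)
    # speed to previous / next neighbour for each retained fix
    prev <- c(Inf, sp); nxt <- c(sp, Inf)
    # interior: both neighbours too fast; ends: nearest two hops too fast
    bad <- prev > vmax & nxt > vmax
    bad[1] <- sp[1] > vmax && n > 2 && sp[2] > vmax
    bad[n] <- sp[n - 1] > vmax && n > 2 && sp[n - 2] > vmax
    if (!any(bad)) break
    keep <- keep[!bad]
  }
  if (length(keep) < 2) abort("speed filter removed all fixes")
  fixes[sort(keep), , drop = FALSE]
}

#' Fit a continuous-time correlated random walk to one seal's fixes
#'
#' State-space model per axis: position integrates an Ornstein-Uhlenbeck
#' velocity (`dv = -beta v dt + sigma dW`), giving exact linear-Gaussian
#' transitions over the irregular gaps between fixes. The two axes share the
#' process parameters and are treated independently (diagonal covariances).
#' `beta` (1/s) is the inverse velocity-autocorrelation timescale and `sigma`
#' the velocity diffusion; both are estimated by maximising the Kalman-filter
#' likelihood by quasi-Newton on log-parameters with multiple restarts.
#'
#' @param fixes Speed-filtered fixes for a single seal: `time`, `x`, `y`, and
#'   either an `sd` column (per-fix positional error SD, m) or a `class`
#'   column resolved through `classes`.
#' @param classes ARGOS class error model (tibble `class`, `sd`), used when
#'   `fixes` lacks an `sd` column.
#' @param n_restarts Number of optimiser starts (default 3).
#' @return A `ctcrw_fit` object: fitted parameters, log-likelihood, smoothed
#'   states at observation times (`states`: `time, x, y, x_se, y_se`),
#'   standardised one-step innovations (`innovations`), and convergence info.
#' @export
fit_ctcrw <- function(fixes, classes = argos_class_defaults(), n_restarts = 3) {
  assert_cols(fixes, c("time", "x", "y"))
  if ("seal_id" %in% names(fixes) && dplyr::n_distinct(fixes$seal_id) > 1) {
    abort("fit_ctcrw() fits a single seal; see fit_tracks() for many")
  }
  if (nrow(fixes) < 10) abort("need at least 10 fixes to fit the CTCRW")
  fixes <- fixes[order(fixes$time), , drop = FALSE]
  if (!"sd" %in% names(fixes)) {
    assert_cols(fixes, "class")
    sd_map <- setNames(classes$sd, classes$class)
    fixes$sd <- unname(sd_map[as.character(fixes$class)])
  }
  if (any(!is.finite(fixes$sd) | fixes$sd <= 0)) {
    abort("observation SDs must be positive")
  }
  tt <- fixes$time

  nll <- function(par) {
    beta <- exp(par[1]); sigma <- exp(par[2])
    if (!is.finite(beta) || !is.finite(sigma) || beta <= 0) return(1e12)
    lx <- .ctcrw_kalman_cpp(tt, fixes$x, fixes$sd, beta, sigma, FALSE)$loglik
    ly <- .ctcrw_kalman_cpp(tt, fixes$y, fixes$sd, beta, sigma, FALSE)$loglik
    v <- -(lx + ly)
    if (!is.finite(v)) 1e12 else v
  }

  # data-driven starts: crude speed scale from consecutive displacements
  dt <- pmax(diff(tt), 1)
  spd <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2) / dt
  v_guess <- max(stats::median(spd), 0.05)
  beta0 <- 1 / (6 * 3600)
  starts <- list(
    c(log(beta0), log(sqrt(2 * beta0) * v_guess)),
    c(log(beta0 * 4), log(sqrt(8 * beta0) * v_guess)),
    c(log(beta0 / 4), log(sqrt(beta0 / 2) * v_guess))
  )[seq_len(max(1, n_restarts))]

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      nlminb(s, nll, control = list(rel.tol = 1e-10, eval.max = 500, iter.max = 300)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective)) best <- o
  }
  if (is.null(best) || !is.finite(best$objective)) {
    abort("CTCRW likelihood optimisation failed to produce a finite optimum")
  }
  beta <- exp(best$par[1]); sigma <- exp(best$par[2])
  kx <- .ctcrw_kalman_cpp(tt, fixes$x, fixes$sd, beta, sigma, TRUE)
  ky <- .ctcrw_kalman_cpp(tt, fixes$y, fixes$sd, beta, sigma, TRUE)

  innov <- tibble::tibble(
    time = tt,
    x = kx$innovation, y = ky$innovation
  )
  ac1 <- function(z) {
    z <- z[is.finite(z)]
    if (length(z) < 3) return(NA_real_)
    stats::cor(z[-1], z[-length(z)])
  }

  structure(list(
    beta = beta, sigma = sigma,
    speed_rms = sigma / sqrt(2 * beta) * sqrt(2),  # 2-D stationary RMS speed
    loglik = -best$objective,
    n = nrow(fixes),
    convergence = best$convergence,
    fixes = fixes,
    states = tibble::tibble(
      time = tt, x = kx$x, y = ky$x,
      x_se = sqrt(pmax(kx$var, 0)), y_se = sqrt(pmax(ky$var, 0)),
      x_filter_se = sqrt(pmax(kx$filter_var, 0)),
      y_filter_se = sqrt(pmax(ky$filter_var, 0))
    ),
    innovations = innov,
    innovation_acf1 = c(x = ac1(kx$innovation), y = ac1(ky$innovation))
  ), class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat(sprintf(paste0("<ctcrw_fit> %d fixes, logLik %.1f\n",
                     "  beta %.3g /s (velocity timescale %.2f h), sigma %.3g, ",
                     "RMS speed %.2f m/s\n"),
              x$n, x$loglik, x$beta, 1 / x$beta / 3600, x$sigma, x$speed_rms))
  invisible(x)
}

#' Predict positions (with uncertainty) at arbitrary times
#'
#' Runs the Kalman smoother over the union of observation and query times, so
#' predictions interpolate the track continuously and reproduce the smoothed
#' states at observation times. Query times outside the track span are
#' refused unless `allow_extrapolate = TRUE`.
#'
#' @param fit A `ctcrw_fit`.
#' @param times Numeric query times (s).
#' @param allow_extrapolate Permit queries outside the fix span.
#' @return Tibble `time, x, y, x_se, y_se` in query order.
#' @export
predict_positions <- function(fit, times, allow_extrapolate = FALSE) {
  stopifnot(inherits(fit, "ctcrw_fit"))
  fx <- fit$fixes
  span <- range(fx$time)
  out_of_span <- times < span[1] | times > span[2]
  if (any(out_of_span) && !allow_extrapolate) {
    abort(sprintf("%d query time(s) outside track span [%g, %g]; set allow_extrapolate = TRUE to override",
                  sum(out_of_span), span[1], span[2]))
  }
  all_t <- sort(unique(c(fx$time, times)))
  oy_x <- rep(NA_real_, length(all_t)); oy_y <- oy_x; osd <- oy_x
  j <- match(fx$time, all_t)
  oy_x[j] <- fx$x; oy_y[j] <- fx$y; osd[j] <- fx$sd
  kx <- .ctcrw_kalman_cpp(all_t, oy_x, osd, fit$beta, fit$sigma, TRUE)
  ky <- .ctcrw_kalman_cpp(all_t, oy_y, osd, fit$beta, fit$sigma, TRUE)
  q <- match(times, all_t)
  tibble::tibble(time = times, x = kx$x[q], y = ky$x[q],
                 x_se = sqrt(pmax(kx$var[q], 0)),
                 y_se = sqrt(pmax(ky$var[q], 0)))
}

#' Fit CTCRW tracks for many seals
#'
#' @param fixes Fix tibble with a `seal_id` column.
#' @param ... Passed to [fit_ctcrw()].
#' @return Named list of `ctcrw_fit` objects.
#' @export
fit_tracks <- function(fixes, ...) {
  assert_cols(fixes, "seal_id")
  ids <- unique(fixes$seal_id)
  fits <- purrr::map(ids, function(id) {
    fit_ctcrw(fixes[fixes$seal_id == id, , drop = FALSE], ...)
  })
  setNames(fits, ids)
}

#' Predict dive-time positions for many seals
#'
#' @param fits Named list from [fit_tracks()].
#' @param at Tibble with `seal_id` and `time`; rows whose time falls outside
#'   the seal's track span are dropped with a message (count reported).
#' @return Tibble `seal_id, time, x, y, x_se, y_se`.
#' @export
predict_tracks <- function(fits, at) {
  assert_cols(at, c("seal_id", "time"))
  dropped <- 0L
  out <- purrr::map_dfr(names(fits), function(id) {
    tt <- at$time[at$seal_id == id]
    if (length(tt) == 0) return(NULL)
    span <- range(fits[[id]]$fixes$time)
    ok <- tt >= span[1] & tt <= span[2]
    dropped <<- dropped + sum(!ok)
    if (!any(ok)) return(NULL)
    dplyr::mutate(predict_positions(fits[[id]], tt[ok]), seal_id = id,
                  .before = 1)
  })
  if (dropped > 0) {
    inform(sprintf("predict_tracks: dropped %d record(s) outside fix coverage", dropped))
  }
  out
}

#' @export
tidy.ctcrw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta", "sigma", "rms_speed"),
    estimate = c(x$beta, x$sigma, x$speed_rms)
  )
}

#' @export
glance.ctcrw_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, convergence = x$convergence,
                 innovation_acf1_x = unname(x$innovation_acf1["x"]),
                 innovation_acf1_y = unname(x$innovation_acf1["y"]))
}
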