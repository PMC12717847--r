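# ggplot2 visualisations for the main result types.

#' Plot a fitted response model
#'
#' Shows the partial effects from a `pamm_fit`: the linear foraging-success
#' (dDR) effect with its 95% confidence band, and — when present — the
#' fitted smooth of drift rate with pointwise intervals, faceted side by
#' side.
#'
#' @param object A `pamm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pamm_fit <- function(object, ...) {
  design <- object$design
  dd <- seq(min(design$ddr), max(design$ddr), length.out = 50)
  eff <- object$beta1 * dd
  se <- object$beta1_se * abs(dd)
  lin <- tibble::tibble(x = dd, estimate = eff,
                        lower = eff - 1.96 * se, upper = eff + 1.96 * se,
                        panel = "linear dDR effect")
  dat <- lin
  if (design$include_smooth) {
    sm <- smooth_estimate(object)
    dat <- dplyr::bind_rows(
      lin,
      tibble::tibble(x = sm$dr, estimate = sm$estimate, lower = sm$lower,
                     upper = sm$upper, panel = "smooth of drift rate"))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "drift rate (change) [m/s]",
                  y = sprintf("partial effect on %s", object$metric),
                  title = sprintf("%s: dDR coefficient %.3g (SE %.2g) [%s]",
                                  object$metric, object$beta1, object$beta1_se,
                                  object$significance)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted track with its fixes
#'
#' @param object A `ctcrw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctcrw_fit <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_point(data = object$fixes,
                        ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000),
                        colour = "grey60", size = 0.7) +
    ggplot2::geom_path(data = object$states,
                       ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000),
                       colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [km]", y = "y [km]",
                  title = sprintf("CTCRW smoothed track (%d fixes)", object$n)) +
    ggplot2::theme_minimal()
}

#' Forest-style coefficient plot across windows and strata
#'
#' Mirrors the usual presentation of the linear foraging-success
#' coefficients: points with +-1 SE bars per temporal window, faceted by
#' metric, with non-significant fits hollow.
#'
#' @param coef_table Output of [coefficient_table()].
#' @return A ggplot object.
#' @export
plot_coefficients <- function(coef_table) {
  assert_cols(coef_table, c("metric", "window_days", "beta1", "se", "flag"))
  ggplot2::ggplot(coef_table,
                  ggplot2::aes(x = factor(.data$window_days), y = .data$beta1,
                               colour = .data$habitat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$beta1 - .data$se,
                   ymax = .data$beta1 + .data$se,
                   shape = .data$flag),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_shape_manual(values = c(sig = 16, `~` = 17, ns = 1)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "temporal window [days]",
                  y = "linear dDR coefficient (metric units per m/s)") +
    ggplot2::theme_minimal()
}

#' Daily drift-rate series plot
#'
#' @param daily Output of [daily_drift_rate()].
#' @param estimates Optional [kalman_screen()] output; rejected candidates
#'   are shown as crosses.
#' @return A ggplot object.
#' @export
plot_drift_series <- function(daily, estimates = NULL) {
  assert_cols(daily, c("seal_id", "day", "dr"))
  p <- ggplot2::ggplot(daily, ggplot2::aes(x = .data$day, y = .data$dr)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(group = .data$seal_id), colour = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~seal_id) +
    ggplot2::labs(x = "days since departure", y = "drift rate [m/s]") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    rej <- estimates[!is.na(estimates$z) & !estimates$retained, , drop = FALSE]
    if (nrow(rej) > 0) {
      rej$day <- floor(rej$time / 86400) + 1
      p <- p + ggplot2::geom_point(data = rej,
                                   ggplot2::aes(x = .data$day, y = .data$speed),
                                   shape = 4, colour = "firebrick", size = 0.8)
    }
  }
  p
}
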