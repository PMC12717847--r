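# Reporting: coefficient tables across strata/windows and the
# window-attenuation summary.

#' Tidy coefficient table across fitted response models
#'
#' One row per fitted model with its linear foraging-success coefficient,
#' standard error, Wald p-value and a significance flag: `"sig"` for
#' p < 0.05, `"~"` for marginally significant p in [0.05, 0.10), `"ns"`
#' otherwise.
#'
#' @param fits A list of `pamm_fit` objects (each may carry `meta` labels
#'   such as `sex`, `habitat`, `window_days` from [build_design()]).
#' @return Tibble with columns `metric`, any metadata labels, `beta1`, `se`,
#'   `p`, `flag`, `r2_fitted_obs`, `n`.
#' @export
coefficient_table <- function(fits) {
  if (inherits(fits, "pamm_fit")) fits <- list(fits)
  if (length(fits) == 0) abort("no fits supplied")
  purrr::map_dfr(fits, function(f) {
    stopifnot(inherits(f, "pamm_fit"))
    meta <- f$meta
    tibble::tibble(
      metric = f$metric,
      sex = meta$sex %||% "all",
      habitat = meta$habitat %||% "all",
      window_days = meta$window_days %||% NA_real_,
      beta1 = f$beta1, se = f$beta1_se, p = f$beta1_p,
      flag = f$significance,
      r2_fitted_obs = f$r2_fitted_obs,
      n = f$n
    )
  })
}

# Kendall tau-a (ties contribute zero, so a constant sequence gives tau 0).
kendall_tau <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]) * sign(y[(i + 1):n] - y[i]))
  }
  s / (n * (n - 1) / 2)
}

#' Attenuation of the foraging-success effect with window length
#'
#' For each metric (and stratum), tabulates the absolute linear coefficient
#' by temporal window and computes a monotonicity statistic: the Kendall
#' rank correlation (tau-a) between |beta1| and window length. Negative tau
#' indicates coefficients weakening as the window lengthens. Groups with
#' fewer windows than requested are flagged as partial.
#'
#' @param coef_table Output of [coefficient_table()] across windows.
#' @param windows The window lengths expected (default `c(1, 2, 3, 7, 10)`).
#' @return Tibble grouped by `metric`, `sex`, `habitat` with `tau`,
#'   `n_windows`, `complete` and a list-column `abs_beta1` of per-window
#'   absolute coefficients.
#' @export
attenuation_report <- function(coef_table, windows = c(1, 2, 3, 7, 10)) {
  assert_cols(coef_table, c("metric", "window_days", "beta1"))
  out <- coef_table |>
    dplyr::filter(!is.na(.data$window_days)) |>
    dplyr::group_by(.data$metric, .data$sex, .data$habitat) |>
    dplyr::arrange(.data$window_days, .by_group = TRUE) |>
    dplyr::summarise(
      tau = kendall_tau(abs(.data$beta1), .data$window_days),
      n_windows = dplyr::n(),
      complete = all(windows %in% .data$window_days),
      abs_beta1 = list(setNames(abs(.data$beta1), .data$window_days)),
      .groups = "drop"
    )
  if (any(!out$complete)) {
    warn(sprintf("attenuation_report: %d group(s) missing some of the requested windows",
                 sum(!out$complete)))
  }
  out
}
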