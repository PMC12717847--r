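# Speed filtering and the CTCRW state-space model.

test_that("speed filter removes displaced fixes and keeps plausible tracks", {
  # straight track at 1 m/s with one fix displaced 100 km
  t <- seq(0, 86400, by = 3600)
  fx <- tibble::tibble(seal_id = "s1", time = t, x = t * 1.0, y = 0)
  fx$y[10] <- 1e5
  kept <- speed_filter(fx)
  expect_equal(nrow(kept), length(t) - 1)
  expect_false(1e5 %in% kept$y)
  # track entirely at 2 m/s: everything retained
  fx2 <- tibble::tibble(seal_id = "s1", time = t, x = t * 2, y = 0)
  expect_equal(nrow(speed_filter(fx2)), length(t))
})

test_that("exactly the planted spikes are removed from a long track", {
  set.seed(31)
  t <- sort(runif(200, 0, 20 * 86400))
  fx <- tibble::tibble(seal_id = "s1", time = t, x = t * 0.5,
                       y = cumsum(rnorm(200, 0, 200)))
  spikes <- c(40, 100, 160)
  fx$x[spikes] <- fx$x[spikes] + 3e5
  kept <- speed_filter(fx)
  expect_equal(nrow(kept), 197)
  expect_equal(setdiff(fx$x, kept$x), fx$x[spikes])
  expect_error(speed_filter(fx[1:1, ]), "at least 2")
})

test_that("near-zero observation noise pins the smoothed track to the fixes", {
  tr <- sim_ctcrw_track(1, n_fix = 120, days = 10)
  fx <- tr$fixes
  fx$sd <- 1  # metres: essentially noiseless at track scale
  f <- fit_ctcrw(fx)
  expect_lt(max(abs(f$states$x - fx$x)), 5)
  expect_lt(max(abs(f$states$y - fx$y)), 5)
  # posterior SD at observation times never exceeds the observation SD
  # (information is never lost; 1% numerical headroom)
  expect_true(all(f$states$x_se <= fx$sd * 1.01))
})

test_that("parameters recover and smoothing beats the raw fixes", {
  res <- purrr::map_dfr(1:5, function(s) {
    tr <- sim_ctcrw_track(s)
    f <- fit_ctcrw(speed_filter(tr$fixes))
    keep <- tr$truth$time >= min(f$fixes$time) & tr$truth$time <= max(f$fixes$time)
    pr <- predict_positions(f, tr$truth$time[keep])
    tru <- tr$truth[keep, ]
    tibble::tibble(beta = f$beta, sigma = f$sigma,
                   rmse = sqrt(mean((pr$x - tru$x)^2 + (pr$y - tru$y)^2) / 2),
                   mean_sd = mean(f$fixes$sd))
  })
  expect_lt(abs(mean(res$beta) - 1 / 86400) / (1 / 86400), 0.25)
  expect_lt(abs(mean(res$sigma) - sim_ctcrw_track(1)$sigma) /
              sim_ctcrw_track(1)$sigma, 0.25)
  expect_lt(mean(res$rmse / res$mean_sd), 0.6)
})

test_that("inflating observation noise inflates posterior variance everywhere", {
  tr <- sim_ctcrw_track(3, n_fix = 150, days = 15)
  f1 <- fit_ctcrw(tr$fixes)
  fx2 <- tr$fixes
  f2 <- fit_ctcrw(fx2, classes = dplyr::mutate(argos_class_defaults(),
                                               sd = sd * 2))
  # compare at fixed parameters: rerun the smoother of fit 1 with doubled SDs
  fx3 <- f1$fixes; fx3$sd <- fx3$sd * 2
  k1 <- driftforage:::.ctcrw_kalman_cpp(f1$fixes$time, f1$fixes$x, f1$fixes$sd,
                                        f1$beta, f1$sigma, TRUE)
  k2 <- driftforage:::.ctcrw_kalman_cpp(fx3$time, fx3$x, fx3$sd,
                                        f1$beta, f1$sigma, TRUE)
  expect_true(all(k2$var >= k1$var - 1e-6))
})

test_that("predictions are smoother-consistent and refuse extrapolation", {
  tr <- sim_ctcrw_track(5, n_fix = 100, days = 10)
  f <- fit_ctcrw(tr$fixes)
  at <- f$fixes$time[c(10, 50)]
  pr <- predict_positions(f, at)
  expect_equal(pr$x, f$states$x[c(10, 50)], tolerance = 1e-8)
  expect_equal(pr$x_se, f$states$x_se[c(10, 50)], tolerance = 1e-6)
  expect_error(predict_positions(f, max(f$fixes$time) + 10), "span")
  expect_silent(predict_positions(f, max(f$fixes$time) + 10,
                                  allow_extrapolate = TRUE))
  # between two fixes 1 s apart, the prediction variance cannot exceed
  # either neighbour's
  fx <- tr$fixes
  fx <- fx[order(fx$time), ]
  fx$time[2] <- fx$time[1] + 1
  f2 <- fit_ctcrw(fx)
  pm <- predict_positions(f2, fx$time[1] + 0.5)
  expect_lte(pm$x_se, max(f2$states$x_se[1:2]) + 1e-6)
})

test_that("smoother variance never exceeds filter variance", {
  tr <- sim_ctcrw_track(7, n_fix = 150, days = 15)
  f <- fit_ctcrw(tr$fixes)
  expect_true(all(f$states$x_se <= f$states$x_filter_se + 1e-9))
  expect_true(all(f$states$y_se <= f$states$y_filter_se + 1e-9))
})

test_that("time reversal mirrors the smoothed means", {
  tr <- sim_ctcrw_track(9, n_fix = 80, days = 8)
  f <- fit_ctcrw(tr$fixes)
  rev_fx <- tr$fixes
  rev_fx$time <- max(tr$fixes$time) - rev(tr$fixes$time)
  rev_fx$x <- rev(tr$fixes$x); rev_fx$y <- rev(tr$fixes$y)
  rev_fx$class <- rev(tr$fixes$class)
  k_f <- driftforage:::.ctcrw_kalman_cpp(f$fixes$time, f$fixes$x, f$fixes$sd,
                                         f$beta, f$sigma, TRUE)
  sdv <- rev(f$fixes$sd)
  k_r <- driftforage:::.ctcrw_kalman_cpp(rev_fx$time, rev_fx$x, sdv,
                                         f$beta, f$sigma, TRUE)
  expect_equal(rev(k_r$x), k_f$x, tolerance = 1e-6)
})

test_that("tidy and glance expose the movement parameters", {
  tr <- sim_ctcrw_track(2, n_fix = 80, days = 8)
  f <- fit_ctcrw(tr$fixes)
  td <- tidy(f)
  expect_equal(td$term, c("beta", "sigma", "rms_speed"))
  gl <- glance(f)
  expect_equal(gl$nobs, 80)
  expect_true(is.finite(gl$logLik))
})
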