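# The four dive-effort metrics, window aggregation, habitat classification.

test_that("transit rates are the inflection-point ratios", {
  d <- tibble::tibble(
    seal_id = "s1", dive_id = "d1", start_time = 0,
    t1 = 50, t2 = 500, t3 = 700, t4 = 1100,
    d1 = 100, d2 = 160, d3 = 140, d4 = 150,
    max_depth = 160, duration = 1200, surface_interval = 120)
  tr <- transit_rates(d)
  expect_equal(tr$descent_rate, 100 / 50)   # 2.0 m/s
  expect_equal(tr$ascent_rate, 150 / 100)   # 1.5 m/s
  # symmetric V dive: descent equals ascent
  d2 <- dplyr::mutate(d, t1 = 300, t4 = 900, d1 = 450, d4 = 450,
                      t2 = 400, t3 = 500, d2 = 440, d3 = 450)
  tr2 <- transit_rates(d2)
  expect_equal(tr2$descent_rate, tr2$ascent_rate)
  # degenerate transit dropped with a message
  d3 <- dplyr::mutate(d, t4 = 1200)
  expect_message(out <- transit_rates(d3), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("dive residuals are OLS residuals of duration on depth", {
  set.seed(2)
  d <- tibble::tibble(seal_id = rep(c("a", "b"), each = 25),
                      max_depth = runif(50, 100, 900))
  d$duration <- 200 + 1.5 * d$max_depth + rnorm(50, 0, 40)
  out <- dive_residual(d)
  expect_equal(sum(out$dive_residual), 0, tolerance = 1e-8)
  ref <- resid(lm(duration ~ max_depth, data = d))
  expect_equal(out$dive_residual, unname(ref))
  # two dives at equal depth with durations d +- delta sit at +- delta
  d2 <- d
  d2$max_depth[1:2] <- 500
  d2$duration[1:2] <- predict(lm(duration ~ max_depth, data = d2[-(1:2), ]),
                              tibble::tibble(max_depth = 500)) + c(30, -30)
  out2 <- dive_residual(d2)
  expect_equal(out2$dive_residual[1] - out2$dive_residual[2], 60,
               tolerance = 1.5)
  expect_error(dive_residual(d[1:10, ]), "at least 30")
  d$max_depth <- 400
  expect_error(dive_residual(d), "degenerate")
})

test_that("pooled depth-duration slope is positive on simulator output", {
  b <- simulate_world(sim_config(n_seals = 3, days_per_seal = 20, seed = 23))
  dv <- filter_dives(b$dives)$dives
  expect_gt(coef(lm(duration ~ max_depth, data = dv))[["max_depth"]], 0)
})

test_that("surface residual uses a tau-quantile minimum envelope", {
  set.seed(9)
  n <- 10000
  d <- tibble::tibble(seal_id = "s1", duration = runif(n, 300, 2000))
  d$surface_interval <- 60 + 0.05 * d$duration + rexp(n, 1 / 40)
  out <- surface_residual(d, tau = 0.05)
  frac_neg <- mean(out$surface_residual < 0)
  expect_lt(abs(frac_neg - 0.05), 0.02)
  # adding 60 s to every interval shifts the fitted envelope by the same
  # amount, so residuals against the refitted envelope are unchanged; against
  # the original envelope they shift by exactly +60
  d2 <- dplyr::mutate(d, surface_interval = surface_interval + 60)
  out2 <- surface_residual(d2, tau = 0.05)
  expect_equal(out2$surface_residual, out$surface_residual, tolerance = 0.5)
  qf <- quantile_line(d$duration, d$surface_interval, tau = 0.05)
  fixed_env <- qf$intercept + qf$slope * d$duration
  expect_equal((d2$surface_interval - fixed_env) -
                 (d$surface_interval - fixed_env), rep(60, nrow(d)))
  expect_error(surface_residual(d[1:50, ]), "at least 100")
})

test_that("quantile_line minimises pinball loss near the true quantile line", {
  set.seed(11)
  x <- runif(5000, 0, 10)
  y <- 2 + 0.7 * x + rexp(5000, 1)   # exact tau->0 envelope: 2 + 0.7 x
  qf <- quantile_line(x, y, tau = 0.05)
  expect_lt(abs(qf$slope - 0.7), 0.05)
  expect_lt(abs(qf$intercept - (2 + qexp(0.05))), 0.15)
})

test_that("window aggregation averages metrics within the dDR windows", {
  metrics <- tibble::tibble(
    seal_id = "s1", dive_id = sprintf("d%d", 1:12),
    day = rep(1:2, each = 6),
    descent_rate = c(rep(1.0, 3), rep(1.2, 3), rep(1.4, 6)),
    ascent_rate = 1, dive_residual = 0, surface_residual = 10)
  win <- tibble::tibble(
    seal_id = "s1", window_days = 1, block = 0:1,
    day_start = 1:2, day_end = 1:2, mid_day = c(1, 2),
    n_days = 1L, n_segments = 1L,
    dr_window = c(-0.3, -0.28), ddr = c(NA, 0.02))
  out <- window_aggregate(metrics, win, min_dives = 5)
  expect_equal(out$descent_rate, c(1.1, 1.4))
  expect_equal(out$n_dives, c(6L, 6L))
  # invariant to within-window dive order
  out2 <- window_aggregate(metrics[sample(12), ], win, min_dives = 5)
  expect_equal(dplyr::arrange(out2, block)$descent_rate, out$descent_rate)
  # sparse windows are dropped and counted
  out3 <- window_aggregate(metrics, win, min_dives = 7)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_dropped_sparse"), 2L)
})

test_that("window record count never exceeds ceiling(days / w)", {
  b <- simulate_world(sim_config(n_seals = 3, days_per_seal = 30, seed = 25))
  fl <- filter_dives(b$dives)
  suppressMessages(est <- kalman_screen(candidate_segments(fl$dives)))
  daily <- daily_drift_rate(est)
  met <- compute_dive_metrics(fl$dives)
  for (w in c(1, 3, 7)) {
    rec <- window_aggregate(met, delta_dr(daily, w), min_dives = 1)
    per_seal <- table(rec$seal_id)
    expect_true(all(per_seal <= ceiling(30 / w)))
  }
})

test_that("habitat splits at the 1,500 m isobath with the strict boundary", {
  bathy <- make_bathymetry()
  # depth field is linear: find positions at known depths
  sp <- bathymetry_spec()
  y_at <- function(target, x) (target - sp$offset - sp$gx * x) / sp$gy
  expect_equal(classify_habitat(bathy, 1e5, y_at(800, 1e5)), "shelf")
  expect_equal(classify_habitat(bathy, 1e5, y_at(3500, 1e5)), "oceanic")
  # exactly 1,500 m is oceanic (strict "shallower" reading)
  expect_equal(classify_habitat(bathy, 1e5, y_at(1500, 1e5)), "oceanic")
  expect_true(is.na(classify_habitat(bathy, -1, -1)))
})

test_that("bathymetry grids round-trip through the plain-text format", {
  b <- make_bathymetry()
  path <- withr::local_tempfile(fileext = ".grid")
  write_bathymetry(b, path)
  b2 <- read_bathymetry(path)
  expect_equal(b2$x, b$x)
  expect_equal(b2$y, b$y)
  expect_equal(b2$z, b$z)
  # bilinear interpolation reproduces the linear field exactly
  expect_equal(bathy_depth(b2, 123456, 654321),
               sp <- with(bathymetry_spec(), offset + gx * 123456 + gy * 654321))
})
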