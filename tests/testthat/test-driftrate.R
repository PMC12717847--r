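# Drift-segment candidates, Kalman screening, daily drift rate, windowed dDR.

test_that("candidates come only from deep dives with long slow interior segments", {
  # shallow dive (90 m) with a slow interior segment: no candidates
  d <- tibble::tibble(
    seal_id = "s1", dive_id = c("a", "b", "c"), start_time = c(0, 4000, 8000),
    t1 = c(100, 100, 100), t2 = c(400, 400, 180),
    t3 = c(448, 448, 260), t4 = c(496, 496, 340),
    d1 = c(90, 400, 450), d2 = c(80, 475, 330),
    d3 = c(85, 430, 450), d4 = c(82, 475, 330),
    max_depth = c(90, 475, 450), duration = c(600, 900, 700),
    surface_interval = 120)
  cands <- candidate_segments(d)
  expect_false("a" %in% cands$dive_id)       # too shallow
  # dive b: planted drift segment at depth rate +0.25 (sinking at 0.25 m/s)
  cb <- cands[cands$dive_id == "b", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$speed, -0.25)
  expect_equal(cb$segment, 2L)
  # dive c: V-shaped transits at 1.5 m/s, no slow segment
  expect_false("c" %in% cands$dive_id)
})

test_that("planted drift segments from the simulator are recovered exactly", {
  p <- simulate_dive(list(dr = -0.25, seafloor = 2000, depth = 500,
                          drift = list(duration = 300, speed = -0.25)),
                     seed = 8)
  v <- attr(p, "vertices")
  v$seal_id <- "s1"; v$dive_id <- "d1"; v$start_time <- 0
  cands <- candidate_segments(v)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$speed, -0.25, tolerance = 1e-9)
})

test_that("screening retains smooth trajectories and rejects contaminants", {
  # pure inlier limit: all points near a smooth trajectory
  cc <- contaminated_candidates(1, n = 150, contam_rate = 0)
  z <- kalman_screen(cc)
  expect_gt(mean(z$z > 0.5), 0.9)
  # 20% active-swim contaminants
  cc2 <- contaminated_candidates(2, n = 200, contam_rate = 0.2)
  z2 <- kalman_screen(cc2)
  expect_gt(mean(z2$retained[!cc2$contam]), 0.8)
  contam_frac <- sum(z2$retained & cc2$contam) / sum(z2$retained)
  expect_lt(contam_frac, 0.05)
})

test_that("a single extreme outlier has Z below 0.5, monotonely in distance", {
  set.seed(4)
  n <- 60
  cand <- tibble::tibble(seal_id = "s1", time = (1:n) * 43200,
                         speed = rnorm(n, -0.02, 0.004))
  zs <- purrr::map_dbl(c(0.2, 0.5, 1.0), function(off) {
    x <- cand; x$speed[30] <- off
    kalman_screen(x)$z[30]
  })
  expect_lt(zs[3], 0.5)
  expect_true(all(diff(zs) <= 1e-6))  # moving further never raises Z
})

test_that("Z is invariant to a location shift of all speeds", {
  cc <- contaminated_candidates(5, n = 120, contam_rate = 0.15)
  z1 <- kalman_screen(cc)$z
  cc2 <- cc; cc2$speed <- cc2$speed + 0.3
  z2 <- kalman_screen(cc2)$z
  expect_equal(z1, z2, tolerance = 1e-6)
})

test_that("seals with too few candidates are left unscreened", {
  cand <- tibble::tibble(seal_id = "s1", time = (1:3) * 86400,
                         speed = c(-0.2, -0.21, -0.19))
  expect_message(out <- kalman_screen(cand), "unscreened")
  expect_true(all(is.na(out$z)))
  expect_false(any(out$retained))
})

test_that("daily drift rate is the unweighted mean; empty days stay missing", {
  est <- tibble::tibble(
    seal_id = "s1",
    time = c(3600, 7200, 90000, 260000),
    speed = c(-0.20, -0.22, -0.30, 0.5),
    retained = c(TRUE, TRUE, TRUE, FALSE))
  daily <- daily_drift_rate(est)
  expect_equal(daily$dr[daily$day == 1], -0.21)
  expect_equal(daily$n_segments[daily$day == 1], 2L)
  expect_false(2 %in% daily$day[daily$seal_id == "s1" & daily$n_segments == 0])
  expect_false(4 %in% daily$day)   # day with only a rejected segment
})

test_that("windowed dDR follows the block arithmetic", {
  daily <- tibble::tibble(seal_id = "s1", day = 1:4,
                          dr = c(-0.3, -0.28, -0.25, -0.24),
                          n_segments = 1L)
  w2 <- delta_dr(daily, 2)
  expect_equal(w2$dr_window, c(-0.29, -0.245))
  expect_equal(w2$ddr, c(NA, 0.045))
  # constant series: all dDR zero
  daily2 <- tibble::tibble(seal_id = "s1", day = 1:10, dr = -0.2,
                           n_segments = 1L)
  w5 <- delta_dr(daily2, 5)
  expect_true(all(w5$ddr[-1] == 0))
  # w = 1 equals day-to-day differences where both days observed
  daily3 <- tibble::tibble(seal_id = "s1", day = c(1, 2, 3, 5, 6),
                           dr = c(-0.3, -0.27, -0.26, -0.2, -0.21),
                           n_segments = 1L)
  w1 <- delta_dr(daily3, 1)
  expect_equal(w1$ddr, c(NA, 0.03, 0.01, NA, -0.01))
})

test_that("dDR propagates missingness and respects min_segments", {
  daily <- tibble::tibble(seal_id = "s1", day = c(1, 2, 3, 4),
                          dr = c(-0.3, -0.28, -0.26, -0.24),
                          n_segments = c(1L, 1L, 3L, 3L))
  w2 <- delta_dr(daily, 2, min_segments = 3)
  expect_equal(nrow(w2), 1)          # only the second block qualifies
  expect_true(is.na(w2$ddr))         # its predecessor is missing
})

test_that("windowed dDR on a simulated bundle tracks the generative truth", {
  b <- simulate_world(sim_config(n_seals = 10, days_per_seal = 90, seed = 19))
  fl <- filter_dives(b$dives)
  suppressMessages(est <- kalman_screen(candidate_segments(fl$dives)))
  daily <- daily_drift_rate(est)
  cmp <- merge(daily, b$truth[, c("seal_id", "day", "dr_true")])
  expect_lt(sqrt(mean((cmp$dr - cmp$dr_true)^2)), 0.02)
  w1 <- delta_dr(daily, 1)
  w1$day <- w1$mid_day
  cmp2 <- merge(w1[!is.na(w1$ddr), ], b$truth[, c("seal_id", "day", "ddr_true")])
  expect_gt(cor(cmp2$ddr, cmp2$ddr_true), 0.8)
})
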