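# Synthetic world generator.

test_that("a fixed seed reproduces the bundle exactly", {
  cfg <- sim_config(n_seals = 2, days_per_seal = 8, seed = 4)
  b1 <- simulate_world(cfg)
  b2 <- simulate_world(cfg)
  expect_identical(b1$dives, b2$dives)
  expect_identical(b1$fixes, b2$fixes)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_world(sim_config(n_seals = 2, days_per_seal = 8, seed = 5))
  expect_false(identical(b1$dives, b3$dives))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(drift_dive_prob = 1.4), "probability")
  expect_error(sim_config(transmitted_dives_range = c(0, 10)), "1, 186")
  expect_error(sim_config(transmitted_dives_range = c(5, 200)), "1, 186")
  expect_error(sim_config(gain_scale = NaN), "gain_scale")
  expect_error(sim_config(n_seals = 0), "positive")
})

test_that("drift segments occur at the configured rate and only in deep dives", {
  b <- simulate_world(sim_config(n_seals = 10, days_per_seal = 100,
                                 drift_dive_prob = 0.035, seed = 12))
  dt <- b$dive_truth
  deep <- dt[merge(dt, b$dives, by = c("seal_id", "dive_id"))$max_depth > 100, ]
  # no drift segments in shallow dives
  shallow_ids <- b$dives$dive_id[b$dives$max_depth <= 100]
  expect_false(any(dt$is_drift[dt$dive_id %in% shallow_ids]))
  # fraction of eligible dives carrying a drift segment within binomial
  # 99% bounds of 0.035
  dv <- merge(b$dives, dt, by = c("seal_id", "dive_id"))
  eligible <- dv[dv$max_depth > 100 | dv$is_drift, ]
  n <- nrow(eligible); k <- sum(eligible$is_drift)
  bounds <- qbinom(c(0.005, 0.995), n, 0.035)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("drift-rate trajectories start negative, stay in range, and rise", {
  b <- simulate_world(sim_config(n_seals = 8, days_per_seal = 120, seed = 3))
  tr <- b$truth
  expect_true(all(tr$dr_true >= -0.35 - 1e-9 & tr$dr_true <= 0.10 + 1e-9))
  first <- tapply(tr$dr_true, tr$seal_id, function(x) x[1])
  last <- tapply(tr$dr_true, tr$seal_id, function(x) mean(tail(x, 20)))
  expect_true(all(first < 0))
  expect_gt(mean(last - first), 0)  # progressive increase in buoyancy
})

test_that("surface residuals are generatively unlinked to foraging success", {
  b <- simulate_world(sim_config(n_seals = 10, days_per_seal = 60, seed = 21))
  dv <- merge(b$dives, b$dive_truth, by = c("seal_id", "dive_id"))
  # per-day mean surface offset (duration trend removed) vs true daily dDR
  dv$surf_off <- dv$surface_interval - 0.04 * dv$duration
  agg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(dv), seal_id, day),
                          surf = mean(surf_off), .groups = "drop")
  agg <- merge(agg, b$truth[, c("seal_id", "day", "ddr_true")])
  ct <- cor.test(agg$surf, agg$ddr_true)
  expect_gt(ct$p.value, 0.05)
})

test_that("generated descent rates recover gamma_descent in a binned regression", {
  b <- simulate_world(sim_config(n_seals = 30, days_per_seal = 180, seed = 8))
  dv <- merge(b$dives, b$dive_truth, by = c("seal_id", "dive_id"))
  dv <- dv[dv$max_depth > 100 & !dv$is_drift, ]
  dv$descent <- dv$d1 / dv$t1
  dv$bin <- cut(dv$dr_true, breaks = unique(quantile(dv$dr_true, seq(0, 1, 0.1))),
                include.lowest = TRUE)
  fit <- lm(descent ~ ddr_true + bin + max_depth, data = dv)
  expect_lt(abs(coef(fit)[["ddr_true"]] - 3) / 3, 0.15)
})

test_that("dive profiles respect the sampling grid, surface endpoints and seafloor", {
  p <- simulate_dive(list(dr = -0.2, seafloor = 500, depth = 800), seed = 2)
  expect_lte(max(p$depth), 500)
  expect_equal(p$depth[1], 0)
  expect_equal(p$depth[nrow(p)], 0)
  expect_true(all(p$depth >= 0))
  expect_equal(unique(diff(p$time)), 4)

  # requested drift segment: 300 s at -0.25 m/s from 400 m sinks 75 m
  pd <- simulate_dive(list(dr = -0.25, seafloor = 2000, depth = 400,
                           drift = list(duration = 300, speed = -0.25)),
                      seed = 3)
  v <- attr(pd, "vertices")
  expect_equal(v$d2 - v$d1, 75)
  expect_equal(v$t2 - v$t1, 300)
  ds <- attr(pd, "drift_segment")
  expect_equal(ds$speed, -0.25)

  # sample count is duration / interval + 1, both endpoints included:
  # a 20-minute dive sampled at 4 s has 301 samples
  v20 <- tibble::tibble(seal_id = "s", dive_id = "d", start_time = 0,
                        t1 = 300, t2 = 500, t3 = 700, t4 = 900,
                        d1 = 400, d2 = 420, d3 = 410, d4 = 400,
                        duration = 1200, surface_interval = 120)
  expect_equal(nrow(driftforage:::expand_profiles(v20)), 301)
  expect_equal(nrow(pd), max(pd$time) / 4 + 1)
})

test_that("ARGOS noise matches the class error model", {
  truth <- tibble::tibble(seal_id = "s1", time = seq_len(10000),
                          x = 0, y = 0, class = "B")
  fx <- add_argos_noise(truth, seed = 6)
  expect_equal(fx$sd[1], 10000)
  expect_lt(abs(sd(fx$x) - 10000) / 10000, 0.05)
  # zero-noise classes reproduce the truth; empty input stays empty
  cls0 <- tibble::tibble(class = "B", sd = 0, prob = 1)
  fx0 <- add_argos_noise(truth, classes = cls0)
  expect_equal(fx0$x, truth$x)
  expect_equal(nrow(add_argos_noise(truth[0, ])), 0)
})

test_that("schedules respect the configured transmission regimes", {
  b <- simulate_world(sim_config(n_seals = 4, days_per_seal = 40, seed = 14))
  fx_per_day <- table(b$fixes$seal_id, floor(b$fixes$time / 86400))
  expect_true(all(fx_per_day >= 2 & fx_per_day <= 15))
  expect_true(all(b$truth$n_dives_transmitted <= 30))
  expect_true(all(b$truth$n_dives_transmitted <=
                    b$truth$n_dives_performed))
})

test_that("a bundle writes its observable tables, bathymetry and truth", {
  b <- simulate_world(sim_config(n_seals = 1, days_per_seal = 5, seed = 40))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_setequal(list.files(dir),
                  c("dives.csv", "fixes.csv", "truth.csv", "bathymetry.grid",
                    "truth_params.json"))
  back <- read_dive_table(file.path(dir, "dives.csv"))
  expect_equal(nrow(back), nrow(b$dives))
  tp <- jsonlite::read_json(file.path(dir, "truth_params.json"))
  expect_equal(tp$gamma$descent, 3)
})
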