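# Penalized additive mixed model with continuous AR1 errors.

test_that("design has the documented dimensions and a partition-of-unity basis", {
  dat <- make_pamm_data(1, n_seal = 12, n_day = 20)
  d <- build_design(dat, "y")
  expect_equal(ncol(d$X), 3)                  # intercept, ddr, linear dr
  expect_equal(ncol(d$Xs), 8)                 # 10-basis rank-8 penalty range
  expect_equal(d$n_seals, 12)
  # raw B-spline basis sums to one at interior points (before the
  # mixed-model reparameterisation)
  sm <- d$smooth
  grid <- seq(min(dat$dr_window), max(dat$dr_window), length.out = 7)
  B <- splines::splineDesign(sm$knots, grid, ord = 4, outer.ok = TRUE)
  expect_equal(rowSums(B), rep(1, 7))
  # degenerate smooth covariate is rejected
  dat2 <- dat; dat2$dr_window <- -0.2
  expect_error(build_design(dat2, "y"), "constant")
  # rank deficiency is reported with the offending column
  dat3 <- dat; dat3$ddr <- 0
  expect_error(build_design(dat3, "y", include_smooth = FALSE), "ddr")
})

test_that("with no smooth, no random effects and phi = 0 the fit is exactly OLS", {
  dat <- make_pamm_data(2, n_seal = 10, n_day = 25, sd_slope = 0,
                        sd_int = 0, phi = 0, smooth_amp = 0)
  f <- fit_pamm(build_design(dat, "y", include_smooth = FALSE,
                             random_effects = FALSE), phi = 0)
  ols <- lm(y ~ ddr, data = dat)
  expect_equal(f$beta1, unname(coef(ols)["ddr"]), tolerance = 1e-7)
  expect_equal(f$beta1_se, unname(summary(ols)$coefficients["ddr", 2]),
               tolerance = 1e-7)
})

test_that("phi recovers in the independence limit and at moderate correlation", {
  dat0 <- make_pamm_data(3, n_seal = 15, n_day = 60, phi = 0,
                         sd_int = 0, sd_slope = 0, smooth_amp = 0)
  f0 <- fit_pamm(build_design(dat0, "y", include_smooth = FALSE,
                              random_effects = FALSE))
  expect_lt(f0$phi, 0.2)
  dat5 <- make_pamm_data(4, n_seal = 15, n_day = 60, phi = 0.5,
                         sd_int = 0, sd_slope = 0, smooth_amp = 0)
  f5 <- fit_pamm(build_design(dat5, "y", include_smooth = FALSE,
                              random_effects = FALSE))
  expect_gt(f5$phi, 0.3)
  expect_lt(f5$phi, 0.7)
})

test_that("zero random-slope variance collapses to the fixed-effects fit", {
  # informative ddr (the slope covariate) so the slope variance is well
  # identified; generated without random slopes
  set.seed(55)
  dat <- make_pamm_data(5, n_seal = 15, n_day = 40, sd_slope = 0,
                        sd_int = 0.3)
  dat$ddr <- rnorm(nrow(dat), 0, 0.05)
  dat$y <- dat$y + 2 * (dat$ddr)  # add back the effect on the new covariate
  f <- fit_pamm(build_design(dat, "y"))
  # slope variance is negligible at the scale of its covariate
  expect_lt(f$var_slope * var(dat$ddr), 0.05 * f$sigma2)
  f_fix <- fit_pamm(build_design(dat, "y", random_effects = FALSE))
  expect_lt(abs(f$beta1_se - f_fix$beta1_se) / f_fix$beta1_se, 0.1)
  expect_lt(abs(f$beta1 - f_fix$beta1), 2 * f$beta1_se)
})

test_that("the accepted REML optimum does not exceed the starting objective", {
  dat <- make_pamm_data(6, n_seal = 12, n_day = 30)
  f <- fit_pamm(build_design(dat, "y"))
  expect_lte(f$objective_final, f$objective_start + 1e-6)
  expect_true(f$phi > 0 && f$phi < 1)
  expect_true(all(c(f$var_intercept, f$var_slope, f$sigma2) >= 0))
})

test_that("estimates agree with an independent mgcv::gamm fit", {
  skip_if_not_installed("mgcv")
  skip_if_not_installed("nlme")
  dat <- make_pamm_data(33, n_seal = 20, n_day = 50)
  f <- fit_pamm(build_design(dat, "y"))
  dat$seal <- factor(dat$seal_id)
  g <- mgcv::gamm(y ~ ddr + s(dr_window, k = 10),
                  random = list(seal = ~ 1 + ddr),
                  correlation = nlme::corCAR1(form = ~ mid_day | seal),
                  data = dat)
  sg <- summary(g$gam)
  expect_equal(f$beta1, unname(sg$p.coeff["ddr"]), tolerance = 0.02)
  expect_equal(f$beta1_se, unname(sg$se["ddr"]), tolerance = 0.1)
})

test_that("the smooth estimate tracks the generative buoyancy curve", {
  dat <- make_pamm_data(7, n_seal = 20, n_day = 60, smooth_amp = 0.8,
                        sd_int = 0.2, sd_slope = 0.2)
  f <- fit_pamm(build_design(dat, "y"))
  grid <- seq(-0.3, -0.05, length.out = 30)
  sm <- smooth_estimate(f, at = grid)
  truth <- 0.8 * tanh((grid + 0.125) / 0.12)
  # compare shapes after centering both
  expect_gt(cor(sm$estimate - mean(sm$estimate), truth - mean(truth)), 0.95)
})

test_that("coefficient table flags significance as printed", {
  dat <- make_pamm_data(8, n_seal = 12, n_day = 25)
  f <- fit_pamm(build_design(dat, "y", meta = list(window_days = 1)))
  # synthesise three fits with controlled p-values via direct flagging
  expect_equal(driftforage:::signif_flag(0.03), "sig")
  expect_equal(driftforage:::signif_flag(0.07), "~")
  expect_equal(driftforage:::signif_flag(0.5), "ns")
  ct <- coefficient_table(list(f))
  expect_equal(ct$metric, "y")
  expect_equal(ct$window_days, 1)
  expect_true(ct$flag %in% c("sig", "~", "ns"))
})

test_that("attenuation report computes Kendall tau with tie handling", {
  fits_df <- tibble::tibble(
    metric = "descent_rate", sex = "all", habitat = "all",
    window_days = c(1, 2, 3, 7, 10),
    beta1 = c(3, 2, 1.5, 0.8, 0.5), se = 0.1, p = 0.01, flag = "sig",
    r2_fitted_obs = 0.3, n = 100)
  rep <- attenuation_report(fits_df)
  expect_equal(rep$tau, -1)
  # identical coefficients across windows give tau 0
  fits_df$beta1 <- 2
  expect_equal(attenuation_report(fits_df)$tau, 0)
  # missing windows flagged as partial
  expect_warning(out <- attenuation_report(fits_df[1:3, ]), "missing")
  expect_false(out$complete)
})

test_that("tidy and glance summarise the fit in broom style", {
  dat <- make_pamm_data(9, n_seal = 10, n_day = 20)
  f <- fit_pamm(build_design(dat, "y"))
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_true("ddr" %in% td$term)
  gl <- glance(f)
  expect_equal(gl$nobs, f$n)
  expect_true(gl$r2_fitted_obs >= 0 && gl$r2_fitted_obs <= 1)
})
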