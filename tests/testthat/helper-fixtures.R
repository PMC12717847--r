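# Shared fixtures and independent oracles, built in code at test time.

# Independent naive broken-stick oracle: step-by-step greedy max-vertical-
# deviation selection with earliest-time tie-break (O(n*k) scan). Kept
# deliberately separate from the package implementation.
oracle_broken_stick <- function(t, d, k = 4) {
  sel <- c(1L, length(t))
  chosen <- integer(0)
  for (it in seq_len(k)) {
    dev <- rep(-1, length(t))
    s <- sort(sel)
    for (j in seq_len(length(s) - 1)) {
      a <- s[j]; b <- s[j + 1]
      if (b - a < 2) next
      slope <- (d[b] - d[a]) / (t[b] - t[a])
      for (i in (a + 1):(b - 1)) {
        dev[i] <- abs(d[i] - (d[a] + slope * (t[i] - t[a])))
      }
    }
    best <- which.max(dev)
    if (dev[best] < 0) {
      best <- setdiff(2:(length(t) - 1), sel)[1]
    }
    chosen <- c(chosen, best)
    sel <- c(sel, best)
  }
  chosen
}

# Random sampled dive-like profile on the 4-s grid (surface endpoints).
random_profile <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- 4 * (0:(n - 1))
  d <- c(0, runif(n - 2, 0, 500), 0)
  list(time = t, depth = d)
}

# Small clean summarised-dive table that passes every filter rule.
clean_dive_table <- function(n = 100, seed = 1) {
  withr::with_seed(seed, {
    b <- simulate_world(sim_config(n_seals = 2, days_per_seal = 30, seed = seed))
    fl <- filter_dives(b$dives)
    head(fl$dives, n)
  })
}

# Self-simulated OU-velocity track with class-mixed ARGOS noise; returns the
# noisy fixes and the true positions at independent "dive" times.
sim_ctcrw_track <- function(seed, n_fix = 500, days = 60,
                            beta = 1 / 86400, speed_sd = 0.5,
                            classes = argos_class_defaults(),
                            n_dive = 300) {
  set.seed(seed)
  sigma <- sqrt(2 * beta) * speed_sd
  ft <- sort(runif(n_fix, 0, days * 86400))
  dt_times <- sort(runif(n_dive, 0, days * 86400))
  allt <- sort(unique(c(ft, dt_times)))
  ax <- driftforage:::sim_ou_axis(allt, beta, sigma, 0, rnorm(1, 0, speed_sd))
  ay <- driftforage:::sim_ou_axis(allt, beta, sigma, 0, rnorm(1, 0, speed_sd))
  ci <- sample.int(nrow(classes), n_fix, TRUE, prob = classes$prob)
  fixes <- tibble::tibble(
    seal_id = "s1", time = ft,
    x = ax$x[match(ft, allt)] + rnorm(n_fix, 0, classes$sd[ci]),
    y = ay$x[match(ft, allt)] + rnorm(n_fix, 0, classes$sd[ci]),
    class = classes$class[ci])
  list(fixes = fixes,
       truth = tibble::tibble(time = dt_times,
                              x = ax$x[match(dt_times, allt)],
                              y = ay$x[match(dt_times, allt)]),
       beta = beta, sigma = sigma)
}

# Labelled drift-rate candidate series with planted active-swim contaminants.
contaminated_candidates <- function(seed, n = 200, contam_rate = 0.2) {
  set.seed(seed)
  t <- sort(cumsum(rexp(n, 2)))
  dr <- -0.3 + cumsum(rnorm(n, 0.0015, 0.02 * sqrt(c(0.5, diff(t)))))
  v <- dr + rnorm(n, 0, 0.002)
  contam <- runif(n) < contam_rate
  v[contam] <- sample(c(-1, 1), sum(contam), TRUE) * runif(sum(contam), 0.5, 1.5)
  tibble::tibble(seal_id = "s1", time = t * 86400, speed = v, contam = contam)
}

# Window-record-like data with known linear effect, AR1 errors and optional
# per-seal random effects, for response-model tests.
make_pamm_data <- function(seed, n_seal = 15, n_day = 50, beta1 = 2,
                           sd_int = 0.5, sd_slope = 0.6, phi = 0.4,
                           sd_e = 0.3, smooth_amp = 0.8) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_seal), function(i) {
    u <- rnorm(1, 0, sd_int)
    s <- rnorm(1, beta1, sd_slope)
    dr <- -0.3 + cumsum(rnorm(n_day, 0.004, 0.015))
    ddr <- c(0, diff(dr))
    e <- numeric(n_day)
    e[1] <- rnorm(1, 0, sd_e)
    if (n_day > 1) {
      for (d in 2:n_day) {
        e[d] <- phi * e[d - 1] + rnorm(1, 0, sd_e * sqrt(1 - phi^2))
      }
    }
    tibble::tibble(seal_id = sprintf("s%02d", i), mid_day = seq_len(n_day),
                   ddr = ddr, dr_window = dr,
                   y = 1 + u + s * ddr +
                     smooth_amp * tanh((dr + 0.125) / 0.12) + e)
  })
}
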