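# End-to-end orchestration: configuration, staged execution, artifact
# manifest, and the parameter-recovery experiment harness.

#' Pipeline configuration
#'
#' Assembles and validates the full analysis configuration. Either the
#' simulate stage is enabled (synthetic data, the default) or input paths
#' must be supplied for the dive table, ARGOS fixes, and — when habitat
#' classification is enabled — a bathymetry grid file.
#'
#' @param simulate `NULL` to disable the simulate stage, otherwise a list of
#'   [sim_config()] arguments (the pipeline seed overrides `seed`).
#' @param inputs List of paths (`dive_table`, `fixes`, `bathymetry`) used
#'   when `simulate` is `NULL`.
#' @param windows Window lengths in days (default `c(1, 2, 3, 7, 10)`).
#' @param window_mode `"block"` or `"running"` (see [delta_dr()]).
#' @param min_segments,min_dives Sparsity thresholds for drift windows and
#'   window records.
#' @param classify_habitat Classify window records against the 1,500 m
#'   isobath (default TRUE).
#' @param metrics Response metrics to model.
#' @param stratify `"none"` (pooled fits), `"habitat"`, `"sex"`, or
#'   `"sex_habitat"` (sex requires simulated data, which carries the label).
#' @param basis_dim Spline rank for the drift-rate smooth.
#' @param trackfit_restarts Optimiser restarts for the track model.
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory (`NULL` keeps results in memory only).
#' @param resume Do not rewrite stage outputs already present in `out_dir`;
#'   all stages are deterministic given `seed`, so a resumed rerun yields an
#'   identical manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), inputs = list(),
                            windows = c(1, 2, 3, 7, 10),
                            window_mode = c("block", "running"),
                            min_segments = 1, min_dives = 5,
                            classify_habitat = TRUE,
                            metrics = c("descent_rate", "ascent_rate",
                                        "dive_residual", "surface_residual"),
                            stratify = c("none", "habitat", "sex",
                                         "sex_habitat"),
                            basis_dim = 10,
                            trackfit_restarts = 3,
                            seed = 1L, out_dir = NULL, resume = FALSE) {
  cfg <- list(simulate = simulate, inputs = inputs, windows = windows,
              window_mode = match.arg(window_mode),
              min_segments = min_segments, min_dives = min_dives,
              classify_habitat = classify_habitat, metrics = metrics,
              stratify = match.arg(stratify), basis_dim = basis_dim,
              trackfit_restarts = trackfit_restarts,
              seed = as.integer(seed), out_dir = out_dir, resume = resume)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!is.numeric(cfg$windows) || any(cfg$windows < 1)) {
    abort("`windows` must be positive day counts")
  }
  assert_scalar_num(cfg$seed, "seed")
  if (is.null(cfg$simulate)) {
    for (f in c("dive_table", "fixes")) {
      if (is.null(cfg$inputs[[f]])) {
        abort(sprintf("simulate stage disabled but `inputs$%s` is missing", f))
      }
    }
    if (isTRUE(cfg$classify_habitat) && is.null(cfg$inputs$bathymetry)) {
      abort("habitat classification enabled but `inputs$bathymetry` is missing")
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load inputs), abstract (broken-stick
#' summarisation when high-resolution profiles are present), filter,
#' trackfit, driftrate, divemetrics, model, report. Each stage logs row
#' counts and drop reasons; when `out_dir` is set, stage outputs are written
#' as CSV/JSON and a manifest with md5 checksums is produced. With
#' `resume = TRUE`, stage outputs already present in `out_dir` are reused.
#'
#' @param config A `pipeline_config`, a list of its arguments, or a YAML
#'   path.
#' @return A `pipeline_result` list: `bundle` (when simulated), `dives`,
#'   `filter_report`, `track_fits`, `positions`, `daily_dr`, `windows`
#'   (per window length), `records`, `fits`, `coefficients`, `attenuation`,
#'   `manifest` (when written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage_path <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  reuse <- function(name) {
    isTRUE(config$resume) && !is.null(out_dir) && file.exists(stage_path(name))
  }

  log_msg <- function(...) inform(sprintf(...))
  bundle <- NULL

  # --- simulate / load -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- utils::modifyList(config$simulate, list(seed = config$seed))
    bundle <- simulate_world(do.call(sim_config, sim_args))
    dives_raw <- bundle$dives
    fixes <- bundle$fixes
    bathy <- bundle$bathy
    log_msg("simulate: %d dives, %d fixes, %d seals",
            nrow(dives_raw), nrow(fixes), nrow(bundle$seals))
    # --- abstract ------------------------------------------------------------
    if (!is.null(bundle$profiles)) {
      dives_raw <- summarise_dives(bundle$profiles)
      log_msg("abstract: summarised %d profiles via broken-stick", nrow(dives_raw))
    }
  } else {
    dives_raw <- read_dive_table(config$inputs$dive_table,
                                 dialect = config$inputs$dialect %||% "native")
    fixes <- readr::read_csv(config$inputs$fixes, show_col_types = FALSE,
                             progress = FALSE)
    bathy <- if (!is.null(config$inputs$bathymetry)) {
      read_bathymetry(config$inputs$bathymetry)
    } else NULL
    log_msg("load: %d dives, %d fixes", nrow(dives_raw), nrow(fixes))
  }
  if (!is.null(out_dir) && !reuse("dives_raw.csv")) {
    write_dive_table(dives_raw, stage_path("dives_raw.csv"))
  }

  # --- filter ----------------------------------------------------------------
  fl <- filter_dives(dives_raw)
  dives <- fl$dives
  log_msg("filter: retained %d / %d dives", fl$report$retained, fl$report$input)
  if (!is.null(out_dir)) {
    write_dive_table(dives, stage_path("dives_filtered.csv"))
    write_filter_report(fl$report, stage_path("filter_report.json"))
  }

  # --- trackfit --------------------------------------------------------------
  fixes_f <- speed_filter(fixes)
  log_msg("trackfit: speed filter retained %d / %d fixes", nrow(fixes_f), nrow(fixes))
  track_fits <- fit_tracks(fixes_f, n_restarts = config$trackfit_restarts)
  positions <- predict_tracks(
    track_fits, dplyr::transmute(dives, seal_id = .data$seal_id,
                                 dive_id = .data$dive_id,
                                 time = .data$start_time))
  # keep dive_id on predictions
  positions <- dplyr::left_join(
    positions,
    dplyr::transmute(dives, seal_id = .data$seal_id, time = .data$start_time,
                     dive_id = .data$dive_id),
    by = c("seal_id", "time"))
  if (!is.null(out_dir)) {
    readr::write_csv(positions, stage_path("positions.csv"), progress = FALSE)
  }

  # --- driftrate -------------------------------------------------------------
  cands <- candidate_segments(dives)
  est <- kalman_screen(cands)
  daily <- daily_drift_rate(est)
  log_msg("driftrate: %d candidates, %d retained, %d seal-days with DR",
          nrow(est), sum(est$retained), nrow(daily))
  win_list <- purrr::map(config$windows, function(w) {
    delta_dr(daily, w, min_segments = config$min_segments,
             mode = config$window_mode)
  })
  names(win_list) <- paste0("w", config$windows)
  if (!is.null(out_dir)) {
    readr::write_csv(est, stage_path("drift_estimates.csv"), progress = FALSE)
    readr::write_csv(daily, stage_path("drift_daily.csv"), progress = FALSE)
    purrr::iwalk(win_list, function(wdf, nm) {
      readr::write_csv(wdf, stage_path(sprintf("drift_windows_%s.csv", nm)),
                       progress = FALSE)
    })
  }

  # --- divemetrics -----------------------------------------------------------
  metrics <- compute_dive_metrics(dives)
  rec_list <- purrr::map(win_list, function(wdf) {
    window_aggregate(metrics, wdf, positions = positions,
                     bathy = if (isTRUE(config$classify_habitat)) bathy else NULL,
                     min_dives = config$min_dives)
  })
  if (!is.null(out_dir)) {
    purrr::iwalk(rec_list, function(rdf, nm) {
      readr::write_csv(rdf, stage_path(sprintf("window_records_%s.csv", nm)),
                       progress = FALSE)
    })
  }

  # --- model -----------------------------------------------------------------
  if (!is.null(bundle) && config$stratify %in% c("sex", "sex_habitat")) {
    rec_list <- purrr::map(rec_list, function(rec) {
      dplyr::left_join(rec, bundle$seals[c("seal_id", "sex")], by = "seal_id")
    })
  }
  strata <- function(records) {
    vars <- switch(config$stratify,
                   none = character(0),
                   habitat = "habitat",
                   sex = "sex",
                   sex_habitat = c("sex", "habitat"))
    vars <- intersect(vars, names(records))
    if (length(vars) == 0) return(list(all = records))
    split(records, interaction(records[vars], drop = TRUE, sep = "_"))
  }
  fits <- list()
  for (wi in seq_along(config$windows)) {
    w <- config$windows[wi]
    strat <- strata(rec_list[[wi]])
    for (srt in names(strat)) {
      rec <- strat[[srt]]
      for (m in config$metrics) {
        key <- sprintf("%s_w%s_%s", m, w, srt)
        meta <- list(window_days = w,
                     habitat = if (nrow(rec) > 0 && "habitat" %in% names(rec) &&
                                   config$stratify %in% c("habitat", "sex_habitat"))
                       rec$habitat[1] else "all",
                     sex = if (nrow(rec) > 0 && "sex" %in% names(rec) &&
                               config$stratify %in% c("sex", "sex_habitat"))
                       rec$sex[1] else "all")
        f <- tryCatch(
          fit_pamm(build_design(rec, m, basis_dim = config$basis_dim,
                                meta = meta)),
          error = function(e) {
            warn(sprintf("model %s failed: %s", key, conditionMessage(e)))
            NULL
          })
        if (!is.null(f)) fits[[key]] <- f
      }
    }
  }
  log_msg("model: %d fits", length(fits))

  # --- report ----------------------------------------------------------------
  if (length(fits) > 0) {
    coefs <- coefficient_table(fits)
    atten <- suppressWarnings(attenuation_report(coefs, windows = config$windows))
  } else {
    warn("no model fits succeeded; coefficient table is empty")
    coefs <- tibble::tibble(metric = character(0), sex = character(0),
                            habitat = character(0), window_days = numeric(0),
                            beta1 = numeric(0), se = numeric(0), p = numeric(0),
                            flag = character(0), r2_fitted_obs = numeric(0),
                            n = integer(0))
    atten <- tibble::tibble()
  }
  if (!is.null(out_dir)) {
    readr::write_csv(coefs, stage_path("coefficients.csv"), progress = FALSE)
    jsonlite::write_json(
      purrr::map(fits, function(f) as.list(glance(f))),
      stage_path("fits.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    # provenance: full configuration serialised alongside the outputs
    yaml::write_yaml(unclass_config(config), file.path(out_dir, "config.yaml"))
    files <- sort(list.files(out_dir, full.names = TRUE))
    files <- files[!basename(files) %in% "manifest.json"]
    manifest <- tibble::tibble(file = basename(files),
                               md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }

  structure(list(
    bundle = bundle, dives = dives, filter_report = fl$report,
    track_fits = track_fits, positions = positions,
    drift_estimates = est, daily_dr = daily, windows = win_list,
    records = rec_list, fits = fits, coefficients = coefs,
    attenuation = atten, manifest = manifest, config = config
  ), class = "pipeline_result")
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  # run-specific paths are not part of the scientific configuration
  cfg$out_dir <- NULL
  cfg$resume <- NULL
  cfg
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d dives retained, %d window sets, %d model fits\n",
              nrow(x$dives), length(x$records), length(x$fits)))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline on `n_replicates` independently seeded synthetic
#' worlds and tabulates, per metric and window: the fitted foraging-success
#' coefficient, whether its sign matches the generative coefficient, whether
#' the 95% CI covers the generative value and zero, and (per replicate) the
#' attenuation statistic across windows. Replicate failures are recorded,
#' not fatal.
#'
#' @param sim_args List of [sim_config()] arguments for each replicate (the
#'   replicate seed is derived from `seed` and the replicate index).
#' @param n_replicates Number of replicates.
#' @param windows Window lengths to fit.
#' @param metrics Metrics to fit.
#' @param seed Base seed.
#' @param positive_subset Also refit the 1-day window using only records
#'   with positive drift-rate change (robustness check).
#' @param trackfit_restarts Optimiser restarts for the track stage.
#' @return A `recovery_report` list: `estimates` (tibble: replicate, metric,
#'   window, beta1, se, p, truth, sign_correct, ci_covers_truth,
#'   ci_covers_zero, positive-subset columns at w = 1), `attenuation`
#'   (tibble: replicate, metric, tau), `failures` (tibble).
#' @export
recovery_experiment <- function(sim_args = list(),
                                n_replicates = 20,
                                windows = c(1, 2, 3, 7, 10),
                                metrics = c("descent_rate", "ascent_rate",
                                            "dive_residual",
                                            "surface_residual"),
                                seed = 1L,
                                positive_subset = TRUE,
                                trackfit_restarts = 1) {
  truth_key <- c(descent_rate = "descent", ascent_rate = "ascent",
                 dive_residual = "dive_residual",
                 surface_residual = "surface_residual")
  est_rows <- list(); att_rows <- list(); fail_rows <- list()

  for (rep_i in seq_len(n_replicates)) {
    res <- tryCatch({
      cfg <- pipeline_config(
        simulate = sim_args, windows = windows, metrics = metrics,
        stratify = "none", seed = child_seed(seed, rep_i),
        trackfit_restarts = trackfit_restarts)
      suppressMessages(run_pipeline(cfg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_rows[[length(fail_rows) + 1L]] <-
        tibble::tibble(replicate = rep_i, error = conditionMessage(res))
      next
    }
    gam <- res$bundle$truth_params$gamma
    for (m in metrics) {
      truth <- gam[[truth_key[[m]]]]
      for (w in windows) {
        key <- sprintf("%s_w%s_all", m, w)
        f <- res$fits[[key]]
        if (is.null(f)) next
        crit <- stats::qt(0.975, df = f$df)
        ci <- f$beta1 + c(-crit, crit) * f$beta1_se
        row <- tibble::tibble(
          replicate = rep_i, metric = m, window_days = w,
          beta1 = f$beta1, se = f$beta1_se, p = f$beta1_p,
          truth = truth,
          sign_correct = sign(f$beta1) == sign(truth),
          ci_covers_truth = ci[1] <= truth & truth <= ci[2],
          ci_covers_zero = ci[1] <= 0 & 0 <= ci[2],
          beta1_pos = NA_real_, sign_correct_pos = NA
        )
        if (positive_subset && w == 1) {
          rec <- res$records[[paste0("w", w)]]
          rec_pos <- rec[!is.na(rec$ddr) & rec$ddr > 0, , drop = FALSE]
          fp <- tryCatch(
            fit_pamm(build_design(rec_pos, m,
                                  meta = list(window_days = w, subset = "ddr>0"))),
            error = function(e) NULL)
          if (!is.null(fp)) {
            row$beta1_pos <- fp$beta1
            row$sign_correct_pos <- sign(fp$beta1) == sign(truth)
          }
        }
        est_rows[[length(est_rows) + 1L]] <- row
      }
    }
    ct <- coefficient_table(res$fits)
    att <- suppressWarnings(attenuation_report(ct, windows = windows))
    att_rows[[length(att_rows) + 1L]] <-
      dplyr::mutate(att[c("metric", "tau", "n_windows")], replicate = rep_i)
  }

  structure(list(
    estimates = dplyr::bind_rows(est_rows),
    attenuation = dplyr::bind_rows(att_rows),
    failures = dplyr::bind_rows(fail_rows)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  est <- x$estimates
  if (nrow(est) == 0) {
    cat("<recovery_report> no successful replicates\n")
    return(invisible(x))
  }
  cat(sprintf("<recovery_report> %d replicates, %d fits, %d failures\n",
              dplyr::n_distinct(est$replicate), nrow(est), nrow(x$failures)))
  smry <- est |>
    dplyr::group_by(.data$metric, .data$window_days) |>
    dplyr::summarise(sign_correct = mean(.data$sign_correct),
                     ci_covers_truth = mean(.data$ci_covers_truth),
                     ci_covers_zero = mean(.data$ci_covers_zero),
                     .groups = "drop")
  print(smry, n = 30)
  invisible(x)
}
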