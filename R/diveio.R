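# Summarised-dive data model: SRDL-like CSV readers/writers and the dive
# exclusion rules, with an auditable filter report.

dive_filter_rules <- function() {
  c("shallow", "short", "missing_or_duplicate", "fast_segment",
    "too_long", "too_deep", "long_surface")
}

#' Apply the dive exclusion rules
#'
#' Retains a summarised dive iff it has maximum depth > 15 m AND duration
#' > 5 min AND no missing or duplicate-time depth values AND every
#' inter-point vertical rate at most 4 m/s AND total duration at most 90 min
#' AND maximum depth at most 2,000 m AND post-dive surface interval at most
#' 10 min. Thresholds are strict in the printed direction, so boundary dives
#' (exactly 15 m deep, exactly 90 min long) are removed/retained accordingly.
#' A dive failing several rules is counted once, under the first failing rule
#' in the fixed order: shallow, short, missing/duplicate, fast segment, too
#' long, too deep, long surface.
#'
#' @param dives Summarised-dive tibble (`t1..t4`, `d1..d4`, `max_depth`,
#'   `duration`, `surface_interval`; see [summarise_dives()]).
#' @return A list with `dives` (the retained tibble, input order preserved)
#'   and `report` (a `filter_report`: per-rule removal counts plus the
#'   retained count; counts are invariant to input order).
#' @examples
#' b <- simulate_world(sim_config(n_seals = 1, days_per_seal = 5))
#' filter_dives(b$dives)$report
#' @export
filter_dives <- function(dives) {
  assert_cols(dives, c("t1", "t2", "t3", "t4", "d1", "d2", "d3", "d4",
                       "max_depth", "duration", "surface_interval"))
  n <- nrow(dives)
  tmat <- cbind(0, dives$t1, dives$t2, dives$t3, dives$t4, dives$duration)
  dmat <- cbind(0, dives$d1, dives$d2, dives$d3, dives$d4, 0)
  vals <- cbind(tmat, dmat, dives$max_depth, dives$surface_interval)

  any_na <- rowSums(is.na(vals)) > 0
  dtime <- tmat[, -1, drop = FALSE] - tmat[, -6, drop = FALSE]
  nonincreasing <- rowSums(dtime <= 0, na.rm = TRUE) > 0
  rate <- abs(dmat[, -1, drop = FALSE] - dmat[, -6, drop = FALSE]) / dtime

  fails <- cbind(
    shallow = !(dives$max_depth > 15),
    short = !(dives$duration > 300),
    missing_or_duplicate = any_na | nonincreasing,
    fast_segment = rowSums(rate > 4, na.rm = TRUE) > 0,
    too_long = dives$duration > 5400,
    too_deep = dives$max_depth > 2000,
    long_surface = dives$surface_interval > 600
  )
  fails[is.na(fails)] <- TRUE  # NA thresholds count as the missing bucket only
  fails[is.na(dives$max_depth), "shallow"] <- FALSE
  fails[is.na(dives$duration), c("short", "too_long")] <- FALSE
  fails[is.na(dives$max_depth), "too_deep"] <- FALSE
  fails[is.na(dives$surface_interval), "long_surface"] <- FALSE

  first_fail <- apply(fails, 1L, function(f) {
    w <- which(f)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  removed <- !is.na(first_fail)
  counts <- tabulate(first_fail[removed], nbins = length(dive_filter_rules()))
  report <- structure(list(
    rules = tibble::tibble(rule = dive_filter_rules(), removed = counts),
    retained = sum(!removed),
    input = n
  ), class = "filter_report")
  list(dives = dives[!removed, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d dives in, %d retained, %d removed\n",
              x$input, x$retained, x$input - x$retained))
  print(x$rules)
  invisible(x)
}

#' Serialise a filter report to JSON
#'
#' @param report A `filter_report` from [filter_dives()].
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_filter_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  obj <- list(input = report$input, retained = report$retained,
              removed = setNames(as.list(report$rules$removed), report$rules$rule))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Plant one exclusion-rule violation per rule into a dive table
#'
#' Testing/audit utility: mutates the first `length(rules)` rows of a clean
#' dive table so that row `i` violates exactly rule `i` (and no earlier rule),
#' giving a fixture with a known filter report.
#'
#' @param dives Clean summarised-dive tibble (all rows passing the filter).
#' @param rules Character vector of rules to plant, default all seven.
#' @return The mutated tibble.
#' @export
plant_filter_violations <- function(dives, rules = dive_filter_rules()) {
  stopifnot(nrow(dives) >= length(rules))
  set_geom <- function(row, t, d, duration, max_depth, surface = 120) {
    row[c("t1", "t2", "t3", "t4")] <- as.list(t)
    row[c("d1", "d2", "d3", "d4")] <- as.list(d)
    row$duration <- duration
    row$max_depth <- max_depth
    row$surface_interval <- surface
    row
  }
  for (i in seq_along(rules)) {
    r <- rules[i]
    row <- dives[i, ]
    # each planted row violates rule r and passes every earlier rule
    row <- switch(
      r,
      shallow = set_geom(row, c(300, 320, 340, 360),
                         c(14, 13.5, 13.8, 14), 700, 14),
      short = set_geom(row, c(120, 140, 160, 180),
                       c(150, 145, 148, 150), 280, 150),
      missing_or_duplicate = { row$d2 <- NA_real_; row },
      fast_segment = set_geom(row, c(300, 320, 340, 360),
                              c(450, 550, 460, 450), 700, 550),
      too_long = set_geom(row, c(2000, 2600, 3200, 3800),
                          c(450, 420, 430, 450), 5700, 450),
      too_deep = set_geom(row, c(1050, 1100, 1200, 1350),
                          c(2100, 2050, 2080, 2100), 2400, 2100),
      long_surface = { row$surface_interval <- 660; row },
      abort(sprintf("unknown rule '%s'", r))
    )
    dives[i, ] <- row
  }
  dives
}

# ---- CSV dialects -----------------------------------------------------------

dive_dialects <- function() {
  list(
    native = c(seal_id = "seal_id", dive_id = "dive_id",
               start_time = "start_time",
               t1 = "t1", t2 = "t2", t3 = "t3", t4 = "t4",
               d1 = "d1", d2 = "d2", d3 = "d3", d4 = "d4",
               max_depth = "max_depth", duration = "duration",
               surface_interval = "surface_interval"),
    srdl = c(seal_id = "REF", dive_id = "DIVE_ID", start_time = "DE_DATE",
             t1 = "T1", t2 = "T2", t3 = "T3", t4 = "T4",
             d1 = "D1", d2 = "D2", d3 = "D3", d4 = "D4",
             max_depth = "MAX_DEP", duration = "DIVE_DUR",
             surface_interval = "SURF_DUR")
  )
}

#' Read and write summarised-dive CSV tables
#'
#' Supports two CSV dialects: `"native"` (this package's column names) and
#' `"srdl"` (tag-vendor style upper-case headers), or a custom named character
#' vector mapping native names to file headers. Timestamps are numeric epoch
#' seconds (UTC convention); within-dive times are seconds from dive start.
#' The round trip `write_dive_table()` then `read_dive_table()` is lossless.
#'
#' @param path CSV file path.
#' @param dialect `"native"`, `"srdl"`, or a named character vector
#'   (native name -> file header).
#' @param dives A summarised-dive tibble.
#' @return `read_dive_table()` returns a summarised-dive tibble; an empty file
#'   yields an empty tibble with a warning. `write_dive_table()` returns
#'   `path` invisibly.
#' @export
read_dive_table <- function(path, dialect = "native") {
  map <- resolve_dialect(dialect)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warn(sprintf("empty dive table: %s", path))
    out <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(map)), names(map)))
    out$seal_id <- character(0); out$dive_id <- character(0)
    return(out[names(map)])
  }
  missing_cols <- map[!(map %in% names(df))]
  if (length(missing_cols) > 0) {
    abort(sprintf("dive table %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  out <- df[, unname(map)]
  names(out) <- names(map)
  numcols <- setdiff(names(map), c("seal_id", "dive_id"))
  bad <- which(rowSums(vapply(out[numcols], function(col)
    !is.na(col) & is.na(suppressWarnings(as.numeric(col))), logical(nrow(out)))) > 0)
  if (length(bad) > 0) {
    abort(sprintf("unparseable numeric value(s) in %s at row(s): %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  }
  out[numcols] <- lapply(out[numcols], as.numeric)
  out$seal_id <- as.character(out$seal_id)
  out$dive_id <- as.character(out$dive_id)
  tibble::as_tibble(out)
}

#' @rdname read_dive_table
#' @export
write_dive_table <- function(dives, path, dialect = "native") {
  map <- resolve_dialect(dialect)
  assert_cols(dives, names(map))
  out <- dives[, names(map)]
  names(out) <- unname(map)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1) {
    d <- dive_dialects()[[dialect]]
    if (is.null(d)) abort(sprintf("unknown dive-table dialect '%s'", dialect))
    return(d)
  }
  if (is.character(dialect) && !is.null(names(dialect))) return(dialect)
  abort("`dialect` must be a dialect name or a named character vector")
}
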