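# Dive exclusion rules and SRDL-style table I/O.

test_that("boundary dives are removed in the printed direction", {
  d <- clean_dive_table(4)
  d$max_depth[1] <- 14           # shallower than the >15 m retention rule
  d$d1[1] <- 10; d$d2[1] <- 12; d$d3[1] <- 11; d$d4[1] <- 14
  d$duration[2] <- 95 * 60       # longer than 90 min
  d[2, c("t1", "t2", "t3", "t4")] <- list(1500, 2500, 3500, 4500)
  res <- filter_dives(d)
  rules <- setNames(res$report$rules$removed, res$report$rules$rule)
  expect_equal(unname(rules["shallow"]), 1)
  expect_equal(unname(rules["too_long"]), 1)
  expect_equal(res$report$retained, 2)
  # exact boundaries: 15 m and 300 s are NOT retained (strict > to retain)
  d2 <- clean_dive_table(2)
  d2$max_depth[1] <- 15
  sc <- 300 / d2$duration[2]
  d2[2, c("t1", "t2", "t3", "t4")] <- as.list(unlist(d2[2, c("t1","t2","t3","t4")]) * sc)
  d2$duration[2] <- 300
  res2 <- filter_dives(d2)
  expect_equal(res2$report$retained, 0)
})

test_that("planted fixture: 100 dives, one violation per rule, 93 retained", {
  d <- clean_dive_table(100, seed = 11)
  expect_equal(filter_dives(d)$report$retained, 100)
  planted <- plant_filter_violations(d)
  res <- filter_dives(planted)
  expect_equal(res$report$retained, 93)
  expect_equal(res$report$rules$removed, rep(1L, 7))
  expect_equal(res$report$input, 100)
  # removed + retained = input
  expect_equal(sum(res$report$rules$removed) + res$report$retained, 100)
})

test_that("filter is idempotent and report counts are order-invariant", {
  d <- plant_filter_violations(clean_dive_table(60, seed = 13))
  r1 <- filter_dives(d)
  r2 <- filter_dives(r1$dives)
  expect_equal(r2$dives, r1$dives)
  expect_equal(r2$report$retained, nrow(r1$dives))
  set.seed(1)
  perm <- sample(nrow(d))
  r3 <- filter_dives(d[perm, ])
  expect_equal(r3$report$rules$removed, r1$report$rules$removed)
})

test_that("a dive failing several rules is counted once under the first rule", {
  d <- clean_dive_table(1)
  d$max_depth[1] <- 2100   # too deep...
  d$duration[1] <- 6000    # ...and too long: precedence says too_long first?
  # order is shallow, short, missing, fast, too_long, too_deep, long_surface
  d[1, c("t1","t2","t3","t4")] <- list(1000, 2000, 3000, 4000)
  d[1, c("d1","d2","d3","d4")] <- list(2100, 2050, 2080, 2100)
  res <- filter_dives(d)
  rules <- setNames(res$report$rules$removed, res$report$rules$rule)
  expect_equal(unname(rules["too_long"]), 1)
  expect_equal(unname(rules["too_deep"]), 0)
})

test_that("dives with missing or duplicate-time depths go to that bucket", {
  d <- clean_dive_table(3)
  d$d2[1] <- NA
  d$t3[2] <- d$t2[2]  # duplicated timestamp within the dive
  res <- filter_dives(d)
  rules <- setNames(res$report$rules$removed, res$report$rules$rule)
  expect_equal(unname(rules["missing_or_duplicate"]), 2)
  expect_equal(res$report$retained, 1)
})

test_that("dive tables round-trip losslessly in both dialects", {
  d <- clean_dive_table(50, seed = 17)
  for (dialect in c("native", "srdl")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_dive_table(d, path, dialect = dialect)
    back <- read_dive_table(path, dialect = dialect)
    expect_equal(as.data.frame(back), as.data.frame(d[names(back)]),
                 tolerance = 1e-12)
  }
  # unknown columns fail with a clear message
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d[, 1:5], path2)
  expect_error(read_dive_table(path2), "lacks column")
})

test_that("an empty dive file yields an empty table with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("seal_id,dive_id,start_time,t1,t2,t3,t4,d1,d2,d3,d4,max_depth,duration,surface_interval", path)
  expect_warning(out <- read_dive_table(path), "empty")
  expect_equal(nrow(out), 0)
})

test_that("filter report serialises to JSON", {
  res <- filter_dives(plant_filter_violations(clean_dive_table(20)))
  js <- jsonlite::fromJSON(write_filter_report(res$report))
  expect_equal(js$retained, 13)
  expect_equal(js$removed$shallow, 1)
  expect_equal(js$input, 20)
})
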