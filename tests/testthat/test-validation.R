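write_occ <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

test_that("occurrence reading validates headers, coordinates and years", {
  f <- write_occ(data.frame(lon = c(7.1, 7.2, 7.3), lat = c(46, 46.1, 46.2),
                            year = c(2010, 2015, 2019)))
  on.exit(unlink(f))
  recs <- read_occurrences(f)
  expect_equal(nrow(recs), 3)

  f2 <- write_occ(data.frame(lon = 7.1, lat = 46, yr = 2010))
  on.exit(unlink(f2), add = TRUE)
  expect_error(read_occurrences(f2), "lacks column")

  # out-of-range year reported with its line number, then skipped
  f3 <- write_occ(data.frame(lon = c(7.1, 7.2), lat = c(46, 46),
                             year = c(1990, 2012)))
  on.exit(unlink(f3), add = TRUE)
  expect_warning(recs <- read_occurrences(f3), "line.*2")
  expect_equal(recs$year, 2012L)
  expect_error(read_occurrences(f3, malformed = "error"), "line")

  f4 <- write_occ(data.frame(lon = numeric(), lat = numeric(),
                             year = integer()))
  on.exit(unlink(f4), add = TRUE)
  expect_equal(nrow(read_occurrences(f4)), 0)
})

test_that("overlap fractions count records in suitable cells", {
  res <- data.frame(lon = c(7.00, 7.02, 7.04), lat = rep(46, 3),
                    ei = c(10, 2, 20))
  attr(res, "cell_size") <- 0.02
  recs <- data.frame(lon = c(7.001, 7.019, 7.041), lat = rep(46.001, 3),
                     year = c(2010, 2011, 2012))
  ov <- overlap_statistics(recs, res)
  expect_equal(ov$fraction_suitable, 2 / 3)
  expect_equal(ov$fraction_highly_suitable, 1 / 3)
  expect_equal(ov$n_in_bounds, 3)
  # higher threshold can never beat the lower one; order does not matter
  expect_lte(ov$fraction_highly_suitable, ov$fraction_suitable)
  ov2 <- overlap_statistics(recs[3:1, ], res)
  expect_equal(ov2$fraction_suitable, ov$fraction_suitable)
  # far-away records error out
  expect_error(overlap_statistics(data.frame(lon = 9, lat = 49, year = 2010),
                                  res),
               "within the grid")
})

test_that("records just off the grid snap to the nearest cell within one width", {
  res <- data.frame(lon = 7.00, lat = 46, ei = 10)
  attr(res, "cell_size") <- 0.02
  near <- data.frame(lon = 7.015, lat = 46, year = 2010)   # 0.015 deg off
  expect_equal(overlap_statistics(near, res)$fraction_suitable, 1)
  far <- data.frame(lon = 7.05, lat = 46, year = 2010)     # > one cell width
  expect_error(overlap_statistics(far, res), "within the grid")
})

test_that("per-year breakdown works against one grid and against per-year grids", {
  g <- small_synthetic()
  res <- run_grid(g)
  recs <- sample_occurrences(res, 60, seed = 4, year_range = c(2015, 2019))
  ov <- overlap_statistics(recs, res)
  expect_equal(ov$fraction_suitable, 1)  # sampled only from EI > 5 cells
  expect_equal(sort(unique(ov$per_year$year)), sort(unique(recs$year)))
  expect_equal(sum(ov$per_year$n), nrow(recs))

  warm <- run_grid(apply_deltas(g, make_change_signal("w", "p", 2, 0)))
  by_year <- list("2015" = res, "2016" = warm)
  recs2 <- recs[recs$year %in% c(2015, 2016), , drop = FALSE]
  ov2 <- overlap_statistics(recs2, by_year)
  expect_equal(ov2$n_in_bounds, nrow(recs2))
  expect_true(all(ov2$per_year$fraction_suitable >= 0 &
                  ov2$per_year$fraction_suitable <= 1))
})
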