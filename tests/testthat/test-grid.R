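test_that("climate grid CSV round-trips losslessly", {
  g <- small_synthetic(seed = 7)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_monthly_grid(g, f)
  g2 <- read_monthly_grid(f)
  expect_equal(g2$lon, g$lon)
  expect_equal(g2$lat, g$lat)
  expect_identical(g2$tmin, g$tmin)
  expect_identical(g2$tmax, g$tmax)
  expect_identical(g2$prec, g$prec)
  expect_equal(g2$elevation, g$elevation)
  expect_equal(g2$cell_size, g$cell_size)
})

test_that("grid validation names offending cells and rejects implausible values", {
  g <- one_cell_grid()
  g$tmin[1, 5] <- 20  # above tmax
  expect_error(validate_climate_grid(g), "tmin > tmax.*8.0*")
  g <- one_cell_grid()
  g$prec[1, 2] <- -1
  expect_error(validate_climate_grid(g), "negative precipitation")
  expect_error(climate_grid(lon = 8, lat = 47, tmin = matrix(5, 1, 12),
                            tmax = matrix(70, 1, 12),
                            prec = matrix(10, 1, 12), cell_size = 0.02),
               "implausible temperature")
  expect_error(climate_grid(lon = c(7, 7.02, 7.05), lat = rep(46, 3),
                            tmin = matrix(0, 3, 12), tmax = matrix(9, 3, 12),
                            prec = matrix(10, 3, 12), cell_size = 0.02),
               "spacing")
})

test_that("point-in-cell lookup uses half-open boxes with the low edge closed", {
  g <- make_synthetic_grid(synthetic_config(n_lon = 2, n_lat = 1,
                                            noise_sd = 0, n_ridges = 0))
  # cell centres at 7.00 and 7.02; the shared edge is 7.01
  expect_equal(locate_cell(g, 7.00, 46.00), 1L)
  expect_equal(locate_cell(g, 7.01, 46.00), 2L)  # low edge of cell 2
  expect_equal(locate_cell(g, 7.0099999, 46.00), 1L)
  expect_error(locate_cell(g, 7.5, 46.0), "outside")
  g$land_mask[2] <- FALSE
  expect_error(locate_cell(g, 7.02, 46.0), "masked")
})

test_that("the ten Swiss reference localities fall in distinct cells of a Swiss-extent grid", {
  g <- make_synthetic_grid(synthetic_config(n_lon = 32, n_lat = 18,
                                            cell_size = 0.1, lon0 = 6.5,
                                            lat0 = 45.9, seed = 3))
  locs <- swiss_reference_locations()
  expect_equal(nrow(locs), 10)
  idx <- vapply(seq_len(nrow(locs)),
                function(i) locate_cell(g, locs$lon[i], locs$lat[i]),
                integer(1))
  expect_equal(length(unique(idx)), 10)
})

test_that("run_grid equals mapped run_cell on a singleton and a full synthetic grid", {
  g1 <- one_cell_grid(tmin = 10, tmax = 22, prec = 90)
  res1 <- run_grid(g1)
  r1 <- run_cell(as_weekly_series(extract_location(g1, 8, 47)))
  expect_equal(res1$ei, r1$ei, tolerance = 1e-12)
  expect_equal(res1$generations, r1$generations, tolerance = 1e-12)

  g <- small_synthetic(seed = 11)
  res <- run_grid(g)
  expect_equal(nrow(res), 300)
  worst <- 0
  for (i in seq_len(nrow(res))) {
    rc <- run_cell(as_weekly_series(extract_location(g, g$lon[i], g$lat[i])),
                   keep_weekly = FALSE)
    worst <- max(worst,
                 abs(rc$ei - res$ei[i]), abs(rc$gi_a - res$gi_a[i]),
                 abs(rc$dd_annual - res$dd_annual[i]),
                 abs(rc$cs - res$cs[i]), abs(rc$ds - res$ds[i]),
                 abs(rc$ws - res$ws[i]), abs(rc$hw - res$hw[i]),
                 abs(rc$growth_weeks - res$growth_weeks[i]))
  }
  expect_lt(worst, 1e-10)
})

test_that("masked cells are excluded from grid results", {
  g <- small_synthetic()
  g$land_mask[1:50] <- FALSE
  res <- run_grid(g)
  expect_equal(nrow(res), 250)
  expect_false(any(res$lon == g$lon[1] & res$lat == g$lat[1]))
})
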