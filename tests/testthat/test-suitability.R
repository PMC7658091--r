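test_that("suitability classes respect the strict thresholds at 1, 5 and 15", {
  got <- classify_suitability(c(0, 0.5, 0.999, 1, 5, 5.0001, 15, 15.0001, 100))
  expect_equal(as.character(got),
               c("unsuitable", "unsuitable", "unsuitable",
                 "marginal", "marginal",
                 "suitable", "suitable",
                 "highly_suitable", "highly_suitable"))
  expect_true(is.ordered(got))
  expect_error(classify_suitability(150), "0, 100")
})

test_that("area percentages count cells over the full grid denominator", {
  res <- data.frame(ei = c(0, 0, 2, 6, 10, 20, 0, 4, 50, 0),
                    generations = c(0, 0, 0.5, 1, 1.2, 2.5, 0, 0.9, 3, 0))
  s <- area_percentages(res)
  expect_equal(s$pct_suitable, 40)          # EI > 5: 4 of 10
  expect_equal(s$pct_highly_suitable, 20)   # EI > 15: 2 of 10
  expect_equal(s$pct_one_gen, 40)
  expect_equal(s$pct_two_gen, 20)
  expect_equal(s$n_cells, 10)
  # permutation invariance
  perm <- res[sample(nrow(res)), ]
  expect_equal(area_percentages(perm), s)
  # degenerate all-zero grid
  z <- area_percentages(data.frame(ei = rep(0, 5), generations = rep(0, 5)))
  expect_equal(z$pct_suitable, 0)
  expect_equal(z$pct_two_gen, 0)
  expect_error(area_percentages(res[0, ]), "empty")
})

test_that("class shares are nested on random synthetic grids", {
  for (seed in c(2, 9, 31)) {
    res <- run_grid(small_synthetic(seed = seed))
    s <- area_percentages(res)
    expect_lte(s$pct_highly_suitable, s$pct_suitable)
    expect_lte(s$pct_two_gen, s$pct_one_gen)
  }
})

test_that("the location table projects per-cell engine output with table rounding", {
  g <- small_synthetic()
  locs <- data.frame(name = c("low", "high"),
                     lon = c(g$lon[1], g$lon[300]),
                     lat = c(g$lat[1], g$lat[300]))
  tab <- location_table(list(baseline = g), locs)
  expect_equal(nrow(tab), 2)
  r <- run_cell(as_weekly_series(extract_location(g, g$lon[1], g$lat[1])))
  expect_equal(tab$ei[tab$location == "low"], round(r$ei))
  expect_equal(tab$generations[tab$location == "low"],
               round(r$generations, 2))
  expect_equal(tab$growth_weeks[tab$location == "low"],
               as.integer(r$growth_weeks))

  # a warm scenario strictly raises generations at thermally limited cells
  warm <- apply_deltas(g, make_change_signal("warm", "p", 3, 0))
  tab2 <- location_table(list(baseline = g, warm = warm), locs)
  for (nm in locs$name) {
    expect_gt(tab2$generations[tab2$location == nm & tab2$scenario == "warm"],
              tab2$generations[tab2$location == nm &
                               tab2$scenario == "baseline"])
  }

  empty <- location_table(list(baseline = g),
                          data.frame(name = character(), lon = numeric(),
                                     lat = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("phenology windows and shifts count weeks as expected", {
  gi <- rep(0, 52)
  expect_equal(phenology_window(gi)$growth_weeks, 0)
  gi[12:42] <- 0.5
  gi[25] <- 0  # mid-season dip is ignored by the window bounds
  w <- phenology_window(gi)
  expect_equal(w$first_week, 12)
  expect_equal(w$last_week, 42)
  expect_equal(w$growth_weeks, 30)

  base <- rep(0, 52); base[12:42] <- 1
  scen <- rep(0, 52); scen[10:44] <- 1
  sh <- phenology_shift(base, scen)
  expect_equal(sh$spring_shift, 2)
  expect_equal(sh$autumn_shift, 2)
  expect_equal(phenology_shift(base, base),
               list(spring_shift = 0, autumn_shift = 0))
  expect_error(phenology_shift(rep(0, 52), scen), "undefined")
})
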