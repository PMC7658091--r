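test_that("the generator is deterministic given its seed", {
  g1 <- small_synthetic(seed = 13)
  g2 <- small_synthetic(seed = 13)
  expect_identical(g1$tmin, g2$tmin)
  expect_identical(g1$prec, g2$prec)
  expect_identical(g1$elevation, g2$elevation)
  g3 <- small_synthetic(seed = 14)
  expect_false(identical(g1$tmin, g3$tmin))
})

test_that("flat, noise-free topography yields a spatially uniform climate", {
  g <- make_synthetic_grid(synthetic_config(n_ridges = 0, elev_base = 0,
                                            noise_sd = 0))
  expect_equal(g$elevation, rep(0, 300))
  expect_equal(apply(g$tmin, 2, function(x) diff(range(x))), rep(0, 12))
  expect_equal(apply(g$prec, 2, function(x) diff(range(x))), rep(0, 12))
})

test_that("the temperature lapse is -6.5 degC per km of elevation", {
  low <- make_synthetic_grid(synthetic_config(n_lon = 2, n_lat = 2,
                                              n_ridges = 0, elev_base = 0,
                                              noise_sd = 0))
  high <- make_synthetic_grid(synthetic_config(n_lon = 2, n_lat = 2,
                                               n_ridges = 0, elev_base = 2000,
                                               noise_sd = 0))
  d <- mean((low$tmin + low$tmax) / 2) - mean((high$tmin + high$tmax) / 2)
  expect_equal(d, 13)
})

test_that("synthetic occurrences land only in suitable cells, deterministically", {
  res <- run_grid(small_synthetic())
  r1 <- sample_occurrences(res, 100, seed = 9)
  r2 <- sample_occurrences(res, 100, seed = 9)
  expect_identical(r1, r2)
  expect_equal(overlap_statistics(r1, res)$fraction_suitable, 1)
  expect_true(all(r1$year >= 2004 & r1$year <= 2019))

  # forced support: a single suitable cell receives every record
  res2 <- data.frame(lon = c(7, 7.02), lat = c(46, 46), ei = c(0, 30))
  attr(res2, "cell_size") <- 0.02
  r3 <- sample_occurrences(res2, 25, seed = 1)
  expect_true(all(abs(r3$lon - 7.02) <= 0.01))
  expect_error(sample_occurrences(
    {z <- data.frame(lon = 7, lat = 46, ei = 1); attr(z, "cell_size") <- 0.02; z},
    5),
    "no suitable cells")
})

test_that("suitability declines with elevation across the synthetic alps", {
  res <- run_grid(small_synthetic())
  expect_lt(cor(res$elevation, res$ei, method = "spearman"), 0)
  # high-altitude cells fail on season length, exactly as the EI = 0 gate says
  alpine <- res$elevation > 2000
  expect_true(all(res$ei[alpine] == 0 |
                  res$dd_annual[alpine] >= default_parameters()$PDD))
})

test_that("a +3 degC signal expands the suitable area on the default grid", {
  g <- small_synthetic()
  base <- area_percentages(run_grid(g))
  warm <- area_percentages(run_grid(apply_deltas(
    g, make_change_signal("warm", "p", 3, 0))))
  expect_gt(warm$pct_suitable, base$pct_suitable)
})
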