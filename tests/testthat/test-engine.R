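p_default <- default_parameters()

test_that("temperature and moisture indices are the four-point trapezoids", {
  expect_equal(temperature_index(27), 1)
  expect_equal(temperature_index(12), 0)
  expect_equal(temperature_index(19.5), 0.5)
  expect_equal(temperature_index(33), 0)
  expect_equal(temperature_index(31.5), 0.5)
  expect_equal(moisture_index(0.75), 1)
  expect_equal(moisture_index(0.3), 0.5)
  expect_equal(moisture_index(1.6), 0)
  # full range property on a fine sweep
  t <- seq(-30, 50, by = 0.1)
  expect_true(all(temperature_index(t) >= 0 & temperature_index(t) <= 1))
  s <- seq(0, 3, by = 0.01)
  expect_true(all(moisture_index(s) >= 0 & moisture_index(s) <= 1))
})

test_that("soil bucket drains, balances, and saturates as expected", {
  # pure drainage ends (and stays) empty
  s <- soil_moisture_series(rep(0, 52), rep(10, 52), s0 = 0.5)
  expect_equal(tail(s, 40), rep(0, 40))
  # exact balance is the identity
  s <- soil_moisture_series(rep(7, 52), rep(7, 52), s0 = 0.5)
  expect_equal(s, rep(0.5, 52))
  # persistent surplus pins the store at its ceiling
  s <- soil_moisture_series(rep(25, 52), rep(5, 52), capacity = 100,
                            s0 = 0.5, s_max = 2)
  expect_equal(tail(s, 40), rep(2, 40))
  s1 <- soil_moisture_series(rep(25, 52), rep(5, 52), capacity = 100, s0 = 0.5)
  expect_equal(tail(s1, 40), rep(1, 40))  # default ceiling: field capacity
})

test_that("soil bucket reaches a 52-periodic state independent of the start value", {
  rain <- 15 + 10 * cos(2 * pi * (1:52) / 52)
  evap <- 18 + 14 * cos(2 * pi * ((1:52) - 26) / 52)  # net annual deficit
  runs <- lapply(c(0, 0.5, 2), function(s0)
    soil_moisture_series(rain, evap, capacity = 100, s0 = s0))
  expect_equal(runs[[1]], runs[[2]])
  expect_equal(runs[[1]], runs[[3]])
  # and it is a fixed point of a further annual pass
  again <- soil_moisture_series(rain, evap, capacity = 100,
                                s0 = runs[[1]][52])
  expect_equal(again, runs[[1]])
})

test_that("winter diapause switches on cold short days and off on warm lengthening days", {
  dl <- day_length(46.5, 1:52)
  # warm everywhere: no induction
  expect_equal(diapause_series(rep(20, 52), dl), rep(1L, 52))
  # equatorial day length never below the induction threshold
  expect_equal(diapause_series(rep(2, 52), rep(12.5, 52)), rep(1L, 52))
  # alpine-like winter: cold short days from week 44, warm again from week 12
  tavg <- rep(15, 52)
  tavg[c(44:52, 1:10)] <- 2
  tavg[11] <- 4
  di <- diapause_series(tavg, dl)
  expect_equal(which(di == 0L), sort(c(44:52, 1:11)))
  expect_error(diapause_series(rep(5, 52), dl, species_parameters(DPSW = 1)),
               "winter diapause")
})

test_that("growth index is the annihilating product of its components", {
  ones <- rep(1, 52)
  expect_equal(growth_index_series(ones, ones, ones), ones)
  di <- ones; di[10:20] <- 0
  gi <- growth_index_series(ones, ones, di)
  expect_equal(gi[10:20], rep(0, 11))
  expect_equal(growth_index_series(rep(0.5, 52), rep(0.5, 52), ones),
               rep(0.25, 52))
  expect_equal(annual_growth_index(ones), 100)
  expect_equal(annual_growth_index(rep(0, 52)), 0)
  expect_equal(annual_growth_index(c(rep(1, 26), rep(0, 26))), 50)
})

test_that("stress accumulation is linear in weekly exceedance at the published rates", {
  benign_t <- rep(10, 52)
  benign_s <- rep(0.8, 52)
  st <- stress_indices(benign_t, benign_t + 5, benign_t + 2.5, benign_s)
  expect_equal(unlist(st), c(cs = 0, hs = 0, ds = 0, ws = 0, hw = 0))

  tmin <- benign_t; tmin[3] <- -20
  st <- stress_indices(tmin, benign_t + 5, benign_t + 2.5, benign_s)
  expect_equal(st$cs, 100 * 0.01 * 2)  # one week, 2 degC below -18

  tmax <- benign_t + 5; tmax[30] <- 35
  st <- stress_indices(benign_t, tmax, benign_t + 2.5, benign_s)
  expect_equal(st$hs, 100 * 0.01 * 2)

  dry <- benign_s; dry[40] <- 0.05
  st <- stress_indices(benign_t, benign_t + 5, benign_t + 2.5, dry)
  expect_equal(st$ds, 100 * 0.01 * 0.05)

  wet <- benign_s; wet[20] <- 1.7
  st <- stress_indices(benign_t, benign_t + 5, benign_t + 2.5, wet)
  expect_equal(st$ws, 100 * 0.002 * 0.2)

  # hot-wet needs both conditions in the same week
  hotwet_t <- rep(30, 52)
  st <- stress_indices(hotwet_t - 5, hotwet_t + 5, hotwet_t, wet)
  expect_equal(st$hw, 100 * 0.007 * 2)  # only week 20 has soil > 1.5
})

test_that("degree days and generations follow the closed forms", {
  expect_equal(degree_days_annual(rep(12, 52))$dd_annual, 0)
  expect_equal(degree_days_annual(rep(12, 52))$generations, 0)
  dd <- degree_days_annual(rep(24, 52))
  expect_equal(dd$dd_annual, 7 * 12 * 52)
  expect_equal(dd$generations, 4368 / 595)
  expect_equal(degree_days_annual(rep(12 + 595 / 364, 52))$generations, 1)
})

test_that("the Ecoclimatic Index combines growth, survival and the degree-day gate", {
  expect_equal(ecoclimatic_index(100, 0, 0, 0, 0, 0, 600), 100)
  expect_equal(ecoclimatic_index(50, 20, 0, 0, 0, 0, 600), 40)
  # warm enough to grow a little but not to finish a generation
  expect_equal(ecoclimatic_index(40, 0, 0, 0, 0, 0, 364), 0)
  expect_equal(ecoclimatic_index(80, 100, 0, 0, 0, 0, 2000), 0)
  ei <- ecoclimatic_index(runif(100, 0, 100), runif(100, 0, 100),
                          runif(100, 0, 100), 0, 0, 0, runif(100, 0, 4000))
  expect_true(all(ei >= 0 & ei <= 100))
})

test_that("run_cell composes the closed forms for constant climates", {
  # constant optimal: saturated growth, ~10 generations
  r <- run_cell(const_series(tavg = 28.5, prec = 20))
  expect_equal(r$ei, 100)
  expect_equal(r$gi_a, 100)
  expect_equal(r$generations, 7 * 16.5 * 52 / 595)
  expect_equal(r$growth_weeks, 52L)
  expect_equal(unlist(r[c("cs", "hs", "ds", "ws", "hw")]),
               c(cs = 0, hs = 0, ds = 0, ws = 0, hw = 0))

  # constant cool: no degree days, no growth
  r <- run_cell(const_series(tavg = 10, prec = 20))
  expect_equal(r$ei, 0)
  expect_equal(r$dd_annual, 0)
  expect_equal(r$growth_weeks, 0L)
})

test_that("run_cell agrees with the independent scalar oracle on varied synthetic cells", {
  g <- small_synthetic()
  idx <- c(1, 57, 150, 222, 300)
  for (i in idx) {
    cell <- extract_location(g, g$lon[i], g$lat[i])
    s <- as_weekly_series(cell)
    got <- run_cell(s)
    want <- oracle_cell(s$tmin, s$tmax, s$prec, s$rh09, s$rh15, s$daylength)
    for (f in c("ei", "gi_a", "cs", "hs", "ds", "ws", "hw", "dd_annual",
                "generations"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, info = f)
    expect_equal(got$growth_weeks, want$growth_weeks)
    expect_equal(got$weekly$soil, want$soil, tolerance = 1e-10)
  }
})

test_that("warming a thermally sub-optimal, moisture-saturated cell never hurts", {
  # saturated air keeps evaporation at zero, isolating the thermal pathway
  base <- const_series(tavg = 14 + 6 * cos(2 * pi * ((1:52) - 30) / 52),
                       prec = 30)
  r0 <- run_cell(base)
  for (dt in c(0.5, 1, 2, 3)) {
    warmed <- const_series(tavg = base$tavg + dt, prec = 30)
    r1 <- run_cell(warmed)
    expect_gte(r1$gi_a, r0$gi_a)
    expect_gte(r1$dd_annual, r0$dd_annual)
    expect_gte(r1$generations, r0$generations)
    expect_gte(r1$ei, r0$ei)
  }
})
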