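# Fixture builders shared across the test files.

# A weekly series with constant (or supplied) components; rh defaults make
# the air saturated so that evaporation is zero unless stated otherwise.
const_series <- function(tavg = 20, diurnal = 0, prec = 20,
                         rh09 = 100, rh15 = 100, latitude = 47) {
  rep52 <- function(x) if (length(x) == 52) x else rep(x, length.out = 52)
  tavg <- rep52(tavg)
  weekly_series(tmin = tavg - diurnal / 2, tmax = tavg + diurnal / 2,
                prec = rep52(prec), rh09 = rep52(rh09), rh15 = rep52(rh15),
                daylength = day_length(latitude, 1:52))
}

# A small flat single-cell grid with constant climate.
one_cell_grid <- function(tmin = 5, tmax = 15, prec = 80,
                          lon = 8.0, lat = 47.0) {
  climate_grid(lon = lon, lat = lat,
               tmin = matrix(tmin, 1, 12), tmax = matrix(tmax, 1, 12),
               prec = matrix(prec, 1, 12), cell_size = 0.02)
}

small_synthetic <- function(seed = 42, ...) {
  make_synthetic_grid(synthetic_config(seed = seed, ...))
}
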