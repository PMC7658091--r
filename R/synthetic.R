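#' Configuration for the synthetic alpine climate generator
#'
#' Describes a Switzerland-like test world: a regular 0.02-degree grid, an
#' elevation surface built from a valley floor plus smooth Gaussian ridges,
#' a sea-level annual temperature cycle lapsed with altitude, a fixed
#' diurnal range, and orographically enhanced, summer-peaked precipitation.
#' The defaults were fixed once from alpine climatology (annual mean
#' 14 degC at sea level with 9 degC seasonal amplitude, -6.5 degC/km lapse,
#' 8 degC diurnal range, 85 mm/month precipitation plus 25 mm/month per km
#' of altitude, elevation capped at 2600 m) and deliberately keep weekly
#' temperatures inside (-18, 33) degC so the published zero-stress regime
#' for Switzerland holds across the whole grid.
#'
#' @param n_lon,n_lat grid dimensions (cells).
#' @param cell_size grid spacing (degrees).
#' @param lon0,lat0 south-west cell-centre origin (degrees).
#' @param elev_base valley-floor elevation (m).
#' @param n_ridges number of Gaussian ridges added to the surface; `NULL`
#'   (default) scales the count with domain area (one ridge per ~130 cells,
#'   at least two) so the alpine share of the landscape is preserved at any
#'   grid size.
#' @param elev_max elevation cap (m).
#' @param t_sea sea-level annual mean temperature (degrees C).
#' @param seasonal_amplitude half-range of the annual temperature cycle
#'   (degrees C).
#' @param lapse_rate temperature lapse rate (degrees C per km; negative).
#' @param diurnal_range tmax - tmin (degrees C).
#' @param prec_base precipitation at sea level (mm/month).
#' @param prec_orographic precipitation increase per km of altitude
#'   (mm/month).
#' @param prec_seasonality relative amplitude of the summer precipitation
#'   peak (0 = uniform).
#' @param noise_sd standard deviation of cell/month temperature noise
#'   (degrees C).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @param preset `"default"` (20 x 15 = 300 cells) or `"swiss_size"`
#'   (111 x 101 = 11,211 cells, the cell count of the 0.02-degree Swiss
#'   climatology).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lon = 20, n_lat = 15, cell_size = 0.02,
                             lon0 = 7.0, lat0 = 46.0,
                             elev_base = 300, n_ridges = NULL,
                             elev_max = 2600,
                             t_sea = 14, seasonal_amplitude = 9,
                             lapse_rate = -6.5, diurnal_range = 8,
                             prec_base = 85, prec_orographic = 25,
                             prec_seasonality = 0.4,
                             noise_sd = 0.3, seed = 42,
                             preset = c("default", "swiss_size")) {
  preset <- match.arg(preset)
  if (preset == "swiss_size") {
    n_lon <- 111
    n_lat <- 101
  }
  if (is.null(n_ridges))
    n_ridges <- max(2, round(n_lon * n_lat / 130))
  cfg <- list(n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
              cell_size = cell_size, lon0 = lon0, lat0 = lat0,
              elev_base = elev_base, n_ridges = as.integer(n_ridges),
              elev_max = elev_max, t_sea = t_sea,
              seasonal_amplitude = seasonal_amplitude,
              lapse_rate = lapse_rate, diurnal_range = diurnal_range,
              prec_base = prec_base, prec_orographic = prec_orographic,
              prec_seasonality = prec_seasonality,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_lon < 1 || cfg$n_lat < 1) stop("grid dimensions must be >= 1")
  if (cfg$cell_size <= 0) stop("cell_size must be positive")
  if (cfg$diurnal_range < 0 || cfg$noise_sd < 0 || cfg$prec_base < 0)
    stop("diurnal_range, noise_sd and prec_base must be non-negative")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic alpine monthly climate grid
#'
#' Builds the [climate_grid()] described by a [synthetic_config()]:
#' `tmean(month, cell) = t_sea + A cos(2 pi (month - 7) / 12) +
#' lapse_rate * elev / 1000 + noise`, with `tmin`/`tmax` half a diurnal
#' range below/above, and monthly precipitation
#' `(prec_base + prec_orographic * elev / 1000) *
#' (1 + s cos(2 pi (month - 7) / 12))`. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return A `climate_grid` with an elevation layer.
#' @export
#' @examples
#' g <- make_synthetic_grid(synthetic_config(n_lon = 4, n_lat = 3))
#' length(g$lon)
make_synthetic_grid <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) stop("need a synthetic_config")
  cfg <- config
  with_seed(cfg$seed, {
    lon_axis <- cfg$lon0 + (seq_len(cfg$n_lon) - 1) * cfg$cell_size
    lat_axis <- cfg$lat0 + (seq_len(cfg$n_lat) - 1) * cfg$cell_size
    cells <- expand.grid(lon = lon_axis, lat = lat_axis,
                         KEEP.OUT.ATTRS = FALSE)
    n <- nrow(cells)
    lon_span <- max(cfg$n_lon - 1, 1) * cfg$cell_size
    lat_span <- max(cfg$n_lat - 1, 1) * cfg$cell_size
    elev <- rep(cfg$elev_base, n)
    if (cfg$n_ridges > 0) {
      amp <- stats::runif(cfg$n_ridges, 1200, 2000)
      cx <- cfg$lon0 + stats::runif(cfg$n_ridges) * lon_span
      cy <- cfg$lat0 + stats::runif(cfg$n_ridges) * lat_span
      # ridge footprint ~ span / sqrt(n): the expected alpine share of the
      # landscape is then independent of the grid size
      wx <- lon_span * 0.32 / sqrt(cfg$n_ridges) *
        stats::runif(cfg$n_ridges, 0.7, 1.3)
      wy <- lat_span * 0.32 / sqrt(cfg$n_ridges) *
        stats::runif(cfg$n_ridges, 0.7, 1.3)
      for (k in seq_len(cfg$n_ridges)) {
        elev <- elev + amp[k] *
          exp(-((cells$lon - cx[k])^2 / (2 * wx[k]^2) +
                (cells$lat - cy[k])^2 / (2 * wy[k]^2)))
      }
    }
    elev <- pmin(cfg$elev_max, elev)
    season <- cos(2 * pi * ((1:12) - 7) / 12)
    tmean <- outer(cfg$t_sea + cfg$lapse_rate * elev / 1000,
                   cfg$seasonal_amplitude * season, "+")
    if (cfg$noise_sd > 0)
      tmean <- tmean + matrix(stats::rnorm(n * 12, 0, cfg$noise_sd), n, 12)
    prec <- outer(cfg$prec_base + cfg$prec_orographic * elev / 1000,
                  1 + cfg$prec_seasonality * season, "*")
    climate_grid(lon = cells$lon, lat = cells$lat,
                 tmin = tmean - cfg$diurnal_range / 2,
                 tmax = tmean + cfg$diurnal_range / 2,
                 prec = prec, elevation = elev,
                 cell_size = cfg$cell_size)
  })
}

#' Sample synthetic occurrence records from a suitability surface
#'
#' Emulates citizen-science observation points: cells are drawn with
#' probability proportional to `max(0, EI - 5)` (so every record lies in a
#' climatically suitable cell), points are placed uniformly within the cell
#' box, and years are drawn uniformly from `year_range`. Deterministic given
#' the seed.
#'
#' @param result a `suitability_result` from [run_grid()].
#' @param n number of records.
#' @param seed RNG seed.
#' @param year_range inclusive year range; default 2004--2019.
#' @return An occurrence data frame (`lon`, `lat`, `year`, `stage`,
#'   `source`).
#' @export
sample_occurrences <- function(result, n, seed = 1,
                               year_range = c(2004, 2019)) {
  w <- pmax(0, result$ei - 5)
  if (all(w == 0))
    stop("no suitable cells (EI > 5) to sample occurrences from")
  cs <- attr(result, "cell_size") %||% infer_cell_size(result$lon, result$lat)
  with_seed(seed, {
    idx <- sample.int(nrow(result), n, replace = TRUE, prob = w)
    data.frame(
      lon = result$lon[idx] + stats::runif(n, -cs / 2, cs / 2),
      lat = result$lat[idx] + stats::runif(n, -cs / 2, cs / 2),
      year = sample(seq(year_range[1], year_range[2]), n, replace = TRUE),
      stage = sample(c("adult", "nymph", "egg"), n, replace = TRUE,
                     prob = c(0.7, 0.25, 0.05)),
      source = "synthetic",
      stringsAsFactors = FALSE)
  })
}
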