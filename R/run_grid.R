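# Whole-grid engine: the same computation as run_cell, vectorised across
# cells (52 x n week-by-cell matrices, with the week loops shared).

grid_weekly_matrices <- function(g) {
  n <- length(g$lon)
  W <- interp_matrix(); A <- apportion_matrix()
  tmin <- matrix(0, 52, n); tmax <- matrix(0, 52, n)
  rain <- matrix(0, 52, n); rh09 <- matrix(0, 52, n); rh15 <- matrix(0, 52, n)
  for (i in seq_len(n)) {
    # per-cell mat-vec keeps the arithmetic identical to the scalar path
    tmin[, i] <- W %*% g$tmin[i, ]
    tmax[, i] <- W %*% g$tmax[i, ]
    rain[, i] <- A %*% g$prec[i, ]
    rh <- derive_relative_humidity(g$tmin[i, ], g$tmax[i, ])
    rh09[, i] <- pmin(100, W %*% rh$rh09)
    rh15[, i] <- pmin(100, W %*% rh$rh15)
  }
  dl <- matrix(0, 52, n)
  for (la in unique(g$lat)) {
    cols <- which(g$lat == la)
    dl[, cols] <- day_length(la, 1:52)
  }
  list(tmin = tmin, tmax = tmax, tavg = (tmin + tmax) / 2,
       rain = rain, rh09 = rh09, rh15 = rh15, daylength = dl)
}

soil_moisture_matrix <- function(rain, evap, capacity, s0, s_max,
                                 tol = 1e-9, max_passes = 20) {
  n <- ncol(rain)
  delta <- (rain - evap) / capacity
  s <- matrix(0, 52, n)
  prev <- matrix(min(s_max, s0), 52, n)
  cur <- rep(min(s_max, max(0, s0)), n)
  for (pass in seq_len(max_passes)) {
    for (w in 1:52) {
      cur <- pmin(s_max, pmax(0, cur + delta[w, ]))
      s[w, ] <- cur
    }
    if (max(abs(s - prev)) < tol) break
    prev <- s
  }
  s
}

diapause_matrix <- function(tavg, daylength, params) {
  n <- ncol(tavg)
  nxt <- c(2:52, 1)
  shortening <- daylength[nxt, , drop = FALSE] < daylength
  lengthening <- daylength[nxt, , drop = FALSE] > daylength
  state <- rep(1L, n)
  days_in <- numeric(n)
  di <- matrix(1L, 52, n)
  prev <- NULL
  for (pass in 1:4) {
    for (w in 1:52) {
      on <- state == 1L
      induce <- on & shortening[w, ] & daylength[w, ] < params$DPD0 &
        tavg[w, ] < params$DPT0
      days_in[induce] <- 0
      state[induce] <- 0L
      off <- state == 0L & !induce
      days_in[off] <- days_in[off] + 7
      terminate <- off & lengthening[w, ] & tavg[w, ] > params$DPT1 &
        days_in >= params$DPD
      state[terminate] <- 1L
      di[w, ] <- state
    }
    if (!is.null(prev) && identical(di, prev)) break
    prev <- di
  }
  di
}

#' Run the engine over a whole climate grid
#'
#' Converts every cell's monthly climate to weekly series (identically to
#' [as_weekly_series()]) and computes the full annual result --- growth
#' index, stresses, degree-day voltinism, growth-season window and the
#' Ecoclimatic Index --- for each land cell. The computation is vectorised
#' across cells and agrees with per-cell [run_cell()] calls to within
#' floating-point roundoff.
#'
#' @param g a [climate_grid()].
#' @param params a [species_parameters()] object.
#' @param capacity,s0,k_e,s_max water-balance settings as in [run_cell()].
#' @param keep_weekly_gi attach the 52 x n weekly growth-index matrix as
#'   attribute `"gi_weekly"`?
#' @return A data frame of class `suitability_result` with one row per land
#'   cell: `lon`, `lat`, `elevation`, `ei`, `gi_a`, `si`, `cs`, `hs`, `ds`,
#'   `ws`, `hw`, `dd_annual`, `generations`, `growth_weeks`,
#'   `first_growth_week`, `last_growth_week`. The grid cell size is kept as
#'   attribute `"cell_size"`.
#' @export
run_grid <- function(g, params = default_parameters(),
                     capacity = 100, s0 = 0.5, k_e = 0.8, s_max = 1,
                     keep_weekly_gi = FALSE) {
  validate_climate_grid(g)
  keep <- which(g$land_mask)
  if (length(keep) == 0) stop("no land cells in grid")
  gl <- g
  gl$lon <- g$lon[keep]; gl$lat <- g$lat[keep]
  gl$tmin <- g$tmin[keep, , drop = FALSE]
  gl$tmax <- g$tmax[keep, , drop = FALSE]
  gl$prec <- g$prec[keep, , drop = FALSE]
  gl$elevation <- if (!is.null(g$elevation)) g$elevation[keep]
  m <- grid_weekly_matrices(gl)
  evap <- pmax(k_e * 7 * pmax(m$tavg, 0) * (1 - (m$rh09 + m$rh15) / 200), 0)
  soil <- soil_moisture_matrix(m$rain, evap, capacity, s0, s_max)
  ti <- temperature_index(m$tavg, params)
  mi <- moisture_index(soil, params)
  di <- diapause_matrix(m$tavg, m$daylength, params)
  gi <- ti * mi * di
  gi_a <- 100 * colSums(gi) / 52
  p <- params
  cs <- pmin(100, colSums(100 * abs(p$THCS) * pmax(p$TTCS - m$tmin, 0)))
  hs <- pmin(100, colSums(100 * p$THHS * pmax(m$tmax - p$TTHS, 0)))
  ds <- pmin(100, colSums(100 * abs(p$HDS) * pmax(p$SMDS - soil, 0)))
  ws <- pmin(100, colSums(100 * p$HWS * pmax(soil - p$SMWS, 0)))
  hw <- pmin(100, colSums(100 * p$PHW * pmax(m$tavg - p$TTHW, 0) *
                            (soil > p$MTHW)))
  dd <- colSums(7 * pmax(m$tavg - p$DV0, 0))
  gens <- dd / p$PDD
  ei <- ecoclimatic_index(gi_a, cs, hs, ds, ws, hw, dd, params)
  pos <- gi > 0
  growth_weeks <- colSums(pos)
  first_w <- apply(pos, 2, function(z) if (any(z)) which(z)[1] else NA_integer_)
  last_w <- apply(pos, 2, function(z) {
    i <- which(z); if (length(i)) i[length(i)] else NA_integer_
  })
  out <- data.frame(
    lon = gl$lon, lat = gl$lat,
    elevation = gl$elevation %||% NA_real_,
    ei = ei, gi_a = gi_a,
    si = (1 - cs / 100) * (1 - hs / 100) * (1 - ds / 100) *
         (1 - ws / 100) * (1 - hw / 100),
    cs = cs, hs = hs, ds = ds, ws = ws, hw = hw,
    dd_annual = dd, generations = gens,
    growth_weeks = as.integer(growth_weeks),
    first_growth_week = as.integer(first_w),
    last_growth_week = as.integer(last_w))
  attr(out, "cell_size") <- g$cell_size
  if (keep_weekly_gi) attr(out, "gi_weekly") <- gi
  class(out) <- c("suitability_result", "data.frame")
  out
}
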