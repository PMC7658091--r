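# Core weekly/annual ecoclimatic engine.
#
# The growth side follows the classic four-point response curves: a
# piecewise-linear trapezoid that is 0 at or below the limiting low
# threshold, rises linearly to 1 at the lower optimum, stays 1 across the
# optimal plateau, and falls back to 0 at the limiting high threshold.
# Stresses accumulate linearly in weekly threshold exceedance at the
# published weekly rates and are capped at 100.

trapezoid_index <- function(x, a, b, c_, d) {
  y <- ifelse(x <= a | x >= d, 0,
       ifelse(x < b, (x - a) / (b - a),
       ifelse(x <= c_, 1, (d - x) / (d - c_))))
  y
}

#' Weekly temperature index
#'
#' Piecewise-linear suitability response of population growth to weekly mean
#' temperature: 0 at or below `DV0` and at or above `DV3`, 1 on the optimal
#' plateau `[DV1, DV2]`, linear in between.
#'
#' @param tavg weekly mean temperature (degrees C); vectorised.
#' @param params a [species_parameters()] object.
#' @return index in \[0, 1\].
#' @export
#' @examples
#' p <- default_parameters()
#' temperature_index(c(12, 19.5, 27), p)  # 0, 0.5, 1
temperature_index <- function(tavg, params = default_parameters()) {
  trapezoid_index(tavg, params$DV0, params$DV1, params$DV2, params$DV3)
}

#' Weekly soil-moisture index
#'
#' The moisture analogue of [temperature_index()]: a trapezoid over
#' `(SM0, SM1, SM2, SM3)` in units of fraction of soil capacity.
#'
#' @param s weekly soil moisture (fraction of capacity, >= 0); vectorised.
#' @param params a [species_parameters()] object.
#' @return index in \[0, 1\].
#' @export
moisture_index <- function(s, params = default_parameters()) {
  trapezoid_index(s, params$SM0, params$SM1, params$SM2, params$SM3)
}

#' Weekly soil-moisture series (one-bucket balance)
#'
#' Iterates the weekly bucket recurrence
#' `S_w = min(s_max, max(0, S_{w-1} + (rain_w - evap_w) / capacity))`
#' around the 52-week year until a periodic steady state is reached
#' (`max |dS| < tol` between successive annual passes) or `max_passes`
#' passes have run. The default ceiling `s_max = 1` treats moisture above
#' field capacity as immediate runoff, which is what keeps humid temperate
#' winters free of spurious wet stress; raising `s_max` allows storage above
#' capacity so that wet-stress thresholds beyond 1 become reachable.
#'
#' @param rain 52 weekly precipitation values (mm).
#' @param evap 52 weekly evaporation values (mm).
#' @param capacity soil water holding capacity (mm); default 100.
#' @param s0 initial moisture (fraction of capacity); default 0.5.
#' @param s_max storage ceiling (fraction of capacity); default 1.
#' @param tol convergence tolerance on the pass-to-pass change.
#' @param max_passes maximum number of annual passes.
#' @return 52 weekly soil-moisture fractions.
#' @export
soil_moisture_series <- function(rain, evap, capacity = 100, s0 = 0.5,
                                 s_max = 1, tol = 1e-9, max_passes = 20) {
  stopifnot_len52(rain = rain, evap = evap)
  if (capacity <= 0) stop("capacity must be positive")
  if (s0 < 0) stop("initial soil moisture must be non-negative")
  delta <- (rain - evap) / capacity
  s <- numeric(52)
  prev <- rep(min(s_max, s0), 52)
  cur <- min(s_max, max(0, s0))
  for (pass in seq_len(max_passes)) {
    for (w in 1:52) {
      cur <- min(s_max, max(0, cur + delta[w]))
      s[w] <- cur
    }
    if (max(abs(s - prev)) < tol) break
    prev <- s
  }
  s
}

#' Weekly diapause indicator series
#'
#' Winter diapause (`DPSW = 0`): growth is switched off (indicator 0) at the
#' first week in the shortening-day half of the year where day length drops
#' below `DPD0` and mean temperature below `DPT0`, and switched back on at
#' the first later week in the lengthening-day half where mean temperature
#' exceeds `DPT1` and at least `DPD` days of diapause development have
#' accumulated. If induction never occurs the indicator is 1 all year.
#' The year is treated as periodic (the winter spans the calendar wrap), so
#' the switching rule is iterated to its annual fixed point.
#'
#' @param tavg 52 weekly mean temperatures (degrees C).
#' @param daylength 52 weekly day lengths (hours).
#' @param params a [species_parameters()] object (`DPSW` must be 0).
#' @return 52 indicators in \{0, 1\}.
#' @export
diapause_series <- function(tavg, daylength, params = default_parameters()) {
  stopifnot_len52(tavg = tavg, daylength = daylength)
  if (params$DPSW != 0)
    stop("only winter diapause (DPSW = 0) is implemented")
  nxt <- c(2:52, 1)
  shortening <- daylength[nxt] < daylength
  lengthening <- daylength[nxt] > daylength
  state <- 1L
  days_in <- 0
  di <- integer(52)
  prev <- NULL
  for (pass in 1:4) {
    for (w in 1:52) {
      if (state == 1L) {
        if (shortening[w] && daylength[w] < params$DPD0 &&
            tavg[w] < params$DPT0) {
          state <- 0L
          days_in <- 0
        }
      } else {
        days_in <- days_in + 7
        if (lengthening[w] && tavg[w] > params$DPT1 && days_in >= params$DPD)
          state <- 1L
      }
      di[w] <- state
    }
    if (!is.null(prev) && identical(di, prev)) break
    prev <- di
  }
  di
}

#' Weekly growth index
#'
#' `GI_w = TI_w * MI_w * DI_w`: the product of the temperature and moisture
#' suitability indices, annihilated during diapause.
#'
#' @param ti,mi 52 weekly indices in \[0, 1\].
#' @param di 52 weekly diapause indicators in \{0, 1\}.
#' @return 52 weekly growth indices in \[0, 1\].
#' @export
growth_index_series <- function(ti, mi, di) {
  stopifnot_len52(ti = ti, mi = mi, di = di)
  ti * mi * di
}

#' Annual growth index
#'
#' `GI_A = 100 * sum(GI_w) / 52`, on the 0--100 scale.
#'
#' @param gi 52 weekly growth indices in \[0, 1\].
#' @return annual growth index in \[0, 100\].
#' @export
annual_growth_index <- function(gi) {
  stopifnot_len52(gi = gi)
  100 * sum(gi) / 52
}

#' Annual stress indices
#'
#' Linear weekly accumulation of threshold exceedances at the published
#' per-week rates, each total capped at 100:
#' cold stress on weekly tmin below `TTCS`; heat stress on weekly tmax above
#' `TTHS`; dry stress on soil moisture below `SMDS`; wet stress on soil
#' moisture above `SMWS`; and the hot-wet interaction on weekly tavg above
#' `TTHW` while soil moisture exceeds `MTHW`. Rates printed with a negative
#' sign enter by their magnitude.
#'
#' @param tmin,tmax,tavg 52 weekly temperatures (degrees C).
#' @param soil 52 weekly soil-moisture fractions.
#' @param params a [species_parameters()] object.
#' @return list with components `cs`, `hs`, `ds`, `ws`, `hw`, each in
#'   \[0, 100\].
#' @export
stress_indices <- function(tmin, tmax, tavg, soil,
                           params = default_parameters()) {
  stopifnot_len52(tmin = tmin, tmax = tmax, tavg = tavg, soil = soil)
  p <- params
  list(
    cs = min(100, sum(100 * abs(p$THCS) * pmax(0, p$TTCS - tmin))),
    hs = min(100, sum(100 * p$THHS * pmax(0, tmax - p$TTHS))),
    ds = min(100, sum(100 * abs(p$HDS) * pmax(0, p$SMDS - soil))),
    ws = min(100, sum(100 * p$HWS * pmax(0, soil - p$SMWS))),
    hw = min(100, sum(100 * p$PHW * pmax(0, tavg - p$TTHW) * (soil > p$MTHW)))
  )
}

#' Annual degree days and generations
#'
#' Weekly degree days above the developmental threshold `DV0` accumulate as
#' `DD_w = 7 * max(0, tavg_w - DV0)`; the annual sum divided by the thermal
#' constant `PDD` gives the (real-valued) number of generations per year.
#'
#' @param tavg 52 weekly mean temperatures (degrees C).
#' @param params a [species_parameters()] object.
#' @return list with `dd_weekly` (52 values), `dd_annual`, `generations`.
#' @export
#' @examples
#' degree_days_annual(rep(24, 52))$generations  # 4368 / 595
degree_days_annual <- function(tavg, params = default_parameters()) {
  stopifnot_len52(tavg = tavg)
  dd_w <- 7 * pmax(0, tavg - params$DV0)
  dd <- sum(dd_w)
  list(dd_weekly = dd_w, dd_annual = dd, generations = dd / params$PDD)
}

#' Ecoclimatic Index
#'
#' `EI = GI_A * (1 - CS/100)(1 - HS/100)(1 - DS/100)(1 - WS/100)(1 - HW/100)`,
#' set to 0 when the annual degree days fall short of the thermal constant
#' `PDD` (the growing season is too short to complete a generation), and
#' clamped to \[0, 100\].
#'
#' @param gi_a annual growth index in \[0, 100\].
#' @param cs,hs,ds,ws,hw annual stress totals in \[0, 100\].
#' @param dd_annual annual degree days above `DV0`.
#' @param params a [species_parameters()] object.
#' @return Ecoclimatic Index in \[0, 100\]; vectorised over all arguments.
#' @export
ecoclimatic_index <- function(gi_a, cs, hs, ds, ws, hw, dd_annual,
                              params = default_parameters()) {
  si <- pmax(0, 1 - cs / 100) * pmax(0, 1 - hs / 100) *
        pmax(0, 1 - ds / 100) * pmax(0, 1 - ws / 100) *
        pmax(0, 1 - hw / 100)
  ei <- gi_a * si
  ei[dd_annual < params$PDD] <- 0
  pmin(100, pmax(0, ei))
}

#' Run the engine for one cell-year
#'
#' Composes the weekly water balance, the temperature / moisture / diapause
#' indices, the stress accumulators, degree-day voltinism and the annual
#' Ecoclimatic Index for a single cell's weekly climate.
#'
#' @param series a [weekly_series()] object.
#' @param params a [species_parameters()] object.
#' @param capacity soil water holding capacity (mm).
#' @param s0 initial soil moisture (fraction of capacity).
#' @param k_e evaporation coefficient (mm per degC per day).
#' @param s_max soil storage ceiling (fraction of capacity).
#' @param keep_weekly keep the weekly component series in the result?
#' @return An `annual_result` list: `gi_a`, `cs`, `hs`, `ds`, `ws`, `hw`,
#'   `si`, `dd_annual`, `generations`, `growth_weeks`, `first_growth_week`,
#'   `last_growth_week`, `ei`, and (optionally) `weekly` with `ti`, `mi`,
#'   `di`, `gi`, `soil`, `evap`, `dd`.
#' @export
run_cell <- function(series, params = default_parameters(),
                     capacity = 100, s0 = 0.5, k_e = 0.8, s_max = 1,
                     keep_weekly = TRUE) {
  if (!inherits(series, "weekly_series"))
    stop("series must be a weekly_series object")
  evap <- weekly_evaporation(series$tavg, series$rh09, series$rh15, k_e = k_e)
  soil <- soil_moisture_series(series$prec, evap, capacity = capacity,
                               s0 = s0, s_max = s_max)
  ti <- temperature_index(series$tavg, params)
  mi <- moisture_index(soil, params)
  di <- diapause_series(series$tavg, series$daylength, params)
  gi <- growth_index_series(ti, mi, di)
  gi_a <- annual_growth_index(gi)
  st <- stress_indices(series$tmin, series$tmax, series$tavg, soil, params)
  dd <- degree_days_annual(series$tavg, params)
  ei <- ecoclimatic_index(gi_a, st$cs, st$hs, st$ds, st$ws, st$hw,
                          dd$dd_annual, params)
  pos <- which(gi > 0)
  res <- list(
    gi_a = gi_a, cs = st$cs, hs = st$hs, ds = st$ds, ws = st$ws, hw = st$hw,
    si = (1 - st$cs / 100) * (1 - st$hs / 100) * (1 - st$ds / 100) *
         (1 - st$ws / 100) * (1 - st$hw / 100),
    dd_annual = dd$dd_annual, generations = dd$generations,
    growth_weeks = length(pos),
    first_growth_week = if (length(pos)) min(pos) else NA_integer_,
    last_growth_week = if (length(pos)) max(pos) else NA_integer_,
    ei = ei)
  if (keep_weekly)
    res$weekly <- list(ti = ti, mi = mi, di = di, gi = gi, soil = soil,
                       evap = evap, dd = dd$dd_weekly)
  class(res) <- "annual_result"
  res
}

#' @export
print.annual_result <- function(x, ...) {
  cat(sprintf("<annual_result> EI = %.2f (GI_A = %.2f, SI = %.3f)\n",
              x$ei, x$gi_a, x$si))
  cat(sprintf("  stresses CS/HS/DS/WS/HW: %.2f / %.2f / %.2f / %.2f / %.2f\n",
              x$cs, x$hs, x$ds, x$ws, x$hw))
  cat(sprintf("  degree days %.1f -> %.2f generations; %d growth weeks (%s..%s)\n",
              x$dd_annual, x$generations, x$growth_weeks,
              x$first_growth_week, x$last_growth_week))
  invisible(x)
}
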