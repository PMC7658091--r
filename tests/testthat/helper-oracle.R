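# Straight-line scalar re-implementation of the per-cell engine, written
# independently of the package internals (plain loops and if-chains). Used
# as the second route in the dual-route equivalence checks.

oracle_cell <- function(tmin, tmax, rain, rh09, rh15, daylength,
                        P = default_parameters(),
                        capacity = 100, s0 = 0.5, ke = 0.8, smax = 1) {
  tavg <- (tmin + tmax) / 2

  evap <- numeric(52)
  for (w in 1:52) {
    e <- ke * 7 * max(0, tavg[w]) * (1 - (rh09[w] + rh15[w]) / 200)
    evap[w] <- if (e > 0) e else 0
  }

  s <- numeric(52)
  cur <- min(smax, max(0, s0))
  old <- rep(min(smax, s0), 52)
  for (pass in 1:20) {
    for (w in 1:52) {
      cur <- cur + (rain[w] - evap[w]) / capacity
      if (cur < 0) cur <- 0
      if (cur > smax) cur <- smax
      s[w] <- cur
    }
    if (max(abs(s - old)) < 1e-9) break
    old <- s
  }

  tramp <- function(x, a, b, cc, d) {
    if (x <= a || x >= d) return(0)
    if (x < b) return((x - a) / (b - a))
    if (x <= cc) return(1)
    (d - x) / (d - cc)
  }
  ti <- vapply(tavg, tramp, 0, P$DV0, P$DV1, P$DV2, P$DV3)
  mi <- vapply(s, tramp, 0, P$SM0, P$SM1, P$SM2, P$SM3)

  # winter diapause state machine, iterated to its periodic fixed point
  di <- rep(1L, 52)
  state <- 1L; dev_days <- 0
  last <- NULL
  for (pass in 1:4) {
    for (w in 1:52) {
      dl_next <- daylength[if (w == 52) 1 else w + 1]
      if (state == 1L) {
        if (dl_next < daylength[w] && daylength[w] < P$DPD0 &&
            tavg[w] < P$DPT0) {
          state <- 0L; dev_days <- 0
        }
      } else {
        dev_days <- dev_days + 7
        if (dl_next > daylength[w] && tavg[w] > P$DPT1 && dev_days >= P$DPD)
          state <- 1L
      }
      di[w] <- state
    }
    if (!is.null(last) && all(di == last)) break
    last <- di
  }

  gi <- ti * mi * di
  gi_a <- 100 * sum(gi) / 52

  cs <- 0; hs <- 0; ds <- 0; ws <- 0; hw <- 0
  for (w in 1:52) {
    if (tmin[w] < P$TTCS) cs <- cs + 100 * abs(P$THCS) * (P$TTCS - tmin[w])
    if (tmax[w] > P$TTHS) hs <- hs + 100 * P$THHS * (tmax[w] - P$TTHS)
    if (s[w] < P$SMDS) ds <- ds + 100 * abs(P$HDS) * (P$SMDS - s[w])
    if (s[w] > P$SMWS) ws <- ws + 100 * P$HWS * (s[w] - P$SMWS)
    if (tavg[w] > P$TTHW && s[w] > P$MTHW)
      hw <- hw + 100 * P$PHW * (tavg[w] - P$TTHW)
  }
  cs <- min(100, cs); hs <- min(100, hs); ds <- min(100, ds)
  ws <- min(100, ws); hw <- min(100, hw)

  dd <- 0
  for (w in 1:52) if (tavg[w] > P$DV0) dd <- dd + 7 * (tavg[w] - P$DV0)

  ei <- gi_a * (1 - cs / 100) * (1 - hs / 100) * (1 - ds / 100) *
    (1 - ws / 100) * (1 - hw / 100)
  if (dd < P$PDD) ei <- 0
  if (ei < 0) ei <- 0
  if (ei > 100) ei <- 100

  active <- which(gi > 0)
  list(ei = ei, gi_a = gi_a, cs = cs, hs = hs, ds = ds, ws = ws, hw = hw,
       dd_annual = dd, generations = dd / P$PDD,
       growth_weeks = length(active),
       first_growth_week = if (length(active)) min(active) else NA_integer_,
       last_growth_week = if (length(active)) max(active) else NA_integer_,
       soil = s, gi = gi)
}
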