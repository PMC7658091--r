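#' Saturation vapour pressure (Magnus form)
#'
#' `e_s(T) = 6.112 * exp(17.62 T / (243.12 + T))`, in hPa, valid for air
#' temperatures between -60 and 60 degrees C.
#'
#' @param t air temperature (degrees C); vectorised.
#' @return saturation vapour pressure in hPa.
#' @export
#' @examples
#' saturation_vapour_pressure(0)   # 6.112
#' saturation_vapour_pressure(20)  # ~23.4
saturation_vapour_pressure <- function(t) {
  if (any(t < -60 | t > 60, na.rm = TRUE))
    stop("temperature outside the supported range [-60, 60] degC")
  6.112 * exp(17.62 * t / (243.12 + t))
}

#' Derive morning and afternoon relative humidity from tmin/tmax
#'
#' Completes minimum/maximum temperature climatologies into the 09:00 and
#' 15:00 relative humidities the weekly water balance needs. The dewpoint is
#' assumed equal to the daily minimum (so the actual vapour pressure is
#' `e_s(tmin)`), and the 09:00 / 15:00 air temperatures sit at fixed fractions
#' 0.4 and 0.9 of the diurnal range above tmin. Both humidities are capped at
#' 100%.
#'
#' @param tmin,tmax daily minimum / maximum temperature (degrees C);
#'   vectorised, `tmin <= tmax` elementwise.
#' @return list with components `rh09` and `rh15` (percent, in (0, 100]).
#' @export
derive_relative_humidity <- function(tmin, tmax) {
  if (any(tmin > tmax, na.rm = TRUE))
    stop("tmin must not exceed tmax")
  e_a <- saturation_vapour_pressure(tmin)
  t09 <- tmin + 0.4 * (tmax - tmin)
  t15 <- tmin + 0.9 * (tmax - tmin)
  list(rh09 = pmin(100, 100 * e_a / saturation_vapour_pressure(t09)),
       rh15 = pmin(100, 100 * e_a / saturation_vapour_pressure(t15)))
}

#' Weekly potential evaporation
#'
#' A temperature-and-saturation-deficit bulk formula driving the soil-moisture
#' bucket: `E_w = k_e * 7 * max(0, tavg) * (1 - (rh09 + rh15)/200)` mm per
#' week. Evaporation is zero for frozen weeks (`tavg <= 0`) and saturated air.
#'
#' @param tavg weekly mean temperature (degrees C); vectorised.
#' @param rh09,rh15 relative humidity at 09:00 and 15:00 (percent).
#' @param k_e evaporation coefficient (mm per degC per day); default 0.8.
#' @return weekly evaporation in mm (non-negative).
#' @export
#' @examples
#' weekly_evaporation(10, 50, 50)  # 0.8 * 7 * 10 * 0.5 = 28
weekly_evaporation <- function(tavg, rh09, rh15, k_e = 0.8) {
  if (any(rh09 < 0 | rh09 > 100 | rh15 < 0 | rh15 > 100, na.rm = TRUE))
    stop("relative humidities must lie in [0, 100]")
  pmax(0, k_e * 7 * pmax(0, tavg) * (1 - (rh09 + rh15) / 200))
}

#' Day length from solar declination
#'
#' Standard astronomical day length (hours of light) for a latitude and week
#' of the 52-week model year, evaluated at the week's middle day:
#' declination `delta = 23.44 deg * sin(2 pi (284 + doy) / 365)` and
#' `daylength = (24 / pi) * acos(-tan(lat) tan(delta))`. Latitudes beyond the
#' polar circles are rejected (no polar day/night handling).
#'
#' @param latitude degrees north (scalar), `|latitude| <= 66.5`.
#' @param week week index 1..52; vectorised.
#' @return day length in hours.
#' @export
#' @examples
#' day_length(47.38, 25)  # midsummer at Zurich's latitude, > 15.5 h
day_length <- function(latitude, week = 1:52) {
  if (length(latitude) != 1L || !is.finite(latitude))
    stop("latitude must be a single finite value")
  if (abs(latitude) > 66.5)
    stop("latitude beyond the polar circle is not supported")
  if (any(week < 1 | week > 52)) stop("week must lie in 1..52")
  doy <- 7 * week - 3.5
  decl <- (23.44 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
  x <- pmin(1, pmax(-1, -tan(latitude * pi / 180) * tan(decl)))
  (24 / pi) * acos(x)
}
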