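# Monthly -> weekly disaggregation for the 52-week (364-day) model year.
#
# Temperatures (and humidities) are interpolated linearly between month
# midpoints (day-of-year centres of a non-leap 365-day calendar, periodic
# wrap) and sampled at the midpoints of the 52 seven-day weeks.
# Precipitation sums are apportioned: each month's total is split across the
# weeks in proportion to the number of that month's days falling in each
# week (within days 1..364), so annual totals are conserved exactly.

month_lengths <- function() c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

month_midpoints <- function() {
  len <- month_lengths()
  cumsum(c(0, len[-12])) + len / 2
}

# 52 x 12 linear-interpolation weight matrix (rows sum to 1).
weekly_interp_matrix <- function() {
  mids <- month_midpoints()
  anchors <- c(mids[12] - 365, mids, mids[1] + 365)   # periodic wrap
  anchor_month <- c(12, 1:12, 1)
  t_w <- 7 * (1:52) - 3.5
  W <- matrix(0, 52, 12)
  for (w in 1:52) {
    j <- findInterval(t_w[w], anchors)
    f <- (t_w[w] - anchors[j]) / (anchors[j + 1] - anchors[j])
    W[w, anchor_month[j]] <- W[w, anchor_month[j]] + (1 - f)
    W[w, anchor_month[j + 1]] <- W[w, anchor_month[j + 1]] + f
  }
  W
}

# 52 x 12 apportionment matrix for monthly sums (columns sum to 1).
weekly_apportion_matrix <- function() {
  len <- month_lengths()
  month_of_day <- rep(1:12, times = len)[1:364]   # day 365 dropped
  week_of_day <- rep(1:52, each = 7)
  A <- matrix(0, 52, 12)
  for (d in 1:364)
    A[week_of_day[d], month_of_day[d]] <- A[week_of_day[d], month_of_day[d]] + 1
  sweep(A, 2, colSums(A), "/")
}

the_interp_matrix <- NULL
the_apportion_matrix <- NULL

interp_matrix <- function() {
  if (is.null(the_interp_matrix))
    utils::assignInMyNamespace("the_interp_matrix", weekly_interp_matrix())
  the_interp_matrix
}

apportion_matrix <- function() {
  if (is.null(the_apportion_matrix))
    utils::assignInMyNamespace("the_apportion_matrix", weekly_apportion_matrix())
  the_apportion_matrix
}

#' Convert monthly climate values to 52 weekly values
#'
#' Temperatures are interpolated between month midpoints and sampled at week
#' midpoints of the 364-day model year; the monthly precipitation sums are
#' apportioned to weeks by day counts so that the annual total is conserved
#' exactly.
#'
#' @param tmin,tmax 12 monthly mean daily minimum / maximum temperatures
#'   (degrees C).
#' @param prec 12 monthly precipitation sums (mm).
#' @return list with 52-long components `tmin`, `tmax`, `tavg`, `prec`.
#' @export
#' @examples
#' w <- monthly_to_weekly(rep(5, 12), rep(15, 12), rep(75, 12))
#' range(w$tavg)      # constant 10
#' sum(w$prec)        # 900, conserved
monthly_to_weekly <- function(tmin, tmax, prec) {
  for (v in list(tmin, tmax, prec))
    if (length(v) != 12L || anyNA(v)) stop("need 12 finite monthly values")
  W <- interp_matrix(); A <- apportion_matrix()
  tmin_w <- as.vector(W %*% tmin)
  tmax_w <- as.vector(W %*% tmax)
  list(tmin = tmin_w, tmax = tmax_w, tavg = (tmin_w + tmax_w) / 2,
       prec = as.vector(A %*% prec))
}

#' Weekly climate series for one grid cell
#'
#' Bundles the 52-week climate driving the per-cell engine: temperatures,
#' precipitation, 09:00/15:00 relative humidity and day length. All series
#' must be complete (no gaps).
#'
#' @param tmin,tmax,tavg weekly temperatures (degrees C); `tavg` defaults to
#'   the min/max midpoint.
#' @param prec weekly precipitation (mm, non-negative).
#' @param rh09,rh15 weekly relative humidity at 09:00 / 15:00 (percent).
#' @param daylength weekly day length (hours).
#' @return An object of class `weekly_series`.
#' @export
weekly_series <- function(tmin, tmax, prec, rh09, rh15, daylength,
                          tavg = (tmin + tmax) / 2) {
  stopifnot_len52(tmin = tmin, tmax = tmax, tavg = tavg, prec = prec,
                  rh09 = rh09, rh15 = rh15, daylength = daylength)
  if (any(tmin > tavg + 1e-9) || any(tavg > tmax + 1e-9))
    stop("weekly series must satisfy tmin <= tavg <= tmax")
  if (any(prec < 0)) stop("negative weekly precipitation")
  structure(list(tmin = tmin, tmax = tmax, tavg = tavg, prec = prec,
                 rh09 = rh09, rh15 = rh15, daylength = daylength),
            class = "weekly_series")
}

#' Build the weekly engine input for one cell
#'
#' Converts a cell's monthly climate ([extract_location()]) into the weekly
#' series the engine consumes: monthly relative humidity is derived from
#' tmin/tmax (dewpoint = tmin), temperatures and humidities are interpolated
#' to week midpoints, precipitation is apportioned conservatively, and day
#' length follows from the cell latitude.
#'
#' @param cell a `cell_monthly` object (or any list with `lon`, `lat`,
#'   `tmin`, `tmax`, `prec` monthly components).
#' @return A `weekly_series`.
#' @export
as_weekly_series <- function(cell) {
  rh <- derive_relative_humidity(cell$tmin, cell$tmax)
  w <- monthly_to_weekly(cell$tmin, cell$tmax, cell$prec)
  W <- interp_matrix()
  weekly_series(tmin = w$tmin, tmax = w$tmax, prec = w$prec,
                rh09 = pmin(100, as.vector(W %*% rh$rh09)),
                rh15 = pmin(100, as.vector(W %*% rh$rh15)),
                daylength = day_length(cell$lat, 1:52))
}
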