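#' Monthly climate-change signal
#'
#' A delta-change signal for one emission scenario and future period:
#' 12 monthly temperature deltas (degrees C, added to both tmin and tmax so
#' the diurnal range is unchanged) and 12 monthly precipitation deltas
#' (percent, applied multiplicatively so precipitation can never go
#' negative).
#'
#' @param scenario_id scenario label (e.g. `"RCP3PD"`, `"A1B"`, `"A2"`).
#' @param period period label (e.g. `"2070-2099"`).
#' @param d_temp 12 monthly temperature deltas (degrees C), or a single
#'   value recycled.
#' @param d_prec 12 monthly precipitation deltas (percent, > -100), or a
#'   single value recycled.
#' @return An object of class `change_signal`.
#' @export
change_signal <- function(scenario_id, period, d_temp = 0, d_prec = 0) {
  if (length(d_temp) == 1L) d_temp <- rep(d_temp, 12)
  if (length(d_prec) == 1L) d_prec <- rep(d_prec, 12)
  if (length(d_temp) != 12L || length(d_prec) != 12L)
    stop("change signals need 12 monthly values per variable")
  if (any(d_prec <= -100))
    stop("precipitation deltas must exceed -100 percent")
  structure(list(scenario_id = scenario_id, period = period,
                 d_temp = as.numeric(d_temp), d_prec = as.numeric(d_prec)),
            class = "change_signal")
}

#' @export
print.change_signal <- function(x, ...) {
  cat("<change_signal> ", x$scenario_id, " ", x$period,
      ": mean dT = ", round(mean(x$d_temp), 2), " degC, mean dP = ",
      round(mean(x$d_prec), 2), " %\n", sep = "")
  invisible(x)
}

#' Apply a change signal to a baseline grid (delta-change method)
#'
#' Builds a future-climate grid by adding the monthly temperature deltas to
#' both tmin and tmax and scaling monthly precipitation by
#' `1 + d_prec / 100`. Relative humidity is not stored on the grid; it is
#' re-derived from the new temperatures downstream, so the scenario grid is
#' internally consistent. All grid validation rules are re-checked.
#'
#' @param g a baseline [climate_grid()].
#' @param signal a [change_signal()].
#' @return A new `climate_grid`; a zero signal returns a grid identical to
#'   the baseline.
#' @export
apply_deltas <- function(g, signal) {
  validate_climate_grid(g)
  if (!inherits(signal, "change_signal")) stop("signal must be a change_signal")
  dT <- matrix(signal$d_temp, nrow = length(g$lon), ncol = 12, byrow = TRUE)
  fP <- matrix(1 + signal$d_prec / 100, nrow = length(g$lon), ncol = 12,
               byrow = TRUE)
  out <- g
  out$tmin <- g$tmin + dT
  out$tmax <- g$tmax + dT
  out$prec <- g$prec * fP
  validate_climate_grid(out)
  out
}

#' Construct a seasonally shaped change signal from annual means
#'
#' Emulates the shape of alpine climate-change signals: warming and
#' precipitation change are strongest in summer, with the monthly deltas
#' scaled so their annual means equal the requested values exactly
#' (`delta_m = annual * (1 + 0.3 cos(2 pi (m - 7) / 12))`). A zero annual
#' delta yields an all-zero signal.
#'
#' @param scenario_id,period labels, as in [change_signal()].
#' @param d_temp_annual annual-mean temperature delta (degrees C).
#' @param d_prec_annual annual-mean precipitation delta (percent, > -100).
#' @return A [change_signal()].
#' @export
make_change_signal <- function(scenario_id, period,
                               d_temp_annual = 0, d_prec_annual = 0) {
  shape <- 1 + 0.3 * cos(2 * pi * ((1:12) - 7) / 12)
  change_signal(scenario_id, period,
                d_temp = d_temp_annual * shape,
                d_prec = d_prec_annual * shape)
}

#' Default scenario suite (three scenarios, three periods)
#'
#' Nine seasonally shaped change signals mirroring the magnitude and layout
#' of the Swiss CH2011-style scenario set: the mitigation pathway RCP3PD and
#' the non-intervention pathways A1B and A2, each for 2020--2049, 2045--2074
#' and 2070--2099. Annual warming ranges from +1.2 degC (RCP3PD, near term)
#' to +4.1 degC (A2, end of century), with mild summer drying.
#'
#' @return A named list of nine [change_signal()] objects
#'   (`"RCP3PD 2020-2049"`, ...).
#' @export
default_change_signals <- function() {
  spec <- list(
    RCP3PD = list(dT = c(1.2, 1.5, 1.6), dP = c(-2, -3, -3)),
    A1B = list(dT = c(1.4, 2.8, 3.7), dP = c(-3, -6, -9)),
    A2 = list(dT = c(1.3, 2.7, 4.1), dP = c(-3, -6, -10)))
  periods <- c("2020-2049", "2045-2074", "2070-2099")
  out <- list()
  for (sc in names(spec)) {
    for (k in 1:3) {
      sig <- make_change_signal(sc, periods[k],
                                d_temp_annual = spec[[sc]]$dT[k],
                                d_prec_annual = spec[[sc]]$dP[k])
      out[[paste(sc, periods[k])]] <- sig
    }
  }
  out
}
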