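#' Published Swiss reference results
#'
#' Summary tables from the published Swiss high-resolution ecoclimatic
#' analysis of *Halyomorpha halys* that this package re-implements, shipped
#' as reference data because the underlying 0.02-degree MeteoSwiss
#' climatology and CH2011 change signals are proprietary and cannot be
#' redistributed.
#'
#' `swiss_reference_areas()` returns the national area percentages
#' (suitable EI > 5, highly suitable EI > 15, one/two generations) for the
#' 1981--2010 reference period, the individual years 2015--2019, and the
#' RCP3PD / A1B / A2 scenarios over three future periods, all over the full
#' 11,211-cell grid.
#'
#' `swiss_reference_locations()` returns the ten reference localities with
#' their coordinates, altitudes and published EI, generations and
#' growth-week values for the reference period and the A2 2070--2099
#' scenario.
#'
#' @return A data frame.
#' @export
swiss_reference_areas <- function() {
  utils::read.csv(system.file("extdata", "swiss_area_summary.csv",
                              package = "climsuit"),
                  stringsAsFactors = FALSE,
                  colClasses = c(period = "character"))
}

#' @rdname swiss_reference_areas
#' @export
swiss_reference_locations <- function() {
  utils::read.csv(system.file("extdata", "swiss_locations.csv",
                              package = "climsuit"),
                  stringsAsFactors = FALSE)
}
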