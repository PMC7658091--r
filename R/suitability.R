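#' Classify Ecoclimatic Index values into suitability categories
#'
#' `unsuitable` below 1 (the species cannot persist), `marginal` for
#' 1 <= EI <= 5, `suitable` for 5 < EI <= 15, `highly_suitable` above 15.
#' The thresholds at 5 and 15 are strict, matching the "EI > 5" / "EI > 15"
#' convention of suitability mapping.
#'
#' @param ei Ecoclimatic Index values in \[0, 100\]; vectorised.
#' @return factor with ordered levels `unsuitable < marginal < suitable <
#'   highly_suitable`.
#' @export
#' @examples
#' classify_suitability(c(0.5, 1, 5, 5.1, 15, 15.1))
classify_suitability <- function(ei) {
  if (any(ei < 0 | ei > 100, na.rm = TRUE))
    stop("EI values must lie in [0, 100]")
  lv <- c("unsuitable", "marginal", "suitable", "highly_suitable")
  out <- ifelse(ei < 1, lv[1],
         ifelse(ei <= 5, lv[2],
         ifelse(ei <= 15, lv[3], lv[4])))
  factor(out, levels = lv, ordered = TRUE)
}

#' Area percentages of suitability and voltinism classes
#'
#' Summarises a grid result into the share of cells that are climatically
#' suitable (EI > 5), highly suitable (EI > 15), and able to support one or
#' two generations per year. Percentages are taken over *all* cells in the
#' result (alpine cells included); rounding is left to the presentation
#' layer.
#'
#' @param result a `suitability_result` data frame from [run_grid()].
#' @param thresholds EI thresholds for (suitable, highly suitable).
#' @return An object of class `suitability_summary`: `pct_suitable`,
#'   `pct_highly_suitable`, `pct_one_gen`, `pct_two_gen`, `n_cells`.
#' @export
area_percentages <- function(result, thresholds = c(5, 15)) {
  if (!is.data.frame(result) || nrow(result) == 0)
    stop("empty result grid")
  n <- nrow(result)
  structure(list(
    pct_suitable = 100 * sum(result$ei > thresholds[1]) / n,
    pct_highly_suitable = 100 * sum(result$ei > thresholds[2]) / n,
    pct_one_gen = 100 * sum(result$generations >= 1) / n,
    pct_two_gen = 100 * sum(result$generations >= 2) / n,
    n_cells = n), class = "suitability_summary")
}

#' @export
print.suitability_summary <- function(x, ...) {
  cat(sprintf(paste0("<suitability_summary> n = %d cells\n",
                     "  suitable (EI > 5):        %5.1f %%\n",
                     "  highly suitable (EI > 15): %5.1f %%\n",
                     "  >= 1 generation:           %5.1f %%\n",
                     "  >= 2 generations:          %5.1f %%\n"),
              x$n_cells, x$pct_suitable, x$pct_highly_suitable,
              x$pct_one_gen, x$pct_two_gen))
  invisible(x)
}

#' Per-location suitability table across scenarios
#'
#' Extracts the grid cell for each query location from each (baseline or
#' delta-adjusted) climate grid, runs the per-cell engine, and tabulates the
#' Ecoclimatic Index, generations per year and number of growth weeks.
#' Presentation follows the conventional rounding: EI to integer,
#' generations to two decimals, weeks to integer.
#'
#' @param grids a named list of [climate_grid()] objects (e.g. baseline and
#'   scenario grids).
#' @param locations a data frame with columns `name`, `lon`, `lat`.
#' @param params a [species_parameters()] object.
#' @param ... water-balance settings passed to [run_cell()].
#' @return A data frame with one row per location x grid: `location`,
#'   `scenario`, `ei`, `generations`, `growth_weeks`.
#' @export
location_table <- function(grids, locations, params = default_parameters(),
                           ...) {
  if (!is.data.frame(locations))
    stop("locations must be a data frame with name, lon, lat")
  if (nrow(locations) == 0)
    return(data.frame(location = character(), scenario = character(),
                      ei = numeric(), generations = numeric(),
                      growth_weeks = integer()))
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("grids must be a named list")
  rows <- list()
  for (sc in names(grids)) {
    for (i in seq_len(nrow(locations))) {
      cell <- extract_location(grids[[sc]], locations$lon[i],
                               locations$lat[i], name = locations$name[i])
      r <- run_cell(as_weekly_series(cell), params, keep_weekly = FALSE, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        location = locations$name[i], scenario = sc,
        ei = round(r$ei), generations = round(r$generations, 2),
        growth_weeks = as.integer(r$growth_weeks))
    }
  }
  do.call(rbind, rows)
}

#' Growth-season window of a weekly growth-index series
#'
#' The first and last calendar week with `GI_w > 0` and the count of such
#' weeks. Mid-season zero dips are ignored: the window is bounded by the
#' outermost active weeks, matching the "start/stop of activity" reading of
#' seasonal phenology.
#'
#' @param gi 52 weekly growth indices.
#' @return list with `first_week`, `last_week`, `growth_weeks`.
#' @export
phenology_window <- function(gi) {
  stopifnot_len52(gi = gi)
  pos <- which(gi > 0)
  list(first_week = if (length(pos)) min(pos) else NA_integer_,
       last_week = if (length(pos)) max(pos) else NA_integer_,
       growth_weeks = length(pos))
}

#' Phenology shift between a baseline and a scenario year
#'
#' Compares growth-season windows: `spring_shift = first_week(baseline) -
#' first_week(scenario)` and `autumn_shift = last_week(scenario) -
#' last_week(baseline)`, so positive values mean an earlier start of spring
#' activity and a later stop of autumn activity.
#'
#' @param gi_baseline,gi_scenario 52 weekly growth indices each.
#' @return list with `spring_shift` and `autumn_shift` (weeks).
#' @export
phenology_shift <- function(gi_baseline, gi_scenario) {
  wb <- phenology_window(gi_baseline)
  ws <- phenology_window(gi_scenario)
  if (wb$growth_weeks == 0 || ws$growth_weeks == 0)
    stop("growth window undefined: a series has no week with GI > 0")
  list(spring_shift = wb$first_week - ws$first_week,
       autumn_shift = ws$last_week - wb$last_week)
}
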