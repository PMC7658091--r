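# High-level pipeline drivers: read/validate -> engine -> summaries, with a
# machine-readable run manifest. These are the programmatic equivalents of a
# command-line front end; the analysis/ scripts are thin wrappers over them.

param_fingerprint <- function(params) {
  # order-stable FNV-1a over the canonical text rendering
  txt <- paste(parameter_names(),
               vapply(parameter_names(), function(nm) fmt_full(params[[nm]]),
                      character(1)),
               collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

resolve_grid <- function(climate) {
  if (inherits(climate, "climate_grid")) return(climate)
  if (is.character(climate) && length(climate) == 1L)
    return(read_monthly_grid(climate))
  stop("climate must be a climate_grid or a path to a climate CSV")
}

write_manifest <- function(out_dir, inputs, params, extra = list()) {
  manifest <- c(list(
    package = "climsuit",
    version = as.character(utils::packageVersion("climsuit")),
    inputs = inputs,
    parameter_fingerprint = param_fingerprint(params)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

summary_row <- function(label, period, s) {
  data.frame(scenario = label, period = period,
             pct_suitable = s$pct_suitable,
             pct_highly_suitable = s$pct_highly_suitable,
             pct_one_gen = s$pct_one_gen,
             pct_two_gen = s$pct_two_gen,
             n_cells = s$n_cells,
             stringsAsFactors = FALSE)
}

#' Run the baseline suitability pipeline
#'
#' Reads (or takes) a monthly climate grid, runs the ecoclimatic engine over
#' every land cell, and writes the per-cell results (`cells.csv`), the area
#' summary (`summary.csv`) and a run manifest (`manifest.json`) to
#' `out_dir`. Output is deterministic: running twice on the same inputs
#' yields byte-identical CSVs.
#'
#' @param climate a [climate_grid()] or path to a climate CSV.
#' @param out_dir output directory (created if needed).
#' @param params a [species_parameters()] object or path to a parameter
#'   file; `NULL` uses the defaults.
#' @param label label for the summary row; default `"reference"`.
#' @param ... water-balance settings passed to [run_grid()].
#' @return Invisibly, a list with `result` (per-cell data frame) and
#'   `summary`.
#' @export
pipeline_run <- function(climate, out_dir, params = NULL,
                         label = "reference", ...) {
  g <- resolve_grid(climate)
  p <- if (is.null(params)) default_parameters()
       else if (inherits(params, "species_parameters")) params
       else load_parameters(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_grid(g, p, ...)
  s <- area_percentages(res)
  utils::write.csv(format(res, digits = 10, trim = TRUE, scientific = FALSE),
                   file.path(out_dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(summary_row(label, "baseline", s),
                   file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir,
                 inputs = list(climate = if (is.character(climate)) climate
                               else sprintf("<in-memory grid, %d cells>",
                                            length(g$lon))),
                 params = p,
                 extra = list(n_cells = nrow(res)))
  invisible(list(result = res, summary = s))
}

#' Run the delta-change scenario suite
#'
#' Applies each change signal to the baseline grid, runs the engine, and
#' writes one summary row per scenario x period (plus the baseline row) to
#' `scenario_summary.csv` in `out_dir`, mirroring the layout of published
#' scenario tables.
#'
#' @param climate a [climate_grid()] or path to a climate CSV.
#' @param signals a named list of [change_signal()] objects; default
#'   [default_change_signals()].
#' @param out_dir output directory.
#' @param params parameters as in [pipeline_run()].
#' @param ... passed to [run_grid()].
#' @return Invisibly, the summary data frame.
#' @export
pipeline_scenarios <- function(climate, signals = default_change_signals(),
                               out_dir, params = NULL, ...) {
  g <- resolve_grid(climate)
  p <- if (is.null(params)) default_parameters()
       else if (inherits(params, "species_parameters")) params
       else load_parameters(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(summary_row("reference", "baseline",
                           area_percentages(run_grid(g, p, ...))))
  for (nm in names(signals)) {
    sig <- signals[[nm]]
    res <- run_grid(apply_deltas(g, sig), p, ...)
    rows[[length(rows) + 1L]] <- summary_row(sig$scenario_id, sig$period,
                                             area_percentages(res))
  }
  out <- do.call(rbind, rows)
  utils::write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                   file.path(out_dir, "scenario_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir,
                 inputs = list(climate = if (is.character(climate)) climate
                               else sprintf("<in-memory grid, %d cells>",
                                            length(g$lon)),
                               signals = names(signals)),
                 params = p,
                 extra = list(n_combinations = length(signals)))
  invisible(out)
}

#' Validate occurrence records against modelled suitability
#'
#' Runs the engine on the supplied climate, overlays the occurrence records,
#' and writes the overlap report (`overlap_report.csv`, with the per-year
#' breakdown when available) to `out_dir`.
#'
#' @param climate a [climate_grid()] or path to a climate CSV.
#' @param occurrences occurrence data frame or path to an occurrence CSV.
#' @param out_dir output directory.
#' @param params parameters as in [pipeline_run()].
#' @param thresholds EI thresholds, default `c(5, 15)`.
#' @param ... passed to [run_grid()].
#' @return Invisibly, the [overlap_statistics()] list.
#' @export
pipeline_validate <- function(climate, occurrences, out_dir, params = NULL,
                              thresholds = c(5, 15), ...) {
  g <- resolve_grid(climate)
  p <- if (is.null(params)) default_parameters()
       else if (inherits(params, "species_parameters")) params
       else load_parameters(params)
  recs <- if (is.data.frame(occurrences)) occurrences
          else read_occurrences(occurrences)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_grid(g, p, ...)
  ov <- overlap_statistics(recs, res, thresholds)
  report <- data.frame(
    scope = "all records",
    n = ov$n_in_bounds,
    fraction_suitable = ov$fraction_suitable,
    fraction_highly_suitable = ov$fraction_highly_suitable)
  if (!is.null(ov$per_year))
    report <- rbind(report, data.frame(
      scope = paste("year", ov$per_year$year), n = ov$per_year$n,
      fraction_suitable = ov$per_year$fraction_suitable,
      fraction_highly_suitable = ov$per_year$fraction_highly_suitable))
  utils::write.csv(format(report, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   file.path(out_dir, "overlap_report.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir,
                 inputs = list(n_records = nrow(recs)),
                 params = p)
  invisible(ov)
}
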