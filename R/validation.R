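#' Read occurrence records from CSV
#'
#' Expects columns `lon`, `lat`, `year` (optional `stage`, `source`).
#' Rows with non-finite or out-of-range coordinates, or years outside
#' `year_range`, are reported with their line numbers and either skipped
#' (default) or treated as fatal.
#'
#' @param path CSV file path.
#' @param year_range allowed observation years (inclusive); default
#'   2004--2019.
#' @param malformed `"skip"` (drop bad rows with a warning) or `"error"`.
#' @return A data frame of validated records with columns `lon`, `lat`,
#'   `year`, `stage`, `source`.
#' @export
read_occurrences <- function(path, year_range = c(2004, 2019),
                             malformed = c("skip", "error")) {
  malformed <- match.arg(malformed)
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "year")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("occurrence CSV lacks column(s): ", paste(missing, collapse = ", "))
  d$stage <- if ("stage" %in% names(d)) as.character(d$stage)
             else rep(NA_character_, nrow(d))
  d$source <- if ("source" %in% names(d)) as.character(d$source)
              else rep(NA_character_, nrow(d))
  lon <- suppressWarnings(as.numeric(d$lon))
  lat <- suppressWarnings(as.numeric(d$lat))
  year <- suppressWarnings(as.integer(d$year))
  bad <- !is.finite(lon) | !is.finite(lat) | is.na(year) |
    abs(lon) > 180 | abs(lat) > 90 |
    year < year_range[1] | year > year_range[2]
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    msg <- paste0("malformed/out-of-range occurrence row(s) at line(s): ",
                  paste(utils::head(lines, 10), collapse = ", "),
                  if (length(lines) > 10) " ...")
    if (malformed == "error") stop(msg)
    warning(msg, call. = FALSE)
  }
  data.frame(lon = lon[!bad], lat = lat[!bad], year = year[!bad],
             stage = d$stage[!bad], source = d$source[!bad],
             stringsAsFactors = FALSE)
}

match_record_cells <- function(records, result, cell_size) {
  idx <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- cell_index_for_point(records$lon[i], records$lat[i],
                                result$lon, result$lat, cell_size)
    if (!is.na(hit)) {
      idx[i] <- hit
    } else {
      # citizen-science jitter: snap to the nearest cell within one width
      cheb <- pmax(abs(result$lon - records$lon[i]),
                   abs(result$lat - records$lat[i]))
      j <- which.min(cheb)
      idx[i] <- if (cheb[j] <= cell_size) j else NA_integer_
    }
  }
  idx
}

#' Overlap of occurrence records with modelled suitability
#'
#' Assigns each record to its grid cell (half-open cell boxes; records just
#' off the modelled cells are snapped to the nearest cell within one cell
#' width, otherwise counted out of bounds) and reports the fraction of
#' in-bounds records falling in suitable (EI > 5) and highly suitable
#' (EI > 15) cells, with a per-year breakdown when records carry years.
#'
#' @param records occurrence data frame (`lon`, `lat`, optional `year`).
#' @param result a `suitability_result` from [run_grid()], or a named list
#'   of per-year results (names = years) to validate each year's records
#'   against its own grid.
#' @param thresholds EI thresholds, default `c(5, 15)`.
#' @param cell_size grid spacing; defaults to the result's `"cell_size"`
#'   attribute.
#' @return list with `fraction_suitable`, `fraction_highly_suitable`,
#'   `n_records`, `n_in_bounds`, `n_out_of_bounds`, and `per_year` (data
#'   frame, or `NULL` when records carry no years).
#' @export
overlap_statistics <- function(records, result, thresholds = c(5, 15),
                               cell_size = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("no occurrence records supplied")
  per_year_grids <- !is.data.frame(result) && is.list(result)
  if (per_year_grids) {
    if (is.null(names(result)) || !"year" %in% names(records))
      stop("per-year validation needs year-named results and record years")
    parts <- lapply(names(result), function(y) {
      sub <- records[records$year == as.integer(y), , drop = FALSE]
      if (nrow(sub) == 0) return(NULL)
      s <- overlap_statistics(sub, result[[y]], thresholds, cell_size)
      data.frame(year = as.integer(y), n = s$n_in_bounds,
                 fraction_suitable = s$fraction_suitable,
                 fraction_highly_suitable = s$fraction_highly_suitable)
    })
    per_year <- do.call(rbind, parts)
    agg <- list(fraction_suitable = sum(per_year$fraction_suitable * per_year$n) /
                  sum(per_year$n),
                fraction_highly_suitable =
                  sum(per_year$fraction_highly_suitable * per_year$n) /
                  sum(per_year$n),
                n_records = nrow(records), n_in_bounds = sum(per_year$n),
                n_out_of_bounds = nrow(records) - sum(per_year$n),
                per_year = per_year)
    return(agg)
  }
  cs <- cell_size %||% attr(result, "cell_size") %||%
    infer_cell_size(result$lon, result$lat)
  idx <- match_record_cells(records, result, cs)
  inb <- !is.na(idx)
  if (!any(inb)) stop("no occurrence records fall within the grid")
  ei <- result$ei[idx[inb]]
  out <- list(
    fraction_suitable = mean(ei > thresholds[1]),
    fraction_highly_suitable = mean(ei > thresholds[2]),
    n_records = nrow(records),
    n_in_bounds = sum(inb),
    n_out_of_bounds = sum(!inb),
    per_year = NULL)
  if ("year" %in% names(records) && !all(is.na(records$year))) {
    yr <- records$year[inb]
    out$per_year <- do.call(rbind, lapply(sort(unique(yr)), function(y) {
      e <- ei[yr == y]
      data.frame(year = y, n = length(e),
                 fraction_suitable = mean(e > thresholds[1]),
                 fraction_highly_suitable = mean(e > thresholds[2]))
    }))
  }
  out
}
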