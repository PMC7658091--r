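#' Gridded monthly climate
#'
#' Container for a regular latitude--longitude grid of monthly climate
#' normals: per-cell centre coordinates, optional elevation, a land mask, and
#' 12 monthly values each of mean daily minimum temperature, mean daily
#' maximum temperature and precipitation sum.
#'
#' Cells are stored row-wise (one row per cell) with `tmin`, `tmax`, `prec`
#' as `n x 12` matrices. Coordinates are WGS84 cell centres; a point belongs
#' to the cell whose half-open box `[lon - d/2, lon + d/2) x
#' [lat - d/2, lat + d/2)` contains it.
#'
#' @param lon,lat numeric vectors of cell-centre coordinates (degrees).
#' @param tmin,tmax,prec `n x 12` matrices (degrees C, degrees C, mm/month).
#' @param elevation optional numeric vector (m).
#' @param land_mask optional logical vector; default all `TRUE`.
#' @param cell_size grid spacing in degrees; inferred from the coordinates
#'   when `NULL` (default 0.02 if it cannot be inferred).
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(lon, lat, tmin, tmax, prec,
                         elevation = NULL, land_mask = NULL,
                         cell_size = NULL) {
  n <- length(lon)
  tmin <- as.matrix(tmin); tmax <- as.matrix(tmax); prec <- as.matrix(prec)
  if (length(lat) != n) stop("lon and lat must have equal length")
  for (nm in c("tmin", "tmax", "prec")) {
    m <- get(nm)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 12L)
      stop(nm, " must be an n x 12 numeric matrix")
  }
  g <- structure(
    list(lon = as.numeric(lon), lat = as.numeric(lat),
         elevation = if (!is.null(elevation)) as.numeric(elevation),
         land_mask = if (is.null(land_mask)) rep(TRUE, n) else as.logical(land_mask),
         tmin = unname(tmin), tmax = unname(tmax), prec = unname(prec),
         cell_size = cell_size %||% infer_cell_size(lon, lat)),
    class = "climate_grid")
  validate_climate_grid(g)
  g
}

# Half-open [low, high) cell membership, computed in index space so points
# on shared cell edges resolve deterministically (the low edge is closed)
# despite floating-point gaps between adjacent cell boxes. Returns the cell
# index, or NA when the point misses every cell.
cell_index_for_point <- function(lon, lat, cells_lon, cells_lat, d) {
  lon0 <- min(cells_lon); lat0 <- min(cells_lat)
  ci <- floor((lon - lon0 + d / 2) / d + 1e-9)
  cj <- floor((lat - lat0 + d / 2) / d + 1e-9)
  if (ci < 0 || cj < 0) return(NA_integer_)
  hit <- which(abs(cells_lon - (lon0 + ci * d)) < d / 4 &
               abs(cells_lat - (lat0 + cj * d)) < d / 4)
  if (length(hit) == 0) NA_integer_ else hit[[1]]
}

infer_cell_size <- function(lon, lat) {
  steps <- c(diff(sort(unique(lon))), diff(sort(unique(lat))))
  steps <- steps[steps > 1e-12]
  if (length(steps) == 0) return(0.02)
  min(steps)
}

#' Validate a gridded monthly climate object
#'
#' Enforces `tmin <= tmax` elementwise (offending cells are reported with
#' their coordinates), non-negative precipitation, physically plausible
#' ranges (|T| <= 60 degC, monthly precipitation <= 5000 mm), and constant
#' grid spacing along each axis (within 1e-9 degrees).
#'
#' @param g a `climate_grid`.
#' @return `g`, invisibly.
#' @export
validate_climate_grid <- function(g) {
  stopifnot(inherits(g, "climate_grid"))
  n <- length(g$lon)
  if (n == 0) stop("empty climate grid")
  if (anyNA(g$tmin) || anyNA(g$tmax) || anyNA(g$prec))
    stop("climate grid contains missing values")
  bad <- which(apply(g$tmin > g$tmax, 1, any))
  if (length(bad) > 0)
    stop("tmin > tmax at cell(s): ",
         paste(sprintf("(%.4f, %.4f)", g$lon[bad[seq_len(min(5, length(bad)))]],
                       g$lat[bad[seq_len(min(5, length(bad)))]]),
               collapse = ", "),
         if (length(bad) > 5) sprintf(" and %d more", length(bad) - 5))
  if (any(g$prec < 0)) stop("negative precipitation in climate grid")
  if (any(abs(g$tmin) > 60) || any(abs(g$tmax) > 60))
    stop("physically implausible temperature (|T| > 60 degC)")
  if (any(g$prec > 5000))
    stop("physically implausible precipitation (> 5000 mm/month)")
  for (ax in c("lon", "lat")) {
    u <- sort(unique(g[[ax]]))
    if (length(u) > 1) {
      d <- diff(u)
      # spacing must be a constant (cells may be missing: allow multiples)
      k <- round(d / g$cell_size)
      if (any(k < 1) || any(abs(d - k * g$cell_size) > 1e-9))
        stop("inconsistent ", ax, " grid spacing (not a regular lattice)")
    }
  }
  invisible(g)
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("<climate_grid> ", length(x$lon), " cells, ",
      x$cell_size, " deg spacing\n", sep = "")
  cat("  lon ", min(x$lon), "..", max(x$lon),
      ", lat ", min(x$lat), "..", max(x$lat), "\n", sep = "")
  if (!is.null(x$elevation))
    cat("  elevation ", round(min(x$elevation)), "..",
        round(max(x$elevation)), " m\n", sep = "")
  cat("  annual tmean ", round(mean((x$tmin + x$tmax) / 2), 2),
      " degC, annual precip ", round(mean(rowSums(x$prec))), " mm\n", sep = "")
  invisible(x)
}

#' Read a gridded monthly climate from long-format CSV
#'
#' Expects columns `lon, lat, month, tmin, tmax, prec` with optional
#' `elevation` and `land`; one row per cell and month, months 1..12 complete
#' for every cell. The same dialect [write_monthly_grid()] emits.
#'
#' @param path CSV file path.
#' @param cell_size grid spacing override (degrees); inferred by default.
#' @return A validated `climate_grid`.
#' @export
read_monthly_grid <- function(path, cell_size = NULL) {
  if (!file.exists(path)) stop("climate file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "month", "tmin", "tmax", "prec")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("climate CSV lacks column(s): ", paste(missing, collapse = ", "))
  key <- paste(d$lon, d$lat, sep = "|")
  cells <- !duplicated(key)
  idx <- match(key, key[cells])
  n <- sum(cells)
  if (nrow(d) != 12L * n || any(table(idx) != 12L) ||
      any(sort(unique(d$month)) != 1:12))
    stop("every cell must have exactly the 12 months 1..12")
  mk <- function(col) {
    m <- matrix(NA_real_, n, 12)
    m[cbind(idx, d$month)] <- d[[col]]
    m
  }
  climate_grid(lon = d$lon[cells], lat = d$lat[cells],
               tmin = mk("tmin"), tmax = mk("tmax"), prec = mk("prec"),
               elevation = if ("elevation" %in% names(d)) d$elevation[cells],
               land_mask = if ("land" %in% names(d)) as.logical(d$land[cells]),
               cell_size = cell_size)
}

#' Write a gridded monthly climate as long-format CSV
#'
#' Numeric values are printed with 17 significant digits, so
#' `read_monthly_grid(write_monthly_grid(g, f))` reproduces `g` exactly.
#'
#' @param g a `climate_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_monthly_grid <- function(g, path) {
  validate_climate_grid(g)
  n <- length(g$lon)
  rows <- data.frame(
    lon = rep(fmt_full(g$lon), each = 12),
    lat = rep(fmt_full(g$lat), each = 12),
    month = rep(1:12, times = n),
    tmin = fmt_full(as.vector(t(g$tmin))),
    tmax = fmt_full(as.vector(t(g$tmax))),
    prec = fmt_full(as.vector(t(g$prec))),
    stringsAsFactors = FALSE)
  if (!is.null(g$elevation)) rows$elevation <- rep(fmt_full(g$elevation), each = 12)
  rows$land <- rep(g$land_mask, each = 12)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate the grid cell containing a point
#'
#' Cell membership is half-open: a point on the shared edge of two cells
#' belongs to the cell on the low side (the `[low, high)` box). Returns the
#' cell index into the grid's cell vectors.
#'
#' @param g a `climate_grid`.
#' @param lon,lat query coordinates (degrees).
#' @param require_land error when the matched cell is masked out?
#' @return integer cell index.
#' @export
locate_cell <- function(g, lon, lat, require_land = TRUE) {
  i <- cell_index_for_point(lon, lat, g$lon, g$lat, g$cell_size)
  if (is.na(i))
    stop(sprintf("point (%.4f, %.4f) is outside the grid", lon, lat))
  if (require_land && !g$land_mask[i])
    stop(sprintf("point (%.4f, %.4f) falls on a masked (water) cell", lon, lat))
  i
}

#' Extract one cell's monthly climate
#'
#' Selects the grid cell in which a query location falls (by longitude and
#' latitude, half-open cell boxes) and returns its monthly series.
#'
#' @param g a `climate_grid`.
#' @param lon,lat query coordinates (degrees).
#' @param name optional label carried through to the result.
#' @return A `cell_monthly` list: `name`, `lon`, `lat` (cell centre),
#'   `elevation`, `tmin`, `tmax`, `prec` (12 monthly values each).
#' @export
extract_location <- function(g, lon, lat, name = NULL) {
  i <- locate_cell(g, lon, lat)
  structure(list(name = name %||% sprintf("(%.3f, %.3f)", lon, lat),
                 lon = g$lon[i], lat = g$lat[i],
                 elevation = if (!is.null(g$elevation)) g$elevation[i],
                 tmin = g$tmin[i, ], tmax = g$tmax[i, ], prec = g$prec[i, ]),
            class = "cell_monthly")
}
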