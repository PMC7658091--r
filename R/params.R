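#' Species bioclimatic parameter set
#'
#' Constructs and validates the full parameter set that drives the ecoclimatic
#' engine: the four-point temperature (`DV0`--`DV3`) and soil-moisture
#' (`SM0`--`SM3`) growth responses, the thermal constant `PDD` (degree days
#' above `DV0` per generation), winter diapause induction/termination
#' (`DPD0`, `DPT0`, `DPT1`, `DPD`, `DPSW`), and the five stress accumulators
#' (cold, heat, dry, wet, hot-wet) with their thresholds and weekly rates.
#'
#' Defaults are the published values fitted for *Halyomorpha halys*.
#' Note the hot-wet pair: `TTHW` (28) is the temperature threshold in degrees C
#' and `MTHW` (1.5) the soil-moisture threshold; source tables occasionally
#' transpose the two labels, but dimensional consistency with the `DV` and
#' `SM` ranges fixes the interpretation used here.
#'
#' Negative printed rates (`THCS`, `HDS`) are stored with their sign as
#' published; the engine uses their absolute value as the accumulation
#' magnitude.
#'
#' @param DV0,DV1,DV2,DV3 limiting low / lower optimal / upper optimal /
#'   limiting high temperature (degrees C).
#' @param PDD degree days per generation (degree C days above `DV0`).
#' @param SM0,SM1,SM2,SM3 limiting low / lower optimal / upper optimal /
#'   limiting high soil moisture (fraction of soil capacity).
#' @param DPD0 diapause induction day length (hours of light).
#' @param DPT0 diapause induction temperature (degrees C).
#' @param DPT1 diapause termination temperature (degrees C).
#' @param DPD diapause development days required before termination.
#' @param DPSW diapause season: 0 = winter, 1 = summer.
#' @param TTCS cold-stress temperature threshold (degrees C, on weekly tmin).
#' @param THCS cold-stress accumulation rate (per week; negative as printed).
#' @param TTHS heat-stress temperature threshold (degrees C, on weekly tmax).
#' @param THHS heat-stress accumulation rate (per week).
#' @param SMDS dry-stress soil-moisture threshold.
#' @param HDS dry-stress accumulation rate (per week; negative as printed).
#' @param SMWS wet-stress soil-moisture threshold.
#' @param HWS wet-stress accumulation rate (per week).
#' @param TTHW hot-wet temperature threshold (degrees C).
#' @param MTHW hot-wet soil-moisture threshold.
#' @param PHW hot-wet stress accumulation rate (per week).
#'
#' @return An object of class `species_parameters` (a validated named list).
#' @seealso [default_parameters()], [load_parameters()], [write_parameters()]
#' @export
#' @examples
#' p <- species_parameters(PDD = 471)  # lower literature estimate
#' p$PDD
species_parameters <- function(DV0 = 12, DV1 = 27, DV2 = 30, DV3 = 33,
                               PDD = 595,
                               SM0 = 0.1, SM1 = 0.5, SM2 = 1, SM3 = 1.5,
                               DPD0 = 12, DPT0 = 5, DPT1 = 5, DPD = 0,
                               DPSW = 0,
                               TTCS = -18, THCS = -0.01,
                               TTHS = 33, THHS = 0.01,
                               SMDS = 0.1, HDS = -0.01,
                               SMWS = 1.5, HWS = 0.002,
                               TTHW = 28, MTHW = 1.5, PHW = 0.007) {
  p <- list(DV0 = DV0, DV1 = DV1, DV2 = DV2, DV3 = DV3, PDD = PDD,
            SM0 = SM0, SM1 = SM1, SM2 = SM2, SM3 = SM3,
            DPD0 = DPD0, DPT0 = DPT0, DPT1 = DPT1, DPD = DPD, DPSW = DPSW,
            TTCS = TTCS, THCS = THCS, TTHS = TTHS, THHS = THHS,
            SMDS = SMDS, HDS = HDS, SMWS = SMWS, HWS = HWS,
            TTHW = TTHW, MTHW = MTHW, PHW = PHW)
  p <- lapply(p, as.numeric)
  class(p) <- "species_parameters"
  validate_parameters(p)
  p
}

#' Default *Halyomorpha halys* parameters
#'
#' The published parameter set fitted for the brown marmorated stink bug
#' (see [species_parameters()] for the meaning of each field).
#'
#' @return A `species_parameters` object.
#' @export
#' @examples
#' default_parameters()$DV0
default_parameters <- function() {
  species_parameters()
}

parameter_names <- function() {
  c("DV0", "DV1", "DV2", "DV3", "PDD",
    "SM0", "SM1", "SM2", "SM3",
    "DPD0", "DPT0", "DPT1", "DPD", "DPSW",
    "TTCS", "THCS", "TTHS", "THHS",
    "SMDS", "HDS", "SMWS", "HWS",
    "TTHW", "MTHW", "PHW")
}

#' Validate a species parameter set
#'
#' Checks completeness, finiteness, the monotone orderings
#' `DV0 < DV1 <= DV2 < DV3` and `SM0 < SM1 <= SM2 < SM3`, `PDD > 0`,
#' stress-rate magnitudes below 1, and `DPSW` in \{0, 1\}.
#'
#' @param p a `species_parameters` object (or plain named list).
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(p) {
  missing <- setdiff(parameter_names(), names(p))
  if (length(missing) > 0)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  for (nm in parameter_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number")
  }
  if (!(p$DV0 < p$DV1 && p$DV1 <= p$DV2 && p$DV2 < p$DV3))
    stop("ordering violation: temperature thresholds must satisfy ",
         "DV0 < DV1 <= DV2 < DV3 (got ",
         paste(c(p$DV0, p$DV1, p$DV2, p$DV3), collapse = ", "), ")")
  if (!(p$SM0 < p$SM1 && p$SM1 <= p$SM2 && p$SM2 < p$SM3))
    stop("ordering violation: soil-moisture thresholds must satisfy ",
         "SM0 < SM1 <= SM2 < SM3 (got ",
         paste(c(p$SM0, p$SM1, p$SM2, p$SM3), collapse = ", "), ")")
  if (p$PDD <= 0) stop("PDD must be positive")
  for (nm in c("THCS", "THHS", "HDS", "HWS", "PHW")) {
    if (abs(p[[nm]]) >= 1)
      stop("stress accumulation rate ", nm, " must have magnitude < 1")
  }
  if (!p$DPSW %in% c(0, 1)) stop("DPSW must be 0 (winter) or 1 (summer)")
  invisible(p)
}

#' Load species parameters from a key-value file
#'
#' Reads a flat YAML or JSON document whose keys are the standard parameter
#' abbreviations (`DV0`, `PDD`, `TTCS`, ...). Fields absent from the document
#' fall back to the *H. halys* defaults when `defaults = TRUE`; with
#' `defaults = FALSE` every field must be supplied.
#'
#' @param source path to a YAML/JSON file, or a named list of values.
#' @param defaults fall back to [default_parameters()] for unspecified fields?
#' @return A validated `species_parameters` object.
#' @export
load_parameters <- function(source, defaults = TRUE) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("parameter file not found: ", source)
    values <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::fromJSON(source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    values <- source
  } else {
    stop("source must be a file path or a named list")
  }
  if (is.null(values)) values <- list()
  unknown <- setdiff(names(values), parameter_names())
  if (length(unknown) > 0)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  if (!defaults) {
    missing <- setdiff(parameter_names(), names(values))
    if (length(missing) > 0)
      stop("missing parameter field(s) with defaults disabled: ",
           paste(missing, collapse = ", "))
  }
  p <- unclass(default_parameters())
  for (nm in names(values)) p[[nm]] <- as.numeric(values[[nm]])
  class(p) <- "species_parameters"
  validate_parameters(p)
  p
}

#' Write species parameters to a key-value file
#'
#' Emits a flat `KEY: value` YAML document (or JSON for `.json` paths) that
#' [load_parameters()] reads back exactly: values are printed with 17
#' significant digits so the round trip is lossless.
#'
#' @param p a `species_parameters` object.
#' @param path output path (`.yml`/`.yaml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- vapply(parameter_names(), function(nm) {
      paste0(nm, ": ", formatC(p[[nm]], digits = 17, format = "g"))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.species_parameters <- function(x, ...) {
  cat("<species_parameters>\n")
  cat("  temperature response (degC): ",
      paste(c(x$DV0, x$DV1, x$DV2, x$DV3), collapse = " / "), "\n", sep = "")
  cat("  moisture response:           ",
      paste(c(x$SM0, x$SM1, x$SM2, x$SM3), collapse = " / "), "\n", sep = "")
  cat("  degree days per generation:  ", x$PDD, "\n", sep = "")
  cat("  diapause: DPD0=", x$DPD0, "h DPT0=", x$DPT0, " DPT1=", x$DPT1,
      " DPD=", x$DPD, " (", if (x$DPSW == 0) "winter" else "summer", ")\n",
      sep = "")
  cat("  stress thresholds/rates: cold ", x$TTCS, "/", x$THCS,
      ", heat ", x$TTHS, "/", x$THHS, ", dry ", x$SMDS, "/", x$HDS,
      ", wet ", x$SMWS, "/", x$HWS,
      ", hot-wet ", x$TTHW, "&", x$MTHW, "/", x$PHW, "\n", sep = "")
  invisible(x)
}
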