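# Format boundary: TIFF image pairs, CSV table schemas with unit checks,
# and the YAML pipeline configuration. Percent/fraction ambiguity is
# resolved here only; internally FDC is always a fraction.

#' Write / read a FISH+DAPI image pair as 8-bit TIFFs
#'
#' \code{writeImagePair} writes \code{<prefix>_fish.tif} and
#' \code{<prefix>_dapi.tif} (single-channel, 8-bit) and, when a truth table
#' is supplied, a JSON sidecar \code{<prefix>_truth.json}.
#' \code{readImagePair} restores an [ImagePair-class] from such files.
#'
#' @param pair an [ImagePair-class].
#' @param prefix output path prefix.
#' @param truth optional truth data.frame (from [simulateImagePair()]).
#' @return \code{writeImagePair}: the written paths, invisibly;
#'   \code{readImagePair}: an [ImagePair-class].
#' @export
writeImagePair <- function(pair, prefix, truth = NULL) {
  stopifnot(is(pair, "ImagePair"))
  paths <- paste0(prefix, c("_fish.tif", "_dapi.tif"))
  tiff::writeTIFF(pair@fish / 255, paths[1], bits.per.sample = 8L)
  tiff::writeTIFF(pair@dapi / 255, paths[2], bits.per.sample = 8L)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, paste0(prefix, "_truth.json"))
  }
  invisible(paths)
}

#' @rdname writeImagePair
#' @param fishPath,dapiPath TIFF file paths.
#' @param pixelSize um per pixel of the stored images.
#' @param sampleId,taxon,date labels.
#' @export
readImagePair <- function(fishPath, dapiPath, pixelSize,
                          sampleId = "sample", taxon = "unknown",
                          date = "") {
  readOne <- function(p) {
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  }
  ImagePair(readOne(fishPath), readOne(dapiPath), pixelSize = pixelSize,
            sampleId = sampleId, taxon = taxon, date = date)
}

.schemas <- list(
  dilution = c("experiment_id", "taxon", "date", "dilution_fraction",
               "replicate", "N0", "Nt", "t_days"),
  bloom = c("date", "taxon", "N", "fdc"),
  manifest = c("sample_id", "fish_path", "dapi_path", "pixel_size",
               "taxon", "date"),
  calibration = c("taxon", "fdc", "mu")
)

.checkFraction <- function(x, column) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad))
    stop(sprintf(
      "column '%s' must contain fractions in [0, 1]; value %g looks like a percentage (divide by 100?)",
      column, x[bad][1]))
}

.checkPositive <- function(x, column, strict = TRUE) {
  bad <- !is.na(x) & (if (strict) x <= 0 else x < 0)
  if (any(bad))
    stop(sprintf("column '%s' must be %s (found %g)",
                 column, if (strict) "positive" else "non-negative",
                 x[bad][1]))
}

#' Validate and parse an input table against a documented schema
#'
#' Reads a CSV and checks it against one of the package's table schemas,
#' including unit sanity checks: concentrations must be positive and FDC /
#' dilution fractions must lie in [0, 1] (a value like 12.5 where a
#' fraction is expected raises an error suggesting division by 100). Dates
#' are parsed as ISO-8601.
#'
#' Schemas (required columns):
#' \describe{
#'   \item{dilution}{experiment_id, taxon, date, dilution_fraction,
#'     replicate, N0, Nt, t_days}
#'   \item{bloom}{date, taxon, N, fdc}
#'   \item{manifest}{sample_id, fish_path, dapi_path, pixel_size, taxon,
#'     date}
#'   \item{calibration}{taxon, fdc, mu}
#' }
#'
#' @param path CSV file path.
#' @param schema one of \code{"dilution"}, \code{"bloom"},
#'   \code{"manifest"}, \code{"calibration"}.
#' @return the parsed data.frame.
#' @export
validateTable <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty table: ", path)
  missing <- setdiff(.schemas[[schema]], names(tab))
  if (length(missing))
    stop(sprintf("schema '%s': missing required column(s): %s",
                 schema, paste(missing, collapse = ", ")))
  if (schema == "dilution") {
    .checkFraction(tab$dilution_fraction, "dilution_fraction")
    .checkPositive(tab$dilution_fraction, "dilution_fraction")
    .checkPositive(tab$N0, "N0"); .checkPositive(tab$Nt, "Nt")
    .checkPositive(tab$t_days, "t_days")
  } else if (schema == "bloom") {
    .checkPositive(tab$N, "N")
    .checkFraction(tab$fdc, "fdc")
    tab$date <- as.Date(tab$date)
    if (anyNA(tab$date)) stop("column 'date' must be ISO-8601 dates")
  } else if (schema == "manifest") {
    .checkPositive(tab$pixel_size, "pixel_size")
  } else if (schema == "calibration") {
    .checkFraction(tab$fdc, "fdc")
    .checkPositive(tab$mu, "mu", strict = FALSE)
  }
  tab
}

.configDefaults <- function() list(
  cytometry = list(
    thresholdMethod = "otsu", fixedThreshold = 64, backgroundRadius = 7,
    minArea = 0.05, smoothingSigma = 1, minSeparation = 3,
    minProminence = 0.1, countMultiAsDividing = FALSE
  ),
  span = 0.4, window = 5, smoothAbundance = FALSE, seed = 1
)

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected (they usually indicate a typo), known keys
#' are range-checked, and missing keys fall back to the documented
#' defaults.
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return nested list: \code{cytometry} (see [cytometryConfig()]),
#'   \code{span}, \code{window}, \code{smoothAbundance}, \code{seed}.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$cytometry)) {
    unknownCy <- setdiff(names(user$cytometry), names(cfg$cytometry))
    if (length(unknownCy))
      stop("unknown cytometry key(s): ", paste(unknownCy, collapse = ", "))
    cfg$cytometry[names(user$cytometry)] <- user$cytometry
  }
  for (k in setdiff(names(user), "cytometry")) cfg[[k]] <- user[[k]]
  stopifnot(cfg$span > 0, cfg$span <= 1,
            cfg$window >= 3, cfg$window %% 2 == 1)
  do.call(cytometryConfig, cfg$cytometry)  # range checks
  cfg
}
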