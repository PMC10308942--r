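#' Accessors for bloomrates S4 objects
#'
#' Small accessor generics: channel matrices and pixel calibration of an
#' [ImagePair-class], fitted rates of a [DilutionResult-class], per-taxon
#' coefficients of a [CalibrationModel-class], and the rate table of a
#' [RateSeries-class].
#'
#' @param x an object of the documented class.
#' @return \code{fishChannel}/\code{dapiChannel}: numeric matrix;
#'   \code{pixelSize}: scalar (um/px); \code{divisionRate}/\code{grazingRate}:
#'   scalar (per day); \code{calibCoefficients}: data.frame;
#'   \code{rateTable}: data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fishChannel", function(x) standardGeneric("fishChannel"))
#' @rdname accessors
#' @export
setGeneric("dapiChannel", function(x) standardGeneric("dapiChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("divisionRate", function(x) standardGeneric("divisionRate"))
#' @rdname accessors
#' @export
setGeneric("grazingRate", function(x) standardGeneric("grazingRate"))
#' @rdname accessors
#' @export
setGeneric("calibCoefficients",
           function(x) standardGeneric("calibCoefficients"))
#' @rdname accessors
#' @export
setGeneric("rateTable", function(x) standardGeneric("rateTable"))

#' @rdname accessors
setMethod("fishChannel", "ImagePair", function(x) x@fish)
#' @rdname accessors
setMethod("dapiChannel", "ImagePair", function(x) x@dapi)
#' @rdname accessors
setMethod("pixelSize", "ImagePair", function(x) x@pixelSize)
#' @rdname accessors
setMethod("divisionRate", "DilutionResult", function(x) x@mu)
#' @rdname accessors
setMethod("grazingRate", "DilutionResult", function(x) x@grazing)
#' @rdname accessors
setMethod("calibCoefficients", "CalibrationModel",
          function(x) x@coefficients)
#' @rdname accessors
setMethod("rateTable", "RateSeries", function(x) x@data)

setMethod("show", "ImagePair", function(object) {
  cat(sprintf(
    "ImagePair '%s' (%s, %s): %d x %d px, %.4g um/px\n",
    object@sampleId, object@taxon, object@date,
    nrow(object@fish), ncol(object@fish), object@pixelSize
  ))
})

setMethod("show", "DilutionSeries", function(object) {
  cat(sprintf(
    "DilutionSeries '%s' (%s, %s): %d points, dilutions {%s}, t = %g d\n",
    object@experimentId, object@taxon, object@date, nrow(object@data),
    paste(sort(unique(object@data$dilution), decreasing = TRUE),
          collapse = ", "),
    object@incubationTime
  ))
})

setMethod("show", "DilutionResult", function(object) {
  cat(sprintf(
    "DilutionResult: mu = %.4g +/- %.3g /d, g = %.4g +/- %.3g /d (R2 = %.3f, n = %d)%s\n",
    object@mu, object@muSE, object@grazing, object@grazingSE,
    object@r2, object@nPoints,
    if (isTRUE(object@negativeMu)) " [negative mu]" else ""
  ))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: FDC ~ mu * taxon, %d taxa, n = %d, R2 = %.3f, p = %.3g\n",
              nrow(object@coefficients), object@n, object@r2, object@pValue))
  print(object@coefficients, row.names = FALSE, digits = 4)
})

setMethod("show", "RateSeries", function(object) {
  d <- object@data
  cat(sprintf(
    "RateSeries '%s': %d timepoints over %g d; mu defined at %d, r at %d, d at %d\n",
    object@taxon, nrow(d), diff(range(d$timepoint)),
    sum(!is.na(d$mu)), sum(!is.na(d$r)), sum(!is.na(d$d))
  ))
})
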