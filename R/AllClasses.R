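#' @import methods
#' @importFrom stats lm loess predict coef vcov pf rnorm rpois runif sd
#'   setNames approxfun complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' Paired FISH/DAPI micrograph
#'
#' Container for one registered two-channel epifluorescence field of view:
#' a taxon-specific FISH channel (cell bodies) and a DAPI channel (DNA).
#' Both channels are 8-bit grayscale rasters stored as numeric matrices in
#' \code{[0, 255]}, with a physical pixel calibration in micrometres.
#'
#' @slot fish numeric matrix, FISH channel gray values in [0, 255].
#' @slot dapi numeric matrix, DAPI channel, same dimensions as \code{fish}.
#' @slot pixelSize positive scalar, edge length of one pixel in um.
#' @slot sampleId,taxon,date character labels carried through to outputs.
#'
#' @seealso [ImagePair()] for the constructor, [simulateImagePair()],
#'   [segmentCells()], [measureCells()]
#' @export
setClass("ImagePair",
  representation(
    fish = "matrix", dapi = "matrix", pixelSize = "numeric",
    sampleId = "character", taxon = "character", date = "character"
  )
)

setValidity("ImagePair", function(object) {
  msg <- character()
  if (!identical(dim(object@fish), dim(object@dapi)))
    msg <- c(msg, "fish and dapi channels must have identical dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/px)")
  rng <- range(object@fish, object@dapi)
  if (any(!is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    msg <- c(msg, "gray values must lie in [0, 255] (8-bit)")
  if (length(msg)) msg else TRUE
})

#' One Landry-Hassett dilution experiment
#'
#' Rows of paired start/end concentrations across a dilution series of
#' unfiltered seawater, with replicates. The dilution fraction D is the
#' proportion of unfiltered (grazer-containing) water, so D = 1 is the
#' undiluted treatment and D = 0.1 the 1:9 dilution.
#'
#' @slot data data.frame with columns \code{dilution} (fraction in (0,1]),
#'   \code{replicate}, \code{N0} and \code{Nt} (cells/mL, positive).
#' @slot experimentId,taxon,date character labels.
#' @slot incubationTime positive scalar, incubation length in days.
#'
#' @seealso [DilutionSeries()], [fitDilutionSeries()],
#'   [simulateDilutionSeries()]
#' @export
setClass("DilutionSeries",
  representation(
    data = "data.frame", experimentId = "character",
    taxon = "character", date = "character", incubationTime = "numeric"
  )
)

setValidity("DilutionSeries", function(object) {
  msg <- character()
  d <- object@data
  need <- c("dilution", "replicate", "N0", "Nt")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (length(object@incubationTime) != 1L || object@incubationTime <= 0)
    msg <- c(msg, "incubationTime must be a single positive number of days")
  if (any(d$dilution <= 0 | d$dilution > 1))
    msg <- c(msg, "dilution fractions must lie in (0, 1]")
  if (any(d$N0 <= 0) || any(d$Nt <= 0))
    msg <- c(msg, "all concentrations must be positive")
  if (length(unique(d$dilution)) < 2L)
    msg <- c(msg, "at least 2 distinct dilution fractions are required")
  if (length(msg)) msg else TRUE
})

#' Fitted division and grazing rates from a dilution series
#'
#' Result of the Landry-Hassett regression of apparent growth rate
#' k = ln(Nt/N0)/t on dilution fraction D: k(D) = mu - g D. The intercept is
#' the grazer-free cell division rate mu, the negated slope the grazing
#' rate g, both per day.
#'
#' @slot mu,grazing point estimates (per day).
#' @slot muSE,grazingSE standard errors from the OLS fit.
#' @slot r2 coefficient of determination of the fit.
#' @slot nPoints number of replicate points entering the regression.
#' @slot negativeMu TRUE when the fitted division rate is below zero
#'   (reported as-is; a warning is raised at fit time).
#' @slot fit the underlying \code{lm} object.
#'
#' @seealso [fitDilutionSeries()]
#' @export
setClass("DilutionResult",
  representation(
    mu = "numeric", grazing = "numeric", muSE = "numeric",
    grazingSE = "numeric", r2 = "numeric", nPoints = "integer",
    negativeMu = "logical", fit = "ANY"
  )
)

setValidity("DilutionResult", function(object) {
  msg <- character()
  if (object@muSE < 0 || object@grazingSE < 0)
    msg <- c(msg, "standard errors must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-taxon FDC-to-division-rate calibration
#'
#' Linear map between the frequency of dividing cells and the cell division
#' rate, fitted jointly across taxa as FDC ~ mu * taxon (main effects plus
#' interaction) and reshaped into per-taxon intercept a and slope b, so that
#' FDC = a + b mu and, inverted, mu = (FDC - a)/b. Taxa with b <= 0 are kept
#' in the model but flagged non-invertible.
#'
#' @slot coefficients data.frame with columns \code{taxon},
#'   \code{intercept}, \code{slope}, \code{slopeSE}, \code{invertible}.
#' @slot vcov covariance matrix of the underlying model coefficients.
#' @slot r2,pValue,n fit diagnostics: R-squared, overall F-test p, points.
#' @slot fit the underlying \code{lm} object (may be NULL after
#'   deserialization from JSON).
#'
#' @seealso [buildCalibration()], [predictDivisionRate()],
#'   [writeCalibration()]
#' @export
setClass("CalibrationModel",
  representation(
    coefficients = "data.frame", vcov = "matrix",
    r2 = "numeric", pValue = "numeric", n = "integer", fit = "ANY"
  )
)

setValidity("CalibrationModel", function(object) {
  msg <- character()
  need <- c("taxon", "intercept", "slope", "invertible")
  if (!all(need %in% names(object@coefficients)))
    return(paste("coefficients must have columns:",
                 paste(need, collapse = ", ")))
  if (!all(is.finite(object@r2)) || !all(is.finite(object@pValue)))
    msg <- c(msg, "fit diagnostics must be finite")
  if (length(msg)) msg else TRUE
})

#' Decomposed rate time series for one taxon
#'
#' Time-indexed cell division rate mu(t), net growth r(t) and mortality
#' d(t) = mu(t) - r(t), together with the observations they derive from.
#' Undefined values (window edges, non-positive window fits, missing FDC)
#' are NA with a per-point flag.
#'
#' @slot taxon character label.
#' @slot data data.frame with columns \code{timepoint} (days, strictly
#'   increasing), \code{N} (cells/mL), \code{fdc}, \code{fdcSmooth}
#'   (fractions), \code{mu}, \code{r}, \code{d} (per day, NA-able) and
#'   \code{flag} (comma-separated markers: edge, nonpositive-model,
#'   clamped, no-fdc).
#'
#' @seealso [runRatePipeline()], [netGrowth()], [mortalityRate()]
#' @export
setClass("RateSeries",
  representation(taxon = "character", data = "data.frame")
)

setValidity("RateSeries", function(object) {
  msg <- character()
  d <- object@data
  need <- c("timepoint", "N", "fdc", "fdcSmooth", "mu", "r", "d", "flag")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(d$timepoint, strictly = TRUE))
    msg <- c(msg, "timepoints must be strictly increasing")
  ok <- !is.na(d$mu) & !is.na(d$r) & !is.na(d$d)
  if (any(ok) && max(abs(d$d[ok] - (d$mu[ok] - d$r[ok]))) > 1e-12)
    msg <- c(msg, "identity d = mu - r violated at a defined point")
  if (length(msg)) msg else TRUE
})
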