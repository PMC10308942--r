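#' Construct an ImagePair
#'
#' @param fish,dapi numeric matrices of 8-bit gray values (same dimensions).
#'   Integer matrices are accepted and converted.
#' @param pixelSize pixel edge length in um (> 0).
#' @param sampleId,taxon,date optional character labels.
#' @return an [ImagePair-class] object.
#' @examples
#' img <- matrix(0, 32, 32)
#' ImagePair(img, img, pixelSize = 0.1)
#' @export
ImagePair <- function(fish, dapi, pixelSize, sampleId = "sample",
                      taxon = "unknown", date = "") {
  storage.mode(fish) <- "double"
  storage.mode(dapi) <- "double"
  new("ImagePair", fish = fish, dapi = dapi, pixelSize = pixelSize,
      sampleId = sampleId, taxon = taxon, date = date)
}

#' Construct a DilutionSeries
#'
#' @param data data.frame with columns \code{dilution}, \code{replicate},
#'   \code{N0}, \code{Nt} (one row per bottle).
#' @param incubationTime incubation length in days (the standard 24 h
#'   incubation is \code{1}).
#' @param experimentId,taxon,date optional character labels.
#' @return a [DilutionSeries-class] object.
#' @examples
#' d <- data.frame(dilution = rep(c(1, .5, .25, .1), 2), replicate = rep(1:2, each = 4),
#'                 N0 = 1e5 * rep(c(1, .5, .25, .1), 2))
#' d$Nt <- d$N0 * exp(1.0 - 0.5 * d$dilution)
#' DilutionSeries(d)
#' @export
DilutionSeries <- function(data, incubationTime = 1,
                           experimentId = "exp", taxon = "unknown",
                           date = "") {
  new("DilutionSeries", data = as.data.frame(data),
      incubationTime = incubationTime, experimentId = experimentId,
      taxon = taxon, date = date)
}
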