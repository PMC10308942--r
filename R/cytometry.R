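# Image cytometry: segmentation of FISH-positive cells, per-cell geometry /
# biovolume / fluorescence, dividing-cell classification from DAPI local
# maxima, and per-sample aggregation (FDC, concentrations).

#' Cytometry parameter set
#'
#' Bundles the tunable parameters of the image-cytometry stage. Defaults are
#' chosen so that well-separated synthetic cells are recovered exactly; all
#' are exposed because detection settings for real micrographs are
#' instrument-dependent.
#'
#' @param thresholdMethod \code{"otsu"} (parameter-free, default) or
#'   \code{"fixed"} (uses \code{fixedThreshold}).
#' @param fixedThreshold gray-value threshold in [0, 255] for
#'   \code{thresholdMethod = "fixed"}.
#' @param backgroundRadius radius (px) of the median filter used for
#'   background subtraction before thresholding.
#' @param minArea minimum cell area in um^2; smaller components are
#'   discarded as hot pixels / debris.
#' @param smoothingSigma Gaussian sigma (px) applied to the DAPI channel
#'   before maxima detection.
#' @param minSeparation DAPI maxima closer than this (px) are merged.
#' @param minProminence minimum topographic prominence of a DAPI maximum,
#'   as a fraction of the in-cell DAPI dynamic range.
#' @param countMultiAsDividing if TRUE, cells with three or more DAPI
#'   maxima are counted as dividing; by default they are non-dividing and
#'   tallied separately (the dividing definition is exactly two maxima).
#' @return a named list of class \code{"cytometryConfig"}.
#' @export
cytometryConfig <- function(thresholdMethod = c("otsu", "fixed"),
                            fixedThreshold = 64, backgroundRadius = 7,
                            minArea = 0.05, smoothingSigma = 1,
                            minSeparation = 3, minProminence = 0.1,
                            countMultiAsDividing = FALSE) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(minArea > 0, smoothingSigma >= 0, minSeparation >= 0,
            minProminence >= 0, minProminence <= 1,
            fixedThreshold >= 0, fixedThreshold <= 255)
  structure(
    list(thresholdMethod = thresholdMethod, fixedThreshold = fixedThreshold,
         backgroundRadius = backgroundRadius, minArea = minArea,
         smoothingSigma = smoothingSigma, minSeparation = minSeparation,
         minProminence = minProminence,
         countMultiAsDividing = countMultiAsDividing),
    class = "cytometryConfig"
  )
}

#' Segment FISH-positive cells
#'
#' Thresholds the (background-subtracted) FISH channel and labels connected
#' components. Components smaller than \code{minArea} are discarded;
#' components touching the image border are excluded from the returned set
#' and tallied separately, since partial cells bias both volume and FDC.
#'
#' @param pair an [ImagePair-class].
#' @param config a [cytometryConfig()] list.
#' @return list with \code{labels} (integer label matrix), \code{ids}
#'   (labels of retained cells; empty for a blank image),
#'   \code{edgeExcluded} and \code{smallExcluded} tallies, and
#'   \code{threshold} (gray value used).
#' @examples
#' sim <- simulateImagePair(nCells = 10, seed = 1)
#' length(segmentCells(sim$pair)$ids)
#' @export
segmentCells <- function(pair, config = cytometryConfig()) {
  stopifnot(is(pair, "ImagePair"))
  norm <- pair@fish / 255
  if (config$backgroundRadius > 0) {
    bg <- as.matrix(EBImage::imageData(
      EBImage::medianFilter(norm, size = config$backgroundRadius)))
    norm <- pmax(norm - bg, 0)
  }
  if (config$thresholdMethod == "otsu") {
    thr <- if (max(norm) > min(norm))
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
    else 1  # flat image: nothing above threshold
  } else {
    thr <- config$fixedThreshold / 255
  }
  labels <- EBImage::bwlabel(norm > thr)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(norm), ncol(norm))
  ids <- seq_len(max(labels, 0L))
  if (length(ids) == 0L)
    return(list(labels = labels, ids = integer(), edgeExcluded = 0L,
                smallExcluded = 0L, threshold = thr * 255))
  areaPx <- tabulate(labels[labels > 0L], nbins = max(ids))
  minAreaPx <- config$minArea / pair@pixelSize^2
  small <- ids[areaPx < minAreaPx]
  borderIds <- unique(c(labels[1, ], labels[nrow(labels), ],
                        labels[, 1], labels[, ncol(labels)]))
  borderIds <- setdiff(borderIds, 0L)
  keep <- setdiff(ids[areaPx >= minAreaPx], borderIds)
  list(labels = labels, ids = keep,
       edgeExcluded = length(setdiff(borderIds, small)),
       smallExcluded = length(small), threshold = thr * 255)
}

#' Biovolume of a capped cylinder
#'
#' Cell volume from the two-dimensional projection, approximating the cell
#' as a cylinder with hemispherical caps: V = (4/3) pi r^3 + pi r^2 l with
#' radius r = width/2 and cylinder length l = totalLength - 2 r. For
#' totalLength equal to width this reduces to the sphere volume.
#'
#' @param totalLength total cell length in um (cap to cap).
#' @param width cell width in um; must satisfy
#'   \code{totalLength >= width > 0} (otherwise the caps would overlap).
#' @return volume in um^3 (vectorized).
#' @examples
#' cellVolume(1, 1)            # sphere: (4/3) pi 0.5^3
#' cellVolume(1.5, 0.5)        # 0.2618 um^3
#' @export
cellVolume <- function(totalLength, width) {
  if (any(width <= 0) || any(totalLength <= 0))
    stop("totalLength and width must be positive")
  if (any(width > totalLength))
    stop("width must not exceed totalLength (hemispherical caps would overlap)")
  r <- width / 2
  l <- totalLength - 2 * r
  4 / 3 * pi * r^3 + pi * r^2 * l
}

# Topographic prominence of every local peak inside a masked crop, by
# descending-order flooding with union-find (persistence): when two growing
# components meet, the lower peak dies and its prominence is its height
# above the saddle level.
.maskPeaks <- function(sub, maskSub) {
  nr <- nrow(sub); nc <- ncol(sub)
  idx <- which(maskSub)
  if (length(idx) == 0L) return(NULL)
  vals <- sub[idx]
  rng <- range(vals)
  # flat signal (to numerical tolerance, e.g. after smoothing a constant
  # patch): no maxima
  if (rng[2] - rng[1] <= 1e-6 * max(abs(rng), 1)) return(NULL)
  ord <- idx[order(sub[idx], decreasing = TRUE)]
  pos <- integer(nr * nc)          # 0 = unassigned, else component root id
  parent <- integer(0)             # union-find over components
  peakIdx <- integer(0)            # birth pixel of each component
  peakVal <- numeric(0)
  prom <- numeric(0)               # NA until the component dies
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (p in ord) {
    r <- ((p - 1L) %% nr) + 1L
    nb <- p + off
    ok <- rep(TRUE, 8L)
    if (r == 1L) ok[c(1L, 5L, 7L)] <- FALSE
    if (r == nr) ok[c(2L, 6L, 8L)] <- FALSE
    nb <- nb[ok]
    nb <- nb[nb >= 1L & nb <= nr * nc]
    roots <- unique(vapply(nb[pos[nb] > 0L], function(q) findRoot(pos[q]),
                           integer(1)))
    if (length(roots) == 0L) {
      k <- length(parent) + 1L
      parent[k] <- k; peakIdx[k] <- p; peakVal[k] <- sub[p]
      prom[k] <- NA_real_
      pos[p] <- k
    } else if (length(roots) == 1L) {
      pos[p] <- roots
    } else {
      # merge: highest-peak component survives, the others die here
      win <- roots[which.max(peakVal[roots])]
      for (rt in setdiff(roots, win)) {
        prom[rt] <- peakVal[rt] - sub[p]
        parent[rt] <- win
      }
      pos[p] <- win
    }
  }
  alive <- which(is.na(prom))
  prom[alive] <- peakVal[alive] - rng[1]
  rows <- ((peakIdx - 1L) %% nr) + 1L
  cols <- ((peakIdx - 1L) %/% nr) + 1L
  data.frame(row = rows, col = cols, value = peakVal, prominence = prom)
}

#' Count DAPI local maxima within one cell
#'
#' Counts local maxima of the Gaussian-smoothed DAPI signal restricted to a
#' cell mask. Maxima with topographic prominence below
#' \code{minProminence} times the in-mask dynamic range are discarded, and
#' surviving maxima closer than \code{minSeparation} pixels are merged
#' (the higher one is kept). A flat signal has no maxima.
#'
#' @param dapi DAPI channel matrix (gray values).
#' @param mask logical matrix of the same dimensions selecting the cell.
#' @param smoothingSigma,minSeparation,minProminence see
#'   [cytometryConfig()].
#' @param presmoothed set TRUE when \code{dapi} is already smoothed (used
#'   internally to smooth once per image rather than once per cell).
#' @return integer count of retained maxima.
#' @export
countDapiMaxima <- function(dapi, mask, smoothingSigma = 1,
                            minSeparation = 3, minProminence = 0.1,
                            presmoothed = FALSE) {
  stopifnot(identical(dim(dapi), dim(mask)), is.logical(mask))
  if (!any(mask)) stop("mask is empty")
  if (!presmoothed && smoothingSigma > 0)
    dapi <- .gaussianBlur(dapi, smoothingSigma)
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sub <- dapi[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  maskSub <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  .countMaximaCore(sub, maskSub, minSeparation, minProminence)
}

# prominence filter + distance merge on a cropped masked patch
.countMaximaCore <- function(sub, maskSub, minSeparation, minProminence) {
  peaks <- .maskPeaks(sub, maskSub)
  if (is.null(peaks)) return(0L)
  rng <- range(sub[maskSub])
  peaks <- peaks[peaks$prominence >= minProminence * (rng[2] - rng[1]), ,
                 drop = FALSE]
  if (nrow(peaks) == 0L) return(0L)
  peaks <- peaks[order(peaks$value, decreasing = TRUE), , drop = FALSE]
  keptR <- keptC <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    if (length(keptR) == 0L ||
        all((keptR - peaks$row[i])^2 + (keptC - peaks$col[i])^2 >=
            minSeparation^2)) {
      keptR <- c(keptR, peaks$row[i]); keptC <- c(keptC, peaks$col[i])
    }
  }
  length(keptR)
}

#' Classify cells as dividing from their DAPI maxima count
#'
#' A cell is dividing if and only if it shows exactly two intracellular
#' DAPI maxima (one maximum marks a non-dividing cell). Cells with three or
#' more maxima are non-dividing by default and tallied via the
#' \code{multiMaxima} attribute; set \code{countMultiAsDividing} to include
#' them.
#'
#' @param nMaxima integer vector of per-cell DAPI maxima counts.
#' @param countMultiAsDividing include cells with >= 3 maxima as dividing.
#' @return logical vector with attribute \code{multiMaxima} (count of
#'   cells with three or more maxima).
#' @export
classifyDividing <- function(nMaxima, countMultiAsDividing = FALSE) {
  out <- nMaxima == 2L
  if (countMultiAsDividing) out <- out | nMaxima >= 3L
  structure(out, multiMaxima = sum(nMaxima >= 3L))
}

#' Measure segmented cells
#'
#' For each retained mask: area, centroid, ellipse-equivalent major/minor
#' axis lengths from the second moments of the pixel set (with the 1/12
#' pixel-extent correction), capped-cylinder biovolume, total FISH
#' fluorescence (sum of gray values over the mask), DAPI maxima count and
#' dividing flag.
#'
#' @param masks output of [segmentCells()].
#' @param pair the [ImagePair-class] the masks came from.
#' @param config a [cytometryConfig()] list.
#' @return data.frame with one row per cell: \code{id}, \code{row},
#'   \code{col} (centroid, px), \code{areaUm2}, \code{totalLength},
#'   \code{width} (um), \code{volume} (um^3), \code{totalFluorescence}
#'   (AU), \code{nDapiMaxima}, \code{isDividing}, \code{multiMaxima}.
#' @examples
#' sim <- simulateImagePair(nCells = 10, seed = 1)
#' cells <- measureCells(segmentCells(sim$pair), sim$pair)
#' @export
measureCells <- function(masks, pair, config = cytometryConfig()) {
  stopifnot(is(pair, "ImagePair"))
  px <- pair@pixelSize
  dapiSm <- if (config$smoothingSigma > 0)
    .gaussianBlur(pair@dapi, config$smoothingSigma) else pair@dapi
  labels <- masks$labels
  inside <- which(labels > 0L)
  pixByCell <- split(inside, labels[inside])
  out <- lapply(masks$ids, function(id) {
    idx <- pixByCell[[as.character(id)]]
    ri <- ((idx - 1L) %% nrow(labels)) + 1L
    ci <- ((idx - 1L) %/% nrow(labels)) + 1L
    # central second moments + 1/12 px^2 (finite pixel extent)
    mrr <- mean(ri^2) - mean(ri)^2 + 1 / 12
    mcc <- mean(ci^2) - mean(ci)^2 + 1 / 12
    mrc <- mean(ri * ci) - mean(ri) * mean(ci)
    tr <- mrr + mcc
    det <- mrr * mcc - mrc^2
    eig <- (tr + c(1, -1) * sqrt(pmax(tr^2 - 4 * det, 0))) / 2
    lTot <- 4 * sqrt(eig[1]) * px      # full major axis, um
    w <- 4 * sqrt(pmax(eig[2], 0)) * px
    w <- min(w, lTot)
    rr <- range(ri); cc <- range(ci)
    sub <- dapiSm[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    maskSub <- matrix(FALSE, nrow(sub), ncol(sub))
    maskSub[cbind(ri - rr[1] + 1L, ci - cc[1] + 1L)] <- TRUE
    nMax <- .countMaximaCore(sub, maskSub, config$minSeparation,
                             config$minProminence)
    data.frame(
      id = id, row = mean(ri), col = mean(ci),
      areaUm2 = length(idx) * px^2,
      totalLength = lTot, width = w,
      volume = cellVolume(lTot, w),
      totalFluorescence = sum(pair@fish[idx]),
      nDapiMaxima = nMax
    )
  })
  cells <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(), row = numeric(), col = numeric(),
               areaUm2 = numeric(), totalLength = numeric(),
               width = numeric(), volume = numeric(),
               totalFluorescence = numeric(), nDapiMaxima = integer())
  div <- classifyDividing(cells$nDapiMaxima,
                          countMultiAsDividing = config$countMultiAsDividing)
  cells$isDividing <- as.logical(div)
  cells$multiMaxima <- cells$nDapiMaxima >= 3L
  cells
}

#' Frequency of dividing cells
#'
#' FDC = (number of dividing cells) / (number of all cells), as a fraction.
#' Undefined (NA) for an empty cell set; the counts are attached as
#' attributes.
#'
#' @param cells either the data.frame returned by [measureCells()] (column
#'   \code{isDividing}) or a logical vector of per-cell dividing flags.
#' @return fraction in [0, 1] (NA if no cells), with attributes
#'   \code{nCells} and \code{nDividing}.
#' @examples
#' computeFdc(c(rep(TRUE, 10), rep(FALSE, 90)))   # 0.1
#' @export
computeFdc <- function(cells) {
  flags <- if (is.data.frame(cells)) cells$isDividing else cells
  stopifnot(is.logical(flags))
  n <- length(flags)
  structure(if (n > 0) sum(flags) / n else NA_real_,
            nCells = n, nDividing = sum(flags))
}

#' Cell concentration from filter counts
#'
#' Standard epifluorescence counting arithmetic: cells per field, scaled by
#' the filter-to-field area ratio, per volume filtered.
#'
#' @param nCells total cells counted (>= 0).
#' @param nFields number of fields of view counted (> 0).
#' @param fieldArea area of one field in mm^2 (> 0).
#' @param filterArea effective filtration area in mm^2 (> 0).
#' @param volumeFiltered sample volume filtered in mL (> 0).
#' @return concentration in cells/mL.
#' @examples
#' cellConcentration(100, 10, 0.01, 100, 10)  # 1e4 cells/mL
#' @export
cellConcentration <- function(nCells, nFields, fieldArea, filterArea,
                              volumeFiltered) {
  if (any(nCells < 0)) stop("nCells must be non-negative")
  if (any(nFields <= 0) || any(fieldArea <= 0) || any(filterArea <= 0) ||
      any(volumeFiltered <= 0))
    stop("nFields, fieldArea, filterArea and volumeFiltered must be positive")
  (nCells / nFields) * (filterArea / fieldArea) / volumeFiltered
}

#' Summarize a measured cell table into per-sample statistics
#'
#' @param cells data.frame from [measureCells()].
#' @param sampleId,taxon,date labels.
#' @param nFields,fieldArea,filterArea,volumeFiltered optional counting
#'   metadata; when all are supplied, a cell concentration is computed.
#' @return one-row data.frame: labels, \code{nCells}, \code{nDividing},
#'   \code{fdc}, \code{meanVolume}, \code{sdVolume},
#'   \code{meanFluorescence}, \code{sdFluorescence},
#'   \code{cellConcentration} (NA without counting metadata).
#' @export
summarizeCytometry <- function(cells, sampleId = "sample",
                               taxon = "unknown", date = "",
                               nFields = NA, fieldArea = NA,
                               filterArea = NA, volumeFiltered = NA) {
  fdc <- computeFdc(cells)
  conc <- if (!anyNA(c(nFields, fieldArea, filterArea, volumeFiltered)))
    cellConcentration(nrow(cells), nFields, fieldArea, filterArea,
                      volumeFiltered)
  else NA_real_
  data.frame(
    sampleId = sampleId, taxon = taxon, date = date,
    nCells = attr(fdc, "nCells"), nDividing = attr(fdc, "nDividing"),
    fdc = as.numeric(fdc),
    meanVolume = if (nrow(cells)) mean(cells$volume) else NA_real_,
    sdVolume = if (nrow(cells) > 1) sd(cells$volume) else NA_real_,
    meanFluorescence = if (nrow(cells)) mean(cells$totalFluorescence)
                       else NA_real_,
    sdFluorescence = if (nrow(cells) > 1) sd(cells$totalFluorescence)
                     else NA_real_,
    cellConcentration = conc
  )
}

#' Run the full cytometry stage on one image pair
#'
#' Segmentation, per-cell measurement and per-sample aggregation in one
#' call.
#'
#' @param pair an [ImagePair-class].
#' @param config a [cytometryConfig()] list.
#' @param ... counting metadata forwarded to [summarizeCytometry()].
#' @return list with \code{cells} (per-cell table), \code{sample}
#'   (one-row summary) and \code{segmentation} (tallies from
#'   [segmentCells()]).
#' @export
analyzeImagePair <- function(pair, config = cytometryConfig(), ...) {
  masks <- segmentCells(pair, config)
  cells <- measureCells(masks, pair, config)
  smp <- summarizeCytometry(cells, sampleId = pair@sampleId,
                            taxon = pair@taxon, date = pair@date, ...)
  smp$edgeExcluded <- masks$edgeExcluded
  list(cells = cells, sample = smp,
       segmentation = masks[c("edgeExcluded", "smallExcluded", "threshold")])
}
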