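# Seeded generators with known ground truth: synthetic micrographs, dilution
# experiments and bloom trajectories. All randomness flows through R's RNG so
# identical arguments + seed give bit-identical output.

# 8-bit acquisition noise: Poisson shot noise at the signal level plus
# Gaussian read noise, both scaled by `level`; level = 0 returns the clean
# rounded image.
.addAcquisitionNoise <- function(img, level) {
  stopifnot(level >= 0)
  if (level > 0) {
    shot <- rpois(length(img), lambda = as.vector(pmax(img, 0)))
    img <- img + level * (shot - img) +
      rnorm(length(img), mean = 0, sd = 12.75 * level)
  }
  matrix(pmin(pmax(round(img), 0), 255), nrow = nrow(img))
}

.gaussianBlur <- function(img, sigma) {
  as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = sigma)))
}

#' Simulate a paired FISH/DAPI micrograph with known ground truth
#'
#' Draws \code{nCells} non-overlapping rod/coccoid cells (blurred ellipses)
#' on the FISH channel. On the DAPI channel, non-dividing cells carry one
#' central Gaussian DNA focus; dividing cells carry two foci separated along
#' the major axis by 0.5-0.7 of the cell length (uniform draw), emulating
#' the two intracellular DAPI maxima that define a dividing cell. Exactly
#' \code{round(nCells * fractionDividing)} cells are flagged dividing in the
#' returned truth table. Both channels receive Poisson + Gaussian
#' acquisition noise scaled by \code{noiseLevel} and are quantized to 8 bit.
#'
#' Cells are placed by rejection sampling with at most \code{maxRetries}
#' candidate positions per cell; a field too dense to pack raises an error
#' of class \code{"bloomrates_placement_error"}.
#'
#' @param nCells number of cells to draw (0 gives a blank field and an
#'   empty truth table).
#' @param fractionDividing fraction of cells flagged dividing, in [0, 1].
#' @param pixelSize um per pixel (> 0).
#' @param meanLength,meanWidth mean total cell length and width in um
#'   (length >= width > 0); per-cell values are drawn around these.
#' @param noiseLevel acquisition noise scale (fraction; 0 = noiseless).
#' @param seed integer RNG seed.
#' @param imageSide optional image side in px; sized from \code{nCells}
#'   when NULL.
#' @param maxRetries placement attempts per cell before giving up.
#' @param sampleId,taxon,date labels forwarded to the [ImagePair-class].
#' @return list with elements \code{pair} (an [ImagePair-class]) and
#'   \code{truth}, a data.frame with one row per cell: \code{id},
#'   \code{row}, \code{col} (centroid, px), \code{lengthUm},
#'   \code{widthUm}, \code{orientation} (rad), \code{dividing},
#'   \code{focusSepFrac} (fraction of length; NA for non-dividing cells).
#' @examples
#' sim <- simulateImagePair(nCells = 20, fractionDividing = 0.2, seed = 1)
#' sum(sim$truth$dividing)
#' @export
simulateImagePair <- function(nCells = 100, fractionDividing = 0.1,
                              pixelSize = 0.1, meanLength = 1.4,
                              meanWidth = 0.5, noiseLevel = 0.05,
                              seed = 1, imageSide = NULL,
                              maxRetries = 100, sampleId = "synthetic",
                              taxon = "synthetic", date = "") {
  stopifnot(nCells >= 0, fractionDividing >= 0, fractionDividing <= 1,
            pixelSize > 0, meanWidth > 0, meanLength >= meanWidth)
  set.seed(seed)
  lenPx <- meanLength / pixelSize
  if (is.null(imageSide))
    imageSide <- max(96L, ceiling(sqrt(max(nCells, 1)) * 2.4 * lenPx))
  fish <- matrix(0, imageSide, imageSide)
  dapi <- matrix(0, imageSide, imageSide)

  truth <- data.frame(
    id = integer(), row = numeric(), col = numeric(),
    lengthUm = numeric(), widthUm = numeric(), orientation = numeric(),
    dividing = logical(), focusSepFrac = numeric()
  )

  if (nCells > 0) {
    lengthUm <- pmax(meanWidth, rnorm(nCells, meanLength, 0.12 * meanLength))
    widthUm <- pmin(lengthUm,
                    pmax(0.4 * meanWidth,
                         rnorm(nCells, meanWidth, 0.08 * meanWidth)))
    orientation <- runif(nCells, 0, pi)
    nDividing <- round(nCells * fractionDividing)
    dividing <- rep(FALSE, nCells)
    if (nDividing > 0) dividing[sample.int(nCells, nDividing)] <- TRUE
    sepFrac <- ifelse(dividing, runif(nCells, 0.5, 0.7), NA_real_)

    # rejection-sampled centroids: pairwise centre distance must exceed the
    # mean of the two cell lengths plus a 3 px guard band
    margin <- max(lengthUm) / pixelSize / 2 + 4
    if (2 * margin >= imageSide)
      stop(errorCondition(
        "image too small for the requested cell size",
        class = c("bloomrates_placement_error", "error", "condition")))
    rows <- cols <- numeric(nCells)
    for (i in seq_len(nCells)) {
      placed <- FALSE
      for (try in seq_len(maxRetries)) {
        r <- runif(1, margin, imageSide - margin)
        c <- runif(1, margin, imageSide - margin)
        if (i == 1L) { placed <- TRUE } else {
          j <- seq_len(i - 1L)
          minDist <- (lengthUm[i] + lengthUm[j]) / (2 * pixelSize) + 3
          placed <- all((rows[j] - r)^2 + (cols[j] - c)^2 > minDist^2)
        }
        if (placed) { rows[i] <- r; cols[i] <- c; break }
      }
      if (!placed)
        stop(errorCondition(
          sprintf("could not place cell %d without overlap after %d retries",
                  i, maxRetries),
          class = c("bloomrates_placement_error", "error", "condition")))
    }

    for (i in seq_len(nCells)) {
      a <- lengthUm[i] / pixelSize / 2   # semi-major, px
      b <- widthUm[i] / pixelSize / 2    # semi-minor, px
      th <- orientation[i]
      half <- ceiling(a) + 3L
      ri <- max(1L, floor(rows[i]) - half):min(imageSide, ceiling(rows[i]) + half)
      ci <- max(1L, floor(cols[i]) - half):min(imageSide, ceiling(cols[i]) + half)
      dr <- outer(ri - rows[i], rep(1, length(ci)))
      dc <- outer(rep(1, length(ri)), ci - cols[i])
      u <- dr * cos(th) + dc * sin(th)
      v <- -dr * sin(th) + dc * cos(th)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      fish[ri, ci][inside] <- 180

      foci <- if (dividing[i]) {
        s <- sepFrac[i] * a
        rbind(c(rows[i] + s * cos(th), cols[i] + s * sin(th)),
              c(rows[i] - s * cos(th), cols[i] - s * sin(th)))
      } else {
        rbind(c(rows[i], cols[i]))
      }
      sig <- 1.3
      for (k in seq_len(nrow(foci))) {
        d2 <- (dr + rows[i] - foci[k, 1])^2 + (dc + cols[i] - foci[k, 2])^2
        dapi[ri, ci] <- dapi[ri, ci] + 220 * exp(-d2 / (2 * sig^2))
      }
    }
    fish <- .gaussianBlur(fish, sigma = 1)

    truth <- data.frame(
      id = seq_len(nCells), row = rows, col = cols,
      lengthUm = lengthUm, widthUm = widthUm, orientation = orientation,
      dividing = dividing, focusSepFrac = sepFrac
    )
  }

  fish <- .addAcquisitionNoise(fish, noiseLevel)
  dapi <- .addAcquisitionNoise(pmin(dapi, 255), noiseLevel)
  pair <- ImagePair(fish, dapi, pixelSize = pixelSize,
                    sampleId = sampleId, taxon = taxon, date = date)
  list(pair = pair, truth = truth)
}

#' Simulate a Landry-Hassett dilution experiment
#'
#' For each dilution fraction D and replicate, the start concentration is
#' \code{D * N0Undiluted} and the end concentration follows
#' \code{Nt = N0(D) * exp((mu - grazing * D) * t) * eps}, where \code{eps}
#' is median-one (log-symmetric) lognormal observation noise with CV
#' \code{noiseCv} (0 gives exact values). Defaults mirror the standard
#' series of 100/50/25/10 percent unfiltered seawater incubated for one day
#' in duplicate.
#'
#' @param mu grazer-free cell division rate (per day).
#' @param grazing grazing rate (per day). Negative values are accepted
#'   (biologically odd but representable).
#' @param dilutions fractions of unfiltered seawater, each in (0, 1].
#' @param replicates bottles per dilution.
#' @param t incubation time in days.
#' @param N0Undiluted start concentration of the undiluted treatment
#'   (cells/mL, > 0).
#' @param noiseCv coefficient of variation of lognormal counting noise.
#' @param seed integer RNG seed.
#' @param experimentId,taxon,date labels.
#' @return a [DilutionSeries-class] object.
#' @examples
#' fitDilutionSeries(simulateDilutionSeries(mu = 1, grazing = 0.5, noiseCv = 0))
#' @export
simulateDilutionSeries <- function(mu, grazing,
                                   dilutions = c(1, 0.5, 0.25, 0.1),
                                   replicates = 2, t = 1,
                                   N0Undiluted = 1e5, noiseCv = 0,
                                   seed = 1, experimentId = "sim",
                                   taxon = "synthetic", date = "") {
  stopifnot(all(dilutions > 0), all(dilutions <= 1), t > 0, noiseCv >= 0,
            replicates >= 1)
  if (N0Undiluted <= 0) stop("N0Undiluted must be positive")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), dilution = dilutions)
  N0 <- grid$dilution * N0Undiluted
  Nt <- N0 * exp((mu - grazing * grid$dilution) * t)
  if (noiseCv > 0) {
    # log-symmetric (median-one) multiplicative error: unbiased in rate space
    sdlog <- sqrt(log(1 + noiseCv^2))
    Nt <- Nt * exp(rnorm(nrow(grid), 0, sdlog))
  }
  DilutionSeries(
    data.frame(dilution = grid$dilution, replicate = grid$replicate,
               N0 = N0, Nt = Nt),
    incubationTime = t, experimentId = experimentId,
    taxon = taxon, date = date
  )
}

#' Simulate a bloom abundance/FDC time series with known rates
#'
#' The latent abundance obeys dN/dt = (mu(t) - d(t)) N, integrated
#' deterministically (classical Runge-Kutta on a grid of step <= 0.05 day,
#' with mu and d linearly interpolated between timepoints) and sampled at
#' the requested timepoints. Observations add median-one lognormal noise to N
#' (CV = \code{noiseCv}) and report FDC as
#' \code{clip(a + b * mu(t) + Gaussian noise, 0, 1)} — a linear coupling of
#' the dividing fraction to the division rate, as used for calibration.
#'
#' @param timepoints sampling times in days, strictly increasing.
#' @param mu,d per-day division and mortality rate series (same length as
#'   \code{timepoints}, non-negative).
#' @param N0 start concentration (cells/mL, > 0).
#' @param calibIntercept,calibSlope true FDC calibration line a + b * mu
#'   (fraction, fraction per (per day)); slope must be positive.
#' @param noiseCv lognormal CV of abundance observations.
#' @param fdcSd Gaussian SD of FDC observations (fraction). The default,
#'   0.01, is the binomial counting error of an FDC near 6 percent scored
#'   over a few hundred cells.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{timepoint}, \code{N},
#'   \code{fdc}; the latent truth is attached as
#'   \code{attr(, "truth")} (list with \code{mu}, \code{d}, \code{r},
#'   \code{Nlatent}, \code{calibIntercept}, \code{calibSlope}).
#' @examples
#' tp <- 0:20
#' bl <- simulateBloom(tp, mu = rep(0.693, 21), d = rep(0, 21), noiseCv = 0)
#' @export
simulateBloom <- function(timepoints, mu, d, N0 = 1e5,
                          calibIntercept = 0.02, calibSlope = 0.05,
                          noiseCv = 0.1, fdcSd = 0.01, seed = 1) {
  n <- length(timepoints)
  stopifnot(n >= 2, !is.unsorted(timepoints, strictly = TRUE),
            length(mu) == n, length(d) == n, all(mu >= 0), all(d >= 0),
            N0 > 0, calibSlope > 0, noiseCv >= 0, fdcSd >= 0)
  set.seed(seed)
  muF <- approxfun(timepoints, mu, rule = 2)
  dF <- approxfun(timepoints, d, rule = 2)
  grid <- sort(unique(c(
    seq(timepoints[1], timepoints[n], by = 0.05), timepoints)))
  sol <- deSolve::ode(
    y = c(N = N0), times = grid,
    func = function(t, y, p) list((muF(t) - dF(t)) * y[1]),
    parms = NULL, method = "rk4"
  )
  idx <- match(timepoints, sol[, "time"])
  Nlatent <- unname(sol[idx, "N"])

  Nobs <- Nlatent
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    Nobs <- Nlatent * exp(rnorm(n, 0, sdlog))
  }
  fdc <- calibIntercept + calibSlope * mu
  if (fdcSd > 0) fdc <- fdc + rnorm(n, 0, fdcSd)
  fdc <- pmin(pmax(fdc, 0), 1)

  out <- data.frame(timepoint = timepoints, N = Nobs, fdc = fdc)
  attr(out, "truth") <- list(
    mu = mu, d = d, r = mu - d, Nlatent = Nlatent,
    calibIntercept = calibIntercept, calibSlope = calibSlope
  )
  out
}
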