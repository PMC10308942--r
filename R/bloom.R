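# Bloom dynamics: loess smoothing, sliding-window net growth, mortality
# decomposition d = mu - r, and the composed per-taxon pipeline.

#' Loess smoothing of a time series
#'
#' Locally weighted quadratic regression with tricube weights
#' (\code{stats::loess}), evaluated at the observation times. The default
#' span of 0.4 is the setting used throughout for cell volumes,
#' fluorescence intensities and FDC.
#'
#' @param t times in days.
#' @param y values (NAs are dropped from the fit but predictions are
#'   returned at every \code{t}).
#' @param span fraction of the data in each local fit, in (0, 1].
#' @param degree local polynomial degree (2 = quadratic, the default).
#' @return numeric vector of smoothed values at \code{t}.
#' @examples
#' t <- 1:20
#' loessSmooth(t, rep(3, 20))   # constants are reproduced
#' @export
loessSmooth <- function(t, y, span = 0.4, degree = 2) {
  stopifnot(length(t) == length(y), span > 0, span <= 1)
  ok <- !is.na(t) & !is.na(y)
  if (sum(ok) < 5)
    stop("loess smoothing needs at least 5 non-missing points")
  if (max(3, floor(span * sum(ok))) < degree + 1)
    stop("span too small: fewer points in the local window than parameters")
  fit <- loess(y ~ t, data = data.frame(t = t[ok], y = y[ok]),
               span = span, degree = degree, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  unname(predict(fit, newdata = data.frame(t = t)))
}

#' Sliding-window net growth rate
#'
#' For each timepoint with two preceding and two succeeding observations
#' (window of five by default), a linear regression of abundance on time is
#' fitted over the window; with the fitted abundances at the window's first
#' and last times, the net growth rate is
#' r = ln(N_End / N_Start) / (t_End - t_Start). When a fitted abundance is
#' non-positive the logarithm is undefined and r is missing with flag
#' \code{nonpositive-model}; the first and last (window-1)/2 points are
#' missing with flag \code{edge}. The regression is on the abundance
#' itself, not its logarithm — which is why non-positive fitted values can
#' occur in crashing populations.
#'
#' @param t times in days, strictly increasing within any window.
#' @param N abundances (cells/mL).
#' @param window odd window size >= 3 (default 5 timepoints).
#' @return data.frame with columns \code{timepoint}, \code{r} (per day,
#'   NA-able) and \code{flag} (\code{""}, \code{"edge"} or
#'   \code{"nonpositive-model"}).
#' @examples
#' t <- 0:9
#' netGrowth(t, 1e5 * exp(0.3 * t))$r   # ~0.3 at interior points
#' @export
netGrowth <- function(t, N, window = 5) {
  stopifnot(length(t) == length(N), window >= 3, window %% 2 == 1)
  n <- length(t)
  h <- (window - 1L) / 2L
  r <- rep(NA_real_, n)
  flag <- rep("", n)
  for (i in seq_len(n)) {
    if (i <= h || i > n - h) { flag[i] <- "edge"; next }
    idx <- (i - h):(i + h)
    tw <- t[idx]; Nw <- N[idx]
    if (anyDuplicated(tw))
      stop("duplicate timepoints within a window")
    if (anyNA(Nw)) { flag[i] <- "missing-abundance"; next }
    fit <- lm(Nw ~ tw)
    ends <- unname(predict(fit, newdata = data.frame(tw = range(tw))))
    if (any(ends <= 0)) { flag[i] <- "nonpositive-model"; next }
    r[i] <- logRatioRate(ends[1], ends[2], diff(range(tw)))
  }
  data.frame(timepoint = t, r = r, flag = flag)
}

#' Mortality rate from division and net growth
#'
#' d = mu - r, elementwise. Negative mortality (net growth exceeding the
#' measured division rate) is reported, not clamped — it is diagnostic of
#' observation noise or calibration error — and flagged via the
#' \code{negative} attribute. Missing inputs give missing output.
#'
#' @param mu cell division rates (per day).
#' @param r net growth rates (per day).
#' @return mortality rates per day, with attribute \code{negative}.
#' @examples
#' mortalityRate(1.9, 0.15)   # 1.75
#' @export
mortalityRate <- function(mu, r) {
  stopifnot(length(mu) == length(r))
  d <- mu - r
  structure(d, negative = !is.na(d) & d < 0)
}

#' Decompose a bloom time series into division, net growth and mortality
#'
#' Composes the stages: the FDC series is loess-smoothed (span 0.4),
#' clipped to [0, 1] and inverted through the calibration model to give
#' mu(t); net growth r(t) comes from the sliding-window regression on the
#' abundances (raw by default; set \code{smoothAbundance} to fit windows on
#' the loess-smoothed series instead); mortality is d = mu - r. Every
#' intermediate is kept in the returned table. With no usable FDC, mu and
#' d are missing everywhere but r is still computed.
#'
#' @param data data.frame with columns \code{timepoint} (days, strictly
#'   increasing), \code{N} (cells/mL) and \code{fdc} (fraction, NA-able).
#' @param model a [CalibrationModel-class], invertible for \code{taxon}
#'   (only needed when FDC data are present).
#' @param taxon taxon label used for the calibration lookup.
#' @param span loess span for the FDC (and optional abundance) smoothing.
#' @param window sliding-window size for [netGrowth()].
#' @param smoothAbundance fit net-growth windows on loess-smoothed
#'   abundances instead of raw ones.
#' @return a [RateSeries-class].
#' @examples
#' bl <- simulateBloom(0:24, mu = rep(1, 25), d = rep(0.8, 25),
#'                     noiseCv = 0, fdcSd = 0)
#' m <- buildCalibration(fdc = 0.02 + 0.05 * (0:4) / 2, mu = (0:4) / 2,
#'                       taxon = rep("syn", 5))
#' rs <- runRatePipeline(bl, m, taxon = "syn")
#' @export
runRatePipeline <- function(data, model, taxon, span = 0.4, window = 5,
                            smoothAbundance = FALSE) {
  stopifnot(all(c("timepoint", "N", "fdc") %in% names(data)))
  t <- data$timepoint
  hasFdc <- any(!is.na(data$fdc))
  flags <- rep("", length(t))
  addFlag <- function(flags, where, what)
    ifelse(where, ifelse(flags == "", what, paste(flags, what, sep = ",")),
           flags)

  if (hasFdc) {
    fdcSmooth <- pmin(pmax(loessSmooth(t, data$fdc, span = span), 0), 1)
    mu <- predictDivisionRate(model, fdcSmooth, taxon)
    flags <- addFlag(flags, attr(mu, "clamped"), "clamped")
    mu <- as.numeric(mu)
  } else {
    fdcSmooth <- rep(NA_real_, length(t))
    mu <- rep(NA_real_, length(t))
    flags <- addFlag(flags, rep(TRUE, length(t)), "no-fdc")
  }

  Nin <- if (smoothAbundance) loessSmooth(t, data$N, span = span) else data$N
  ng <- netGrowth(t, Nin, window = window)
  flags <- addFlag(flags, ng$flag != "", ng$flag)
  d <- as.numeric(mortalityRate(mu, ng$r))

  new("RateSeries", taxon = taxon,
      data = data.frame(
        timepoint = t, N = data$N, fdc = data$fdc, fdcSmooth = fdcSmooth,
        mu = mu, r = ng$r, d = d, flag = flags
      ))
}

#' Plot a decomposed rate series
#'
#' Three-rate panel: cell division mu, net growth r and mortality d over
#' time, in base graphics.
#'
#' @param x a [RateSeries-class].
#' @param ... forwarded to \code{matplot}.
#' @return invisibly, \code{x}.
#' @export
plotRateSeries <- function(x, ...) {
  stopifnot(is(x, "RateSeries"))
  d <- x@data
  graphics::matplot(d$timepoint, cbind(d$mu, d$r, d$d), type = "b",
                    pch = c(16, 17, 15), lty = 1,
                    col = c("forestgreen", "steelblue", "firebrick"),
                    xlab = "time (days)", ylab = "rate (per day)",
                    main = x@taxon, ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright",
                   legend = c("cell division", "net growth", "mortality"),
                   col = c("forestgreen", "steelblue", "firebrick"),
                   pch = c(16, 17, 15), bty = "n")
  invisible(x)
}
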