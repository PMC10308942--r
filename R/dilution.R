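# Landry-Hassett dilution analysis: apparent growth rates per bottle and
# the linear regression k(D) = mu - g D across the dilution series.

# summary.lm warns on exact fits; noiseless oracle inputs are a designed
# use here, so that specific warning is muffled
.quietSummary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

#' Log-ratio rate of change
#'
#' The shared primitive of the growth accounting: the exponential rate
#' implied by a start and end abundance over an interval,
#' \code{log(Nend / Nstart) / dt}. Used both for per-bottle apparent growth
#' rates in dilution experiments and for sliding-window net growth.
#'
#' @param Nstart,Nend abundances (cells/mL, > 0), vectorized.
#' @param dt elapsed time in days (> 0).
#' @return rate per day (negative when \code{Nend < Nstart}).
#' @examples
#' logRatioRate(1.4e5, 3.0e5, 5)   # ~0.15/day
#' @export
logRatioRate <- function(Nstart, Nend, dt) {
  if (any(Nstart <= 0) || any(Nend <= 0))
    stop("abundances must be positive (log of a non-positive value)")
  if (any(dt <= 0)) stop("dt must be positive")
  log(Nend / Nstart) / dt
}

#' Apparent growth rate of one incubation
#'
#' k = ln(Nt / N0) / t for a single bottle.
#'
#' @param N0,Nt start and end concentrations (cells/mL, > 0).
#' @param t incubation time in days (> 0).
#' @return apparent growth rate per day (vectorized).
#' @examples
#' apparentGrowthRate(1e5, 2e5, 1)   # ln 2
#' @export
apparentGrowthRate <- function(N0, Nt, t) logRatioRate(N0, Nt, t)

#' Fit the Landry-Hassett dilution regression
#'
#' Computes the apparent growth rate of every bottle and fits the ordinary
#' least squares regression k ~ D on the individual replicate points
#' (replicates are not averaged, preserving degrees of freedom). The
#' intercept is the grazer-free cell division rate mu (rate as D tends to
#' 0) and the negated slope the grazing rate g. A negative fitted mu is
#' reported as-is with a warning and the \code{negativeMu} flag set.
#'
#' @param series a [DilutionSeries-class].
#' @return a [DilutionResult-class].
#' @examples
#' s <- simulateDilutionSeries(mu = 1, grazing = 0.5, noiseCv = 0)
#' fitDilutionSeries(s)
#' @export
fitDilutionSeries <- function(series) {
  stopifnot(is(series, "DilutionSeries"))
  d <- series@data
  k <- apparentGrowthRate(d$N0, d$Nt, series@incubationTime)
  if (length(unique(d$dilution)) < 2L)
    stop("rank-deficient dilution series: need >= 2 distinct dilution fractions")
  fit <- lm(k ~ dilution, data = data.frame(k = k, dilution = d$dilution))
  sm <- .quietSummary(fit)
  co <- sm$coefficients
  mu <- unname(co["(Intercept)", "Estimate"])
  if (mu < 0)
    warning(sprintf("fitted division rate is negative (%.3g /d) in '%s'",
                    mu, series@experimentId))
  new("DilutionResult",
      mu = mu,
      grazing = -unname(co["dilution", "Estimate"]),
      muSE = unname(co["(Intercept)", "Std. Error"]),
      grazingSE = unname(co["dilution", "Std. Error"]),
      r2 = sm$r.squared,
      nPoints = nrow(d),
      negativeMu = mu < 0,
      fit = fit)
}
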