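# Calibration of FDC against experimentally determined division rates:
# the interaction regression y ~ x * group, its reshaping into per-taxon
# (intercept, slope) pairs, and the inversion FDC -> mu.

#' Interaction linear regression across groups
#'
#' Ordinary least squares of \code{y ~ x * group} (main effects plus
#' interaction), the general utility behind the FDC calibration and the
#' other cross-characteristic regressions (volume, ribosome content, FDC;
#' mortality versus grazing). With a single group it degenerates to simple
#' regression \code{y ~ x}.
#'
#' @param y,x numeric vectors (response and predictor).
#' @param group optional factor/character of group labels.
#' @return list of class \code{"interactionFit"}: \code{fit} (the
#'   \code{lm}), \code{coefficients}, \code{vcov}, \code{r2},
#'   \code{pValue} (overall F-test), \code{n}.
#' @examples
#' g <- rep(c("a", "b"), each = 10); x <- rep(1:10, 2)
#' y <- ifelse(g == "a", 1 + 2 * x, 3 - x)
#' fitInteractionModel(y, x, g)$r2   # 1
#' @export
fitInteractionModel <- function(y, x, group = NULL) {
  stopifnot(length(y) == length(x))
  if (is.null(group)) group <- rep("all", length(y))
  stopifnot(length(group) == length(y))
  df <- data.frame(y = y, x = x, group = factor(group))
  df <- df[complete.cases(df), ]
  xvar <- tapply(df$x, df$group, function(v) length(unique(v)))
  bad <- names(xvar)[xvar < 2]
  if (length(bad))
    stop(sprintf("x is constant within group(s): %s (rank-deficient fit)",
                 paste(bad, collapse = ", ")))
  nGroups <- nlevels(droplevels(df$group))
  nPar <- if (nGroups > 1) 2 * nGroups else 2
  if (nrow(df) <= nPar)
    stop(sprintf("insufficient data: %d points for %d parameters",
                 nrow(df), nPar))
  fit <- if (nGroups > 1) lm(y ~ x * group, data = df)
         else lm(y ~ x, data = df)
  sm <- .quietSummary(fit)
  fs <- sm$fstatistic
  p <- if (!is.null(fs) && all(is.finite(fs)))
    unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  else if (sm$r.squared > 1 - 1e-12) 0 else NA_real_
  structure(
    list(fit = fit, coefficients = coef(fit),
         vcov = sm$sigma^2 * sm$cov.unscaled,
         r2 = sm$r.squared, pValue = p, n = nrow(df)),
    class = "interactionFit"
  )
}

#' @export
print.interactionFit <- function(x, ...) {
  cat(sprintf("interactionFit: n = %d, R2 = %.4f, overall p = %.3g\n",
              x$n, x$r2, x$pValue))
  print(x$coefficients)
  invisible(x)
}

# per-taxon (a, b) and their variances from a treatment-contrast fit
.perTaxonLines <- function(fit, V, taxa) {
  co <- coef(fit)
  base <- taxa[1]
  out <- lapply(taxa, function(tx) {
    aTerms <- "(Intercept)"
    bTerms <- "x"
    if (tx != base) {
      aTerms <- c(aTerms, paste0("group", tx))
      bTerms <- c(bTerms, paste0("x:group", tx))
    }
    aTerms <- intersect(aTerms, names(co))
    bTerms <- intersect(bTerms, names(co))
    a <- sum(co[aTerms]); b <- sum(co[bTerms])
    varA <- sum(V[aTerms, aTerms])
    varB <- sum(V[bTerms, bTerms])
    covAB <- sum(V[aTerms, bTerms, drop = FALSE])
    data.frame(taxon = tx, intercept = a, slope = b,
               slopeSE = sqrt(varB), varIntercept = varA,
               varSlope = varB, covInterceptSlope = covAB)
  })
  do.call(rbind, out)
}

#' Build a per-taxon FDC calibration
#'
#' Fits FDC ~ mu * taxon via [fitInteractionModel()] and reshapes the
#' coefficients into per-taxon calibration lines FDC = a + b mu. Taxa whose
#' fitted slope b is not positive are retained but flagged non-invertible
#' (their FDC carries no usable rate signal).
#'
#' @param fdc frequencies of dividing cells (fractions in [0, 1]).
#' @param mu experimentally derived division rates (per day), paired with
#'   \code{fdc}.
#' @param taxon taxon (FISH probe) labels; at least 2 paired observations
#'   per taxon.
#' @return a [CalibrationModel-class].
#' @examples
#' m <- buildCalibration(fdc = 0.02 + 0.05 * (1:5), mu = 1:5,
#'                       taxon = rep("SAR11", 5))
#' calibCoefficients(m)
#' @export
buildCalibration <- function(fdc, mu, taxon = NULL) {
  if (is.null(taxon)) taxon <- rep("all", length(fdc))
  keep <- complete.cases(fdc, mu, taxon)
  fdc <- fdc[keep]; mu <- mu[keep]; taxon <- as.character(taxon)[keep]
  if (any(fdc < 0 | fdc > 1))
    stop("fdc values must be fractions in [0, 1] (divide percentages by 100)")
  cnt <- table(taxon)
  if (any(cnt < 2))
    stop(sprintf("need >= 2 paired observations per taxon; too few for: %s",
                 paste(names(cnt)[cnt < 2], collapse = ", ")))
  ifit <- fitInteractionModel(fdc, mu, taxon)
  taxa <- levels(factor(taxon))
  lines <- .perTaxonLines(ifit$fit, ifit$vcov, taxa)
  lines$invertible <- lines$slope > 0
  if (any(!lines$invertible))
    warning(sprintf("non-positive slope; taxon marked non-invertible: %s",
                    paste(lines$taxon[!lines$invertible], collapse = ", ")))
  new("CalibrationModel",
      coefficients = lines, vcov = ifit$vcov, r2 = ifit$r2,
      pValue = ifit$pValue, n = as.integer(ifit$n), fit = ifit$fit)
}

#' Convert FDC observations into division rates
#'
#' Inverts the per-taxon calibration line: mu = (fdc - a) / b. Negative
#' predictions (fdc below the taxon's intercept) are clamped to zero and
#' flagged — division rates are non-negative, and the paper's range starts
#' at no cell division.
#'
#' @param model a [CalibrationModel-class].
#' @param fdc FDC values (fractions in [0, 1]), vectorized.
#' @param taxon single taxon label, or vector matched to \code{fdc}.
#' @param se also return a delta-method standard error (ignores error in
#'   the fdc observation itself).
#' @return division rates per day, with attribute \code{clamped} (logical
#'   vector) and, when \code{se = TRUE}, attribute \code{se}.
#' @examples
#' m <- buildCalibration(fdc = 0.02 + 0.05 * (1:5), mu = 1:5,
#'                       taxon = rep("SAR11", 5))
#' predictDivisionRate(m, 0.12, "SAR11")   # 2 /day
#' @export
predictDivisionRate <- function(model, fdc, taxon, se = FALSE) {
  stopifnot(is(model, "CalibrationModel"))
  if (any(fdc < 0 | fdc > 1, na.rm = TRUE))
    stop("fdc must lie in [0, 1]")
  co <- model@coefficients
  if (length(taxon) == 1L) taxon <- rep(taxon, length(fdc))
  stopifnot(length(taxon) == length(fdc))
  m <- match(taxon, co$taxon)
  if (anyNA(m))
    stop(sprintf("unknown taxon: %s",
                 paste(unique(taxon[is.na(m)]), collapse = ", ")))
  if (any(!co$invertible[m]))
    stop(sprintf("non-invertible calibration (slope <= 0) for taxon: %s",
                 paste(unique(taxon[!co$invertible[m]]), collapse = ", ")))
  a <- co$intercept[m]; b <- co$slope[m]
  mu <- (fdc - a) / b
  clamped <- !is.na(mu) & mu < 0
  mu[clamped] <- 0
  out <- structure(mu, clamped = clamped)
  if (se) {
    dev <- fdc - a
    varMu <- co$varIntercept[m] / b^2 + dev^2 * co$varSlope[m] / b^4 +
      2 * dev * co$covInterceptSlope[m] / b^3
    attr(out, "se") <- sqrt(pmax(varMu, 0))
  }
  out
}

#' Serialize / restore a calibration model as JSON
#'
#' The JSON records per-taxon lines, the coefficient covariance, fit
#' diagnostics and a provenance stamp. The underlying \code{lm} object is
#' not serialized; a restored model predicts identically but cannot be
#' refitted.
#'
#' @param model a [CalibrationModel-class].
#' @param path file path for the JSON document.
#' @return \code{writeCalibration}: \code{path}, invisibly;
#'   \code{readCalibration}: a [CalibrationModel-class].
#' @export
writeCalibration <- function(model, path) {
  stopifnot(is(model, "CalibrationModel"))
  obj <- list(
    type = "bloomrates.CalibrationModel",
    version = as.character(utils::packageVersion("bloomrates")),
    coefficients = model@coefficients,
    vcov = list(values = model@vcov, names = rownames(model@vcov)),
    r2 = model@r2, pValue = model@pValue, n = model@n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "bloomrates.CalibrationModel"))
    stop("not a serialized CalibrationModel: ", path)
  V <- as.matrix(obj$vcov$values)
  dimnames(V) <- list(obj$vcov$names, obj$vcov$names)
  new("CalibrationModel",
      coefficients = as.data.frame(obj$coefficients),
      vcov = V, r2 = obj$r2, pValue = obj$pValue,
      n = as.integer(obj$n), fit = NULL)
}
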