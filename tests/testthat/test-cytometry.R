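test_that("capped-cylinder volume matches hand-evaluated cases", {
  # sphere limit: l_tot = w = 1 um
  expect_equal(cellVolume(1, 1), 4 / 3 * pi * 0.5^3, tolerance = 1e-12)
  # r = 0.25, l = 1.0: (4/3) pi r^3 + pi r^2 l = 0.06545 + 0.19635
  expect_equal(cellVolume(1.5, 0.5),
               4 / 3 * pi * 0.25^3 + pi * 0.25^2 * 1.0, tolerance = 1e-12)
  expect_equal(round(cellVolume(1.5, 0.5), 4), 0.2618)
  expect_error(cellVolume(0.4, 0.5), "caps")
  expect_error(cellVolume(-1, 0.5), "positive")
  expect_error(cellVolume(1, 0), "positive")
})

test_that("volume is strictly increasing in each argument", {
  set.seed(42)
  w <- runif(50, 0.2, 1); l <- w + runif(50, 0, 2)
  eps <- 1e-6
  expect_true(all(cellVolume(l + eps, w) > cellVolume(l, w)))
  expect_true(all(cellVolume(l + eps, w + eps) > cellVolume(l, w)))
})

test_that("segmentation recovers well-separated cells one-to-one", {
  sim <- simulateImagePair(nCells = 50, fractionDividing = 0.1,
                           noiseLevel = 0.02, seed = 21)
  masks <- segmentCells(sim$pair)
  expect_length(masks$ids, 50)
  cells <- measureCells(masks, sim$pair)
  # match each truth cell to the nearest detected centroid, within 2 px
  d <- sqrt(outer(sim$truth$row, cells$row, "-")^2 +
            outer(sim$truth$col, cells$col, "-")^2)
  nearest <- apply(d, 1, min)
  expect_true(all(nearest < 2))
})

test_that("blank images segment to an empty cell list", {
  blank <- rawPair(matrix(0, 64, 64))
  masks <- segmentCells(blank)
  expect_length(masks$ids, 0)
  expect_identical(nrow(measureCells(masks, blank)), 0L)
  expect_true(is.na(computeFdc(measureCells(masks, blank))))
})

test_that("border-touching components are excluded and tallied", {
  fish <- matrix(0, 64, 64)
  fish[1:6, 30:36] <- 200       # touches row 1
  fish[30:36, 30:36] <- 200     # interior
  masks <- segmentCells(rawPair(fish), cytometryConfig(backgroundRadius = 0))
  expect_length(masks$ids, 1)
  expect_identical(masks$edgeExcluded, 1L)
})

test_that("total fluorescence is the sum of gray values and is translation invariant", {
  fish <- matrix(0, 64, 64)
  fish[20:29, 20:24] <- 37      # 10 x 5 rectangle, uniform gray
  pair <- rawPair(fish)
  masks <- segmentCells(pair, cytometryConfig(backgroundRadius = 0))
  cells <- measureCells(masks, pair, cytometryConfig(backgroundRadius = 0))
  expect_identical(nrow(cells), 1L)
  expect_equal(cells$totalFluorescence, 50 * 37)

  fish2 <- matrix(0, 64, 64)
  fish2[40:49, 31:35] <- 37     # same rectangle, translated
  cells2 <- measureCells(
    segmentCells(rawPair(fish2), cytometryConfig(backgroundRadius = 0)),
    rawPair(fish2), cytometryConfig(backgroundRadius = 0))
  expect_equal(cells2$totalFluorescence, cells$totalFluorescence)
  expect_equal(cells2$areaUm2, cells$areaUm2)
  expect_equal(cells2$volume, cells$volume)
})

test_that("measured axes recover known ellipse geometry within 10 percent", {
  sim <- simulateImagePair(nCells = 1, fractionDividing = 0,
                           meanLength = 2.0, meanWidth = 0.8,
                           noiseLevel = 0, seed = 5)
  cells <- measureCells(segmentCells(sim$pair), sim$pair)
  expect_identical(nrow(cells), 1L)
  expect_lt(abs(cells$totalLength / sim$truth$lengthUm - 1), 0.1)
  expect_lt(abs(cells$width / sim$truth$widthUm - 1), 0.1)
})

test_that("DAPI maxima counting follows the two-vs-one contract", {
  mk <- function(foci, n = 41, amp = 200, sigma = 1.3) {
    img <- matrix(0, n, n)
    for (f in foci) {
      d2 <- outer((1:n - f[1])^2, (1:n - f[2])^2, "+")
      img <- img + amp * exp(-d2 / (2 * sigma^2))
    }
    img
  }
  mask <- matrix(TRUE, 41, 41)
  # flat signal: no maxima
  expect_identical(countDapiMaxima(matrix(7, 41, 41), mask), 0L)
  # one focus
  expect_identical(countDapiMaxima(mk(list(c(21, 21))), mask), 1L)
  # two foci separated well beyond minSeparation
  expect_identical(
    countDapiMaxima(mk(list(c(15, 21), c(27, 21))), mask), 2L)
  # two foci closer than minSeparation merge to one
  expect_identical(
    countDapiMaxima(mk(list(c(20, 21), c(22, 21))), mask,
                    minSeparation = 4), 1L)
  # low-prominence noise bump on a strong focus is discarded
  img <- mk(list(c(15, 21)))
  img[30, 30] <- img[30, 30] + 5
  expect_identical(countDapiMaxima(img, mask, smoothingSigma = 0), 1L)
})

test_that("dividing classification is exactly two maxima", {
  flags <- classifyDividing(c(1L, 2L, 3L, 2L, 4L))
  expect_identical(as.logical(flags), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(attr(flags, "multiMaxima"), 2L)
  withMulti <- classifyDividing(c(1L, 2L, 3L), countMultiAsDividing = TRUE)
  expect_identical(as.logical(withMulti), c(FALSE, TRUE, TRUE))
})

test_that("FDC is the dividing fraction and pools as a count-weighted mean", {
  expect_equal(as.numeric(computeFdc(c(rep(TRUE, 10), rep(FALSE, 90)))), 0.1)
  expect_equal(as.numeric(computeFdc(rep(TRUE, 5))), 1.0)
  empty <- computeFdc(logical(0))
  expect_true(is.na(empty))
  expect_identical(attr(empty, "nCells"), 0L)
  # union of two samples: count-weighted mean
  a <- c(rep(TRUE, 3), rep(FALSE, 7))       # fdc 0.3, n 10
  b <- c(rep(TRUE, 1), rep(FALSE, 29))      # fdc ~0.033, n 30
  pooled <- computeFdc(c(a, b))
  expect_equal(as.numeric(pooled),
               (10 * 0.3 + 30 * (1 / 30)) / 40, tolerance = 1e-12)
  expect_true(all(vapply(list(a, b, c(a, b)),
                         function(v) { f <- as.numeric(computeFdc(v))
                                       f >= 0 && f <= 1 }, logical(1))))
})

test_that("cell concentration arithmetic and proportionality", {
  expect_equal(cellConcentration(100, 10, 0.01, 100, 10), 1e4)
  expect_equal(cellConcentration(0, 10, 0.01, 100, 10), 0)
  expect_equal(cellConcentration(100, 10, 0.01, 100, 20),
               cellConcentration(100, 10, 0.01, 100, 10) / 2)
  expect_error(cellConcentration(100, 0, 0.01, 100, 10), "positive")
  expect_error(cellConcentration(100, 10, 0.01, 100, 0), "positive")
})

test_that("dividing-cell detection is exact on clean, well-separated fields", {
  sim <- simulateImagePair(nCells = 80, fractionDividing = 0.25,
                           noiseLevel = 0.02, seed = 31)
  res <- analyzeImagePair(sim$pair)
  expect_identical(res$sample$nCells, 80L)
  expect_equal(res$sample$fdc, 0.25)
})
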