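test_that("two groups on exact distinct lines are recovered perfectly", {
  x <- rep(seq(0, 2, by = 0.5), 2)
  g <- rep(c("A", "B"), each = 5)
  y <- ifelse(g == "A", 0.01 + 0.04 * x, 0.03 + 0.07 * x)
  fit <- fitInteractionModel(y, x, g)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  co <- fit$coefficients
  expect_equal(unname(co["(Intercept)"]), 0.01, tolerance = 1e-10)
  expect_equal(unname(co["x"]), 0.04, tolerance = 1e-10)
  expect_equal(unname(co["(Intercept)"] + co["groupB"]), 0.03,
               tolerance = 1e-10)
  expect_equal(unname(co["x"] + co["x:groupB"]), 0.07, tolerance = 1e-10)
})

test_that("constant predictor within a group raises a rank error naming it", {
  x <- c(1, 2, 3, 5, 5, 5)
  g <- rep(c("ok", "flat"), each = 3)
  expect_error(fitInteractionModel(rnorm(6), x, g), "flat")
})

test_that("a single group degenerates to simple regression", {
  set.seed(7)
  x <- 1:20; y <- 2 + 0.3 * x + rnorm(20, 0, 0.1)
  fit <- fitInteractionModel(y, x)
  ref <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-12)
  expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-12)
})

test_that("interaction coefficients are unbiased under simulation", {
  # intercepts far enough from 0 that the fraction bounds never truncate
  aT <- c(A = 0.05, B = 0.08); bT <- c(A = 0.03, B = 0.06)
  nrep <- 200; n <- 50
  est <- matrix(NA_real_, nrep, 2)
  set.seed(123)
  for (i in seq_len(nrep)) {
    x <- runif(2 * n, 0, 2)
    g <- rep(c("A", "B"), each = n)
    y <- aT[g] + bT[g] * x + rnorm(2 * n, 0, 0.01)
    m <- buildCalibration(y, x, g)
    est[i, ] <- calibCoefficients(m)$slope
  }
  mcse <- apply(est, 2, sd) / sqrt(nrep)
  expect_lt(abs(mean(est[, 1]) - bT["A"]), 3 * mcse[1])
  expect_lt(abs(mean(est[, 2]) - bT["B"]), 3 * mcse[2])
})

test_that("calibration on exact lines gives exact per-taxon (a, b)", {
  m <- exactCalibration("SAR11")
  co <- calibCoefficients(m)
  expect_equal(co$intercept, 0.02, tolerance = 1e-12)
  expect_equal(co$slope, 0.05, tolerance = 1e-12)
  expect_true(co$invertible)

  mu <- rep(seq(0, 2, by = 0.5), 2)
  tx <- rep(c("SAR11", "SAR86"), each = 5)
  fdc <- ifelse(tx == "SAR11", 0.02 + 0.05 * mu, 0.01 + 0.08 * mu)
  m2 <- buildCalibration(fdc, mu, tx)
  co2 <- calibCoefficients(m2)
  expect_equal(co2$intercept[co2$taxon == "SAR86"], 0.01, tolerance = 1e-10)
  expect_equal(co2$slope[co2$taxon == "SAR86"], 0.08, tolerance = 1e-10)
})

test_that("inversion: mu = (fdc - a)/b with clamping at zero", {
  m <- exactCalibration("syn")
  expect_equal(as.numeric(predictDivisionRate(m, 0.12, "syn")), 2.0,
               tolerance = 1e-10)
  expect_equal(as.numeric(predictDivisionRate(m, 0.02, "syn")), 0)
  low <- predictDivisionRate(m, 0.005, "syn")
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "clamped"))
  expect_error(predictDivisionRate(m, 0.1, "nope"), "unknown taxon")
  expect_error(predictDivisionRate(m, 1.5, "syn"), "0, 1")
})

test_that("round trip through build + predict is exact on the line", {
  m <- exactCalibration("syn")
  mu <- c(0, 0.3, 1.1, 2.4)
  back <- predictDivisionRate(m, 0.02 + 0.05 * mu, "syn")
  expect_equal(as.numeric(back), mu, tolerance = 1e-10)
  # inversion strictly increasing in fdc
  f <- seq(0.02, 0.3, by = 0.01)
  p <- as.numeric(predictDivisionRate(m, f, "syn"))
  expect_true(all(diff(p) > 0))
})

test_that("non-invertible taxa are flagged and refuse prediction", {
  mu <- rep(seq(0, 2, by = 0.5), 2)
  tx <- rep(c("up", "down"), each = 5)
  fdc <- ifelse(tx == "up", 0.02 + 0.05 * mu, pmax(0.2 - 0.05 * mu, 0))
  expect_warning(m <- buildCalibration(fdc, mu, tx), "non-invertible")
  co <- calibCoefficients(m)
  expect_false(co$invertible[co$taxon == "down"])
  expect_error(predictDivisionRate(m, 0.1, "down"), "non-invertible")
  expect_equal(as.numeric(predictDivisionRate(m, 0.12, "up")), 2,
               tolerance = 1e-10)
})

test_that("noisy calibration recovers slopes within 2 SE", {
  set.seed(99)
  taxa <- c("SAR11", "SAR86", "Bacteroidetes", "Aurantivirga")
  slopes <- c(0.05, 0.03, 0.06, 0.04)
  mu <- runif(20, 0.1, 2)                 # 5 experiments x 4 taxa
  tx <- rep(taxa, each = 5)
  fdc <- 0.02 + slopes[match(tx, taxa)] * mu + rnorm(20, 0, 0.01)
  m <- buildCalibration(pmin(pmax(fdc, 0), 1), mu, tx)
  co <- calibCoefficients(m)
  for (i in seq_along(taxa)) {
    row <- co[co$taxon == taxa[i], ]
    expect_lt(abs(row$slope - slopes[i]), 2 * row$slopeSE)
  }
})

test_that("JSON serialization round-trips predictions", {
  m <- exactCalibration("syn")
  path <- tempfile(fileext = ".json")
  writeCalibration(m, path)
  m2 <- readCalibration(path)
  f <- c(0.02, 0.07, 0.12)
  expect_equal(as.numeric(predictDivisionRate(m2, f, "syn")),
               as.numeric(predictDivisionRate(m, f, "syn")),
               tolerance = 1e-12)
  expect_equal(m2@r2, m@r2, tolerance = 1e-12)
  se1 <- attr(predictDivisionRate(m, f, "syn", se = TRUE), "se")
  se2 <- attr(predictDivisionRate(m2, f, "syn", se = TRUE), "se")
  expect_equal(se2, se1, tolerance = 1e-10)
})
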