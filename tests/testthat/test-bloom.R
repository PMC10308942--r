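test_that("loess reproduces constants and straight lines", {
  t <- 1:20
  expect_equal(loessSmooth(t, rep(3.7, 20)), rep(3.7, 20),
               tolerance = 1e-8)
  y <- 2 - 0.4 * t
  expect_equal(loessSmooth(t, y), y, tolerance = 1e-8)
  expect_error(loessSmooth(1:4, 1:4), "at least 5")
})

test_that("loess at span 0.4 beats the noise on a smooth signal", {
  # simulation oracle: mean RMSE against a noisy sine across seeds is
  # well under half the noise SD (per-seed RMSE varies, mean ~ sigma/3)
  t <- seq(0, pi, length.out = 60)
  truth <- sin(t)
  set.seed(17)
  rmse <- replicate(20, {
    y <- truth + rnorm(60, 0, 0.1)
    sqrt(mean((loessSmooth(t, y, span = 0.4) - truth)^2))
  })
  expect_lt(mean(rmse), 0.1 / 2)
})

test_that("two-point rate reproduces the in-field worked example", {
  # doubling from 1.4e5 to 3.0e5 cells/mL over 5 days
  expect_equal(round(logRatioRate(1.4e5, 3.0e5, 5), 2), 0.15)
})

test_that("window regression on an exact exponential matches the closed-form oracle", {
  rho <- 0.3
  t <- 0:9
  N <- 1e5 * exp(rho * t)
  # closed-form evaluation of the estimator on one centered window:
  # linear LS of e^{rho s} on s in {-2..2}, rate from the fitted endpoints
  s <- -2:2
  Ns <- exp(rho * s)
  b <- sum(s * Ns) / sum(s^2)
  a <- mean(Ns)
  expected <- log((a + 2 * b) / (a - 2 * b)) / 4
  ng <- netGrowth(t, N, window = 5)
  interior <- ng$flag == ""
  expect_identical(sum(interior), 6L)
  expect_equal(ng$r[interior], rep(expected, 6), tolerance = 1e-10)
  # the window fit overestimates an accelerating exponential; the bias
  # vanishes as the sampling interval shrinks
  expect_gt(expected, rho)
  tf <- seq(0, 0.9, by = 0.1)
  ngf <- netGrowth(tf, 1e5 * exp(rho * tf), window = 5)
  expect_equal(ngf$r[ngf$flag == ""], rep(rho, 6), tolerance = 5e-3)
})

test_that("net growth flags edges and non-positive window fits", {
  t <- 0:9
  ng <- netGrowth(t, 1e5 * exp(0.1 * t), window = 5)
  expect_identical(ng$flag[1:2], c("edge", "edge"))
  expect_identical(ng$flag[9:10], c("edge", "edge"))
  expect_true(all(is.na(ng$r[ng$flag == "edge"])))
  # crashing linear series: fitted window values go negative
  Ncrash <- seq(5e4, -4e4, length.out = 10)
  Nobs <- pmax(Ncrash, 1)    # observations stay positive, the fit does not
  ng2 <- netGrowth(t, Nobs, window = 5)
  expect_true("nonpositive-model" %in% ng2$flag)
  expect_true(all(is.na(ng2$r[ng2$flag == "nonpositive-model"])))
  expect_error(netGrowth(c(0, 1, 1, 2, 3, 4), rep(1e5, 6), window = 5),
               "duplicate")
  expect_error(netGrowth(t, t, window = 4))
})

test_that("net growth is invariant to abundance rescaling and time shifts", {
  set.seed(5)
  t <- cumsum(runif(12, 0.5, 2))          # irregular sampling
  N <- 1e5 * exp(0.2 * t) * exp(rnorm(12, 0, 0.05))
  a <- netGrowth(t, N)
  b <- netGrowth(t, N * 13.7)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  c_ <- netGrowth(t + 100, N)
  expect_equal(a$r, c_$r, tolerance = 1e-10)
})

test_that("mortality is division minus net growth, negatives flagged", {
  expect_equal(as.numeric(mortalityRate(1.9, 0.15)), 1.75)
  expect_equal(as.numeric(mortalityRate(0.4, 0.4)), 0)
  d <- mortalityRate(0.5, 0.8)
  expect_equal(as.numeric(d), -0.3)
  expect_true(attr(d, "negative"))
  expect_true(is.na(as.numeric(mortalityRate(NA_real_, 0.1))))
})

test_that("pipeline preserves the identity mu = r + d wherever defined", {
  tp <- 0:30
  mu <- 1.9 * exp(-(tp - 15)^2 / 50)
  bl <- simulateBloom(tp, mu, d = 0.9 * mu, noiseCv = 0.1, seed = 8)
  rs <- runRatePipeline(bl, exactCalibration("syn"), taxon = "syn")
  d <- rateTable(rs)
  ok <- !is.na(d$mu) & !is.na(d$r)
  expect_true(any(ok))
  expect_equal(d$d[ok], d$mu[ok] - d$r[ok], tolerance = 1e-12)
})

test_that("noiseless constant-rate bloom is decomposed accurately", {
  tp <- seq(0, 12, by = 0.5)
  n <- length(tp)
  bl <- simulateBloom(tp, mu = rep(1, n), d = rep(0.8, n),
                      noiseCv = 0, fdcSd = 0)
  d <- rateTable(runRatePipeline(bl, exactCalibration("syn"), taxon = "syn"))
  expect_equal(d$mu, rep(1, n), tolerance = 1e-6)
  interior <- !is.na(d$r)
  expect_equal(d$r[interior], rep(0.2, sum(interior)), tolerance = 0.02)
  expect_equal(d$d[interior], rep(0.8, sum(interior)), tolerance = 0.02)
})

test_that("a bloom without mortality decomposes to d near zero", {
  tp <- seq(0, 12, by = 0.5)
  n <- length(tp)
  bl <- simulateBloom(tp, mu = rep(0.3, n), d = rep(0, n),
                      noiseCv = 0, fdcSd = 0)
  d <- rateTable(runRatePipeline(bl, exactCalibration("syn"), taxon = "syn"))
  expect_lt(max(abs(d$d), na.rm = TRUE), 0.02)
})

test_that("missing FDC leaves mu and d undefined but r computed", {
  tp <- 0:9
  bl <- data.frame(timepoint = tp, N = 1e5 * exp(0.1 * tp), fdc = NA_real_)
  rs <- runRatePipeline(bl, exactCalibration("syn"), taxon = "syn")
  d <- rateTable(rs)
  expect_true(all(is.na(d$mu)))
  expect_true(all(is.na(d$d)))
  expect_true(any(!is.na(d$r)))
  expect_true(all(grepl("no-fdc", d$flag)))
})
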