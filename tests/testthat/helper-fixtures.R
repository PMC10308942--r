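# Shared fixture builders. All fixtures are built in code at test time.

# calibration model on the exact line FDC = 0.02 + 0.05 mu, single taxon
exactCalibration <- function(taxon = "syn") {
  mu <- seq(0, 2, by = 0.5)
  buildCalibration(fdc = 0.02 + 0.05 * mu, mu = mu,
                   taxon = rep(taxon, length(mu)))
}

# noiseless dilution series with known (mu, g)
exactDilutionSeries <- function(mu = 1.0, g = 0.5,
                                dilutions = c(1, 0.5, 0.25, 0.1),
                                replicates = 2) {
  simulateDilutionSeries(mu = mu, grazing = g, dilutions = dilutions,
                         replicates = replicates, noiseCv = 0, seed = 1)
}

# an ImagePair built by hand from raw matrices (labels empty)
rawPair <- function(fish, dapi = fish * 0, pixelSize = 0.1) {
  ImagePair(fish, dapi, pixelSize = pixelSize)
}
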