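# bloomrates

Growth accounting for marine bacterioplankton populations during
phytoplankton blooms.

Heterotrophic bacterioplankton clades (SAR11, SAR86, *Bacteroidetes*,
*Aurantivirga*, ...) can divide more than once per day while their
standing stocks hardly move: grazing and viral lysis remove cells about
as fast as they are produced. Abundance counts alone therefore see only
*net* growth. `bloomrates` implements the full accounting that separates
the gross terms for anyone working with FISH/DAPI micrographs and
dilution experiments:

* **Image cytometry** — segment FISH-positive cells from paired
  two-channel 8-bit micrographs; measure biovolume with the
  capped-cylinder model *V = (4/3)πr³ + πr²l* (r = width/2,
  l = length − 2r) and total fluorescence (sum of gray values); classify
  a cell as **dividing** iff its DAPI signal shows exactly two
  intracellular local maxima (topographic-prominence peak detection);
  aggregate the frequency of dividing cells
  FDC = Σ(dividing)/Σ(all) and cell concentrations.
* **Dilution experiments** (Landry–Hassett) — regress per-bottle apparent
  growth rates k = ln(N<sub>t</sub>/N<sub>0</sub>)/t on the dilution
  fraction D; the intercept is the grazer-free cell division rate µ, the
  negated slope the grazing rate g.
* **Calibration** — fit FDC ~ µ·taxon (interaction linear model), reshape
  into per-taxon lines FDC = a + bµ, and invert to convert FDC time
  series into division rates.
* **Bloom decomposition** — loess-smooth FDC (span 0.4), compute net
  growth r = ln(N_End/N_Start)/(t_End − t_Start) in a sliding window of
  five timepoints (linear window fit of N on t), and obtain mortality
  from the balance **r = µ − d**.
* **Synthetic data** — seeded generators for micrographs, dilution series
  and bloom trajectories with known ground truth, so the whole pipeline
  is testable without any field data.

Everything is exposed both as R functions (S4 classes `ImagePair`,
`DilutionSeries`, `DilutionResult`, `CalibrationModel`, `RateSeries`) and
through a thin command-line wrapper (`inst/exec/bloomrates` with
subcommands `simulate`, `cytometry`, `dilution`, `calibrate`, `rates`).

## Worked example

```r
library(bloomrates)

# A dilution experiment with known truth (mu = 1.0/d, g = 0.5/d, 10% noise)
fitDilutionSeries(simulateDilutionSeries(mu = 1.0, grazing = 0.5,
                                         noiseCv = 0.1, seed = 42))
#> DilutionResult: mu = 1.049 +/- 0.0462 /d, g = 0.5114 +/- 0.0804 /d (R2 = 0.871, n = 8)
```

The intercept of the dilution regression recovers the division rate
(1.05/d vs the true 1.0/d), the slope the grazing rate (0.51/d vs 0.5/d).

```r
# A synthetic 200-cell micrograph, 12% of cells dividing
sim <- simulateImagePair(nCells = 200, fractionDividing = 0.12, seed = 1)
analyzeImagePair(sim$pair)$sample[, c("nCells", "nDividing", "fdc", "meanVolume")]
#>   nCells nDividing  fdc meanVolume
#> 1    200        24 0.12  0.2854331
```

All 200 cells are found and the 24 cells carrying two DAPI maxima give
FDC = 0.12, exactly the generated dividing fraction; mean biovolume is in
µm³.

```r
# Decompose a noiseless bloom with constant mu = 1/d and d = 0.8/d
tp <- seq(0, 12, by = 0.5)
bl <- simulateBloom(tp, mu = rep(1, length(tp)), d = rep(0.8, length(tp)),
                    noiseCv = 0, fdcSd = 0)
calib <- buildCalibration(fdc = 0.02 + 0.05 * seq(0, 2, 0.5),
                          mu = seq(0, 2, 0.5), taxon = rep("syn", 5))
head(rateTable(runRatePipeline(bl, calib, taxon = "syn"))[,
     c("timepoint", "N", "mu", "r", "d", "flag")], 5)
#>   timepoint        N mu         r         d flag
#> 1       0.0 100000.0  1        NA        NA edge
#> 2       0.5 110517.1  1        NA        NA edge
#> 3       1.0 122140.3  1 0.2018353 0.7981647
#> 4       1.5 134985.9  1 0.2018353 0.7981647
#> 5       2.0 149182.5  1 0.2018353 0.7981647
```

The calibrated division rate is recovered exactly (µ = 1/d), net growth
comes out at 0.202/d against the true 0.2/d (the ~1% excess is the
documented curvature bias of fitting a line to an exponential inside the
window), mortality is µ − r, and window edges are flagged rather than
extrapolated. A classic field observation — an abundance doubling from
1.4 × 10⁵ to 3.0 × 10⁵ cells/mL in 5 days — corresponds to

```r
round(logRatioRate(1.4e5, 3.0e5, 5), 2)
#> [1] 0.15
```

per day of net growth.

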