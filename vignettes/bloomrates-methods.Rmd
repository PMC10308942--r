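---
title: "Growth accounting for bacterioplankton: methods and design notes"
author: "bloomrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth accounting for bacterioplankton: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomrates)
```

## The problem

During phytoplankton spring blooms, heterotrophic bacterioplankton clades
(SAR11, SAR86, *Bacteroidetes*, *Aurantivirga*, ...) can divide several
times per day while their standing stocks barely change: mortality —
mostly protist grazing, partly viral lysis — removes cells nearly as fast
as they are produced. Counting cells over time therefore measures only
*net* growth. This package implements the accounting needed to separate
the gross terms:

* **Cell division rate** $\mu$ (per day) — how fast cells actually divide,
  independent of losses.
* **Net growth rate** $r$ (per day) — the rate of change of abundance,
  $r = \ln(N_\mathrm{End}/N_\mathrm{Start}) / (t_\mathrm{End} -
  t_\mathrm{Start})$.
* **Mortality** $d$ (per day) — defined by the balance $r = \mu - d$.

$\mu$ is estimated two ways: directly, from dilution experiments; and
continuously, from the **frequency of dividing cells** (FDC) read off
micrographs, calibrated against the dilution experiments.

## Image cytometry

Input is a pair of registered 8-bit grayscale micrographs per field of
view: a taxon-specific FISH channel showing cell bodies and a DAPI channel
showing intracellular DNA.

**Segmentation.** The FISH channel is background-subtracted with a median
filter (radius 7 px) and thresholded; the default threshold is Otsu's
method because it is parameter-free, with a fixed-gray-value alternative
in `cytometryConfig()`. Connected components smaller than `minArea`
(default 0.05 µm², i.e. hot pixels) are dropped, and components touching
the image border are excluded from all statistics but tallied — partial
cells bias both volume and FDC.

**Geometry and biovolume.** Cell length and width are the
ellipse-equivalent axis lengths computed from the second moments of the
mask pixel set (with the 1/12 px² finite-pixel correction). This estimator
is robust for both rods and cocci; axis ordering guarantees
length ≥ width. Biovolume uses the capped-cylinder model

$$V = \tfrac{4}{3}\pi r^3 + \pi r^2 l, \qquad r = w/2,\;
l = l_\mathrm{tot} - 2r,$$

which reduces to a sphere when $l_\mathrm{tot} = w$ and differs from more
elaborate shape models by on the order of a percent for typical
bacterioplankton. Total fluorescence is the plain sum of FISH gray values
over the mask — no background re-subtraction, so it is exactly
translation-invariant.

**Dividing-cell classification.** A cell is *dividing* iff its DAPI
signal, Gaussian-smoothed at `smoothingSigma` (default 1 px) and
restricted to the cell mask, shows exactly **two** local maxima; one
maximum marks a non-dividing cell. The maxima detector computes true
topographic prominence by descending flooding with union–find
(persistence): a peak's prominence is its height above the saddle where
its basin meets a higher peak's basin. Peaks with prominence below
`minProminence` (default 0.1) times the in-cell dynamic range are
discarded, and surviving peaks closer than `minSeparation` (default 3 px)
are merged, keeping the higher. Prominence-based filtering is what makes
the two-focus test robust: a noise bump riding on the flank of a genuine
DNA focus has prominence on the order of the noise amplitude and is
rejected, while the second focus of a dividing cell keeps essentially its
full height above the inter-focus saddle. Cells with three or more maxima
are non-dividing by default and tallied separately (`multiMaxima`); a
configuration switch counts them as dividing instead, since the strict
definition is exactly two versus one.

Then, per sample, $\mathrm{FDC} = \sum(\text{dividing cells}) /
\sum(\text{all cells})$, stored as a fraction throughout; conversion to
percent happens only at report boundaries.

## Dilution experiments

Seawater sieved free of mesozooplankton is diluted with sterile-filtered
seawater to fractions $D \in \{1, 0.5, 0.25, 0.1\}$ of unfiltered water
and incubated (24 h = 1 day by default) in duplicate. Encounter rates with
grazers scale with $D$, so the apparent growth rate of each bottle,
$k = \ln(N_t/N_0)/t$, follows

$$k(D) = \mu - g D$$

and an OLS regression of $k$ on $D$ gives the grazer-free division rate
$\mu$ (intercept) and the grazing rate $g$ (negated slope). The fit uses
individual replicate bottles rather than replicate means, preserving
degrees of freedom. Negative fitted $\mu$ is reported as-is with a flag —
it is informative about noise, not an error. Only the linear model is
implemented; saturated-grazing variants are out of scope.

## Calibration: FDC to division rate

FDC and dilution-derived $\mu$ are joined in the interaction regression

$$\mathrm{FDC} \sim \mu * \mathrm{taxon}$$

(main effects plus interaction), fitted by `fitInteractionModel()` — the
same utility serves the other cross-characteristic regressions (volume,
ribosome content, FDC; mortality against grazing). The coefficients are
reshaped into per-taxon lines $\mathrm{FDC} = a + b\mu$ and inverted,

$$\hat\mu = (\mathrm{FDC} - a)/b,$$

to convert FDC time series into division rates. Design choices:

* The regression direction is FDC on $\mu$, then inverted — not $\mu$ on
  FDC. Under noise the two differ; the direction is fixed and documented.
* Taxa with $b \le 0$ stay in the model but are flagged non-invertible and
  refuse prediction.
* Negative predictions (FDC below the taxon intercept) are clamped to 0
  and flagged: division rates are non-negative and field data do reach
  "no cell division".
* Calibration pairs raw experiment-day FDC with the dilution $\mu$ by
  default; pairing with loess-smoothed FDC is possible by passing the
  smoothed series, but the default avoids coupling the calibration to the
  smoother.
* Point predictions carry no uncertainty by default; `se = TRUE` adds a
  delta-method SE from the coefficient covariance (ignoring FDC
  observation error).

## Time-series decomposition

For a bloom time series of abundance $N$ and FDC:

1. FDC is smoothed with loess (locally weighted quadratic regression,
   tricube weights, span 0.4 — the span used for all cellular
   characteristics), clipped to $[0,1]$, and inverted through the
   calibration to give $\mu(t)$.
2. Net growth uses a sliding window of five timepoints (two before, two
   after). Within each window a *linear* regression of $N$ on $t$ is
   fitted and $r = \ln(N_\mathrm{End}/N_\mathrm{Start})/(t_\mathrm{End} -
   t_\mathrm{Start})$ is computed from the fitted values at the window
   ends. Fitting $N$ itself (not $\ln N$) is deliberate: a crashing
   population can drive the fitted line negative, in which case the
   logarithm is undefined and $r$ is missing with flag
   `nonpositive-model` — a fit on $\ln N$ could never produce that
   documented behaviour. The first and last two points are missing with
   flag `edge`; windows use actual dates, so irregular sampling is
   handled, and the estimator is invariant to rescaling $N$ and to time
   shifts.
3. Mortality is $d = \mu - r$, exactly, wherever both terms exist.
   Negative $d$ is reported and flagged, not clamped — it diagnoses noise
   or calibration error.

**A numerical property worth knowing.** The window regression fits a line
to an exponential, so it overestimates $r$ on accelerating series: on an
exact exponential $e^{\rho t}$ the estimator returns
$\ln((a+2b\Delta)/(a-2b\Delta))/(4\Delta)$ with $a, b$ the local LS
coefficients, a relative bias that grows roughly quadratically in
$\rho \times (\text{window span})$ — about 4% at $\rho = 0.2$/day with
daily sampling, about 1% with half-day sampling. The tests pin the
closed-form value of this bias rather than pretending it away, and the
noiseless decomposition checks sample at 0.5-day intervals so the window
bias stays below the asserted tolerances.

## Synthetic data: what it emulates, what it does not

Every stage is testable offline through seeded generators
(`simulateImagePair()`, `simulateDilutionSeries()`, `simulateBloom()`)
whose defaults are the study conditions the estimators are built for:

* **Micrographs** — non-overlapping blurred ellipses (mean length 1.4 µm,
  width 0.5 µm, 0.1 µm/px) on the FISH channel; DAPI foci as Gaussian
  spots, one central for non-dividing cells, two separated by 0.5–0.7 of
  the cell length (uniform draw) for dividing cells — a geometry chosen so
  foci are resolvable at the stated pixel size, since no detection
  geometry is published for the field instrument. Exactly
  `round(nCells * fractionDividing)` cells are dividing. Noise is Poisson
  shot noise plus Gaussian read noise, scaled by one knob and quantized to
  8 bit. Placement is rejection sampling with a bounded retry count
  (default 100 per cell), so dense fields fail fast with an explicit
  placement error instead of looping forever.
* **Dilution series** — exact Landry–Hassett kinetics
  $N_t = D N_0 e^{(\mu - gD)t}$ with median-one lognormal counting noise
  (log-symmetric; the log of the noise has mean zero, so the regression
  estimators are unbiased by construction, which is what multiplicative
  counting error should mean here).
* **Blooms** — the latent abundance integrates $dN/dt = (\mu(t) -
  d(t))N$ with classical Runge–Kutta on a ≤ 0.05-day grid ($\mu$, $d$
  linearly interpolated); dynamics are deterministic, only observation is
  noisy (lognormal on $N$, Gaussian with SD 0.01 on FDC — the binomial
  counting error of an FDC near 6% scored over a few hundred cells).

Not emulated: realistic optics (point-spread functions beyond Gaussian
blur), z-stacks, autofluorescence, touching or overlapping cells, uneven
illumination, or taxon mixtures within one image. Passing the synthetic
suite therefore demonstrates that the estimators are correct and
well-behaved under their stated models — not that segmentation or focus
counting is robust to every pathology of real micrographs. In particular,
touching cells are a documented limitation (no watershed splitting), and
amplified FISH signals that overshoot true cell boundaries inflate volume
estimates; no correction factor is applied.

## Problem sizes and numerical choices

The test and acceptance workloads use: 500-cell images across 50 seeds for
FDC recovery (the estimate is compared with the exact binomial 95%
interval for the true dividing fraction), 1000 seeded dilution experiments
for bias, a 31-point bloom pulse (peak $\mu$ 1.9/day, $d = 0.9\mu$,
CV 0.1) for decomposition RMSE, and a 25-point half-day-sampled noiseless
bloom for the window-bias check. The noise-matched baseline for pulse
recovery is the closed-form RMSE of inverting raw FDC point by point,
$\sigma_\mathrm{FDC}/b = 0.2$/day; the smoothed pipeline must beat it.

Degenerate inputs are handled explicitly rather than silently: empty
images give empty cell tables and an undefined (missing) FDC with
$n = 0$; flat DAPI signal has zero maxima (with a numerical tolerance for
smoothing round-off); duplicate timepoints inside a regression window are
an error; a dilution design with a single distinct dilution level is
rejected as rank-deficient; loess requires at least five points.

## Worked example

```{r example}
# dilution experiment, known truth (mu = 1.0, g = 0.5), no noise
fit <- fitDilutionSeries(simulateDilutionSeries(mu = 1.0, grazing = 0.5,
                                                noiseCv = 0))
fit

# a synthetic field of 200 cells, 12% dividing
sim <- simulateImagePair(nCells = 200, fractionDividing = 0.12, seed = 1)
res <- analyzeImagePair(sim$pair)
res$sample[, c("nCells", "nDividing", "fdc", "meanVolume")]

# decompose a noiseless constant-rate bloom (mu = 1, d = 0.8)
tp <- seq(0, 12, by = 0.5)
bl <- simulateBloom(tp, mu = rep(1, length(tp)), d = rep(0.8, length(tp)),
                    noiseCv = 0, fdcSd = 0)
calib <- buildCalibration(fdc = 0.02 + 0.05 * seq(0, 2, 0.5),
                          mu = seq(0, 2, 0.5), taxon = rep("syn", 5))
head(rateTable(runRatePipeline(bl, calib, taxon = "syn")), 8)
```

## Known limitations

* No watershed splitting: touching cells merge into one object.
* The calibration inversion assumes the FDC–$\mu$ relation is linear and
  stable over the period it is applied to; applying a calibration from one
  season to another is not supported by the model and should be treated as
  relative activity only.
* Mortality inherits the biases of both $\mu$ (calibration) and $r$
  (window curvature, edge loss), since it is defined as their difference.
* The dilution design assumes grazing scales linearly with dilution and
  does not partition viral lysis from grazing.
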