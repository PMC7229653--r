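# mechq

Quantification of cellular contractility, nuclear dynamics, and morphometry
from fluorescence microscopy, in R.

Fibroblast-mechanics studies read out a cell state through a family of
image-derived quantities: the traction stresses cells exert on a compliant
matrix, the speed at which chromatin reorganizes inside the nucleus, DNA-damage
foci per nucleus, marker intensities, sprout outgrowth from embedded
spheroids, and the contraction of cell-laden collagen gels. `mechq`
implements that full quantification layer as a single tested package, together
with seed-reproducible synthetic-data generators that provide ground truth for
every stage — so each measurement can be validated end to end without any
experimental data.

## What it computes

**Traction force microscopy (FTTC).** Fiducial beads are localized to
sub-pixel precision, matched between a stressed and a relaxed image by optimal
assignment (particle-tracking velocimetry), cleaned with the normalized-median
outlier test, and gridded. Tractions follow from Tikhonov-regularized
inversion of the Boussinesq half-space relation in the frequency domain,

    u^(k) = G(k) T^(k),
    G(k) = 2(1+nu) / (E k^3) * [ (1-nu)k^2 + nu ky^2,  -nu kx ky
                                 -nu kx ky,  (1-nu)k^2 + nu kx^2 ],
    T^ = (G'G + lambda^2 I)^(-1) G' u^ ,

with strain energy `U = 1/2 * sum(T . u) dA` reported in picojoules.

**Nuclear dynamics.** Per-nucleus Pearson correlation of pixel-intensity lists
at increasing time lags gives a decorrelation curve, fitted by bounded
nonlinear least squares with the three-parameter decay model

    y(t) = (1 - alpha) + alpha * exp(-t / tau) - eta,

where `alpha` is the drop rate (how much correlation is ultimately lost),
`tau` the time constant in minutes, and `eta` a lag-independent noise offset.

**Morphometry.** Otsu + watershed nucleus segmentation;
Laplacian-of-Gaussian focus counting per nucleus; region mean/total/
total-per-volume intensities; EdU-positive fractions; skeleton-based average
sprout length of spheroids; collagen-gel contraction series; cell area and
aspect ratio.

**Statistics.** Pooled-variance two-sided t tests, Bonferroni adjustment,
delta-delta-Ct fold changes, and box-plot summaries (quartiles with 1.5 IQR
whiskers).

## Worked example

Recover a known traction field from its own forward-modelled displacements,
then fit nuclear dynamics on simulated nuclei:

```r
library(mechq)

substrate <- ElasticSubstrate(youngModulusPa = 1000, poissonRatio = 0.45)
truth <- tractionDipoleTruth(c(64, 64), spacingUm = 4, substrate,
                             magnitudePa = 100, separationUm = 40,
                             patchSigmaUm = 8)
field <- forwardDisplacement(truth)
result <- invertFTTC(field, substrate, lambda = 1e-9)
result
#> TractionResult: 64 x 64 grid, spacing 4 um
#>   max |T| = 93.96 Pa, strain energy 0.04535 pJ, lambda 1e-09

curves <- lapply(1:200, function(i) {
  sim <- simulateNucleusSeries(alpha = 0.4, tauMin = 8, noiseSd = 0.1,
                               nFrames = 33, seed = i)
  computePCCCurve(nucleusPixelSeries(sim$series, sim$mask), 31)
})
fitDecorrelation(meanPCCCurve(curves)$curve)
#> DecorrelationFit: alpha = 0.3968, tau = 8.155 min, eta = 0.0114
#>   rss = 6.207e-06, converged = TRUE
```

The recovered peak traction and strain energy match the constructed dipole
(100 Pa patches) to within the inversion's ~4% field-of-view truncation
error, and the fitted drop rate and time constant land on the generating
values (`alpha = 0.4`, `tau = 8 min`) within Monte-Carlo noise.

A full synthetic run of every stage, with a checksummed output manifest:

```r
runPipeline(list(seed = 1), "out/")
```

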