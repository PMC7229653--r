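---
title: "Models and methods behind mechq"
author: "mechq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechq)
```

`mechq` quantifies the image-derived read-outs used to compare fibroblast
states: traction stresses and strain energy from bead-displacement
microscopy, the decay of nuclear image correlation over time, and a set of
segmentation-based morphometric measures. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical choices — and
what the synthetic-data tests do and do not establish about real data.

## Traction force microscopy

### Model and assumptions

The substrate is treated as a homogeneous, isotropic, linear-elastic
half-space with Young's modulus $E$ (Pa) and Poisson ratio $\nu < 0.5$,
deformed only by tangential surface tractions. Under these assumptions the
surface displacement is the convolution of the traction field with the
Boussinesq point response; in Fourier space, per wavevector $k$,

$$\hat u(k) = \hat G(k)\,\hat T(k), \qquad
\hat G(k) = \frac{2(1+\nu)}{E k^3}
\begin{pmatrix}(1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y\\
-\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2\end{pmatrix}.$$

`forwardDisplacement()` evaluates this product on a zero-padded grid (padding
factor 4 by default) so that the periodic images inherent to the discrete
transform do not contaminate the field of view. `invertFTTC()` solves the
inverse problem with Tikhonov regularization, per wavevector
$\hat T = (\hat G^\top\hat G + \lambda^2 I)^{-1}\hat G^\top \hat u$, sets the
zero-frequency traction to zero (a half-space cannot carry net force), and
reports the strain energy $U = \tfrac12\sum T\cdot u\,\Delta A$ in picojoules
(1 Pa µm³ = 1e−18 J = 1e−6 pJ).

These assumptions are deliberate simplifications for collagen: fibrous gels
are nonlinear and fibre remodeling makes the medium locally anisotropic. The
package applies the planar linear inversion to per-plane displacement data
and makes no claim of volumetric force reconstruction; a fibrous-matrix
finite-element inversion is out of scope.

### Numerical choices

* **Edge treatment.** The measured displacement field is truncated at the
  field of view, and a hard zero-padded edge injects broadband ringing into
  the inverted tractions (the inversion itself is exact: on periodic
  noiseless data the round trip reproduces tractions to machine precision).
  The displacement grids are therefore mean-subtracted, tapered with a Tukey
  window over the outer 10% of each edge (`taperFraction`), and zero-padded
  to twice their size. On 64×64 noiseless round trips this reduces the
  relative $L_2$ traction error from ~8% to ~3–4%, concentrated at the field
  border; the interior error is below 1%.
* **Regularization.** The data carry no preferred $\lambda$, so the default
  follows a parameter-free heuristic, $\lambda^2 = 10^{-3}\times$ the mean
  diagonal of $\hat G^\top\hat G$, and is overridable everywhere. Total
  recovered traction magnitude is non-increasing in $\lambda$ (tested).
* **Energy.** The quadrature uses the measured (untapered) displacements and
  the recovered tractions, restricted to valid grid nodes.

### The measurement chain

`detectBeads()` finds local maxima above an intensity percentile and refines
them by intensity-weighted centroids in a window of about twice the bead
diameter (sub-pixel accuracy ~0.1 px on synthetic spots; duplicates within
one radius are suppressed, brighter wins). `linkBeads()` solves the optimal
assignment (Hungarian method) minimizing total squared displacement among
pairs within `maxDisplacementUm`; leaving a bead unmatched costs
`maxDisplacementUm^2`, so admissible matches are always preferred and
inadmissible ones never made. `filterOutliers()` applies the normalized
median test against the k nearest neighbours (default k = 8, threshold 2,
floor 0.05 µm — the floor prevents 0/0 on noise-free fields).
`interpolateField()` grids the vectors by linear interpolation on the
Delaunay triangulation; nodes outside the convex hull are filled by nearest
neighbour and flagged invalid, and they are excluded from the energy sum.

### Validation against an independent oracle

The forward model is cross-checked against `boussinesqDirect()`, a real-space
quadrature that integrates the Boussinesq kernel analytically over each grid
cell (the mixed antiderivatives of $1/r$, $x^2/r^3$, $y^2/r^3$, $xy/r^3$ are
closed-form), so the quadrature has no singularity error. The two routes
agree within 2% (relative $L_2$ at grid nodes) on random balanced fields;
this is the package's guard against kernel or FFT-convention mistakes.

## Nuclear decorrelation dynamics

For each nucleus, the pixel intensities inside a fixed mask are listed in
raster order per frame; the Pearson correlation between the lists at frames
$t$ and $t+L$ is averaged over **all** such pairs to give the curve value at
lag $L$ (using one pair per lag is the main alternative; averaging all pairs
uses the full recording and reduces the variance of the curve). The
condition-level mean curve is fitted with

$$y(t) = (1-\alpha) + \alpha e^{-t/\tau} - \eta,$$

by bounded nonlinear least squares ($\alpha\in[0,1]$, $\tau\in(0,10\,t_{max}]$,
$\eta\in[0, 0.5]$), multi-started from a moment-based initialization
($\alpha_0 = 1-\min y$, $\tau_0 = t_{max}/3$, $\eta_0 = \max(0, 1-y(t_1))$)
plus three perturbed variants, keeping the best residual. A flat curve leaves
$\tau$ unidentifiable; the fit then reports $\alpha\approx 0$ with
`converged = FALSE`. Per-cell fits remain available for dispersion analysis.

Whole-nucleus translation would register as decorrelation, so each frame is
first rigidly registered to frame 1 by integer-pixel cross-correlation
(`register = TRUE` default); an edge-gradient diagnostic flags masks whose
boundary intensity step is large, where residual sub-pixel motion still
biases the statistic.

The generator (`simulateNucleusSeries()`) writes per-pixel intensities
$I_t = B + S + D_t + \varepsilon_t$ with a static texture $S$ of variance
$1-\alpha$, an AR(1) process $D_t$ of variance $\alpha$ and autocorrelation
$e^{-k\Delta t/\tau}$, and white noise of SD `noiseSd`. AR(1) is the natural
generative family here because its autocorrelation is exactly exponential —
the fitted model is then the correct model, and recovery failures indicate
estimation problems rather than model mismatch. The analytic expectation is
$\mathrm{PCC}(L) = [(1-\alpha) + \alpha e^{-L\Delta t/\tau}]/(1+\sigma_n^2)$:
a lag-independent rescaling that the fitted $\eta$ absorbs. Default study
conditions follow one-minute frame intervals with about thirty frames per
nucleus, and condition-level fits use hundreds of cells.

## Morphometry

* **Nucleus segmentation**: Otsu threshold, hole filling,
  distance-transform watershed to split touching nuclei, minimum-area filter.
* **Focus counting**: scale-normalized Laplacian-of-Gaussian at
  `spotSigmaUm`, local maxima with prominence at least `prominenceFactor`
  (default 8) times the in-nucleus MAD of the response. The detector is
  background-subtracted by construction (the kernel is zero-sum), so constant
  intensity offsets change nothing. Two foci closer than roughly the filter
  width merge into one detection — a resolution limit, not a bug; the
  synthetic packing therefore enforces a minimum separation of about
  3 spot sigmas, and under that condition counts are exact.
* **Sprout length**: threshold, keep the largest component (spheroid plus
  sprouts), remove the core by a morphological opening at
  `coreRemovalRadiusUm`, skeletonize the rest (Zhang–Suen), and root every
  skeleton component at its pixel nearest the core. A sprout is the path
  from a skeleton endpoint to the root; its length is measured on the path
  resampled every 5 pixels — summing unit/√2 pixel steps overestimates
  oblique straight lines by up to 8% (chamfer bias), which the resampled
  polyline avoids — plus the root-to-core gap and half the estimated sprout
  width (thinning retracts each tip by about half the width). Paths shorter
  than `minSproutLengthUm` (default 10 µm) are opening debris and are
  dropped. On synthetic spheroids with eight 40–120 µm sprouts the average
  length is recovered within ~1%.
* **Gel contraction**: per frame, threshold, largest component, hole fill,
  pixel count; areas are normalized to frame 1. Pixelation limits accuracy to
  ~0.5% of the disk area at radius 100 px.
* **EdU positivity**: per-nucleus mean intensities split by a 1D Otsu rule by
  default (needs at least two nuclei and a genuinely bimodal field) or a
  fixed threshold.
* **Cell shape**: aspect ratio from the square root of the second-moment
  eigenvalue ratio of the mask.

## Statistics

`tTestTwoSided()` is the classic pooled-variance Student test (the Welch
variant is available via `varEqual = FALSE`); zero-variance inputs with equal
means return p = 1, with unequal means they are an error rather than a
fabricated p-value. `bonferroniAdjust()` multiplies by the number of tests
and caps at 1. `deltaDeltaCt()` assumes perfect amplification efficiency (one
Ct unit per two-fold); fold changes are invariant to plate-wide Ct shifts.
`boxSummary()` uses linear interpolation between order statistics for the
quartiles (R type 7) and 1.5 IQR whiskers; the quantile convention is stated
because different conventions move the quartiles of small samples.
Significance stars map `* < 0.05`, `** < 0.01`, `*** < 0.001`.

## What the synthetic tests establish — and what they do not

The generators emulate the geometry and noise structure the measurements
rely on: Gaussian bead/focus spots with sub-pixel centres, additive Gaussian
noise (a simplification of photon statistics adequate for recovery tests),
exact exponential decorrelation, ideal disks and thin sprouts, perfect qPCR
efficiency. Passing tests therefore establish correctness of the
computations — kernels, assignments, fits, quadratures, conversions — under
the stated models. They do not establish robustness to what real data add:
nonlinear fibrous mechanics, bead detachment and focus drift, chromatin
motion beyond rigid translation, irregular gel silhouettes, or qPCR
efficiency below 100%. Parameters exposed for those situations
(`lambda`, `prominenceFactor`, `threshold` overrides, `register`) are the
knobs a user should revisit on experimental images.

Problem sizes in the test-suite and in `scripts/acceptance.R` (64×64 traction
grids, 200 nuclei per decorrelation condition, 200 nuclei for focus counting,
50 spheroids) were chosen so that Monte-Carlo error sits well below the
tolerances being checked while the whole suite runs in minutes on one CPU.

## Known limitations

* Planar, linear-elastic FTTC only; the `lambda` default is a heuristic, not
  an L-curve optimum.
* Traction accuracy is limited by field-of-view truncation (~3–4% relative
  $L_2$ on noiseless 64×64 round trips, concentrated at the border).
* Focus counting undercounts pairs closer than the filter resolution.
* The sprout definition (endpoint-to-core path length) matches the intent of
  "average vessel length" but is not bit-compatible with any specific
  external tool.
* The decorrelation statistic assumes a mask valid across the recording;
  strongly motile nuclei need tracking, which is out of scope.
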