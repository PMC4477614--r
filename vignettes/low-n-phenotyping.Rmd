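---
title: "Aerial low-nitrogen phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aerial low-nitrogen phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeropheno)
```

## The problem

Screening maize hybrids for low-nitrogen tolerance requires measuring canopy
state over hundreds of small two-row plots. Low-altitude multispectral
imagery (green/red/NIR, ~60 mm ground sampling distance) can do this in a
single flight, but turning raw frames into per-plot phenotypes involves a
chain of steps — demosaicing, radiometric calibration, mosaicking, row
extraction, index computation — each of which can silently distort the
numbers. aeropheno implements that chain end to end and, because flight
campaigns cannot be re-flown at will, pairs it with a synthetic field
generator that renders imagery with known ground truth so every stage can be
validated quantitatively.

## Indices

All plot phenotypes derive from four quantities:

* **NDVI** $= (R_{NIR} - R_{red})/(R_{NIR} + R_{red})$, computed from the
  camera's broadband red and NIR reflectances (surrogates for the 670 and
  800 nm narrowbands). Per-plot NDVI is the index of the mean vegetation
  reflectances, not the mean of per-pixel NDVI; with vegetation-only masks
  the two agree closely, and the ratio-of-means form is the one that
  commutes with the round-trip checks below.
* **Nitrogen stress index (NSI)** $= 1 - \mathrm{NDVI}_i /
  \mathrm{NDVI}_m$, where $\mathrm{NDVI}_m$ is the mean NDVI of the plots at
  the highest N rate (160 kg/ha by default). It is 0 for an unstressed plot
  and grows with stress. The reference is pooled over hybrids by default —
  a per-hybrid mode exists, but pooling is what makes NSI comparable across
  genotypes as a tolerance score.
* **Green fractions.** A pixel of a plot-level RGB photograph is *green*
  when its hexagonal hue lies in [60°, 180°] (GF) and *greener* when in
  [80°, 180°] (GGF); [60°, 80°) captures the yellowish hues of senescing
  leaves. Both bounds are inclusive (the ranges are written as closed
  intervals), and achromatic pixels — which have no defined hue — are
  excluded from numerator and denominator alike.
* **Crop senescence index (CSI)** $= 100\,(\mathrm{GF} -
  \mathrm{GGF})/\mathrm{GF}$: the share of the green-range canopy that is
  yellowish. When GF = 0 there is no canopy to attribute senescence to, so
  CSI is undefined (flagged `NA`), not 0 or 100.

## Imaging model

**Demosaicing.** The camera records a single sensor plane behind a 2×2
color-filter tiling (green on the diagonal, red and NIR once each — the
Bayer layout with blue replaced by NIR). Bands are reconstructed by bilinear
interpolation from each band's native sensels, with reflection padding at
the frame edge. Bilinear was chosen over edge-aware schemes deliberately: it
is deterministic, exact for affine signals (which makes it oracle-testable),
and adequate at 60 mm GSD where a crop row is several pixels wide. The
tiling is a shared constant between the renderer and the demosaicer and is
configurable.

**Calibration.** Digital numbers become reflectance through a per-band
empirical line, `reflectance = (DN − offset) × gain`. Gains can be fixed or
estimated from a reference panel of known reflectance (through-origin line
by default, optional dark offset). Calibrated values are clipped to
[0, 1.5] — tolerating modest overshoot — and the clipped-pixel count is
reported rather than silently discarded.

**Mosaicking.** Frames are placed by their absolute positions only; where
frames overlap, each output pixel takes the value of the frame whose center
is nearest (hard nearest-center assignment). Feathered blending would look
better but averages radiometry across frames; hard assignment preserves
pixel values for index arithmetic and is exactly testable against a
brute-force nearest-center oracle.

**Grid conventions.** Rasters are north-up with square pixels; pixel (1,1)
is top-left and owns the half-open square under the pixel-area convention; a
pixel belongs to an ROI when its *center* is inside the polygon. World
coordinates are meters on a local planar frame.

## Row extraction

Each plot's rows are known from the layout, so regions of interest are
derived rather than digitized: the row centerline is buffered into a narrow
rectangle (default half-width 0.15 m) and inset at both row ends. The inset
and the narrow buffer keep the ROI in the center of the row, away from
crown-edge pixels that bilinear demosaicing necessarily mixes with soil —
at 60 mm GSD the blur zone is about one pixel, and the defaults leave one
clear pixel inside a 0.5 m crown. The vegetation cutoff that removes any
remaining soil is estimated per row by Otsu's method, applied to the NDVI
histogram of a *wider* strip (half the row spacing each side), which always
contains both soil and that row's canopy. Estimating it inside the narrow
ROI itself would be wrong in an instructive way: a pure-canopy sample has no
soil mode, and Otsu would then split the canopy's own variation and bias the
means upward. Per-row estimation matters because a vigorous plot at 160
kg/ha and a stunted one at 0 kg/ha need different cutoffs; a fixed numeric
threshold (default 0.3) remains available.

Row summaries aggregate to plots by pixel-count weighting, which is
identical to pooling all the plot's vegetation pixels.

## Field variability

Whole-field NDVI is summarized by mean, min, max, sample (n−1) SD and
CV = 100·SD/mean, over vegetation-masked pixels by default (an all-pixels
mode exists; with soil included, the soil/canopy contrast dominates the CV
and masks genuine field heterogeneity). A moving-window CV map (default
15 px ≈ 0.9 m) localizes the variability, and zones whose local CV exceeds
a threshold are polygonized (8-connected components) so that highly variable
areas can be excluded from future trial layouts.

## Nitrogen-response analysis

The senescence response to N is fitted as a continuous two-segment
("broken-stick") least-squares line. For each candidate breakpoint the
segments are solved in closed form as the linear model
$y \sim x + \max(x - c, 0)$; the breakpoint grid is the interior observed N
rates, which is where a designed trial can actually resolve a breakpoint
(a continuous search between design points would interpolate noise; a
fixed-breakpoint mode is available). Ties are broken toward the smaller
breakpoint. Fewer than four distinct rates cannot support two segments and
fall back to a single line, flagged. Alongside the raw slopes
(index units per kg/ha) the fit reports each segment's drop as a percent of
the fitted range, the form in which segment steepness is usually quoted.

Associations (NDVI–yield, NSI–yield, CSI–yield) use Pearson correlation with
a t-based two-sided p-value (n−2 df) and a Fisher-z 95% CI, computed within
user-specified N-rate strata (e.g. {0, 10} vs {80, 160}) with pairwise
deletion. No multiple-testing correction is applied by default, matching
standard practice for these small correlation tables; Benjamini–Hochberg can
be applied by the user on the returned p-values. Hybrids are ranked for
tolerance by ascending mean NSI over the low rates {0, 10, 20}.

## The synthetic field

The generator emulates the trial the pipeline targets: 10 hybrids (5
tolerant, 5 sensitive) × 6 ammonium-nitrate rates {0, 10, 20, 40, 80, 160}
kg/ha × 3 replicate blocks, in a split-plot layout (hybrids randomized to
main plots within blocks, rates to subplots), two 4 m rows per plot 0.75 m
apart; imagery at 60 mm GSD in 2048 × 1536 frames on a serpentine track with
30% overlap.

The response model is where the generator's assumptions live:

* **NDVI** saturates with N: $\mathrm{NDVI}(n) = a_c\,(n + n_0)/(n + n_0 +
  K)$ with class asymptote $a_c$ (tolerant 0.88, sensitive 0.72), half
  saturation $K = 30$ kg/ha and a residual soil-N offset $n_0 = 15$ kg/ha so
  unfertilized plots still carry a canopy. The saturating form is an
  assumption — the data the pipeline emulates constrain direction
  (non-decreasing, tolerant ≥ sensitive), not shape.
* **Senescence** declines with N as a broken stick: 60% at 0 N, slope −0.5
  %/kg up to the 40 kg/ha breakpoint and −0.05 %/kg beyond. GF tracks NDVI
  (0.35 + 0.5·NDVI) and GGF is derived as GF·(1 − CSI/100), so the fraction
  invariants hold by construction.
* **Yield** is linear in true NDVI (1 + 12·NDVI t/ha, spanning roughly 4–10
  t/ha) with noise that grows with N rate (SD 0.3 + 0.006·n t/ha): at high
  N the canopy saturates and other yield-limiting factors dominate, which is
  exactly why canopy–yield correlations are tighter under low N. This is
  the mechanism the stratified-correlation check exercises.
* **Spatial heterogeneity** is a smooth multiplicative random field (default
  patch scale 8 m, relative amplitude 0.08) applied to canopy vigor and soil
  brightness, emulating management-history patchiness. In the
  field-characterization simulations (a uniformly cropped field, two
  amplitudes) the patch scale is set to 2 m so that a small demo field
  integrates many patches — with 8 m patches a ~10 m field samples barely
  two, and a single realization's CV is dominated by patch sampling noise
  rather than the amplitude being varied.
* **Reflectance.** Canopy green and NIR reflectances are fixed (0.12, 0.50)
  and red is solved from the NDVI identity — only NDVI is constrained, so
  the remaining degrees of freedom are pinned. Soil is (0.15, 0.20, 0.25),
  i.e. soil NDVI ≈ 0.11, comfortably below any canopy. Frames store 16-bit
  DN at a known gain (5·10⁻⁵ reflectance/DN), so the fixed calibration model
  inverts the sensor exactly.
* **RGB plot photographs** invert the hue classifier: pixels are assigned
  hues in (82°, 178°) (green), (62°, 78°) (yellowish-green) and (25°, 55°)
  (soil/straw, chromatic so every pixel classifies) in the exact counts
  implied by the requested GF/GGF, then shuffled spatially. Measured
  fractions therefore equal the requested ones up to one-pixel rounding.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data — includes radiative transfer, BRDF and
shadowing, perspective and lens distortion (frames are nadir-orthographic),
registration error in frame positions, weeds, within-plot plant-to-plant
variation, and senescence gradients along leaves. The generator validates
the *pipeline arithmetic*, not the spectroscopy.

## Numerical choices and degenerate inputs

* Randomness is seed-controlled everywhere; the pipeline derives a named
  substream per stage from one root seed, so reruns are bit-identical.
* NDVI is `NA` when both bands are zero; NSI refuses a non-positive
  reference; CSI is `NA` at GF = 0; achromatic pixels have no hue.
* Plots whose ROIs contain no vegetation pixel are flagged and keep their
  rows with `NA` values — rows are never dropped.
* Moving-window statistics clip the window at raster borders (valid-subset
  semantics) and exclude nodata; windows with fewer than two valid pixels
  are nodata.
* Rasters travel as TIFF with an ESRI world file and a JSON sidecar for band
  names, nodata and value scaling (float TIFFs are stored scaled into the
  unit interval).
* Otsu's threshold is computed on a 256-bin histogram; constant input
  degenerates to the median.

## Problem sizes used in validation

The validation suite renders the full 180-plot trial at native 60 mm GSD
(one ~123 × 92 m frame covers the demo field) for the end-to-end recovery
check, and smaller 24-plot scenes for per-stage tests. Breakpoint recovery
uses 200 replicates at 5%-of-range noise; correlation-CI coverage uses 500
replicates at n = 180. These sizes were chosen to make the Monte-Carlo
assertions stable across seeds while keeping the whole suite fast enough to
run routinely.

## A worked run

```{r, eval = FALSE}
cfg <- validate_config(list(seed = 1,
                            paths = list(out_dir = tempfile("aeropheno_"))))
man <- run_pipeline(cfg)
read.csv(file.path(cfg$paths$out_dir, "broken_stick.csv"))
```

The run directory then contains the layout and truth tables, the CFA
frames, the calibrated mosaic, the ROI GeoJSON, the per-plot index table,
field-variability outputs and the analysis CSVs, plus `manifest.json`
recording parameters, seeds, warnings and artifact checksums.

## Known limitations

* The mosaicker assumes frames on a common grid orientation (north-up) and
  a shared GSD; rotated or multi-resolution inputs would need resampling,
  which is out of scope.
* The broken-stick breakpoint is only identified at design rates; with
  noisy data and few replicates adjacent candidates can tie in RSS, and the
  smaller breakpoint is reported by convention.
* Per-row Otsu assumes the estimation strip is bimodal (soil + canopy); a
  fully closed canopy across the inter-row space would violate it. At the
  emulated row spacing and crown widths this does not occur.
* NSI depends on the reference-rate plots actually being near-unstressed;
  in a trial where even 160 kg/ha is limiting, NSI compresses and ranking
  resolution degrades.
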