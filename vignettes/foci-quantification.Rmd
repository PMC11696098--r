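---
title: "Quantifying fluorescent foci, colocalization and per-cell statistics"
author: "fociQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescent foci, colocalization and per-cell statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociQuant)
```

# The measurement problem

Stimuli such as STING agonists drive a subpopulation of cells to collect
LC3B-positive vesicles into bright perinuclear foci, and co-staining asks
whether markers — ubiquitin chains, the LUBAC ligase HOIP, STING itself —
are enriched at those foci. Three numbers summarize such an experiment:
the percentage of cells carrying foci, the percentage of foci positive
for each marker, and the per-cell pixel correlation between two channels,
each aggregated from fields of view up to the wells of a multi-well
plate. fociQuant implements that analysis ladder as composable,
provenance-recording steps, and ships a synthetic scene generator whose
known ground truth lets every step be validated by parameter recovery
rather than by eye.

# Models and procedures

## Background subtraction

`subtractBackground()` estimates the smooth background of a plane as a
wide Gaussian blur of the plane itself and subtracts it, clipping at
zero. All smoothing in the package replicates edge pixels, so a constant
plane maps exactly to zero. The scale `bgSigmaPx` (default 100 px) must
sit far above the cell scale: at only ~2 cell radii the background
estimate absorbs a locally varying share of cell mass, dimming cells in
crowded neighborhoods by tens of ADU and destabilizing every threshold
downstream — measurably so in the recovery tests, which is why the
default is several cell diameters.

## Cell segmentation

`segmentCells()` follows a fixed pipeline: blur the (background
subtracted) cytosolic channel at `blurSigmaPx`; threshold the blurred
plane (Otsu by default); watershed the blurred intensity landscape
seeded at its regional maxima inside the mask; impose the watershed
separating lines on the mask as background; label 4-connected
components; apply an area gate; optionally drop border-touching cells;
renumber labels in raster order of the centroids.

Parameter defaults were chosen by measured count recovery on the
generator's study conditions (about 15 cells of radius 18 ± 2 px per
256 × 256 field):

* `blurSigmaPx = 5` (~ a quarter cell radius). Larger blurs make the
  blurred domes of small cells fall close to the Otsu split, which then
  clips them below the area gate.
* regional maxima within `2 * blurSigmaPx` of each other are treated as
  one seed, and maxima shallower than `watershedTolFrac = 0.25` of the
  maximum foreground intensity are merged: foci-scale texture inside a
  cell otherwise double-seeds it.
* `minCellAreaPx = 100` keeps cells down to ~3 SD below the mean radius
  (their thresholded masks cover only part of the true disk) while
  rejecting sub-cellular fragments.
* Watershed lines are marked where a pixel's E/S/SE/SW neighbor carries
  a different watershed label. With 4-connected component labeling this
  1-px line is guaranteed to separate regions; the connectivity is
  recorded in the map's provenance.
* Border cells are excluded by default — truncated cells bias per-cell
  statistics.

Across three disjoint 50-field blocks at the study conditions, the
segmented cell count equals the generated count in 49–50 of 50 fields.

## Foci detection

`equalizeLocal()` divides the plane by a Gaussian blur of itself
(regularized by `1e-6` of the mean positive intensity), producing a
ratio image that is ~1 where the plane is locally flat and > 1 on
structures brighter than their neighborhood; it is invariant under
positive rescaling of the input. `detectFoci()` intersects two
conditions — raw intensity at or above `rawThreshold` and equalized
ratio at or above `eqThreshold = 1.5` — and filters the 4-connected
components by area (5–400 px) and optionally by circularity.

Two default choices deserve justification:

* **`rawThreshold = "otsu-foreground"`.** On a background-dominated
  field, plain Otsu separates background from cells and lands *below*
  the cytosolic level; the dual-intensity mask then admits whole cells
  and cell-edge rims, overwhelming the true foci. The default therefore
  re-runs Otsu on the pixels above the plain split, so the cut falls
  between cytosol and punctae. Plain `"otsu"` and explicit values remain
  available, and both Otsu variants are scale-equivariant.
* **Plate-level thresholding.** A per-field adaptive threshold has no
  punctate class to find on fields with few or no foci (negative
  controls!) and collapses into the cytosol. `plateRawThreshold()` pools
  pixels across all fields of a plate/condition and computes one
  threshold; `runPipeline()` does this by default (`thresholdScope:
  "plate"`). A plate consisting *only* of foci-free wells still has no
  punctate class anywhere — in that situation no adaptive method can
  work and an explicit threshold should be supplied.

Circularity is `4πA/P²` with the perimeter estimated by the 4-direction
Crofton (integral-geometry) estimator computed from 2 × 2 pixel
configurations. Among standard estimators it is the only one we found
that treats both regimes acceptably: digitized disks of radius ≥ 8 px
score 0.90–0.96 while a 1-px-wide line scores ~0.10; border-pixel
weighted estimators inflate thin lines (both sides of the boundary run
through the same pixels), and raw crack or chain-code lengths bias disks
badly. Discretization still inflates very small objects (a 2 × 2 square
scores 1.2), which the 5-px minimum focus area keeps out of the tables.
The circularity filter is off by default and intended for occasional use
against elongated debris.

Foci touching the image border stay in the foci *mask* (their pixels
count toward per-cell tallies) but receive no table row: their dilation
rings would be truncated. Per-focus cell assignment is by centroid
containment; per-cell *positivity* is instead driven by pixel counts, so
a focus straddling two cells contributes its pixels to each.

## Cell positivity

`callCellsFociPositive()` counts foci-mask pixels per cell and calls a
cell positive when the count is **strictly greater** than
`minFociPixelsPerCell` (default 10 px — a documented choice, roughly
half of one typical focus). A count exactly at the cutoff is negative.
With zero cells the summary fraction is `NA` with a `noCells` flag,
never 0.

## Donut-ratio colocalization

For each table focus, `donutRatio()` dilates the focus pixel set with a
disk (default radius 2 px), removes the union of **all** foci pixels and
out-of-image pixels, and scores
`ratio = mean(marker over focus) / mean(marker over ring)`. A focus is
marker-positive iff the ratio strictly exceeds 1.75. The ratio is
invariant under multiplicative rescaling of the marker but not under
additive offsets — the marker plane must be background subtracted
upstream. Rings that are empty or have zero mean make the ratio
undefined: flagged `NA`, scored negative, excluded from positivity
denominators, counted and reported.

## Per-cell Pearson and plate aggregation

`pearsonPerCell()` computes, per cell,
`r = Σ(a−ā)(b−b̄) / sqrt(Σ(a−ā)² Σ(b−b̄)²)` over the cell's pixels; cells
with fewer than two pixels or zero variance in either channel are
flagged undefined and never coerced to 0. `aggregatePlate()` takes the
median of defined values per image, the median (default) of per-image
medians per well, and mean ± sd (n − 1) across wells within a condition.
The within-well statistic is switchable to the mean (`aggregation:
mean`): the underlying protocol wording is ambiguous between a
median-of-medians and a restatement of the per-image median, so both
readings are provided rather than guessed; the median is the default for
robustness. Whether the correlation should use whole-cell pixels or a
cytoplasmic subregion is equally unspecified; whole-cell pixels are used.

# The synthetic scene generator

`simulateScene()` renders three channels — `nucleus`, `lc3b`, `marker` —
from explicit truth: cells are soft-edged disks (radial sigmoid, radius
~N(18, 2) px) placed by rejection sampling so that rendered cells never
overlap and sit well inside the field; a Bernoulli draw marks each cell
foci-positive; positive cells receive a zero-truncated Poisson number of
foci (mean 4) placed in a perinuclear annulus (0.2–0.6 of the cell
radius) with a minimum spacing of three focus radii (best-candidate
sampling keeps the drawn count exact); foci are Gaussian spots
(σ = focusRadius/2) carrying marker signal with probability
`pMarkerColoc`; everything is convolved with a 1-px Gaussian PSF
(analytically for spots); noise is Poisson shot noise on the noiseless
render, then additive Gaussian read noise, then clipping at zero.
Identical parameters give bit-identical scenes, and the generator
restores the caller's RNG state.

Default intensities (background 40, cytosol 120, focus 800, marker spot
600 over a 30 ADU diffuse level, read noise 5 ADU) put the assay in the
high-SNR regime of a modern spinning-disk confocal at moderate
magnification; they are chosen for testability, not to match any
specific instrument, whose noise characteristics are not published for
this assay.

What the generator deliberately does **not** emulate: realistic cell
shapes, nuclear-texture, Golgi morphology, 3D stacks, photobleaching, or
overlapping cells. Consequences for interpretation: passing recovery
tests demonstrate the correctness of the measurement ladder on
well-posed scenes, not robustness to segmentation-hostile confluent
monolayers. Two limitations surface even on synthetic data and are
inherent to the method: (i) foci closer than ~3 focus radii merge into
one connected component, so per-focus counts undercount tight clusters
(cell positivity, which is pixel-count based, is unaffected); (ii) with
a per-field adaptive threshold, foci-free fields produce spurious
detections — addressed by plate-level thresholding above.

# Numerical conventions

Pixels are unit squares addressed row-major and 1-based in R; centroids
are in pixel units. Images analyzed are single 2D planes or a caller's
projection of a stack. Smoothing replicates edges; Otsu histograms use
256 bins on the plane's own range (hence scale equivariance). Gaussian
kernels truncate at 3σ (capped at the image size). Undefined
observations (zero-variance cells, empty rings, cell-free images)
propagate as flagged `NA`s and are excluded from aggregates, never
silently zeroed. Ties at thresholds: mask inclusion uses `>=` on both
detection thresholds, while the two positivity calls (foci pixels per
cell, donut ratio) use strict `>` — a value exactly at a positivity
cutoff is negative.

# Validation scale

The bundled tests validate oracle equivalence (per-cell Pearson against
a direct-formula implementation at 1e-12 on 100 randomized cells; donut
means against a per-pixel set-arithmetic oracle, exactly), boundary
semantics at both strict thresholds, segmentation count recovery on 50
simulated fields, positivity recovery on three 14-field conditions
(nominal fractions 0.1/0.5/0.8, ~210 cells each, exact binomial bands
around the recorded ground truth), donut recovery on three 9-field
conditions (marker probabilities 0.2/0.5/0.9, > 200 scoreable foci
each), permutation collapse of the per-cell Pearson median under
within-cell marker shuffling (100 shuffles), scale/shape invariants, and
byte-identical pipeline reruns. These problem sizes keep the full suite
around a minute on one CPU while leaving the binomial bands narrow
enough to be informative.
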