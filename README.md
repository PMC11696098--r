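# fociQuant

Per-cell quantification of fluorescent punctae/foci in high-content
microscopy. The package targets assays in which an innate-immune or
autophagy stimulus (e.g. STING activation) drives a subpopulation of cells
to form bright perinuclear LC3B foci, and the questions of interest are:

* what **percentage of cells** carry foci,
* what **percentage of foci** are positive for a co-stained marker
  (ubiquitin, K63-Ub, HOIP, STING, ...), and
* how strongly two channels **correlate within each cell**,

aggregated from fields of view to the wells of a 96-well plate. It is
written for cell biologists running fixed-cell or high-content imaging
experiments who need a scripted, reproducible alternative to ad hoc
image-analysis macros.

## The analysis

All stages operate on 2D multi-channel fields (`MultiChannelImage`):

1. **Background subtraction** — `I' = max(0, I − G_σbg(I))`, a wide
   Gaussian estimate of the smooth background (`subtractBackground()`).
2. **Cell segmentation** — Gaussian blur of the LC3B channel, Otsu (or
   explicit) threshold, watershed of the blurred intensity landscape
   seeded at its regional maxima, watershed separating lines imposed on
   the mask as background, 4-connected components filtered by area
   (`segmentCells()` → `CellLabelMap`).
3. **Foci detection** — cell-scale equalization by dividing the image by
   a Gaussian blur of itself; foci pixels are bright in *both* the raw
   and the equalized image; components filtered by size and (optionally)
   circularity `4πA/P²` (`equalizeLocal()`, `detectFoci()` → `FociTable`).
4. **Cell positivity** — a cell is foci-positive when strictly more than
   `minFociPixelsPerCell` foci pixels fall inside it
   (`callCellsFociPositive()`).
5. **Donut colocalization** — each focus is dilated by a disk; the
   original foci pixels (of *all* foci) are subtracted to leave a
   surrounding ring; `ratio = mean(marker in focus) / mean(marker in
   ring)`; a focus is marker-positive iff the ratio is strictly greater
   than 1.75 (`donutRatio()`, `percentFociPositive()`).
6. **Per-cell Pearson** — pixel-wise correlation of two channels within
   each cell; per image the median of defined per-cell values; per well
   the median across images; across wells mean ± sd
   (`pearsonPerCell()`, `aggregatePlate()`).

A seeded synthetic-scene generator (`simulateScene()`, `simulatePlate()`)
renders nucleus/LC3B/marker channels with known per-cell and per-focus
ground truth (soft-edged cell disks, perinuclear foci, controllable
marker co-occurrence, shot + read noise), so every stage is validated by
parameter recovery. `runPipeline()` ties everything together from a YAML
config to per-cell/per-focus/per-image/per-well CSVs plus a hashed run
manifest; `inst/cli/fociquant.R` is a thin command-line wrapper.

## Worked example

```r
library(fociQuant)

sc  <- simulateScene(sceneParams(seed = 7L))        # one 256x256 field
bg  <- subtractBackground(getChannel(sc$image, "lc3b"),   100)
mbg <- subtractBackground(getChannel(sc$image, "marker"), 100)

lm  <- segmentCells(bg, segmentationParams())
lm
#> CellLabelMap 256 x 256 px, 15 cell(s)

ft  <- detectFoci(bg, fociParams(), labelMap = lm)
ft
#> FociTable: 19 focus rows, 483 foci-mask pixel(s)

pos <- callCellsFociPositive(lm, ft)
pos$fractionPositive                                  # estimated
#> [1] 0.4
mean(cellRecords(sc$truth)$is_foci_positive)          # ground truth
#> [1] 0.4

dn  <- donutRatio(ft, mbg, dilationRadiusPx = 2L, positivityThreshold = 1.75)
sum(dn$positive); sum(dn$defined)
#> [1] 18
#> [1] 19

pr  <- pearsonPerCell(bg, mbg, lm)
round(median(pr$pearson_r[pr$defined]), 3)
#> [1] 0.154
```

The field was generated with half the cells foci-positive on average; the
pipeline segments all 15 placed cells, calls 6/15 of them foci-positive
(exactly matching this field's ground truth), and scores 18 of 19
scoreable foci marker-positive (the generator's marker co-occurrence
probability is 0.8; small fields fluctuate). The modest median Pearson r
reflects that only foci — a small part of each cell — carry correlated
signal.

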