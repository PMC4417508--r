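---
title: "Muscle-section morphometry with fiberseg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-section morphometry with fiberseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberseg)
```

## The measurement problem

Transverse sections of skeletal muscle, immunostained for a
basement-membrane protein (laminin) plus nuclei (DAPI) and one functional
stain (a myosin heavy chain isoform, or an endothelial marker such as
PECAM), carry most of the routine readouts of muscle physiology: fiber
cross-sectional area (CSA) and its distribution, minimum Feret diameter,
fiber-type proportions, the prevalence of centrally nucleated fibers
(CNFs, a marker of regeneration that dominates dystrophic muscle), and
capillary density. fiberseg computes all of these from a single fiber
segmentation, replacing the interactive steps of GUI tools with
file-driven inputs so analyses are scriptable and reproducible.

## Segmentation model

The outline channel is treated as topography: laminin-bright membrane
bands are ridges, dark fiber interiors are basins. Two operations produce
the fiber mask.

**Depth-limited minima suppression.** Noise creates shallow basins that
the watershed would turn into spurious fibers. `suppress_minima(gray, h)`
fills every regional minimum whose *dynamic* (depth relative to its lowest
escape saddle) is below `h`, and leaves deeper minima untouched at their
original values. This operator satisfies a clean contract: output ≥ input,
output = input wherever no suppression applies, every surviving minimum
retains depth ≥ `h`, and the operator is idempotent. Note this is
deliberately *not* the textbook h-minima transform (reconstruction by
erosion of `I + h` over `I`): the textbook transform uniformly raises
surviving minima by `h`, so it shrinks their depth and is not idempotent.
We compute the textbook fill first, locate the surviving minima, and
reconstruct from those minima at their original values; watershed basin
counts are identical between the two variants, but ours preserves the
measured dynamics and honours the contract above.

**Watershed.** `watershed_segment()` floods the smoothed image from its
regional minima (Meyer's priority-queue algorithm). Basins are
8-connected — fiber cross-sections are compact, and 8-connectivity keeps
single-pixel diagonal necks in one fiber; the original implementation's
connectivity is unstated, so this choice is fixed and documented. Ridge
pixels where fronts meet get label 0 and belong to no fiber; fiber areas
therefore exclude the shared boundary. The watershed runs directly on the
smoothed stain intensity, not on a gradient image, matching the direct use
of the stained boundary in the workflow this package reproduces.

The smoothing depth `h` (default 5, useful range roughly 4–10 on 8-bit
images) is the main tuning parameter: too low leaves noise basins
(over-segmentation), too high merges true fibers (under-segmentation).
Both failure directions are monotone in `h`, which the test suite
verifies.

**Manual edits as files.** Merged fibers are cut by separation strokes — a
JSON list of polylines in pixel coordinates — rasterized 8-connected at
width 1 and stamped as boundary; split pieces are relabelled with the
largest piece keeping the original label. Objects that survive filtering
but are not fibers are deleted by label-id lists. These reproduce the
freehand-drawing and click-to-delete steps of interactive tools without a
GUI.

## Fiber filtering

Four rules run in fixed order (first failure recorded): edge contact
(any region pixel in the first/last row/column), area below
`min_fiber_area` or above `max_fiber_area` (100 and 5000 µm² by default;
bounds inclusive on the keep side — the source material does not state
inclusivity, so the keep-friendly convention was chosen), eccentricity
above 0.95, convexity below 0.8. Eccentricity comes from the ellipse with
the region's central second moments (each pixel contributes its own 1/12
unit-square moment, so a single pixel is circular, eccentricity 0; a 1-px
line approaches 1). Convexity is region area over the area of the convex
hull of the region's *pixel corners*.

The pixel-corner convention matters: with pixel-center hulls, a filled
square would score above 1 by the pixel-count area measure. With corner
hulls, any lattice-aligned convex raster (rectangles) scores exactly 1 and
the five-square plus sign scores exactly 5/7. One subtlety is documented
rather than hidden: for *curved* convex shapes the corner hull clips the
rasterization staircase, so a radius-50 disk scores ≈ 0.982, approaching 1
as the radius grows. The statement "a completely convex region has
convexity 1" is exact only when the union of pixel squares is itself
convex.

## Morphometry

Feret (caliper) diameters are computed by rotating calipers on the
pixel-corner convex hull: `max_feret` is the largest pairwise hull-vertex
distance, `min_feret` the smallest edge-orthogonal width (the width of the
smallest enclosing rectangle), and the direction (radians in [0, π), from
the +x axis) is the axis along which the minimal width is measured. On the
corner hull a w-pixel-wide axis-aligned rectangle has min Feret exactly
w — the physical footprint of the pixels — and a single pixel has min
Feret 1 and max Feret √2 (the unit-square diagonal). Summaries use the
sample standard deviation (n − 1; unspecified in the source material) and
SEM = SD/√n; a single fiber reports SD = SEM = 0 by convention.

## Intensity analyses

**Otsu initialisation.** All automatic thresholds minimize within-class
variance over a 256-bin floored histogram, exhaustively. The returned
threshold is `t + 0.5`, a level strictly *between* the optimal classes, so
the positive-call rule "value > threshold" (ties negative) reproduces the
optimal partition exactly on 8-bit values; per-fiber means falling inside
the last low bin are still classed low. Value sets that cannot be split at
8-bit resolution raise an error and require a manual threshold. Every
threshold actually used is recorded in results and in the CLI run log, so
the interactive adjust-and-look loop becomes re-running with
`--threshold`.

**Fiber typing** applies Otsu to the distribution of per-fiber *mean*
intensities, not raw pixels — it is the average fiber stain that the
analyst thresholds — and reports per-fiber calls plus group summaries
(all/positive/negative mean area and intensity, percent positive). Because
fiber area comes from the mask, blotchy type staining does not distort
positive-fiber sizes. Unlabeled fibers are conventionally interpreted as
type II when a type I stain is used.

**CNF calling** erodes each fiber by the nuclear border distance (10 µm
default) using an exact Euclidean distance transform to the fiber's own
boundary — fiber pixels 8-adjacent to another label, to background, or to
the image edge. Nuclear staining is smoothed by the dual (h-maxima style)
suppression on the bright-nuclei polarity, which removes shallow streak
artifacts of poor DAPI staining, then Otsu-thresholded. A fiber is a CNF
when its thresholded nuclear pixels inside the central region total at
least `min_nuclear_size` (5 µm²), *aggregated* over pixels rather than per
connected nucleus: the source material does not specify contiguity, and
the aggregate rule is simpler and monotone in both border distance and
minimum size. Fibers whose central region erodes away entirely can never
be CNFs — the known small-fiber caveat of this border-distance method.

**Object counting** smooths (depth 10 default), thresholds, and labels
8-connected components, reporting count, per-object area and centroids. No
size filtering is applied by design; the exported areas support downstream
filtering. Capillaries-per-fiber and per-area ratios are derived
conveniences computed by the CLI when a mask is supplied.

## The synthetic world

`generate_section()` builds a ground-truthed section: `n_fibers` seeds,
Lloyd-relaxed (4 iterations, half-resolution grid) into a discrete Voronoi
tessellation whose cells mimic polygonal fiber packing; a membrane band
(3 px wide, intensity 220 over interiors of 30) along every inter-cell
boundary; a type channel filling an exact count
`round(fraction_positive × n_interior)` of interior cells at intensity 180
over 10; a nuclei channel with one central nuclear disk (radius 4 px,
placed at the cell's deepest interior point) per CNF fiber — CNFs are
drawn only from cells deep enough to host a clearly central nucleus — and
peripheral disks centered on the membrane band elsewhere; and a *serial*
object section (same outline and nuclei, capillary-like dots on the
interstitial boundaries instead of the type fill), mirroring the
serial-section staining used for capillary counts in practice. Truth
tables record the label map, per-fiber area/type/CNF and object centroids.
Everything is deterministic given the seed.

Defaults state a realistic world at the published scale: 0.645 µm/px,
1024² px (≈ 660 µm field), 200 cells ≈ 2000 µm² each, 30 % type-positive,
30 % CNF (a dystrophic-like prevalence), 50 capillary dots, camera noise
SD 2 on the 8-bit scale, optional soft streak artifacts in the nuclei
channel. What the generator does *not* emulate — point-spread blur,
chromatic aberration, uneven illumination, real interstitial texture —
bounds what a green test establishes: recovery results validate the
algorithmic contracts, not stain-quality robustness on real slides.

One empirical finding is documented honestly rather than tuned away:
with Gaussian noise of SD 2–3 (iid or spatially correlated), depth-5
suppression cannot remove every noise basin inside ~5000-px fiber
interiors, so exact fiber-count recovery at the default `h = 5` holds only
for noise-free sections. With the default noise (SD 2), recovery of fiber
count, type calls, CNF calls and object count is exact at `h = 10`, inside
the documented 4–10 working range — the same adjustment a microscopist
makes for noisy staining. The noise-free end-to-end recovery test uses the
published defaults; the CSA comparison passes at a mean per-fiber relative
error of ~3.6 % (the watershed ridge is shared between neighbours, so each
fiber loses about half its 1-px perimeter relative to the full-cell
truth — the border-attribution bias inherent to any segmentation
convention).

## Numerical and format choices

* Coordinates are 1-based (row, col) pixel grids internally;
  centroids are reported x = column, y = row. Channel indices are 1-based
  (1 = red, 2 = green, 3 = blue) in configs and the CLI.
* Configs are plain-text `key = value` files (diffable, reproducible); a
  reader for two-column spreadsheet parameter tables is provided as a
  convenience. Spreadsheet *output* is omitted — no xlsx writer exists in
  the supported dependency set — CSVs carry the same per-fiber columns
  plus mean/SD/SEM or group-summary rows.
* Label masks persist as single-channel uncompressed TIFF, 16-bit,
  escalating to 32-bit beyond 65535 labels; the round trip is lossless.
  The mask format is unstated in the source material; TIFF was chosen as
  the interchange standard readable by any imaging tool.
* Images load from BMP/JPEG/PNG/TIFF; ≥ 16-bit inputs are linearly
  rescaled to 0–255; alpha is dropped; grayscale inputs are rejected
  because channel roles would be undefined.
* Otsu ties take the smallest threshold; filter rule order is fixed
  (edge → small → large → eccentricity → convexity) and only the first
  failure is reported; stroke rasterization is 8-connected width-1
  Bresenham.

## Known limitations

Single stain per run (multi-isoform typing needs serial sections or
distinguishable fluorophores); no myonuclear-density or peripheral-nuclei
analysis (central nuclei only); no stitching, proprietary microscope
formats, or H&E-type brightfield stains; no automatic merge repair beyond
user strokes; JPEG input is supported but discouraged (lossy edges bias
the watershed).
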