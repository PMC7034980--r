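---
title: "Measuring individual cell–cell junctions: models, parameters, and validation"
author: "junctmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring individual cell-cell junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Epithelial and endothelial integrity depends on adherens-junction
receptors (E-cadherin, VE-cadherin, β-catenin) that decorate the contact
between neighbouring cells. Perturbations — oncogene expression, RNAi,
inflammatory stimuli — change junctions in ways that whole-image
intensity averages cannot distinguish: staining may fragment into dots,
the contact line may lengthen and undulate as it loses tension, or
receptors may pack into fewer but denser clusters. `junctmorph`
quantifies these phenotypes *per junction*: it reduces a single-channel
fluorescence image to a one-pixel-wide boundary skeleton, finds the
tricellular corners where three or more cells meet, cuts the skeleton
into corner-to-corner **interfaces**, and measures each interface with a
repertoire of primary and size-normalized secondary parameters.

Terminology used throughout: the **interface** is the contact between
two cells, delimited by two corners, measured corner to corner
regardless of staining; the **junction** is the portion of the interface
actually covered by marker staining, possibly split into fragments.

## The pipeline

1. **Boundary detection** (`detect_edges`). The image is Gaussian-blurred
   (sigma 2 px) to suppress shot noise, sharpened with an unsharp mask
   (gain 0.8) to emphasise ridges, and binarized adaptively: a pixel is
   boundary when its sharpened intensity exceeds 1.3 times the mean of
   its 21 × 21 neighbourhood. Fragments smaller than 30 px are discarded
   as specks and 1-px holes are closed. On a uniform image the
   pixel-to-local-mean ratio is 1 everywhere, so the edge map is empty by
   construction. These defaults were calibrated on the package's
   synthetic fixtures — the binarization rule of the original
   interactive tools is not published — and hold the skeleton's
   boundary-pixel recall above 95 % down to a peak signal-to-noise ratio
   (PSNR) of 22 dB, the quality gate below which automatic
   skeletonization should not be trusted.
2. **Skeletonization** (`skeletonize`). Zhang–Suen thinning preserving
   8-connectivity, followed by three cleanup passes: squashing of any
   fully set 2 × 2 block, removal of redundant staircase pixels (any
   8-simple non-endpoint pixel, by the Yokoi connectivity number), and
   spur pruning (default 5 px; pixels on the outermost image rows and
   columns are protected because open boundary paths legitimately end at
   the border). The mask is replicate-padded by 4 px before thinning so
   that band ends touching the border do not retract inward. The result
   satisfies the one-pixel-width invariant: no 2 × 2 block is fully set.
3. **Scripted edits** (`apply_edits`). Interactive skeleton correction is
   replaced by a declarative edit script — ordered `add`/`remove`
   polylines — so that a "semi-automated" analysis is reproducible and
   testable. Additions are rasterized with Bresenham's algorithm
   (8-connected); removals clear a Chebyshev-1 corridor; the skeleton is
   re-thinned afterwards.
4. **Ridge refinement** (`refine_skeleton`). Each skeleton pixel moves to
   the brightest pixel of its (2r+1)² window. A pixel already attaining
   the window maximum stays put, which makes a constant image a fixed
   point; among strictly brighter candidates ties break deterministically
   to the smallest (row, col). Component count is preserved (the original
   pixels are merged back in if re-thinning would change it).
5. **Cells and corners** (`label_cells`, `detect_corners`). Cells are the
   4-connected components of the skeleton's complement — 4-connectivity
   prevents leakage through diagonal skeleton steps. Cells owning pixels
   within 2 px of the image border are flagged so junctions of cells not
   fully surrounded by neighbours can be excluded. A skeleton pixel is a
   corner candidate when ≥ 3 distinct cell labels occur within Chebyshev
   radius 2; candidate clusters merge into one corner (so 4-way meetings
   are a single corner), snap to the skeleton branch point, and are then
   refined: the thinned fork sits systematically 2–3 px inside the blob
   where the staining bands merge, so the vertex is re-estimated as the
   least-squares intersection of straight lines fitted to the skeleton
   arms in a 4–9 px annulus, where the skeleton tracks the band midlines
   without bias. This brings corner placement to ≈ 1–2.5 px of the true
   tricellular vertex on clean synthetic scenes.
6. **Interfaces** (`extract_interfaces`). The skeleton is traversed as a
   graph: corner zones (Chebyshev radius 3, extended by true branch
   pixels) are removed, the remaining simple paths become interface
   records, each re-attached and extended through the zones to the exact
   corner positions. A path passing within the immediate vicinity of a
   corner mid-way is split there (two arms of a junction can touch just
   outside the zone). Duplicates are removed on the canonical
   (corner pair, cell pair) key — a junction shared by two cells is
   measured once. Records are flagged, never silently dropped:
   `border`, `degenerate` (full path < 5 px), `dangling` (an end attached
   to no corner), `loop`, `branched`; only unflagged records are
   measured, and every exclusion is logged with its reason.
7. **Measurement** (`dilate_interface`, `measure_primary`,
   `derive_secondary`). The user-set dilation (1–9 px, as in the original
   protocol) defines the band of pixels within Chebyshev distance of the
   path. Marker area and intensity count only above-threshold pixels
   (strict `>`) inside the band. Each path pixel owns its perpendicular
   cross-section — the band pixels nearest to it, ties to the lower
   index — and is covered when that cross-section contains marker
   staining; maximal covered runs are the staining fragments (gap
   tolerance 0 by default: any uncovered pixel splits runs).

## The parameters

Primary (pixels, px², A.U.): interface contour (geodesic length of the
corner-to-corner path), straight-line interface length (Euclidean
distance between corners), interface area (band pixel count), junction
contour and straight-line junction length (between the outermost covered
pixels), junction area (band pixels between the outermost covered
indices), fragmented junction contour (summed fragment lengths), marker
area and marker intensity.

Secondary (normalized): interface and junction linearity indices
(contour / straight length; 1 = taut, > 1 = undulated), coverage index
(% of the interface contour covered by fragments), interface occupancy
(% of the band area occupied by marker), intensity per interface area,
and cluster density (marker intensity / marker area — the mean intensity
within the marker's own footprint, high when receptors pack densely).

Two documented ambiguities are settled as follows and exposed as
configuration. The cluster-density denominator is the marker's own
stained area (`marker_area`), i.e. cluster density is the mean
above-threshold intensity; the area between the outermost staining
(`junction_area`) is available through `cluster_denominator =
"junction_area"`. Interface occupancy likewise uses the marker pixel
count over the band area.

**The contour metric.** Contours are weighted 8-connected step sums: 1
per orthogonal step, √2 per diagonal step. This chamfer metric guarantees
contour ≥ Euclidean distance, hence linearity indices ≥ 1, and makes
every length an exact, enumerable quantity. Its known cost is a
digitization bias: a straight digital line of orientation θ ∈ [0°, 45°]
measures cos θ + (√2 − 1) sin θ times its true length — up to +8.2 % at
22.5°, about +5.5 % averaged over orientations. Absolute contours of
obliquely oriented interfaces therefore run a few percent long, and the
interface linearity of a perfectly straight oblique interface reads
1.00–1.08 rather than exactly 1. Ratios of like quantities (coverage
index; any between-group comparison of the same parameter) are unaffected
because the bias cancels. We keep the chamfer metric rather than a
sub-pixel length estimator because exactness and the linearity ≥ 1
invariant matter more here than absolute length accuracy; the bias is a
constant of the method, not noise.

## The synthetic monolayer generator

Every pipeline stage is validated against scenes with exact ground truth
(`generate_monolayer`). Cells are a Voronoi tessellation of seed points
placed on a jittered hexagonal lattice and relaxed with four Lloyd
iterations — a confluent monolayer is close to a relaxed honeycomb, with
near-uniform cell areas and tricellular vertices near 120°. The Delaunay
triangulation is computed by an exact brute-force circumcircle test
(ample at ≤ 60 seeds); Voronoi vertices are triangle circumcenters,
edges the dual segments clipped to the image.

Scene well-formedness is enforced by re-sampling (up to 80 attempts):
interior interfaces ≥ 12 px; no edge shorter than 8 px incident to a
measurable vertex (a nearly degenerate neighbouring vertex would merge
with the corner at raster scale); arm angles ≥ 75° at measurable vertices
(an acute fork displaces the thinned branch point); and no cell entering
the 2-px border band by less than 25 px (such slivers make the border
flag ambiguous at raster scale). These are conditions for the geometry to
be *resolvable at raster scale*, chosen once; scenes violating them model
images a careful experimenter would exclude or correct by hand.

Each interior edge is rendered as a disc-brushed staining band
(default width 3 px at 200 A.U. over a 10 A.U. cytoplasm, 8-bit).
Undulation displaces the curve along its normal by a sine (or triangle,
for the zigzag endothelial preset) wave, enveloped to vanish at the
vertices so corners stay exact. Fragmentation realizes a programmed
coverage fraction as ~10 px staining fragments, one per equal arc block,
jittered with ≥ 2 px gap margins; the painted intervals sum to the
programmed coverage exactly. Brush strokes overhang each programmed
fragment boundary by 0.4 px: a run of m raster pixels measures m − 1
chamfer steps, and this end calibration (fixed once against the
cross-section covering rule on raster test strips) makes a painted
interval of length ℓ measure ℓ in expectation, so the programmed
coverage is recoverable to within ±3 percentage points at scene level.
Per-junction coverage values scatter ±10 points simply because a single
2 px quantization step on a 60 px interface is 3 points.

Ground truth records seeds, vertices, per-interface continuous arc
lengths (from a 0.25 px-step polyline of the displaced curve), covered
intervals, the stamped pixel set, the pre-noise image, and the label map.
`truth_skeleton()` and `truth_interfaces()` turn the truth into pipeline
inputs — the outcome of a perfectly corrected interactive session — which
separates measurement validation from detection validation.

What the generator does **not** emulate: a microscope point-spread
function, uneven illumination, out-of-focus light, multinucleated or
overlapping cells, and intensity variation along a fragment. Passing
tests on these scenes therefore validate the measurement machinery and
the detection logic on well-behaved images; they do not certify
performance on poorly contrasted real data, where the semi-automated
edit script (and the PSNR gate) exist precisely because automation
fails.

Noise is additive, zero-mean Gaussian, clipped to the intensity range
(as an 8-bit display image saturates); `degrade_scene()` bisects the
noise sigma to hit a target PSNR within 0.5 dB, which is how the 22 dB
skeletonization guideline is probed.

## Statistics

Per-junction data are typically non-parametric, so two groups are
compared with the two-sided Mann–Whitney U test and three or more with
one-way ANOVA followed by Games–Howell post-hoc pairwise comparisons
(Welch-type statistic with a studentized-range reference; robust to
unequal group sizes and variances). Shapiro–Wilk and Lilliefors
(Kolmogorov–Smirnov) normality diagnostics are reported per group but
never gate the analysis automatically. Phenotype fingerprints normalize
each treated group's **median** to the control median (controls set to
100) — medians, not means, because the per-junction distributions are
skewed — with the Mann–Whitney significance flag per parameter, and can
be drawn as the familiar bubble profile. Technical replicates are pooled
by default; the per-replicate table is always retained (`image_id`
column), so consistency across replicates can be checked first.

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col), row increasing downward — the
  native R matrix convention, shared by every module.
* Thresholds are strict (`intensity > t`): threshold 0 on an all-zero
  image selects nothing, and masks shrink monotonically as t rises.
* PSNR of identical images returns `Inf` — a quality-check pass, not an
  error.
* Empty marker within a band: all junction fields are 0, the interface
  fields remain; cluster density and junction linearity are `NA` where
  their denominators vanish. A zero-length or zero-area interface is an
  error (`degenerate-interface`), not a silent `NaN`.
* All tie-breaks are deterministic (lowest path index for cross-section
  ownership; smallest (row, col) for ridge snapping), so identical
  configuration and seed reproduce results byte for byte.

## Problem sizes used in the shipped validation

The test suite and the acceptance script run entirely on synthetic
scenes generated at run time: geometry recovery on clean monolayers of
10–50 cells at constant cell density (384 px field at 25 cells, scaled
as √n); coverage recovery at 16 cells / 320 px across programmed
coverages of 25–100 %; brute-force oracle equivalence on ≤ 64 × 64
random instances; and fingerprint recovery with ≥ 50 junctions per
phenotype group. These sizes give stable estimates (scene-level coverage
error < 2 pp; corner placement < 2.6 px) while a full run stays in the
minutes range on a single core.

## Known limitations

* Absolute contours carry the chamfer digitization bias discussed above.
* Automatic corner detection requires corners ≥ ~9 px apart; denser
  vertex clusters merge into single (4-way) corners by design.
* Very short interfaces (< 5 px path) are excluded as below measurement
  resolution.
* The zigzag endothelial morphology is skeletonized but its contour is
  systematically under-read when the undulation period approaches the
  staining width — the same limitation the interactive protocol reports
  for strongly zigzagged VE-cadherin junctions.
* Classification of expressing cells assumes the expression mask is
  co-registered; no registration is attempted.
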