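---
title: "Multiangle root phenotyping: models, descriptors, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiangle root phenotyping: models, descriptors, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoshape)
```

## The measurement problem

Root system architecture (RSA) of cutting-propagated plants is typically
captured by photographing each plant in a transparent tube on a turntable:
one image every 15° gives 24 views per plant, with 3 biological replicates
per accession. Each 2D view must be reduced to a fixed-length numeric
vector so that hundreds of accessions can enter association mapping and
trait-correlation analyses. rhizoshape implements that reduction: image →
binary mask → centerline skeleton → a registry of 16 whole-image
**macrophenotypes** and 96 depth-, width- and size-resolved
**microphenotypes**, then per-accession aggregation over views.

## The trait registry

Seven structural descriptors measure where root material sits in space:

* `com_x`, `com_y` — foreground centroid, normalized to the root bounding
  box (0 = top/left edge of the box, 1 = bottom/right). A box that is a
  single pixel wide on an axis reports 0.5 there.
* `convexhull` — shoelace area (px²) of the convex hull of foreground
  pixel centers. Pixel centers (not pixel squares) are the convention, so
  a filled 10 × 10 square reports 9 × 9 = 81.
* `rect` — proportion of root area in each of 4 equal-height strata of
  the bounding box; channels sum to 1. Macro channel = top stratum.
* `ellips` — fraction of root pixels inside concentric ellipses centred
  on the apex (centroid of the topmost foreground row), with base
  semi-axes `a0 = max(W/2, 1)` and `b0 = max(H, 1)`. Each pixel gets the
  normalized coordinate `s = sqrt((dx/a0)² + (dy/b0)²)`; rung *k* of the
  12-rung ladder counts pixels with `s ≤ (k/12)·s_max`. The ladder is
  non-decreasing and its last rung is exactly 1. Macro channel = rung
  `ceiling(K/2)`.
* `coord_x` — per depth layer (10 layers), the horizontal extent of
  foreground in that layer divided by the bounding-box width; 0 for empty
  layers. Macro = mean over layers.
* `diff_x` — first differences of `coord_x` (`diff_x_0 = coord_x_0`);
  larger values mean the silhouette widens faster with depth, i.e. a
  wider opening angle. Macro = mean over layers 1..9.

Nine morphological descriptors come from the mask and its skeleton:
`area` (foreground pixel count), `length` (skeleton length), `diam_mean`,
`directionality`, `tip_count`, and scan-line crossing statistics
`cross_hori_mean` / `cross_hori_max` (runs of root per image row — a
proxy for the number of distinct roots at each depth, hence for lateral
root number) and `cross_vert_mean` / `cross_vert_max` (per column). The
two crossing means are additionally resolved into 30 bands each
(`cross_hori_0_mean` … `cross_hori_29_mean`), and `rect`, `ellips`,
`coord_x`, `diff_x` contribute their layer channels, giving
4 + 12 + 10 + 10 + 30 + 30 = 96 microphenotypes next to the 16 macro
summaries.

Three conventions apply everywhere: 0-based (row, col) indices with depth
= row; all layer bands are computed over the *root bounding box* (not the
frame), so descriptors are invariant to framing and zoom; bands are
half-open and equal-height with the last band absorbing the remainder,
and empty bands report 0 rather than missing so vectors keep a fixed
length.

## Segmentation

`subtract_background()` first normalizes polarity — root systems appear
bright on dark tubes or dark on bright tubes, so the image median is
compared with the two Otsu class means and the image inverted if the
background is the bright class — then estimates the background by
grayscale morphological opening with a disc (default radius 15 px, which
erases structures thinner than the disc) and subtracts it.

Two segmenters are provided. Global Otsu thresholding of the
background-subtracted image suffices for clean, bimodal tube images. For
harder material a random-forest pixel classifier is trained on the
synthetic library: each pixel is described by its raw intensity plus, at
scales σ ∈ {1, 2, 4} px, the Gaussian-smoothed intensity, gradient
magnitude, smaller Hessian eigenvalue (a ridge detector, strongly
negative on bright curvilinear structures) and local variance — 13 planes
in total. Defaults are 100 trees and balanced subsampling of at most
5,000 pixels per class per image; the forest seed is drawn from the
user-supplied seed so training is reproducible, and the feature
configuration travels with the model file and is re-validated before
prediction. These defaults are deliberately conservative, config-exposed
choices: the feature set is a standard trainable-segmentation stack, not
a tuned one.

`clean_mask()` removes 8-connected components below a minimum size,
optionally fills interior holes and keeps the largest component; it is
idempotent.

## Skeleton morphometry

The mask is thinned to a 1-px, 8-connected centerline (Zhang–Suen
parallel thinning). Parallel thinning is not exactly equivariant under
rotation, which would make `length` depend on which way the frame was
held; rhizoshape therefore thins in a *canonical orientation* — the
lexicographically smallest of the mask's 8 dihedral transforms (4
rotations × optional mirror), chosen by hashing — and maps the skeleton
back. Skeleton measurements are then exactly invariant under 90°
rotations and left–right mirroring, which the test suite asserts.

Skeleton pixels with one neighbour become endpoints, 8-connected clusters
of pixels with ≥ 3 neighbours become junction nodes, and chains between
nodes become edges. Measurements:

* `length` — per chain, 1 per rook step and √2 per diagonal step. The
  diagonal-corrected metric slightly overestimates oblique strokes (worst
  case ≈ +8 % at 22.5°), which is why validation uses the strongly
  gravitropic growth regime this species shows — near-vertical axes keep
  the metric error small, and tip erosion by thinning (≈ one local radius
  per endpoint) works in the opposite direction.
* `tip_count` — degree-1 nodes. The endpoint nearest the top-center of
  the bounding box is the cutting's attachment, not a root tip, and is
  excluded by default (`exclude_crown`).
* `diam_mean` — mean over skeleton pixels of `2·EDT − 1`, floored at 1,
  where EDT is the Euclidean distance to background. The −1 makes
  odd-width bars report their true width: a 1-px line has EDT 1 and
  diameter 1, a 5-px bar has EDT 3 and diameter 5.
* `directionality` — each chain is cut into straight sub-segments every
  5 chain pixels (raw per-pixel angles are quantized to multiples of 45°,
  so a coarser step is needed); each sub-segment contributes its absolute
  angle from the downward vertical (0° = vertical, 90° = horizontal),
  weighted by its Euclidean length.

## The synthetic root generator

Because no annotated ground truth exists for tube images, rhizoshape
ships a stochastic 3D generator that doubles as the segmenter's training
library and as the oracle for every skeleton measurement. Axes grow from
a crown by fixed 4-px steps; each step rotates the current direction by
N(0, σ_θ) radians about a random perpendicular axis and then blends it
toward the downward vertical with weight *g* (gravitropism). Branches
arise as a Poisson process (λ expected branches per 100 px of parent),
leave at 40° ± 10° from the local parent direction, and their stroke
radius decays by the taper factor per order. A short, thicker stem stub
points upward from the crown — cuttings keep their shoot stub in the
tube — and the primaries attach radially around its base at evenly
spaced azimuths, as adventitious roots do; this also guarantees the
crown is the skeleton's top endpoint, so `count_tips()` recovers exactly
the number of axes.

Rendering emulates the turntable: polylines are rotated about the
vertical axis by the view angle, orthographically projected, and
rasterized with per-axis stroke radius; the mask is the exact
rasterization and the image adds polarity, Gaussian blur and additive
noise. Views at 0° and 180° are exact mirror images by construction
(`cospi`/`sinpi` keep the trigonometry exact), which pins down the
projection geometry in tests.

Defaults emulate 40-day-old cuttings in 2-cm-wide tubes at roughly
1 px ≈ 0.4 mm: 3 primaries, 40 steps × 4 px, σ_θ = 0.08 rad, g = 0.35
(this species' roots grow vertically or obliquely downward), λ = 1.2,
base radius 1.5 px (3-px strokes), 200 × 260 canvas, blur 0.7, noise
0.03. What the generator does **not** emulate: soil/agar texture,
specular highlights on the tube, root hairs, overlapping root mats, and
growth over time. Passing the recovery suite therefore shows the
geometry pipeline is correct, not that segmentation of arbitrary field
imagery will reach the same accuracy.

Ground truth is exact by construction: total polyline length, tip count
(= number of axes), and — independently of any raster — the maximum
per-row crossing count obtained by intersecting each axis centerline with
every image row. Exact recovery of tips and crossings is only
well-defined when distinct strokes do not merge in projection, so a
rejection sampler (`simulate_nonoverlapping()`) resamples seeds until no
two axes' strokes come within one pixel of each other away from their
attachment points (dilated-mask test: strokes that merely touch still
merge under 8-connectivity).

## Aggregation, correlation, threshold

Per-accession phenotypes are the arithmetic means of all view vectors,
replicates pooled (24 × 3 views at the full protocol); population
standard deviations are available alongside. Incomplete view sets are
aggregated with a warning listing the missing angles. Trait correlation
is plain Pearson *r* over accession-level values (`stats::cor`);
channels that are constant across accessions — e.g. the final ellipse
rung, which is 1 by construction — are reported as missing with a
warning rather than silently dropped. `suggestive_threshold(n)` returns
the 1/*n* suggestive significance cutoff used with an effective number
of independent markers; with n = 639,988 it prints 1.56 × 10⁻⁶.

## Numerical and design choices

* RGB→gray uses ITU-R 601 luminance (0.299, 0.587, 0.114); 8- and 16-bit
  sources are scaled by 1/255 and 1/65535.
* `coord_x` is a band *width* (extent/W), not a boundary coordinate, and
  `diff_x` keeps L channels with `diff_x_0 = coord_x_0`, so both have a
  fixed length per registry.
* The ellipse ladder size K = 12 completes the 96-channel budget next to
  the externally fixed 30/30/10/10/4 layer counts; macro summaries are
  separate channels, not double-counted among the micros.
* The CLI config is YAML (`yaml::read_yaml`) with flag overrides (flags
  win); every output CSV carries `#` provenance comments (version, seed,
  config hash) which readers skip.
* Degenerate inputs: empty masks yield empty graphs and zero length /
  tips but raise measurement errors for descriptors that need foreground;
  an all-background segmentation result warns and returns an empty mask
  rather than failing a batch.
* Validation problem sizes (chosen once): 20 seeded roots for the
  recovery suite, 20 training + 10 held-out renders for segmentation,
  and a 10-accession × 4-view batch for end-to-end determinism.

## Known limitations

Crossing counts undercount where roots truly overlap in projection;
`tip_count` cannot distinguish a tip touching another root from a
junction; the generator's Poisson branching has no spatial correlation
along the parent; physical units require an external mm/px calibration;
and the registry's layer counts, while config-exposed, default to the
30/30/10/10/4/12 split described above.
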