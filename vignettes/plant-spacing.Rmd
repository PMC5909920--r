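---
title: "Measuring within-row plant spacing from nadir UAV imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring within-row plant spacing from nadir UAV imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(plantspace)
```

## The problem

Stand uniformity — how evenly spaced the plants in a row are — is set at
emergence and never improves afterwards; uneven maize stands cost yield, and
agronomists want to quantify spacing right after the V1–V2 stage, when
plants are small, distinct, and countable. A low-flying UAV with an RGB
camera pointed straight down (nadir) can photograph tens of meters of row in
one frame. `plantspace` turns one such frame plus a handful of priors
(camera height, angle of view, plant height, row direction and width) into a
table of within-row interval distances in ground meters, and quantifies how
accurate those intervals are against ground truth.

## The measurement model

### From pixels to ground meters

For a nadir camera at height $H$ with *diagonal* angle of view $v$, the
image diagonal covers a ground length

$$L_{diagonal} = 2\,\tan(v/2)\,H,$$

split between image width and height by the sensor aspect ratio
($L_{width} = L_{diagonal}\cos(\arctan(NL/NS))$ for an $NS \times NL$-pixel
sensor). Pixel coordinates map linearly to ground coordinates,
$x_m = x\,L_{width}/NS$, in a corner-origin frame with $y$ increasing
down-image; distances are then ordinary Euclidean distances. The angle of
view is treated as diagonal throughout: that is the variant consistent with
the footprint formula above, and consumer UAV cameras quote it that way.
Lens distortion and oblique poses are out of scope.

### Vegetation segmentation

The excess-green index on chromatic coordinates,
$EXG = 2g - r - b$ with $r = R^*/(R^*+G^*+B^*)$ etc., separates green
vegetation (up to $+2$) from soil (near or below zero). Band values are
normalized by their per-image maxima by default (`exg_normalize = "image"`),
with a bit-depth option because per-image maxima make the index depend on
scene content. Zero-sum pixels (sensor dropouts) are defined as $EXG = 0$,
i.e. background. Binarization is either Otsu's between-class-variance
threshold on the EXG histogram or a fixed cutoff; in practice a fixed 0
works on clean dark-soil scenes and a fixed 0.1 suppresses brighter field
backgrounds and residue. A constant image has no Otsu threshold and is
rejected rather than guessed at.

Connected components (8-connectivity; the mask is pixel art, and diagonal
leaf pixels belong together) become candidate objects with area, contour
perimeter (diagonal chain steps weighted $\sqrt 2$; single-pixel objects get
the unit-square boundary 4 so perimeter stays positive), and a continuous
centroid with pixel centers at half-integer coordinates.

Two cleanup passes follow. *Relative filtering* keeps objects whose area
exceeds `t_area` (default 0.3) times the collection's mean area and whose
perimeter/area ratio passes the analogous shape test — cutoffs that adapt to
the scene instead of hard-coding a plant size. The shape criterion is
genuinely ambiguous in the field: "keep ratio greater than a fraction of the
mean" (the literal reading, our default `shape_keep = "above"`) admits
nearly everything, while compact plants actually have *low* perimeter/area;
both directions are implemented and the choice is a config switch rather
than a guess. Filtering is deliberately not idempotent — the means move
after removal — so it runs once. *Fragment merging* dilates every object by
a disc (default radius 4 cm in ground units, converted through the GSD) and
merges objects whose buffers overlap, transitively. The radius encodes prior
knowledge of the planting interval: it must stay below roughly half the
interval minus the leaf span, or adjacent plants fuse — which is exactly the
failure mode close plantings exhibit (see below).

### Perspective correction of centroids

An off-nadir plant leans away from the camera in the image: its canopy
centroid $B$ sits radially *outside* its stem position $A$. Modeling the
plant as an upright stick of height $AD$ whose projected centroid bisects
the stem-to-top ground projection ($AC = 2\,AB$), similar triangles give

$$AB = \frac{AD \cdot OB}{2H - AD},$$

where $O$ is the nadir point (the image center) and $OB$ the centroid's
distance from it. The stem estimate moves $B$ radially inward by $AB$,
using the two-argument arctangent so the correction points toward $O$ in
all four quadrants. The correction grows linearly with $OB$ and with plant
height, and vanishes as $H \to \infty$ — low flights need it most. The
bisection assumption is the model's core approximation: real canopies are
not sticks, and the residual error it leaves is part of what the simulator's
leaf-asymmetry noise emulates. Plant height is a single scalar per image
(the crop is assumed to grow uniformly); per-plant heights are out of scope.
The model needs $AD < 2H$ and the package refuses geometry that violates it.

### Row detection and weed removal

Row direction $d$ and row width $w$ are prior knowledge (planting equipment
sets them; the angle is supplied per image). Detection is an iterative
buffer procedure: seed an unassigned plant, cast a line through it at angle
$d$, collect all unassigned plants within a perpendicular buffer of
$w/3$ (the conventional third-of-row-width buffer; configurable via
`buffer_frac`), recentre the line on the members' mean, emit the ridge, and
repeat until every plant is assigned. Choices worth stating:

* **Seeding.** A randomly chosen seed makes the partition run-dependent; the
  default seeds deterministically with the unassigned plant nearest the
  image center (`seed_method = "center"`), and `"random"` remains available.
  On well-separated rows the resulting offsets agree across seed orders to
  within the buffer (property-tested).
* **Refinement.** One collect–recentre pass is the basic procedure;
  `refine_iters` allows re-collecting around the updated line until
  membership stabilizes (capped at 10), which rescues stragglers when the
  seed sat at the buffer's edge.
* **Vertical rows.** All internal line math is point-direction
  parametric, so $d = 90^\circ$ is not special; the $y = kx + b$ form is
  emitted only when $|\cos d| > 10^{-6}$.
* **Ordering.** Ridge ids ascend along a consistently oriented normal
  (left-to-right for vertical rows) — a labeling convention only.
* A wrong row-angle prior degrades membership rather than failing loudly;
  the mean member-to-line residual in the ridge table is the diagnostic to
  watch, and no automatic recovery is attempted.

In weedy fields, most weeds grow *between* the rows. After detection,
sparsely populated ridges (fewer members than `min_members`, or than
`member_frac` times the best-populated ridge) are pruned as weed-seeded
lines, and any object farther than `weed_tolerance_m` (default: the
membership buffer) from every surviving ridge is flagged as a weed and
excluded. Weeds growing *within* a row are indistinguishable from crop by
this geometry and remain — a stated limitation of the approach, not of this
implementation.

### Ordering along the row and intervals

Each kept plant is assigned to its nearest ridge (ties to the lowest id) and
replaced by its perpendicular foot on that line. A reference point is placed
far before the first plant along the row direction — at
`anchor - 10 * scene_diagonal * direction`, which generalizes the classic
"evaluate the row line at $x = -100$" construction to vertical rows and
arbitrarily large scenes — feet are sorted by ascending distance to it, and
consecutive differences are the interval distances. Equal sort keys fall
back to ascending plant id, so output order is deterministic; zero-length
intervals are reported but flagged as duplicate plants. Intervals are
between consecutive *detected* plants: a missed plant produces one long
interval, the documented overestimation mode, rather than a guessed gap.
Objects clipped at the image border are flagged `truncated` and their
intervals can be excluded from evaluation.

### Accuracy metrics

With paired estimated/true intervals ($ed_i$, $d_i$) and design interval
$d$:

$$d_e = \tfrac1n \sum |ed_i - d_i|, \qquad r = d_e / d, \qquad
d_t = \tfrac1n \sum (ed_i - d_i).$$

$d_e \ge |d_t|$ always; $r$ is reported in percent. Pairing is by along-row
rank within offset-matched rows. Because field counts rarely match (missed
plants, merged neighbors), the row-wise variants compare unpaired means,
$d_t = \overline{ed} - \overline{d}$ and $r = d_t / \overline{d}$, per row.
When paired counts differ, the first $\min(n, n')$ ranks pair up and the
row-wise metrics carry the information the trailing ranks would have.

## The scene simulator

`render_scene()` is a forward model of the same geometry, so the pipeline
can be validated end-to-end with known truth. It places stems on parallel
row lines at the configured interval (Gaussian interval jitter, slight
lateral scatter), displaces each plant's canopy center radially *outward*
from nadir by exactly $AB = AD\cdot OB/(2H - AD)$ — the forward counterpart
of the corrector, so the two close to machine precision on the model level —
and renders each plant as a glyph of elliptical leaf lobes in opposite
pairs at a random orientation (V2 leaf phyllotaxy), plus a small stem disk
that keeps thin lobes connected, over noisy brown soil. Radial glyph
elongation by the same projection factor stands in for the full projective
smear. Optional weed blobs are scattered in the inter-row lanes and pale
residue streaks on the soil.

Two presets mirror the validation experiments the method is known from:
`indoor_scene_spec()` (76.5 cm rows, 10 cm plants, bare soil, design
intervals 9–36 cm) and `field_scene_spec()` (53 cm rows, ~20 cm intervals,
15 cm plants, weeds and residue). `scenario_grid()` builds the named
`S_<x>cm_<y>m` interval-by-height product with per-cell seeds; it returns
specs rather than rasters so twenty full scenes need not sit in memory.

Default realism choices, made once: leaves 4 cm long and 1.5 cm wide (a
young V1–V2 plant's footprint), up to 25% length imbalance between opposite
leaves (`leaf_asym` — this displaces the canopy centroid off the stem by up
to ~1 cm and is the dominant, realistic error source in clean scenes),
1 cm interval jitter indoors and 2 cm in the field, soil RGB
(0.50, 0.28, 0.26) and channel noise 0.02 so soil EXG sits near −0.19
(safely below a 0 threshold at this noise level), residue near +0.03
(below the 0.1 field threshold), and plants near +1. Weeds are 1.2–2.5 cm
blobs within ±6 cm of the lane centerline, i.e. well outside the
membership buffer of either adjacent row.

What the simulator deliberately does *not* emulate: 3-D leaf architecture
and its height-dependent self-occlusion, shadows and illumination gradients,
soil texture correlation, in-row weeds, and real lens PSFs. Passing the
built-in validation therefore shows the *geometry and algorithmic chain* are
correct and well-conditioned at realistic noise levels; it does not certify
segmentation performance on arbitrary field imagery, which depends on
radiometric conditions the simulator idealizes.

## Numerical and degenerate-input choices

* Out-of-frame pixel conversions error by default; `clamp = TRUE` supports
  border-truncated plants.
* Labels, ids and orderings are deterministic (raster-scan components,
  offset-sorted ridges, id-tie-broken sorts); the same image and config give
  byte-identical tables, and a config hash rides along in every summary.
* Binary-mask centroids quantize at roughly 0.1 px for the default glyph
  sizes; the model-level forward/inverse closure is exact to machine
  precision, while the full segmentation path on noise-free renders is
  rasterization-limited to a few tenths of a pixel. The validation suite
  asserts both, at 0.1 and 0.5 GSD respectively.
* Empty masks, empty object lists, single-plant ridges and empty ridge sets
  all return empty results or warn rather than error, except where a result
  would be meaningless (no ridges to project onto; metrics of empty lists).

## Problem sizes used in validation

The shipped validation runs 960×720-pixel scenes — twelve indoor-style
scenes (18/27/36 cm × 2–3 m) for the relative-error check, twelve field
scenes (2–5 m, weeds on) for the row-wise bias check, and twenty 480×360
scenes of the 9 cm / 1 m overlap regime for the failure-mode check — sizes
chosen so the full suite re-runs in a few minutes on one core while keeping
per-plant pixel counts (tens to hundreds) in the range where segmentation
behaves as it would on 12-megapixel frames of the same GSD class.

## A worked example

```{r example}
scene <- render_scene(indoor_scene_spec(interval_m = 0.18, height_m = 2,
                                        seed = 42))
cfg <- run_config(camera = scene$cam, plant_height_m = 0.10,
                  row_angle_deg = 90, row_width_m = 0.765,
                  threshold_mode = "fixed", fixed_threshold = 0)
run <- run_pipeline(scene$image, cfg)
glance(run)
evaluate_run(run, scene$truth, "pairwise", design_d_m = 0.18)
```

```{r overlay, fig.height = 5}
autoplot(run, image = scene$image)
```

The overlay mirrors the standard diagnostic figure: red canopy centroids,
blue corrected stems pulled toward the image center, grey ridge lines.

## Known limitations

The method stands on its priors: row angle and width, plant height, and the
segmentation thresholds all come from the user, and a wrong prior biases the
result silently (the ridge residual diagnostic helps, but only for the
angle). Close plantings at low altitude merge neighboring canopies and
overestimate intervals; high altitudes shrink plants toward the filter
cutoff and miss them. Intervals across a missed plant are reported long
rather than imputed. JPEG input is not supported (PNG/TIFF only), and
georeferencing, orthomosaics and multispectral indices are out of scope.
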