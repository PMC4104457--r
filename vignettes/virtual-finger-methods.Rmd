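---
title: "From 2D gestures to 3D structures: the models behind vfinger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 2D gestures to 3D structures: the models behind vfinger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfinger)
```

## The inverse problem

A volumetric microscopy stack is explored on a flat screen, almost always
through a maximum intensity projection (MIP): each screen pixel shows the
brightest voxel along the viewing ray.  Marking a cell, tracing a neurite,
or boxing a region therefore happens in 2D, while the objects of interest
live in 3D.  Recovering the 3D locus a user means from a single 2D click,
stroke or zoom is an inverse problem: every screen point corresponds to an
entire ray of voxels.  `vfinger` resolves that ambiguity the way a
practitioner's eye does — by assuming the intended object is the bright
structure visible under the cursor — and turns one gesture into a 3D
point, curve, or box.

The package is GUI-free: cameras and strokes are plain serializable
objects (JSON), volumes are multi-page TIFF / NRRD / raw files, curves are
SWC, landmarks are marker CSV.  Everything a windowed viewer would do
interactively can be scripted, tested, and reproduced.

## Viewing geometry

The camera is orthographic: a 3×3 orthonormal matrix whose rows are the
screen x axis, the screen y axis (top-left origin, y down) and the view
direction, plus a `zoom` (screen pixels per voxel) and a 2D `pan`.  A
volume coordinate `q` appears at `zoom * (R q)[1:2] + pan`; a screen point
is inverted into the *shooting ray* along row 3 of `R`.  All rays of one
view are parallel, which matches how a MIP is rendered.  Rays are clipped
to the volume box and sampled at exactly 1-voxel spacing with trilinear
interpolation per channel; coordinates are 0-based and voxel-centered
(voxel `(i,j,k)` owns the half-open cube `[i-0.5, i+0.5) × ...`), so
sub-voxel positions are meaningful everywhere.

## One click: progressive mean-shift pinpointing

`ppa_single()` locates the intended point on one ray by progressive mean
shift over the sampled intensity profile: the search window starts as the
whole ray, repeatedly re-centres on the intensity-weighted centroid of the
samples inside it and halves its width, and stops when the centroid moves
under 0.5 voxel or at most 3 samples remain; the brightest sample of the
final window is returned.  Window halving guarantees termination in
`O(log n)` iterations.  Centroid weights are the in-window intensities
minus their minimum: with raw intensities an additive offset `b` in
`a·I + b` would bias every centroid toward the window middle, so
shift-invariant weights are what make the scheme invariant under affine
rescaling of the data.

`ppa_c()` runs the mean shift independently per colour channel and keeps
the candidate with the brightest raw voxel value (ties to the lowest
channel index).  Raw values are compared because that is what the
rendered MIP shows; a flag switches to per-channel min–max normalized
comparison for data whose channels have very different dynamic ranges.
`ppa_n()` is the noise-robust variant: it runs the globally optimal curve
drawer (below) on a micro-stroke around the click and returns the first
knot, converged onto the local intensity centre.  A single ray can be
fooled by one bright noise voxel; a minimum-total-cost chain through five
nearby rays cannot, unless the noise lines up across all of them.

## One stroke: geodesic curve drawing

The image is treated as a graph: voxels are nodes, spatially adjacent
voxels (6-, 18- or 26-connected; default 18) are joined by edges weighted

    w(u, v) = ||u - v|| * ( g_I(u) + g_I(v) ) / 2
    g_I(x)  = exp( lambda_I * (1 - (I(x) - I_min) / (I_max - I_min))^2 )

so an edge costs its Euclidean length times the mean intensity penalty of
its endpoints: 1 between maximal-intensity voxels, `exp(lambda_I)` (about
22,000 at the default `lambda_I = 10`) through the darkest ones.  Bright
structures are thus corridors of near-Euclidean cost through an
essentially impassable background.  If the image is flat (`I_min ==
I_max`) the penalty is defined as 1 and the metric degrades to plain
Euclidean distance.  Intensity range is computed per designated channel
(default: the per-voxel maximum across channels, i.e. what the MIP viewer
shows).

Shortest paths are found by best-first wavefront propagation from a source
set until the first sink voxel is settled — cost-equivalent to Dijkstra on
the explicit graph, which the test suite proves against an independent
`igraph` oracle on hundreds of random volumes.  Frontier ties are broken
by ascending `(z, y, x)` voxel order so results are identical across
platforms.  The engine is a small C++ core (binary heap, implicit graph)
because a voxel graph of even a 56³ volume has ~4.5 million edges.

Curve drawing maps each stroke point to a shooting ray and chains
geodesics between consecutive rays:

* **`cda1()`** (fast, local): pinpoint the first ray, then pinpoint each
  next ray restricted to samples within ±30 voxels of the previous knot.
  When no sample qualifies the geometrically nearest sample is used, so
  strokes over dark regions still give a (geometric) curve — the intended
  behaviour for dark-region ROI selection.  The ±30-voxel leash is what
  keeps the chain from teleporting to a bright decoy far behind the
  traced structure.
* **`cda2()`** (robust): the neighbourhoods of the first two rays (voxels
  within 1 voxel of the sampled ray polyline) are marched source-to-sink,
  yielding both termini at once; each later knot is the first hit of a
  march from the previous knot to the next ray's neighbourhood.  When two
  consecutive rays lie closer than the neighbourhood radius their voxel
  sets overlap and a zero-length "path" through any shared voxel — however
  dark — would be optimal; shared voxels are therefore removed from the
  source side, and if the sets coincide entirely the brightest shared
  voxel is taken.
* **`cda2_global()`**: thins the stroke to its brightest half
  (`preprocess_stroke()`, endpoints always kept — the curve must span the
  gesture), selects up to `m = 5` candidate samples per ray (brightest,
  at least 2 voxels apart), computes exact geodesic costs between
  candidates of consecutive rays by fast marches bounded to the pair's
  bounding box plus a margin, and stitches the minimum-total-cost chain by
  dynamic programming.  This is the production configuration: a noisy
  bright voxel on an intermediate ray, or a poor first knot, cannot
  derail the curve because the whole chain is optimized jointly.  With
  `m = 1` it degenerates to greedy brightest-point chaining.
* **`cda2_bbox()`**: preliminary per-ray pinpoints define margin-extended
  (default 5 voxels) boxes around consecutive pairs and the march is
  confined to their union.  A margin too small to connect the curve gives
  a no-path error, never a silently wrong curve.

Knots are then corrected and smoothed.  `refine_curve()` moves each knot
to the intensity-weighted centroid of a small ball (radius 2, weights
local-minimum-subtracted, capped steps) — the per-knot optimal correction
that stops stroke jitter and voxel snapping from accumulating.
`smooth_curve()` is a centered moving average, endpoints pinned.  The
window is specified as an arc-length width of about 5 voxels: when knots
sit ~1 voxel apart that is the classic 5-knot window, but for sparser
knots a fixed 5-knot average would span far more arc and flatten genuine
curvature, so the knot count is derived from the observed median spacing
(`adaptive_window()`).

Both CDA2 variants can retain the *dense* curve — the full geodesic
polyline between knots, refined and smoothed the same way — in
`dense_path`.  A live mouse stroke produces rays (hence knots) at roughly
pixel spacing; a simulated 20-point stroke does not, and a 10-vertex
polygon chord-cuts curved anatomy no matter how accurate its vertices
are.  The dense polyline is the curve at the knot density the method
actually produces in interactive use, and it is what the validation
experiment scores.

## Scoring curves: spatial divergence

`spatial_divergence()` resamples both curves to 1-voxel arc-length
spacing, measures each sample's distance to the nearest point of the
other curve (proper point-to-segment distances), and averages the two
directed means.  It reports the symmetric mean, the largest nearest-point
separation, and the fraction of samples at ≥ 2 voxels — the threshold at
which a discrepancy becomes visible on screen.  Resampling first makes
the score independent of knot density; symmetry, identity and the
closed-form parallel-offset case are asserted in the tests.

## One click, stroke or zoom: regions of interest

`roi_from_click()` pinpoints and returns the cube of side 33 voxels
(clipped, centre kept) — the default window for "zoom into what I
clicked".  Even edges split as floor-before / remainder-after, which
reduces to symmetric for the odd default.  `roi_from_stroke()` is the
clipped bounding box of the traced curve; with `cda1` it works in dark
regions too.  `roi_from_zoom()` pinpoints the four viewport corners plus
the centre (corner rays alone often miss sparse signal), boxes the
confident hits, and grows the box to a minimum 8-voxel edge; when nothing
confident is hit it falls back to the geometric frustum–volume
intersection flagged `confident = FALSE`.

## Arbitrarily large volumes: the octree pyramid

`build_octree()` stores the full-resolution stack as a directory of TIFF
tiles, then repeatedly halves every axis (2×2×2 block mean, round half
up; a max aggregator is available for sparse signal; odd dims ceil-halve
with edge blocks averaging what exists) until the coarsest level fits
512×512×256 — small enough to browse whole.  `resolve_roi()` converts a
gesture-derived box at one level into the minimal covering tile set at
another by doubling or ceil-halving coordinates; its work depends only on
the ROI size, never the total volume size, which is what makes
gesture-driven navigation of terabyte-scale stacks constant-work per
interaction.  The tests assert this by operation count, not wall-clock,
and assert bit-exact round trips of full-resolution loads.

## The phantom generator

`make_phantom()` renders tubes (straight, bent through spline control
points, helical, broken, occluded pairs) and blobs as
`background + peak * exp(-d² / 2σ²)` of the distance `d` to an analytic
centerline, plus seeded additive Gaussian noise, quantized to the target
dtype.  It emulates what matters to these algorithms about fluorescence
microscopy — tubular tracts of Gaussian cross-section over darker
background, heavy sensor noise, occluding brighter structures,
multi-channel stacks — and returns the exact centerline with every
volume so accuracy can be scored without manual annotation.  It does not
model anisotropic point-spread functions, depth-dependent attenuation,
photobleaching, or structured (non-Gaussian) noise; passing tests say
nothing about those effects.  `simulate_stroke()` projects evenly spaced
centerline points through a camera and jitters them uniformly within
±`jitter_px`, emulating hand shake.

## The validation experiment

`trace_benchmark()` fixes the study conditions once: seven tracts (one
gentle helix, six spline-bent tubes) in 56³ 8-bit volumes at peak 200
over background 20, cross-section σ 1.5, noise σ 30 (seeds 1–7); five
random viewing rotations per tract, two zooms (1 and 2), three jitter
seeds — 210 strokes of 20 points with 2-pixel jitter — traced by
`cda2_global()` at defaults (λ 10, 18-connectivity, 5-voxel smoothing)
and scored against the analytic centerlines.  Viewing rotations are
redrawn when the projected centerline is foreshortened below 60% of its
arc length or when far-apart parts of the tract project onto the same
screen location: a human cannot trace an end-on or self-occluded view, so
those are not valid gestures.  `summarize_benchmark()` reports the pooled
mean divergence, the percentage of visibly-off samples, and the average
per-curve maximum separation; `scripts/acceptance.R` recomputes all three
from scratch.  The test suite runs a 28-curve slice of the same protocol;
problem sizes throughout (56³ benchmark volumes, ≤12³ oracle volumes,
100-camera sweeps) were chosen so the whole suite stays in the
couple-of-minutes range on a laptop.

## Numerical choices and edge cases

* Degenerate strokes: a curve needs ≥ 2 rays that hit the volume; rays
  that miss are skipped, not fatal, and a fully missing stroke is an
  error.
* Equal-cost frontier ties settle in ascending `(z, y, x)` order;
  equal-brightness pinpoint ties go to the sample nearest the mean-shift
  centroid; equal-intensity channel ties to the lowest channel.
* `join_segments()` merges whenever an endpoint is within the threshold
  (inclusive — exactly 5.0 joins) of any point of another segment,
  inserting the junction into both without moving any existing knot, and
  iterates to a fixpoint.  Because an endpoint-to-interior merge creates
  a branch, the result is a list of connected components, each a set of
  curves sharing junction knots.
* Flat volumes: pinpoints are returned with `confident = FALSE`, the
  geodesic metric is Euclidean, zoom-ROIs fall back to the frustum box.
* All randomness (phantom noise, strokes, rotations) flows through
  explicit seeds; nothing reads global RNG state without restoring it.

## Known limitations

The geodesic metric assumes isotropic voxels; anisotropic voxel sizes are
carried as metadata but not folded into edge weights.  Orthographic
projection only — perspective cameras would bend shooting rays into a
frustum and are out of scope.  The brightest-half stroke preprocessing
assumes the structure is brighter than what the jittered stroke crosses;
for strokes drawn deliberately through dark gaps `cda1`'s geometric
fallback is the right tool.  On tracts whose ends fade gradually the
converged endpoint can sit a voxel or two inside the faded tip — visible
in the benchmark as per-curve maxima concentrating at curve ends.
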