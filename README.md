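# vfinger

Single 2D gestures — a mouse click, a stroke, a zoom — mapped into the 3D
space of a volumetric microscopy image: 3D points, 3D curves, and 3D
regions of interest, computed from the 2D maximum-intensity projection the
user is actually looking at.

Scrolling through slices to mark cells or trace neurites is slow and
biased; the information a biologist needs ("that bright tract, there") is
one gesture away if the inverse projection problem is solved.  `vfinger`
solves it for orthographic views of fluorescence-style data, where the
intended object is the bright structure under the cursor.  It is a
GUI-free library plus CLI: the algorithms that a 3D viewer would call
interactively, exposed as scriptable, testable functions for people who
build image-analysis pipelines and annotation tools — with a synthetic
phantom generator so every accuracy claim can be checked against analytic
ground truth.

## What is inside

* **Pinpointing (one click).** Progressive mean-shift along the shooting
  ray (`ppa_single`), independent per colour channel with a
  brightest-candidate rule (`ppa_c`), and a noise-robust micro-stroke
  variant (`ppa_n`).
* **Curve drawing (one stroke).** The image is a voxel graph with edge
  weights

  `w(u,v) = ||u − v|| · (g_I(u) + g_I(v)) / 2`,
  `g_I(x) = exp( λ_I · (1 − (I(x) − I_min)/(I_max − I_min))² )`,

  (λ_I = 10 by default, 18-connected neighbours) so bright structures
  are cheap corridors.  A C++ fast-marching engine chains shortest
  geodesics between the rays of consecutive stroke points: greedy
  range-restricted chaining (`cda1`), robust geodesic chaining (`cda2`),
  a globally optimal dynamic-programming variant over per-ray candidate
  sets (`cda2_global`), and a bounding-box-restricted search
  (`cda2_bbox`).  Curves are refined onto the local intensity centre,
  smoothed with a ~5-voxel window, editable (`drag_knot`,
  `transform_curve`), auto-joined within 5 voxels (`join_segments`), and
  scored with a resampled symmetric nearest-point metric
  (`spatial_divergence`).
* **Regions of interest (one click / stroke / zoom).** 33³ default cubes
  around a pinpoint, curve bounding boxes, and viewport-corner pinpoint
  boxes with a frustum fallback.
* **Big volumes.** A multi-resolution octree pyramid (`build_octree`:
  tiled TIFF levels, 2× downsampling per axis down to 512×512×256) with
  constant-work ROI-to-tile resolution (`resolve_roi`, `load_block`).
* **Phantoms.** Deterministic tubes, helices, blobs, occluder pairs and
  broken tracts with analytic centerlines (`make_phantom`), plus
  simulated jittered strokes (`simulate_stroke`).
* **I/O.** Multi-page TIFF / NRRD / raw+JSON volumes, SWC curves, marker
  CSV landmarks, JSON cameras/strokes/ROIs.

## Worked example

Trace a noisy synthetic tract from a simulated stroke and score the curve
against the known centerline:

```r
library(vfinger)

spec <- phantom_spec("bent-tube",
  list(control = rbind(c(8, 16, 12), c(22, 26, 20),
                       c(38, 28, 28), c(48, 38, 40))),
  peak = 200, background = 20, sigma = 1.5, noise_sigma = 30, seed = 2)
ph  <- make_phantom(spec, c(56, 56, 56))

cam    <- vf_camera(rotation_about_axis("x", pi / 3))
stroke <- simulate_stroke(ph$centerline, cam, n_points = 20,
                          jitter_px = 2, seed = 11)
curve  <- cda2_global(stroke, cam, ph$volume, keep_dense = TRUE)
curve
#> <vf_curve> 10 knots, length 57.44 voxels

sd_ <- spatial_divergence(vf_curve(curve$dense_path),
                          vf_curve(ph$centerline))
sprintf("mean SD %.3f voxels | max %.3f | visible %.2f%%",
        sd_$mean, sd_$max, 100 * sd_$fraction_visible)
#> "mean SD 0.230 voxels | max 1.331 | visible 0.00%"
```

The traced curve sits a quarter voxel from the true centerline on
average, despite 2-pixel hand jitter and noise at 15% of the peak signal.
One click does the same for a point and its default 33³ window:

```r
p   <- project_point(ph$centerline[100, ], cam)  # "click" on the tract
pin <- ppa_c(p, cam, ph$volume)
sprintf("pinpoint: (%.1f, %.1f, %.1f), intensity %g",
        pin$location[1], pin$location[2], pin$location[3], pin$intensity)
#> "pinpoint: (46.0, 33.1, 35.6), intensity 229.192"   # truth: (46, 33, 35.5)

roi_from_click(p, cam, ph$volume)
#> <vf_box3d> [30,56) x [17,50) x [20,53)
```

The same operations are available from a shell via `exec/vf`
(`vf pinpoint`, `vf curve`, `vf roi`, `vf sd`, `vf phantom`,
`vf octree build|fetch`).

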