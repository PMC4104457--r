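#' Specification of a synthetic phantom
#'
#' Deterministic generator settings for test volumes with analytic ground
#' truth: tubular tracts and blobs with Gaussian cross-sections, optional
#' occluders and gaps, additive Gaussian noise.  The same spec and seed
#' always produce a bit-identical volume.
#'
#' @param kind one of `"straight-tube"`, `"bent-tube"`, `"helix-tube"`,
#'   `"blob"`, `"two-tube-occlusion"`, `"broken-tube"`.
#' @param peak peak intensity added on top of `background` at the
#'   centerline (must exceed 0; `peak > background >= 0` is the regime all
#'   defaults assume).
#' @param background background intensity.
#' @param sigma Gaussian cross-section width (voxels), > 0.
#' @param noise_sigma additive Gaussian noise s.d. (0 = noiseless).
#' @param seed integer seed driving the noise.
#' @param geometry kind-specific parameters, see Details.
#' @param dtype output scalar kind (default 8-bit, the common confocal
#'   case).
#'
#' @details Geometry fields by kind:
#' * `straight-tube`: `from`, `to` (length-3 endpoints).
#' * `bent-tube`: `control` (k x 3 control points, interpolated with a
#'   natural cubic spline).
#' * `helix-tube`: `centre` (x, y), `radius`, `pitch` (voxels of z per
#'   turn), `z_range` (length-2).
#' * `blob`: `centre` (length-3).
#' * `two-tube-occlusion`: `target`, `occluder` (each a geometry list with
#'   its own `kind`, `peak`, and optional `gaps`); ground truth is the
#'   target centerline.
#' * `broken-tube`: as `straight-tube`/`bent-tube` plus `gaps` (list of
#'   arc-length fraction intervals where the tube signal is suppressed).
#' @return object of class `vf_phantom_spec`.
#' @export
phantom_spec <- function(kind, geometry, peak = 200, background = 20,
                         sigma = 1.5, noise_sigma = 0, seed = 1L,
                         dtype = "uint8") {
  kinds <- c("straight-tube", "bent-tube", "helix-tube", "blob",
             "two-tube-occlusion", "broken-tube")
  if (!kind %in% kinds) stop("unknown phantom kind: ", kind)
  if (!(peak > background && background >= 0))
    stop("phantom requires peak > background >= 0")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(kind = kind, geometry = geometry, peak = peak,
                 background = background, sigma = sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 dtype = dtype),
            class = "vf_phantom_spec")
}

# Dense centerline polyline (arc-length spacing ~0.5 voxel) for a geometry.
phantom_centerline <- function(kind, geometry) {
  poly <- switch(kind,
    "straight-tube" = , "broken-tube" = {
      if (!is.null(geometry$control)) spline_polyline(geometry$control)
      else rbind(geometry$from, geometry$to)
    },
    "bent-tube" = spline_polyline(geometry$control),
    "helix-tube" = {
      zr <- geometry$z_range
      n <- max(64L, ceiling((zr[2] - zr[1]) * 8))
      z <- seq(zr[1], zr[2], length.out = n)
      theta <- 2 * pi * (z - zr[1]) / geometry$pitch +
        if (is.null(geometry$phase)) 0 else geometry$phase
      cbind(geometry$centre[1] + geometry$radius * cos(theta),
            geometry$centre[2] + geometry$radius * sin(theta), z)
    },
    "blob" = matrix(geometry$centre, 1, 3),
    stop("no centerline for kind ", kind))
  if (nrow(poly) > 1L) resample_polyline(poly, 0.5) else poly
}

spline_polyline <- function(control, n = 200L) {
  control <- matrix(as.numeric(control), ncol = 3)
  if (nrow(control) < 2L) stop("need at least 2 control points")
  if (nrow(control) == 2L) return(control)
  t0 <- seq(0, 1, length.out = nrow(control))
  tt <- seq(0, 1, length.out = n)
  cbind(stats::spline(t0, control[, 1], xout = tt)$y,
        stats::spline(t0, control[, 2], xout = tt)$y,
        stats::spline(t0, control[, 3], xout = tt)$y)
}

# Per-voxel distance to a polyline, vectorized over segments.
voxel_centerline_distance <- function(dims, poly) {
  gx <- rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3])
  gy <- rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3])
  gz <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  pts <- cbind(gx, gy, gz)
  array(point_polyline_dist(pts, poly), dim = dims)
}

# Tube/blob signal field: peak * exp(-d^2 / (2 sigma^2)), with optional
# arc-length gaps where the signal is suppressed.
signal_field <- function(dims, poly, peak, sigma, gaps = NULL) {
  if (!is.null(gaps) && nrow(poly) > 1L) {
    seg <- sqrt(rowSums(diff(poly)^2))
    frac <- c(0, cumsum(seg)) / sum(seg)
    keep <- rep(TRUE, nrow(poly))
    for (gp in gaps) keep <- keep & !(frac >= gp[1] & frac <= gp[2])
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    total <- array(0, dim = dims)
    for (i in which(runs$values & runs$lengths >= 2)) {
      d <- voxel_centerline_distance(dims, poly[starts[i]:ends[i], ,
                                                drop = FALSE])
      total <- pmax(total, peak * exp(-d^2 / (2 * sigma^2)))
    }
    return(total)
  }
  d <- voxel_centerline_distance(dims, poly)
  peak * exp(-d^2 / (2 * sigma^2))
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Intensity is `background + peak * exp(-d^2 / (2 sigma^2))` where `d`
#' is the distance to the analytic centerline (or blob centre), plus
#' additive Gaussian noise drawn from the spec's seed, clipped and
#' quantized to the dtype.  The analytic centerline/centre is returned
#' with the volume so downstream accuracy can be scored exactly.
#'
#' @param spec a [phantom_spec()].
#' @param dims length-3 volume extent.
#' @return list with `volume` (a [vf_volume]), `centerline` (dense n x 3
#'   polyline, or the 1 x 3 centre for blobs) and `spec`.
#' @export
make_phantom <- function(spec, dims) {
  stopifnot(inherits(spec, "vf_phantom_spec"))
  dims <- as.integer(dims)
  if (spec$kind == "two-tube-occlusion") {
    tgt <- spec$geometry$target
    occ <- spec$geometry$occluder
    cl <- phantom_centerline(tgt$kind, tgt)
    cl_occ <- phantom_centerline(occ$kind, occ)
    check_fits(rbind(cl, cl_occ), dims)
    sig <- pmax(
      signal_field(dims, cl, tgt$peak, spec$sigma, tgt$gaps),
      signal_field(dims, cl_occ, occ$peak, spec$sigma, occ$gaps))
  } else {
    cl <- phantom_centerline(spec$kind, spec$geometry)
    check_fits(cl, dims)
    sig <- signal_field(dims, cl, spec$peak, spec$sigma,
                        spec$geometry$gaps)
  }
  img <- spec$background + sig
  if (spec$noise_sigma > 0) {
    img <- img + withr::with_seed(spec$seed,
      array(stats::rnorm(prod(dims), 0, spec$noise_sigma), dim = dims))
  }
  if (spec$dtype != "float32") {
    img <- pmin(pmax(img, 0), dtype_max(spec$dtype))
    img <- floor(img + 0.5)
  }
  list(volume = vf_volume(array(img, dim = c(dims, 1L)), dtype = spec$dtype),
       centerline = cl, spec = spec)
}

check_fits <- function(poly, dims) {
  if (any(poly < -0.5) || any(sweep(poly, 2, dims - 0.5) > 0))
    stop("phantom geometry exceeds the volume dims")
}

#' Simulate an on-screen stroke along a projected centerline
#'
#' Projects `n_points` equally spaced (by arc length) centerline points
#' through the camera and jitters each screen coordinate uniformly within
#' `+-jitter_px` pixels, emulating the shaking of a user's hand.
#' Deterministic per seed.
#'
#' @param centerline n x 3 polyline.
#' @param cam a [vf_camera].
#' @param n_points number of stroke points (>= 2).
#' @param jitter_px uniform jitter half-width in screen pixels.
#' @param seed integer seed.
#' @return a [vf_stroke].
#' @export
simulate_stroke <- function(centerline, cam, n_points = 20L, jitter_px = 0,
                            seed = 1L) {
  stopifnot(n_points >= 2L)
  len <- polyline_length(centerline)
  pts <- resample_polyline(centerline, len / (n_points - 1))
  # resample_polyline may give one extra point for non-integer ratios
  take <- round(seq(1, nrow(pts), length.out = n_points))
  proj <- t(apply(pts[take, , drop = FALSE], 1, project_point, cam = cam))
  if (jitter_px > 0) {
    jit <- withr::with_seed(seed,
      matrix(stats::runif(2 * n_points, -jitter_px, jitter_px), ncol = 2))
    proj <- proj + jit
  }
  vf_stroke(proj)
}
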