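#' A 3D curve
#'
#' Ordered 3D knots with optional provenance: `ray_index` records which
#' shooting ray of the generating stroke produced each knot (strictly
#' increasing when present), and `dense_path` optionally keeps the full
#' geodesic polyline between knots for export.
#'
#' @param knots n x 3 matrix of 3D points (n >= 1), 0-based voxel
#'   coordinates (continuous).
#' @param ray_index optional integer vector, one entry per knot.
#' @param dense_path optional m x 3 matrix.
#' @return object of class `vf_curve`.
#' @export
vf_curve <- function(knots, ray_index = NULL, dense_path = NULL) {
  knots <- matrix(as.numeric(knots), ncol = 3)
  if (nrow(knots) < 1L) stop("a curve needs at least one knot")
  if (!is.null(ray_index)) {
    ray_index <- as.integer(ray_index)
    stopifnot(length(ray_index) == nrow(knots))
    if (any(diff(ray_index) <= 0))
      stop("ray_index must be strictly increasing")
  }
  structure(list(knots = knots, ray_index = ray_index,
                 dense_path = dense_path), class = "vf_curve")
}

#' @export
print.vf_curve <- function(x, ...) {
  cat(sprintf("<vf_curve> %d knots, length %.2f voxels\n",
              nrow(x$knots), polyline_length(x$knots)))
  invisible(x)
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2)))
}

# The smoothing window is "about 5 voxels wide": when knots are ~1 voxel
# apart that is 5 knots, but for sparser knots a 5-knot average would span
# far more arc and flatten genuine curvature.  Convert the voxel width to
# an odd knot count using the median inter-knot spacing.
adaptive_window <- function(knots, window_voxels) {
  if (nrow(knots) < 3L) return(1L)
  seg <- sqrt(rowSums((knots[-1, , drop = FALSE] -
                       knots[-nrow(knots), , drop = FALSE])^2))
  spacing <- stats::median(seg[seg > 0])
  if (!is.finite(spacing) || spacing <= 0) return(1L)
  w <- round(window_voxels / spacing)
  w <- min(w, window_voxels)
  if (w %% 2 == 0) w <- w + 1
  max(1L, as.integer(w))
}

## --- stroke preprocessing --------------------------------------------------

#' Stroke preprocessing: keep the brightest half of the sampling points
#'
#' Computer mice sample unevenly and hands shake, so only the
#' `ceiling(N/2)` on-screen points whose shooting rays see the highest
#' maximum intensity are kept, in original order.  The first and last
#' points are always retained so the curve spans the whole gesture.
#'
#' @param s a [vf_stroke] with >= 2 points.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param channel channel whose ray maxima are ranked, or `NULL` for the
#'   per-sample maximum across channels.
#' @return the thinned [vf_stroke]; kept indices in attribute `"kept"`.
#' @export
preprocess_stroke <- function(s, cam, vol, channel = NULL) {
  stopifnot(inherits(s, "vf_stroke"))
  n <- nrow(s$points)
  if (n < 2L) stop("stroke preprocessing needs at least 2 points")
  rays <- lapply(seq_len(n), function(i) screen_to_ray(s$points[i, ], cam, vol))
  maxima <- vapply(rays, function(r) {
    if (r$empty) return(-Inf)
    inten <- if (is.null(channel)) apply(r$intensity, 1, max)
             else r$intensity[, channel]
    max(inten)
  }, numeric(1))
  if (all(!is.finite(maxima))) stop("empty stroke: every ray misses the volume")
  keep_n <- max(ceiling(n / 2), 2L)
  interior <- setdiff(seq_len(n), c(1L, n))
  ord <- interior[order(maxima[interior], decreasing = TRUE)]
  kept <- sort(c(1L, n, ord[seq_len(min(keep_n - 2L, length(ord)))]))
  out <- vf_stroke(s$points[kept, , drop = FALSE])
  attr(out, "kept") <- kept
  out
}

## --- ray neighbourhoods ----------------------------------------------------

# Voxels whose centre lies within 1.0 voxel of the sampled ray polyline.
ray_sink_voxels <- function(ray, dims, region_mask = NULL) {
  s <- ray$samples
  n <- nrow(s)
  if (n == 0L) return(matrix(integer(0), 0, 3))
  cand <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    base <- round(s[i, ])
    expand.grid(x = base[1] + (-1:1), y = base[2] + (-1:1),
                z = base[3] + (-1:1))
  })))
  cand <- as.matrix(cand)
  ok <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
        cand[, 2] >= 0 & cand[, 2] < dims[2] &
        cand[, 3] >= 0 & cand[, 3] < dims[3]
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  d <- point_polyline_dist(cand, s)
  cand <- cand[d <= 1.0 + 1e-9, , drop = FALSE]
  if (!is.null(region_mask) && nrow(cand) > 0L) {
    inr <- region_mask[cand[, 1] + 1 + dims[1] *
                       (cand[, 2] + dims[2] * cand[, 3])]
    cand <- cand[inr, , drop = FALSE]
  }
  cand
}

stroke_rays <- function(s, cam, vol) {
  n <- nrow(s$points)
  rays <- lapply(seq_len(n), function(i) screen_to_ray(s$points[i, ], cam, vol))
  nonempty <- which(!vapply(rays, `[[`, logical(1), "empty"))
  list(rays = rays, nonempty = nonempty)
}

ray_metric_intensity <- function(ray, params) {
  if (!is.null(params$channel)) ray$intensity[, params$channel]
  else if (ncol(ray$intensity) == 1L) ray$intensity[, 1]
  else apply(ray$intensity, 1, max)
}

## --- CDA1 ------------------------------------------------------------------

#' Range-restricted pinpoint chaining (CDA1)
#'
#' The first knot comes from multi-channel pinpointing on the first ray;
#' each subsequent knot is a mean-shift pinpoint restricted to the ray
#' samples within `range` voxels (3D distance) of the previous knot.  When
#' no sample qualifies the geometrically nearest ray sample is taken, so
#' strokes over dark regions still produce a curve (the dark-region ROI
#' use case).  Fast but sensitive to the starting point; see [cda2()] for
#' the noise-robust variant.
#'
#' @param s a [vf_stroke] with >= 2 points.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param range search range in voxels around the previous knot
#'   (default +-30).
#' @param channel optional fixed channel.
#' @return a [vf_curve] with one knot per non-empty ray.
#' @export
cda1 <- function(s, cam, vol, range = 30, channel = NULL) {
  stopifnot(inherits(s, "vf_stroke"))
  if (nrow(s$points) < 2L) stop("no curve: stroke needs at least 2 points")
  sr <- stroke_rays(s, cam, vol)
  if (length(sr$nonempty) == 0L || sr$rays[[1]]$empty)
    stop("no curve: first ray misses the volume")
  first <- ppa_c(s$points[1, ], cam, vol, channel = channel)
  ch <- first$channel
  knots <- matrix(first$location, 1)
  idx <- sr$nonempty[1]
  prev <- first$location
  for (k in sr$nonempty[-1]) {
    ray <- sr$rays[[k]]
    d <- sqrt(rowSums((ray$samples -
                       matrix(prev, nrow(ray$samples), 3, byrow = TRUE))^2))
    inr <- which(d <= range)
    if (length(inr) == 0L) {
      p <- ray$samples[which.min(d), ]
    } else {
      sub <- ray
      sub$samples <- ray$samples[inr, , drop = FALSE]
      sub$t <- ray$t[inr]
      sub$intensity <- ray$intensity[inr, , drop = FALSE]
      p <- ppa_single(sub, ch)$location
    }
    knots <- rbind(knots, p)
    idx <- c(idx, k)
    prev <- p
  }
  vf_curve(knots, ray_index = idx)
}

## --- CDA2 ------------------------------------------------------------------

#' Geodesic curve drawing (CDA2)
#'
#' For the first two rays, a single fast march between the two ray
#' neighbourhoods yields both termini at once (the globally shortest
#' geodesic between the rays).  Each later knot is the first hit-point of
#' a fast march from the previous knot to the neighbourhood of the next
#' ray.  The knot sequence is finally smoothed with a small moving window,
#' giving sub-voxel knots.  Bright voxels are cheap under the metric, so
#' the curve is drawn towards bright signal even when the on-screen stroke
#' shakes off it.
#'
#' @param s a [vf_stroke] with >= 2 points.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param params a [geodesic_params()].
#' @param region optional search region (logical array or [box3d]).
#' @param window smoothing width, in voxels of arc (about 5 by default);
#'   converted to an odd knot count from the observed knot spacing.
#' @param refine apply [refine_curve()] to the knots before smoothing.
#' @param keep_dense keep the full geodesic polyline in `dense_path`.
#' @return a [vf_curve] with one knot per non-empty ray.
#' @export
cda2 <- function(s, cam, vol, params = geodesic_params(), region = NULL,
                 window = 5L, refine = TRUE, keep_dense = FALSE) {
  stopifnot(inherits(s, "vf_stroke"))
  if (nrow(s$points) < 2L) stop("no curve: stroke needs at least 2 points")
  sr <- stroke_rays(s, cam, vol)
  ne <- sr$nonempty
  if (length(ne) < 2L) stop("no curve: fewer than 2 rays hit the volume")
  g <- metric_field(vol, params)
  mask <- region_mask(region, vol$dims)
  mask_arr <- if (length(mask)) array(mask, dim = vol$dims) else NULL
  sink_sets <- lapply(ne, function(k)
    ray_sink_voxels(sr$rays[[k]], vol$dims, mask_arr))
  for (i in seq_along(sink_sets))
    if (nrow(sink_sets[[i]]) == 0L)
      stop("no curve: ray ", ne[i], " has no searchable voxels")
  march <- function(sources, sinks, at_ray) {
    tryCatch(fast_march(sources, sinks, vol, params, region = region, g = g),
             error = function(e)
               stop("no curve at ray ", at_ray, ": ", conditionMessage(e)))
  }
  vox_key <- function(m) m[, 1] + vol$dims[1] * (m[, 2] + vol$dims[2] * m[, 3])
  # Consecutive ray neighbourhoods overlap when the on-screen points are
  # close; a zero-length path through the shared voxels would be a
  # degenerate (and arbitrarily dark) optimum, so shared voxels are kept
  # only on the sink side of the initial two-ray march.
  src1 <- sink_sets[[1]][!vox_key(sink_sets[[1]]) %in%
                         vox_key(sink_sets[[2]]), , drop = FALSE]
  visited <- 0
  if (nrow(src1) == 0L) { # nearly identical rays: brightest shared voxel
    best <- which.min(g[cbind(sink_sets[[2]] + 1)])
    knots <- sink_sets[[2]][c(best, best), , drop = FALSE]
    dense <- if (keep_dense) knots[1, , drop = FALSE] else NULL
  } else {
    p0 <- march(src1, sink_sets[[2]], ne[2])
    visited <- visited + p0$visited
    nk <- nrow(p0$voxels)
    knots <- rbind(p0$voxels[1, ], p0$voxels[nk, ])
    dense <- if (keep_dense) p0$voxels else NULL
  }
  for (i in seq_along(ne)[-(1:2)]) {
    prev <- knots[nrow(knots), ]
    snk <- sink_sets[[i]][vox_key(sink_sets[[i]]) !=
                          vox_key(matrix(prev, 1)), , drop = FALSE]
    if (nrow(snk) == 0L) { # ray neighbourhood is just the previous knot
      knots <- rbind(knots, prev)
      next
    }
    pth <- march(matrix(prev, 1), snk, ne[i])
    visited <- visited + pth$visited
    knots <- rbind(knots, pth$voxels[nrow(pth$voxels), ])
    if (keep_dense) dense <- rbind(dense, pth$voxels[-1, , drop = FALSE])
  }
  if (keep_dense)
    dense <- finish_dense(dense, vol, params, window, refine)
  crv <- vf_curve(knots, ray_index = ne, dense_path = dense)
  if (refine) crv <- refine_curve(crv, vol, params = params)
  crv <- smooth_curve(crv, window = adaptive_window(crv$knots, window))
  attr(crv, "visited") <- visited
  crv
}

# The dense curve at full (~1 voxel) knot density: the concatenated
# geodesic polyline is corrected to the local intensity centre and
# smoothed exactly like the per-ray knots.
finish_dense <- function(dense, vol, params, window, refine) {
  if (is.null(dense) || nrow(dense) < 2L) return(dense)
  dense <- dense[c(TRUE, rowSums(abs(diff(dense))) > 0), , drop = FALSE]
  crv <- vf_curve(dense)
  if (refine) crv <- refine_curve(crv, vol, params = params)
  crv <- smooth_curve(crv, window = adaptive_window(crv$knots, window))
  crv$knots
}

# Geodesic costs between candidate points of two consecutive rays, marched
# inside the bounding box of both candidate sets plus a margin.
bounded_pair_crop <- function(from_pts, to_pts, vol, g, bound_margin) {
  all_pts <- rbind(from_pts, to_pts)
  lo <- pmax(floor(apply(all_pts, 2, min)) - bound_margin, 0)
  hi <- pmin(ceiling(apply(all_pts, 2, max)) + bound_margin + 1, vol$dims)
  list(lo = lo,
       g = g[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
             drop = FALSE],
       dims = as.integer(hi - lo),
       shift = function(m) sweep(as_voxel_matrix(m), 2, as.integer(lo)))
}

bounded_pair_costs <- function(from_pts, to_pts, vol, params, g,
                               bound_margin = 10) {
  cr <- bounded_pair_crop(from_pts, to_pts, vol, g, bound_margin)
  to_sub <- cr$shift(to_pts)
  out <- matrix(Inf, nrow(from_pts), nrow(to_pts))
  for (i in seq_len(nrow(from_pts))) {
    res <- fm_march(cr$dims, as.numeric(cr$g),
                    cr$shift(from_pts[i, , drop = FALSE]),
                    to_sub, params$connectivity, logical(0), TRUE)
    out[i, ] <- res$sink_costs
  }
  out
}

bounded_pair_path <- function(from_pt, to_pt, vol, params, g,
                              bound_margin = 10) {
  from_pt <- matrix(from_pt, 1); to_pt <- matrix(to_pt, 1)
  cr <- bounded_pair_crop(from_pt, to_pt, vol, g, bound_margin)
  res <- fm_march(cr$dims, as.numeric(cr$g), cr$shift(from_pt),
                  cr$shift(to_pt), params$connectivity, logical(0), FALSE)
  if (!res$found) return(NULL)
  sweep(res$path, 2, as.integer(cr$lo), `+`)
}

#' Globally optimal CDA2
#'
#' Applies [preprocess_stroke()], selects per ray up to `m` candidate
#' points (brightest ray samples at least 2 voxels apart), computes exact
#' geodesic costs between candidates of consecutive rays by bounded fast
#' marching, and stitches the minimum-total-cost chain from the first to
#' the last ray by dynamic programming.  Unlike the greedy chaining of
#' [cda2()], a noisy bright voxel on an intermediate ray, or an inaccurate
#' first knot, cannot derail the whole curve.  `m = 1` degenerates to
#' greedy brightest-point chaining.
#'
#' @inheritParams cda2
#' @param m candidate points per ray.
#' @param bound_margin margin in voxels around each consecutive candidate
#'   pair's bounding box used to bound the marches.
#' @return a [vf_curve].
#' @export
cda2_global <- function(s, cam, vol, params = geodesic_params(), m = 5L,
                        window = 5L, refine = TRUE, keep_dense = FALSE,
                        bound_margin = 10) {
  stopifnot(inherits(s, "vf_stroke"))
  if (nrow(s$points) < 2L) stop("no curve: stroke needs at least 2 points")
  s <- preprocess_stroke(s, cam, vol, channel = params$channel)
  sr <- stroke_rays(s, cam, vol)
  ne <- sr$nonempty
  if (length(ne) < 2L) stop("no curve: fewer than 2 rays hit the volume")
  g <- metric_field(vol, params)
  cands <- lapply(ne, function(k) {
    ray <- sr$rays[[k]]
    inten <- ray_metric_intensity(ray, params)
    ord <- order(inten, decreasing = TRUE)
    picked <- integer(0)
    for (i in ord) {
      if (length(picked) >= m) break
      if (length(picked) == 0L ||
          min(sqrt(rowSums((ray$samples[picked, , drop = FALSE] -
                            matrix(ray$samples[i, ], length(picked), 3,
                                   byrow = TRUE))^2))) >= 2)
        picked <- c(picked, i)
    }
    ray$samples[picked, , drop = FALSE]
  })
  nl <- length(cands)
  # DP over layers: best[i] = min cost of a chain ending at candidate i
  best <- rep(0, nrow(cands[[1]]))
  back <- vector("list", nl)
  for (k in 2:nl) {
    tc <- bounded_pair_costs(cands[[k - 1]], cands[[k]], vol, params, g,
                             bound_margin)
    tot <- matrix(best, nrow(tc), ncol(tc)) + tc
    best <- apply(tot, 2, min)
    back[[k]] <- apply(tot, 2, which.min)
    if (all(!is.finite(best)))
      stop("no curve at ray ", ne[k],
           ": no geodesic path within the bounded search region")
  }
  chain <- integer(nl)
  chain[nl] <- which.min(best)
  for (k in nl:2) chain[k - 1] <- back[[k]][chain[k]]
  knots <- do.call(rbind, lapply(seq_len(nl),
                                 function(k) cands[[k]][chain[k], ]))
  dense <- NULL
  if (keep_dense) {
    dense <- matrix(round(knots[1, ]), 1)
    for (k in 2:nl) {
      seg <- bounded_pair_path(knots[k - 1, ], knots[k, ], vol, params, g,
                               bound_margin)
      if (!is.null(seg) && nrow(seg) > 1L)
        dense <- rbind(dense, seg[-1, , drop = FALSE])
    }
    dense <- finish_dense(dense, vol, params, window, refine)
  }
  crv <- vf_curve(knots, ray_index = ne, dense_path = dense)
  if (refine) crv <- refine_curve(crv, vol, params = params)
  crv <- smooth_curve(crv, window = adaptive_window(crv$knots, window))
  attr(crv, "total_cost") <- min(best)
  crv
}

#' Bounding-box-restricted CDA2
#'
#' Preliminary per-ray pinpoints define, for every consecutive ray pair, a
#' bounding box expanded by `margin` voxels; [cda2()] is then run with its
#' search confined to the union of those boxes, visiting a small fraction
#' of the voxels the unrestricted search would.  A margin too small to
#' connect the path raises a no-path error (the caller may enlarge it)
#' rather than returning a wrong curve.
#'
#' @inheritParams cda2
#' @param margin box expansion in voxels (default 5).
#' @return a [vf_curve] whose knots lie inside the search region.
#' @export
cda2_bbox <- function(s, cam, vol, params = geodesic_params(), margin = 5,
                      window = 5L) {
  stopifnot(inherits(s, "vf_stroke"))
  if (nrow(s$points) < 2L) stop("no curve: stroke needs at least 2 points")
  sr <- stroke_rays(s, cam, vol)
  ne <- sr$nonempty
  if (length(ne) < 2L) stop("no curve: fewer than 2 rays hit the volume")
  ch <- if (is.null(params$channel)) 1L else params$channel
  hits <- lapply(ne, function(k) {
    ray <- sr$rays[[k]]
    inten <- ray_metric_intensity(ray, params)
    sub <- ray
    sub$intensity <- matrix(inten, ncol = 1)
    ppa_single(sub, 1L)$location
  })
  mask <- array(FALSE, dim = vol$dims)
  for (i in seq_len(length(hits) - 1)) {
    lo <- pmax(floor(pmin(hits[[i]], hits[[i + 1]])) - margin, 0)
    hi <- pmin(ceiling(pmax(hits[[i]], hits[[i + 1]])) + margin,
               vol$dims - 1)
    if (any(lo > hi)) next
    mask[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
         (lo[3] + 1):(hi[3] + 1)] <- TRUE
  }
  cda2(s, cam, vol, params, region = mask, window = window)
}

## --- knot refinement -------------------------------------------------------

#' Refine curve knots to the local intensity centre
#'
#' Corrects each knot towards the intensity-weighted centroid of a small
#' ball around it (weights are local intensities minus their in-ball
#' minimum, so the correction is shift invariant), iterating a few times
#' with a capped step.  This is the per-knot optimal correction that keeps
#' stroke jitter and voxel snapping from accumulating into the curve: a
#' knot dropped within a couple of voxels of a tubular structure's axis
#' converges onto the axis.
#'
#' @param c a [vf_curve].
#' @param vol a [vf_volume].
#' @param radius ball radius in voxels.
#' @param iters refinement iterations.
#' @param params a [geodesic_params()] (designated-channel rule).
#' @return the refined [vf_curve].
#' @export
refine_curve <- function(c, vol, radius = 2, iters = 2L,
                         params = geodesic_params()) {
  stopifnot(inherits(c, "vf_curve"), inherits(vol, "vf_volume"))
  offs <- as.matrix(expand.grid(x = -radius:radius, y = -radius:radius,
                                z = -radius:radius))
  offs <- offs[sqrt(rowSums(offs^2)) <= radius + 1e-9, , drop = FALSE]
  ch <- params$channel
  arr_int <- metric_intensity(vol, params)
  ivol <- vf_volume(array(arr_int, dim = c(dim(arr_int), 1L)),
                    dtype = "float32")
  knots <- c$knots
  for (i in seq_len(nrow(knots))) {
    p <- knots[i, ]
    for (it in seq_len(iters)) {
      pts <- sweep(offs, 2, p, `+`)
      inb <- pts[, 1] > -0.5 & pts[, 1] < vol$dims[1] - 0.5 &
             pts[, 2] > -0.5 & pts[, 2] < vol$dims[2] - 0.5 &
             pts[, 3] > -0.5 & pts[, 3] < vol$dims[3] - 0.5
      if (!any(inb)) break
      w <- sample_trilinear(ivol, pts[inb, , drop = FALSE], 1L)
      w <- w - min(w)
      if (sum(w) <= 0) break
      step <- colSums(offs[inb, , drop = FALSE] * w) / sum(w)
      nrm <- sqrt(sum(step^2))
      if (nrm > 1.5) step <- step * 1.5 / nrm
      p <- p + step
      if (nrm < 0.05) break
    }
    knots[i, ] <- p
  }
  vf_curve(knots, ray_index = c$ray_index, dense_path = c$dense_path)
}

## --- smoothing and editing -------------------------------------------------

#' Moving-average curve smoothing
#'
#' Centered moving average of knot coordinates over `window` knots
#' (shrunk symmetrically near the ends); the first and last knots and the
#' knot count are unchanged.  Straight (collinear) curves are fixed points.
#'
#' @param c a [vf_curve].
#' @param window odd window width in knots, >= 1.
#' @return the smoothed [vf_curve].
#' @export
smooth_curve <- function(c, window = 5L) {
  stopifnot(inherits(c, "vf_curve"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- nrow(c$knots)
  if (window == 1L || n <= 2L) return(c)
  half <- (window - 1L) %/% 2L
  out <- c$knots
  for (i in 2:(n - 1)) {
    h <- min(half, i - 1L, n - i)
    out[i, ] <- colMeans(c$knots[(i - h):(i + h), , drop = FALSE])
  }
  vf_curve(out, ray_index = c$ray_index, dense_path = c$dense_path)
}

#' Rigid/similarity transform or mirror of a curve
#'
#' Applies `q -> scale * R %*% mirror(q) + translation` to every knot
#' exactly (knot count preserved); mirroring reflects one coordinate about
#' a plane.
#'
#' @param c a [vf_curve].
#' @param rotation 3x3 rotation matrix.
#' @param scale positive scalar zoom.
#' @param translation length-3 shift.
#' @param mirror_axis optional axis (1, 2 or 3) to reflect.
#' @param mirror_at plane position for the reflection (default 0).
#' @return the transformed [vf_curve].
#' @export
transform_curve <- function(c, rotation = diag(3), scale = 1,
                            translation = c(0, 0, 0), mirror_axis = NULL,
                            mirror_at = 0) {
  stopifnot(inherits(c, "vf_curve"), scale > 0)
  k <- c$knots
  if (!is.null(mirror_axis))
    k[, mirror_axis] <- 2 * mirror_at - k[, mirror_axis]
  k <- scale * k %*% t(rotation)
  k <- sweep(k, 2, as.numeric(translation), `+`)
  vf_curve(k, ray_index = c$ray_index)
}

#' Drag one knot and smoothly deform the neighbourhood
#'
#' The dragged knot moves by `delta`; knots within `radius` index
#' positions move by `delta` scaled with a raised-cosine falloff
#' `(1 + cos(pi * d / (radius + 1))) / 2` of the index distance `d`;
#' all other knots are unchanged.
#'
#' @param c a [vf_curve].
#' @param knot 1-based knot index to drag.
#' @param delta length-3 displacement.
#' @param radius deformation radius in knot indices (>= 0).
#' @return the deformed [vf_curve].
#' @export
drag_knot <- function(c, knot, delta, radius = 2L) {
  stopifnot(inherits(c, "vf_curve"), radius >= 0)
  n <- nrow(c$knots)
  if (knot < 1L || knot > n) stop("knot index out of range")
  out <- c$knots
  for (i in seq_len(n)) {
    d <- abs(i - knot)
    if (d > radius) next
    f <- (1 + cos(pi * d / (radius + 1))) / 2
    out[i, ] <- out[i, ] + f * as.numeric(delta)
  }
  vf_curve(out, ray_index = c$ray_index)
}

## --- auto-join -------------------------------------------------------------

# Nearest point on a polyline to p: returns list(dist, point, seg, frac).
nearest_on_polyline <- function(p, poly) {
  n <- nrow(poly)
  if (n == 1L) {
    return(list(dist = sqrt(sum((p - poly[1, ])^2)), point = poly[1, ],
                seg = 1L, frac = 0))
  }
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- matrix(p, n - 1, 3, byrow = TRUE) - a
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, pmin(pmax(rowSums(ap * ab) / len2, 0), 1), 0)
  proj <- a + ab * t
  d <- sqrt(rowSums((matrix(p, n - 1, 3, byrow = TRUE) - proj)^2))
  i <- which.min(d)
  list(dist = d[i], point = proj[i, ], seg = i, frac = t[i])
}

#' Automatically join nearby curve segments
#'
#' Whenever an endpoint of one segment lies within `threshold` voxels
#' (inclusive) of any point of another segment, the two are connected at
#' the nearest point: the junction point is appended to the endpoint's
#' segment and, if it falls strictly inside an edge of the other segment,
#' inserted there as a new knot.  No existing knot ever moves.  Merging
#' repeats to a fixpoint; the default 5-voxel threshold matches the
#' proof-editing auto-join used when patching traced neuron segments.
#'
#' @param segments list of [vf_curve] objects.
#' @param threshold join distance in voxels (inclusive).
#' @return list of connected components; each component is a list with
#'   `curves` (the member segments, junctions inserted) and `joins`
#'   (matrix of junction points).
#' @export
join_segments <- function(segments, threshold = 5) {
  stopifnot(threshold >= 0)
  if (inherits(segments, "vf_curve")) segments <- list(segments)
  curves <- lapply(segments, function(s) s$knots)
  comp <- seq_along(curves)
  joins <- matrix(numeric(0), 0, 3)
  repeat {
    merged <- FALSE
    for (i in seq_along(curves)) {
      ends <- curves[[i]][c(1, nrow(curves[[i]])), , drop = FALSE]
      for (e in 1:2) {
        for (j in seq_along(curves)) {
          if (comp[j] == comp[i]) next
          np <- nearest_on_polyline(ends[e, ], curves[[j]])
          if (np$dist <= threshold + 1e-12) {
            # append the junction to segment i's endpoint ...
            if (np$dist > 1e-12) {
              curves[[i]] <- if (e == 1L) rbind(np$point, curves[[i]])
                             else rbind(curves[[i]], np$point)
            }
            # ... and insert it into segment j if strictly inside an edge
            if (np$frac > 1e-9 && np$frac < 1 - 1e-9) {
              curves[[j]] <- rbind(
                curves[[j]][seq_len(np$seg), , drop = FALSE],
                np$point,
                curves[[j]][-seq_len(np$seg), , drop = FALSE])
            }
            joins <- rbind(joins, np$point)
            comp[comp == comp[j]] <- comp[i]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  lapply(unique(comp), function(cc) {
    list(curves = lapply(which(comp == cc), function(i) vf_curve(curves[[i]])),
         joins = joins)
  })
}

## --- spatial divergence ----------------------------------------------------

#' Resample a polyline at fixed arc-length spacing
#'
#' @param p n x 3 matrix.
#' @param spacing target spacing in voxels.
#' @return m x 3 matrix including both endpoints, spacing <= `spacing`.
#' @export
resample_polyline <- function(p, spacing = 1) {
  p <- matrix(as.numeric(p), ncol = 3)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  len <- sum(seg)
  if (len <= 0) stop("degenerate (zero-length) curve")
  n <- max(2L, as.integer(floor(len / spacing)) + 1L)
  s_targets <- seq(0, len, length.out = n)
  cum <- c(0, cumsum(seg))
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- s_targets[i]
    k <- max(which(cum <= s + 1e-12))
    if (k >= length(cum)) { out[i, ] <- p[nrow(p), ]; next }
    f <- if (seg[k] > 0) (s - cum[k]) / seg[k] else 0
    out[i, ] <- p[k, ] + f * (p[k + 1, ] - p[k, ])
  }
  out
}

# Distance from each row of pts to the nearest point of polyline poly.
point_polyline_dist <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  poly <- matrix(as.numeric(poly), ncol = 3)
  n <- nrow(poly)
  if (n == 1L)
    return(sqrt(rowSums((pts - matrix(poly, nrow(pts), 3, byrow = TRUE))^2)))
  a <- poly[-n, , drop = FALSE]
  ab <- poly[-1, , drop = FALSE] - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  best <- rep(Inf, nrow(pts))
  for (k in seq_len(n - 1)) {
    ap <- sweep(pts, 2, a[k, ])
    t <- pmin(pmax((ap %*% ab[k, ]) / len2[k], 0), 1)
    dvec <- ap - outer(as.numeric(t), ab[k, ])
    best <- pmin(best, rowSums(dvec^2))
  }
  sqrt(best)
}

#' Spatial divergence between two curves
#'
#' Both curves are resampled to 1-voxel arc-length spacing; the mean
#' nearest-point distance from each sample of one curve to the other is
#' computed in both directions and averaged (a symmetric premetric).
#' `max` is the largest nearest-point distance in either direction and
#' `fraction_visible` the fraction of samples whose distance is at least
#' 2 voxels — the threshold at which a divergence becomes visible on
#' screen.
#'
#' @param a,b [vf_curve] objects (or n x 3 matrices) with >= 2 knots and
#'   nonzero length.
#' @param spacing resampling spacing (voxels).
#' @param visible_at distance at which a divergence counts as visible.
#' @return list with `mean`, `max` (voxels) and `fraction_visible`.
#' @export
spatial_divergence <- function(a, b, spacing = 1, visible_at = 2) {
  ka <- if (inherits(a, "vf_curve")) a$knots else a
  kb <- if (inherits(b, "vf_curve")) b$knots else b
  if (nrow(ka) < 2L || nrow(kb) < 2L)
    stop("spatial divergence needs curves with at least 2 knots")
  ra <- resample_polyline(ka, spacing)
  rb <- resample_polyline(kb, spacing)
  dab <- point_polyline_dist(ra, rb)
  dba <- point_polyline_dist(rb, ra)
  list(mean = (mean(dab) + mean(dba)) / 2,
       max = max(dab, dba),
       fraction_visible = mean(c(dab, dba) >= visible_at))
}

## --- SWC I/O ---------------------------------------------------------------

#' Read and write curves as SWC
#'
#' Each curve is stored as a chain of SWC nodes with parent links (one
#' tree per curve); the radius column is 1.0 unless supplied.  Coordinates
#' are written as stored (0-based voxel-centered).  Reading splits the
#' node set into maximal unbranched chains.
#'
#' @param curves a [vf_curve] or list of them.
#' @param path SWC file path.
#' @param radius radius column value(s).
#' @return `write_swc`: `path` invisibly; `read_swc`: list of [vf_curve].
#' @export
write_swc <- function(curves, path, radius = 1) {
  if (inherits(curves, "vf_curve")) curves <- list(curves)
  rows <- character(0)
  id <- 0L
  for (crv in curves) {
    k <- crv$knots
    for (i in seq_len(nrow(k))) {
      id <- id + 1L
      parent <- if (i == 1L) -1L else id - 1L
      rows <- c(rows, sprintf("%d 3 %.6f %.6f %.6f %.3f %d",
                              id, k[i, 1], k[i, 2], k[i, 3], radius, parent))
    }
  }
  writeLines(c("# generated by vfinger", "# n type x y z radius parent",
               rows), path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (length(ln) == 0L) return(list())
  m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), as.numeric))
  ids <- m[, 1]; parents <- m[, 7]
  kids <- table(factor(parents[parents > 0], levels = ids))
  starts <- which(parents <= 0 | !(parents %in% ids) |
                  kids[match(parents, ids)] > 1)
  curves <- list()
  used <- rep(FALSE, nrow(m))
  for (s0 in starts) {
    chain <- s0
    repeat {
      nxt <- which(parents == ids[chain[length(chain)]] & !used)
      if (length(nxt) != 1L) break
      if (kids[match(ids[chain[length(chain)]], ids)] > 1) break
      chain <- c(chain, nxt)
    }
    used[chain] <- TRUE
    if (length(chain) >= 1L)
      curves[[length(curves) + 1L]] <- vf_curve(m[chain, 3:5, drop = FALSE])
  }
  curves
}
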