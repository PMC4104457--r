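#' Half-open 3D box
#'
#' Integer voxel box `[min, max)` per axis; the container for every region
#' of interest the gesture methods produce.
#'
#' @param min_corner,max_corner length-3 integer corners, `min < max` on
#'   every axis.
#' @return object of class `vf_box3d`.
#' @export
box3d <- function(min_corner, max_corner) {
  min_corner <- as.integer(round(min_corner))
  max_corner <- as.integer(round(max_corner))
  if (any(min_corner >= max_corner))
    stop("box must satisfy min < max on every axis")
  structure(list(min = min_corner, max = max_corner), class = "vf_box3d")
}

#' @export
print.vf_box3d <- function(x, ...) {
  cat(sprintf("<vf_box3d> [%s) x [%s) x [%s)\n",
              paste(x$min[1], x$max[1], sep = ","),
              paste(x$min[2], x$max[2], sep = ","),
              paste(x$min[3], x$max[3], sep = ",")))
  invisible(x)
}

#' @rdname box3d
#' @param box a [box3d].
#' @export
box_dims <- function(box) box$max - box$min

clip_box <- function(lo, hi, dims) {
  lo <- pmax(pmin(lo, dims - 1), 0)
  hi <- pmin(pmax(hi, lo + 1), dims)
  box3d(lo, hi)
}

# Cube of side `edge` centered at voxel `centre`: floor(edge/2) voxels
# before the centre voxel, the remainder after (symmetric for odd edges).
cube_at <- function(centre, edge, dims) {
  centre <- round(centre)
  lo <- centre - floor(edge / 2)
  clip_box(lo, lo + edge, dims)
}

#' One-click 3D region of interest
#'
#' Pinpoints the clicked location (multi-channel pinpoint, or the
#' noise-robust micro-stroke variant when `stroke` is supplied) and
#' returns the cube of side `edge` voxels centered on it, clipped to the
#' volume.  The default 33-voxel cube is the size normally used when
#' zooming into a clicked structure.
#'
#' @param p length-2 screen point (ignored when `stroke` is given).
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param edge cube side in voxels (>= 1).
#' @param stroke optional short [vf_stroke] for noise-robust pinpointing.
#' @param params a [geodesic_params()] (used with `stroke`).
#' @return a [box3d], always containing the pinpointed centre.
#' @export
roi_from_click <- function(p, cam, vol, edge = 33L, stroke = NULL,
                           params = geodesic_params()) {
  stopifnot(edge >= 1)
  pin <- if (!is.null(stroke)) ppa_n(stroke, cam, vol, params)
         else ppa_c(p, cam, vol)
  cube_at(pin$location, as.integer(edge), vol$dims)
}

#' One-stroke 3D region of interest
#'
#' Generates a 3D curve from the stroke and returns the clipped
#' axis-aligned bounding box of its knots.  With the default `algo =
#' "cda1"` a stroke across a dark region still produces a box around the
#' geometric stroke path (the dark-region fallback); `"cda2"` snaps the
#' box to bright signal.
#'
#' @param s a [vf_stroke] with >= 2 points.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param algo `"cda1"` or `"cda2"`.
#' @param params a [geodesic_params()] (for `"cda2"`).
#' @return a [box3d] containing every curve knot.
#' @export
roi_from_stroke <- function(s, cam, vol, algo = c("cda1", "cda2"),
                            params = geodesic_params()) {
  algo <- match.arg(algo)
  crv <- if (algo == "cda1") cda1(s, cam, vol) else cda2(s, cam, vol, params)
  lo <- floor(apply(crv$knots, 2, min))
  hi <- floor(apply(crv$knots, 2, max)) + 1
  clip_box(lo, hi, vol$dims)
}

#' One-zoom 3D region of interest
#'
#' Applies multi-channel pinpointing to the shooting rays of the four
#' viewport corners plus the viewport centre (the centre ray makes the
#' estimate robust when corner rays graze sparse signal) and returns the
#' clipped bounding box of the pinpointed locations, expanded to a minimum
#' edge of `min_edge` voxels.  When every ray misses the volume or sees
#' only flat intensity, the geometric frustum-volume intersection box is
#' returned with attribute `confident = FALSE`.
#'
#' @param viewport 4 x 2 matrix of distinct corner screen points.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param min_edge minimum box edge in voxels.
#' @return a [box3d]; attribute `"confident"` is `FALSE` on fallback.
#' @export
roi_from_zoom <- function(viewport, cam, vol, min_edge = 8L) {
  viewport <- matrix(as.numeric(viewport), ncol = 2)
  if (nrow(viewport) != 4L) stop("viewport needs exactly 4 corners")
  if (qr(cbind(viewport - matrix(colMeans(viewport), 4, 2,
                                 byrow = TRUE)))$rank < 2)
    stop("degenerate viewport: corners are collinear")
  centre <- colMeans(viewport)
  pts <- rbind(viewport, centre)
  locs <- list()
  for (i in seq_len(nrow(pts))) {
    pin <- tryCatch(ppa_c(pts[i, ], cam, vol), error = function(e) NULL)
    if (!is.null(pin) && pin$confident)
      locs[[length(locs) + 1L]] <- pin$location
  }
  if (length(locs) == 0L) {
    # frustum fallback: clip every in-volume ray sample of the corners
    samp <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
      r <- screen_to_ray(pts[i, ], cam, vol)
      r$samples
    }))
    if (is.null(samp) || nrow(samp) == 0L)
      stop("zoom region misses the volume entirely")
    box <- clip_box(floor(apply(samp, 2, min)),
                    floor(apply(samp, 2, max)) + 1, vol$dims)
    attr(box, "confident") <- FALSE
    return(box)
  }
  locs <- do.call(rbind, locs)
  lo <- floor(apply(locs, 2, min))
  hi <- floor(apply(locs, 2, max)) + 1
  # grow to the minimum edge, symmetrically, before clipping
  for (a in 1:3) {
    short <- min_edge - (hi[a] - lo[a])
    if (short > 0) {
      lo[a] <- lo[a] - floor(short / 2)
      hi[a] <- hi[a] + ceiling(short / 2)
    }
  }
  box <- clip_box(lo, hi, vol$dims)
  attr(box, "confident") <- TRUE
  box
}

#' Serialize a box as JSON
#'
#' Format: `{min: [x,y,z], max: [x,y,z]}`.
#'
#' @param box a [box3d].
#' @param path JSON path.
#' @return `path` invisibly / the read [box3d].
#' @export
write_roi <- function(box, path) {
  jsonlite::write_json(list(min = box$min, max = box$max), path)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  box3d(j$min, j$max)
}
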