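#' One-click 3D pinpointing along a shooting ray
#'
#' Progressive mean-shift along the sampled ray: the search window starts
#' as the whole sampled segment; each iteration moves the window centre to
#' the intensity-weighted centroid of the samples inside it and halves the
#' window length, until the centroid moves less than 0.5 voxel or the
#' window covers at most 3 samples.  The returned location is the
#' brightest sample inside the final window (ties resolved towards the
#' centroid), snapped to the ray's 1-voxel sample grid.  Centroid weights
#' are the in-window intensities minus their minimum, which keeps the
#' scheme invariant under affine intensity rescaling `a*I + b` (a > 0).
#'
#' @param ray a [screen_to_ray()] result with at least one sample.
#' @param channel 1-based channel index.
#' @return object of class `vf_pinpoint`: `location` (length-3, on the
#'   ray), `channel`, `intensity` (raw value at the location), `confident`
#'   (`FALSE` when all ray samples are equal), `sample_index`.
#' @export
ppa_single <- function(ray, channel = 1L) {
  stopifnot(inherits(ray, "vf_ray"))
  n <- nrow(ray$samples)
  if (n == 0L) stop("no point: ray has no in-volume samples")
  w_all <- ray$intensity[, channel]
  flat <- (max(w_all) - min(w_all)) < 1e-12
  t <- seq_len(n) # window coordinates are sample indices (1-voxel spacing)
  lo <- 1; hi <- n
  centre <- (lo + hi) / 2
  repeat {
    inw <- which(t >= lo & t <= hi)
    w <- w_all[inw] - min(w_all[inw])
    new_centre <- if (sum(w) > 0) sum(w * t[inw]) / sum(w)
                  else (lo + hi) / 2
    moved <- abs(new_centre - centre)
    centre <- new_centre
    half <- (hi - lo) / 4 # halve the window length, recentred
    lo <- max(1, centre - half); hi <- min(n, centre + half)
    if (moved < 0.5 || sum(t >= lo & t <= hi) <= 3L) break
  }
  inw <- which(t >= lo & t <= hi)
  if (length(inw) == 0L) inw <- which.min(abs(t - centre))
  best_val <- max(w_all[inw])
  cand <- inw[w_all[inw] >= best_val - 1e-12]
  best <- cand[which.min(abs(t[cand] - centre))]
  structure(list(location = as.numeric(ray$samples[best, ]),
                 channel = as.integer(channel),
                 intensity = w_all[best],
                 confident = !flat,
                 sample_index = best),
            class = "vf_pinpoint")
}

#' Multi-channel one-click pinpointing
#'
#' Runs the mean-shift pinpoint independently on every colour channel of
#' the ray through the clicked screen point and returns the candidate with
#' the brightest raw voxel intensity (ties go to the lowest channel
#' index).  A user-fixed channel bypasses the cross-channel comparison.
#' With `normalized = TRUE` candidates are compared on per-channel
#' min-max-normalized intensities instead of raw values.
#'
#' @param p length-2 screen point.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param channel optional fixed 1-based channel.
#' @param normalized compare candidates on normalized intensities.
#' @return a `vf_pinpoint` (see [ppa_single()]).
#' @export
ppa_c <- function(p, cam, vol, channel = NULL, normalized = FALSE) {
  ray <- screen_to_ray(p, cam, vol)
  if (ray$empty) stop("no point: ray misses the volume")
  if (!is.null(channel)) return(ppa_single(ray, channel))
  cands <- lapply(seq_len(vol$channels), function(ch) ppa_single(ray, ch))
  score <- vapply(seq_along(cands), function(i) {
    if (!normalized) return(cands[[i]]$intensity)
    r <- intensity_range(vol, i)
    if (r$i_max <= r$i_min) return(0)
    (cands[[i]]$intensity - r$i_min) / (r$i_max - r$i_min)
  }, numeric(1))
  cands[[which.max(score)]] # which.max takes the first (lowest channel) tie
}

#' Noise-robust pinpointing from a micro-stroke
#'
#' For noisy images a single ray is unreliable; a very short stroke around
#' the click location is turned into a curve with the globally optimal
#' geodesic curve drawer and the first curve knot is returned as the
#' pinpointed location.  The global variant is what buys the robustness:
#' an isolated pair of bright noise voxels can fool a single two-ray
#' march, but a chain that must run through every ray of the micro-stroke
#' at minimum total cost cannot follow noise that does not line up across
#' rays.  A one-point stroke falls back to [ppa_c()].
#'
#' @param short_stroke a [vf_stroke] (>= 1 point).
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @param params a [geodesic_params()].
#' @return a `vf_pinpoint`.
#' @export
ppa_n <- function(short_stroke, cam, vol, params = geodesic_params()) {
  stopifnot(inherits(short_stroke, "vf_stroke"))
  if (nrow(short_stroke$points) < 2L)
    return(ppa_c(short_stroke$points[1, ], cam, vol))
  crv <- cda2_global(short_stroke, cam, vol, params)
  # converge the local mean shift at the returned point: averages the
  # noise out of the final location the same way ppa_single converges
  # its search window
  first <- vf_curve(crv$knots[1:2, , drop = FALSE])
  loc <- refine_curve(first, vol, radius = 3, iters = 10L,
                      params = params)$knots[1, ]
  ch <- if (is.null(params$channel)) 1L else params$channel
  structure(list(location = as.numeric(loc), channel = as.integer(ch),
                 intensity = sample_trilinear(vol, matrix(loc, 1), ch),
                 confident = TRUE, sample_index = NA_integer_),
            class = "vf_pinpoint")
}

#' Export landmarks as a marker CSV
#'
#' Writes rows `x,y,z,radius,channel,name`.  Coordinates are 1-based on
#' export (Vaa3D marker convention); everything inside this package is
#' 0-based.
#'
#' @param points list of `vf_pinpoint` objects or an n x 3 matrix.
#' @param path output CSV path.
#' @param radius marker radius column value.
#' @return `path`, invisibly.
#' @export
write_markers <- function(points, path, radius = 1) {
  if (inherits(points, "vf_pinpoint")) points <- list(points)
  if (is.list(points)) {
    xyz <- do.call(rbind, lapply(points, function(p) p$location))
    ch <- vapply(points, function(p) p$channel, integer(1))
  } else {
    xyz <- matrix(points, ncol = 3)
    ch <- rep(1L, nrow(xyz))
  }
  df <- data.frame(x = xyz[, 1] + 1, y = xyz[, 2] + 1, z = xyz[, 3] + 1,
                   radius = radius, channel = ch,
                   name = paste0("marker_", seq_len(nrow(xyz))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
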