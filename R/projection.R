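#' Orthographic camera
#'
#' Describes the view used to render a volume on screen.  The rotation
#' matrix rows are the screen axes and view direction expressed in volume
#' coordinates: row 1 = screen x (rightwards), row 2 = screen y (downwards,
#' top-left origin), row 3 = view direction (into the screen).  A 3D point
#' `q` appears on screen at `zoom * (R q)[1:2] + pan`; shooting rays travel
#' along row 3.  Projection is orthographic: all rays of one view are
#' parallel.
#'
#' @param rotation 3x3 orthonormal matrix (checked to 1e-9).
#' @param zoom screen pixels per voxel, > 0.
#' @param pan length-2 screen offset in pixels.
#' @return object of class `vf_camera`.
#' @export
vf_camera <- function(rotation = diag(3), zoom = 1, pan = c(0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("camera rotation must be orthonormal")
  if (zoom <= 0) stop("camera zoom must be positive")
  stopifnot(length(pan) == 2L)
  structure(list(rotation = rotation, zoom = as.numeric(zoom),
                 pan = as.numeric(pan)), class = "vf_camera")
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, 3, byrow = TRUE),
    y = matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, 3, byrow = TRUE),
    z = matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

#' Uniformly random rotation matrix
#'
#' QR-based Haar-ish sampling, determinant forced to +1; deterministic for
#' a given seed.
#'
#' @param seed integer seed.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    t(q)
  })
}

#' A 2D mouse stroke
#'
#' Ordered screen coordinates (pixels, top-left origin) sampled from one
#' gesture.
#'
#' @param points n x 2 matrix (n >= 1) of finite screen coordinates.
#' @return object of class `vf_stroke`.
#' @export
vf_stroke <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 1L) stop("a stroke needs at least one point")
  if (!all(is.finite(points))) stop("stroke coordinates must be finite")
  structure(list(points = points), class = "vf_stroke")
}

#' Project a 3D point onto the screen
#'
#' @param q length-3 point in volume coordinates.
#' @param cam a [vf_camera].
#' @return length-2 screen point.
#' @export
project_point <- function(q, cam) {
  stopifnot(inherits(cam, "vf_camera"))
  as.numeric(cam$zoom * (cam$rotation[1:2, ] %*% as.numeric(q)) + cam$pan)
}

#' Cast a shooting ray through a screen point
#'
#' Generates the ray orthogonal to the screen through the 2D point `p`,
#' clips it to the volume box `[-0.5, dim-0.5]` per axis, and samples it at
#' exactly 1-voxel spacing front to back (samples centered within the
#' clipped segment).  Per-channel intensities are trilinear.  A ray that
#' misses the volume is returned with zero samples and `empty = TRUE`
#' rather than raising; curve drawing treats it as a skip.
#'
#' @param p length-2 screen point.
#' @param cam a [vf_camera].
#' @param vol a [vf_volume].
#' @return object of class `vf_ray`: `origin`, `direction` (unit),
#'   `samples` (n x 3), `t` (depth along the ray), `intensity` (n x C),
#'   `empty`.
#' @export
screen_to_ray <- function(p, cam, vol) {
  stopifnot(inherits(cam, "vf_camera"), inherits(vol, "vf_volume"))
  ab <- (as.numeric(p) - cam$pan) / cam$zoom
  u <- cam$rotation[1, ]; v <- cam$rotation[2, ]; w <- cam$rotation[3, ]
  q0 <- ab[1] * u + ab[2] * v
  lo <- rep(-0.5, 3); hi <- vol$dims - 0.5
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(w[a]) < 1e-12) {
      if (q0[a] < lo[a] || q0[a] > hi[a]) { t0 <- Inf; break }
    } else {
      ta <- (lo[a] - q0[a]) / w[a]; tb <- (hi[a] - q0[a]) / w[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  empty <- !is.finite(t0) || t0 > t1 + 1e-12
  if (empty) {
    return(structure(list(origin = q0, direction = w,
                          samples = matrix(0, 0, 3), t = numeric(0),
                          intensity = matrix(0, 0, vol$channels),
                          empty = TRUE), class = "vf_ray"))
  }
  len <- t1 - t0
  n <- max(1L, as.integer(floor(len + 1e-9)))
  ts <- t0 + (len - (n - 1)) / 2 + seq_len(n) - 1
  samples <- outer(ts, w) + rep(q0, each = n)
  intensity <- vapply(seq_len(vol$channels),
                      function(ch) sample_trilinear(vol, samples, ch),
                      numeric(n))
  intensity <- matrix(intensity, nrow = n)
  structure(list(origin = q0 + t0 * w, direction = w, samples = samples,
                 t = ts, intensity = intensity, empty = FALSE),
            class = "vf_ray")
}

#' Render a maximum intensity projection
#'
#' Casts one shooting ray per output pixel and records the per-channel
#' maximum sampled intensity; pixels whose rays miss the volume are 0.
#' This is the rendering model the gesture algorithms assume the user is
#' looking at.
#'
#' @param vol a [vf_volume].
#' @param cam a [vf_camera].
#' @param size length-2 output extent (width, height) in pixels.
#' @return `width x height x C` numeric array.
#' @export
render_mip <- function(vol, cam, size) {
  stopifnot(all(size >= 1))
  w <- as.integer(size[1]); h <- as.integer(size[2])
  out <- array(0, dim = c(w, h, vol$channels))
  for (j in seq_len(h)) {
    for (i in seq_len(w)) {
      ray <- screen_to_ray(c(i - 1, j - 1), cam, vol)
      if (!ray$empty)
        out[i, j, ] <- apply(ray$intensity, 2, max)
    }
  }
  out
}

## --- JSON serialization ----------------------------------------------------

#' Read/write cameras and strokes as JSON
#'
#' Cameras serialize as `{rotation: 9 floats row-major, zoom, pan}`,
#' strokes as `{points: [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @param cam,stroke objects to write.
#' @return the read object, or `path` invisibly for writers.
#' @export
read_camera <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vf_camera(matrix(j$rotation, 3, 3, byrow = TRUE), j$zoom, j$pan)
}

#' @rdname read_camera
#' @export
write_camera <- function(cam, path) {
  jsonlite::write_json(list(rotation = as.vector(t(cam$rotation)),
                            zoom = cam$zoom, pan = cam$pan),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_camera
#' @export
read_stroke <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vf_stroke(matrix(as.numeric(j$points), ncol = 2))
}

#' @rdname read_camera
#' @export
write_stroke <- function(stroke, path) {
  jsonlite::write_json(list(points = stroke$points), path, digits = NA)
  invisible(path)
}
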