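#' Geodesic metric parameters
#'
#' Parameters of the intensity-weighted voxel-graph metric used by curve
#' drawing.  `lambda_i` controls how strongly dim voxels are penalized
#' (default 10); `connectivity` selects which voxel pairs count as
#' neighbours: 6 (faces), 18 (faces + edges, the default) or 26
#' (faces + edges + corners).
#'
#' @param lambda_i nonnegative intensity weighting factor.
#' @param connectivity one of 6, 18, 26.
#' @param channel channel the metric reads, or `NULL` for the per-voxel
#'   maximum across channels (what a MIP viewer shows).
#' @return object of class `vf_geodesic_params`.
#' @export
geodesic_params <- function(lambda_i = 10, connectivity = 18L,
                            channel = NULL) {
  if (lambda_i < 0) stop("lambda_i must be nonnegative")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(lambda_i = as.numeric(lambda_i),
                 connectivity = as.integer(connectivity),
                 channel = channel),
            class = "vf_geodesic_params")
}

#' Intensity penalty g_I
#'
#' `g_I(i) = exp(lambda_i * (1 - (i - i_min)/(i_max - i_min))^2)`: 1 at the
#' image maximum, `exp(lambda_i)` at the minimum, strictly decreasing in
#' `i`.  A flat image (`i_min == i_max`) is treated as fully bright
#' (`g_I = 1`), so the metric degrades gracefully to Euclidean.
#'
#' @param i intensity value(s).
#' @param r intensity range, as from [intensity_range()].
#' @param params a [geodesic_params()].
#' @return numeric penalty value(s), >= 1.
#' @export
g_intensity <- function(i, r, params = geodesic_params()) {
  if (r$i_max <= r$i_min) return(rep(1, length(i)))
  norm <- (i - r$i_min) / (r$i_max - r$i_min)
  exp(params$lambda_i * (1 - norm)^2)
}

#' Edge weight between neighbouring voxels
#'
#' `||u - v|| * (g_I(I(u)) + g_I(I(v))) / 2`: the Euclidean step length
#' scaled by the mean endpoint intensity penalty.  Symmetric in its
#' arguments; equals the plain Euclidean distance when both voxels sit at
#' the image maximum.
#'
#' @param u,v length-3 integer voxel coordinates, neighbours under
#'   `params$connectivity`.
#' @param vol a [vf_volume].
#' @param params a [geodesic_params()].
#' @return scalar edge weight.
#' @export
edge_weight <- function(u, v, vol, params = geodesic_params()) {
  u <- as.integer(u); v <- as.integer(v)
  d <- v - u
  m <- sum(abs(d))
  ok <- all(abs(d) <= 1) && m >= 1 &&
    m <= switch(as.character(params$connectivity), "6" = 1, "18" = 2,
                "26" = 3)
  if (!ok) stop("voxels are not neighbours under ", params$connectivity,
                "-connectivity")
  g <- metric_field(vol, params)
  r <- list(i_min = attr(g, "i_min"), i_max = attr(g, "i_max"))
  gi <- function(p) g[p[1] + 1, p[2] + 1, p[3] + 1]
  sqrt(sum(d^2)) * (gi(u) + gi(v)) / 2
}

# Designated-channel intensity volume and its g_I field, cached on the
# volume's environment would be overkill; recomputed per call site that
# needs it (cheap relative to the marches it feeds).
metric_intensity <- function(vol, params) {
  ch <- params$channel
  if (!is.null(ch)) {
    arr <- vol$data[, , , ch]
  } else if (vol$channels == 1L) {
    arr <- vol$data[, , , 1]
  } else {
    arr <- apply(vol$data, 1:3, max)
  }
  if (is.null(dim(arr))) dim(arr) <- vol$dims
  arr
}

metric_field <- function(vol, params) {
  arr <- metric_intensity(vol, params)
  i_min <- min(arr); i_max <- max(arr)
  g <- if (i_max <= i_min) array(1, dim = dim(arr))
       else exp(params$lambda_i * (1 - (arr - i_min) / (i_max - i_min))^2)
  attr(g, "i_min") <- i_min
  attr(g, "i_max") <- i_max
  g
}

as_voxel_matrix <- function(x) {
  x <- round(matrix(as.numeric(x), ncol = 3))
  storage.mode(x) <- "integer"
  x
}

#' Multi-source, multi-sink geodesic shortest path
#'
#' Best-first wavefront propagation from a set of source voxels until the
#' first sink voxel is settled (the "first hit-point"), on the implicit
#' voxel graph under the intensity-weighted metric.  Cost-equivalent to an
#' explicit-graph shortest-path search; ties on the frontier are broken by
#' ascending (z, y, x) order so results are deterministic across
#' platforms.  An optional region mask confines the search.
#'
#' @param sources,sinks n x 3 matrices of 0-based voxel coordinates
#'   (continuous inputs are rounded to the grid).
#' @param vol a [vf_volume].
#' @param params a [geodesic_params()].
#' @param region optional logical array of `vol$dims` (TRUE = searchable),
#'   or a [box3d] restricting the search.
#' @param g optional precomputed penalty field from an earlier call, to
#'   amortize across many marches on one volume.
#' @return object of class `vf_geodesic_path`: `voxels` (k x 3, source to
#'   sink, consecutive rows neighbours), `cost` (total accumulated edge
#'   weight).
#' @export
fast_march <- function(sources, sinks, vol, params = geodesic_params(),
                       region = NULL, g = NULL) {
  stopifnot(inherits(vol, "vf_volume"))
  sources <- as_voxel_matrix(sources)
  sinks <- as_voxel_matrix(sinks)
  if (nrow(sources) == 0L || nrow(sinks) == 0L)
    stop("sources and sinks must be nonempty")
  keep_in <- function(m) m[m[, 1] >= 0 & m[, 1] < vol$dims[1] &
                           m[, 2] >= 0 & m[, 2] < vol$dims[2] &
                           m[, 3] >= 0 & m[, 3] < vol$dims[3], , drop = FALSE]
  sources <- keep_in(sources); sinks <- keep_in(sinks)
  if (nrow(sources) == 0L || nrow(sinks) == 0L)
    stop("sources and sinks must intersect the volume")
  if (is.null(g)) g <- metric_field(vol, params)
  mask <- region_mask(region, vol$dims)
  res <- fm_march(as.integer(vol$dims), as.numeric(g), sources, sinks,
                  params$connectivity, mask, FALSE)
  if (!res$found)
    stop("no path: sinks unreachable from sources",
         if (!is.null(region)) " within the search region" else "")
  structure(list(voxels = res$path, cost = res$cost,
                 visited = res$visited),
            class = "vf_geodesic_path")
}

# Costs from a source set to every sink voxel (full Dijkstra until all
# sinks settle); used by the globally optimal curve variant.
fast_march_costs <- function(sources, sinks, vol, params, region = NULL,
                             g = NULL) {
  sources <- as_voxel_matrix(sources)
  sinks <- as_voxel_matrix(sinks)
  if (is.null(g)) g <- metric_field(vol, params)
  mask <- region_mask(region, vol$dims)
  res <- fm_march(as.integer(vol$dims), as.numeric(g), sources, sinks,
                  params$connectivity, mask, TRUE)
  res$sink_costs
}

region_mask <- function(region, dims) {
  if (is.null(region)) return(logical(0))
  if (inherits(region, "vf_box3d")) {
    m <- array(FALSE, dim = dims)
    m[(region$min[1] + 1):region$max[1],
      (region$min[2] + 1):region$max[2],
      (region$min[3] + 1):region$max[3]] <- TRUE
    return(as.logical(m))
  }
  if (!identical(dim(region), as.integer(dims)) &&
      !identical(dim(region), dims))
    stop("region mask dimensions must match the volume")
  as.logical(region)
}
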