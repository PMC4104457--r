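#' Level dimensions of a multi-resolution octree pyramid
#'
#' Starting from the full-resolution dims, each coarser level halves every
#' axis (ceiling on odd dims) until all axes fit the leaf cap.  Returned
#' coarsest first.
#'
#' @param dims full-resolution dims (X, Y, Z).
#' @param leaf_cap per-axis cap of the coarsest level (default
#'   512 x 512 x 256).
#' @return list of length-3 integer dims, coarsest to finest.
#' @export
octree_levels <- function(dims, leaf_cap = c(512L, 512L, 256L)) {
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1L))
  levels <- list(dims)
  while (any(levels[[1]] > leaf_cap)) {
    levels <- c(list(as.integer(ceiling(levels[[1]] / 2))), levels)
  }
  levels
}

tile_grid <- function(dims, tile_size) {
  starts <- lapply(1:3, function(a) seq(0L, dims[a] - 1L, by = tile_size[a]))
  g <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  as.matrix(g)
}

# 2x2x2 block aggregation with ceil-halving; edge blocks aggregate the
# voxels available.  Integer dtypes round half-up.
downsample_volume <- function(vol, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  d <- vol$dims
  nd <- as.integer(ceiling(d / 2))
  out <- array(0, dim = c(nd, vol$channels))
  for (ch in seq_len(vol$channels)) {
    a <- vol$data[, , , ch]
    if (is.null(dim(a))) dim(a) <- d
    acc <- array(0, dim = nd)
    cnt <- array(0, dim = nd)
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
      xs <- seq(1 + ox, d[1], by = 2); ys <- seq(1 + oy, d[2], by = 2)
      zs <- seq(1 + oz, d[3], by = 2)
      if (!length(xs) || !length(ys) || !length(zs)) next
      blk <- a[xs, ys, zs, drop = FALSE]
      ix <- seq_along(xs); iy <- seq_along(ys); iz <- seq_along(zs)
      if (aggregator == "mean") {
        acc[ix, iy, iz] <- acc[ix, iy, iz] + blk
        cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
      } else {
        acc[ix, iy, iz] <- pmax(acc[ix, iy, iz], blk)
      }
    }
    r <- if (aggregator == "mean") acc / pmax(cnt, 1) else acc
    if (vol$dtype != "float32" && aggregator == "mean")
      r <- floor(r + 0.5) # round half-up
    out[, , , ch] <- r
  }
  vf_volume(out, voxel_size = vol$voxel_size * 2, dtype = vol$dtype)
}

#' Build a tiled multi-resolution octree store
#'
#' Stores the full-resolution volume tile-wise, then iteratively
#' downsamples by 2 per axis (block mean by default, block max for sparse
#' signal) until the preset leaf cap is reached, saving every level as a
#' directory of TIFF tiles plus a JSON index.  Byte output is
#' deterministic for a fixed input.
#'
#' @param vol a [vf_volume] (for truly huge data, build per-tile streams
#'   upstream; this builder takes an in-memory source).
#' @param out store directory (created).
#' @param leaf_cap per-axis dims cap of the coarsest level.
#' @param tile_size per-axis tile size (>= 16).
#' @param aggregator `"mean"` or `"max"`.
#' @return an `vf_octree` index (also written to `out/index.json`).
#' @export
build_octree <- function(vol, out, leaf_cap = c(512L, 512L, 256L),
                         tile_size = c(256L, 256L, 256L),
                         aggregator = c("mean", "max")) {
  stopifnot(inherits(vol, "vf_volume"))
  aggregator <- match.arg(aggregator)
  tile_size <- as.integer(tile_size)
  if (any(tile_size < 16L)) stop("tile_size must be >= 16 per axis")
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("store not writable: ", out)
  dims_levels <- octree_levels(vol$dims, leaf_cap)
  nlev <- length(dims_levels)
  # build finest -> coarsest, store coarsest first
  vols <- vector("list", nlev)
  vols[[nlev]] <- vol
  if (nlev > 1L)
    for (k in (nlev - 1):1)
      vols[[k]] <- downsample_volume(vols[[k + 1]], aggregator)
  levels <- vector("list", nlev)
  for (k in seq_len(nlev)) {
    lv <- vols[[k]]
    stopifnot(identical(as.integer(lv$dims), as.integer(dims_levels[[k]])))
    ldir <- file.path(out, sprintf("level_%02d", k - 1))
    dir.create(ldir, showWarnings = FALSE)
    offs <- tile_grid(lv$dims, tile_size)
    tiles <- vector("list", nrow(offs))
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      hi <- pmin(o + tile_size, lv$dims)
      tile <- crop_volume(lv, box3d(o, hi))
      rel <- file.path(sprintf("level_%02d", k - 1),
                       sprintf("z%05d_y%05d_x%05d.tif", o[3], o[2], o[1]))
      write_volume(tile, file.path(out, rel))
      tiles[[i]] <- list(offset = as.integer(o), path = rel)
    }
    levels[[k]] <- list(dims = as.integer(lv$dims),
                        tile_size = tile_size, tiles = tiles)
  }
  index <- structure(list(store = out, levels = levels,
                          channels = vol$channels, dtype = vol$dtype,
                          aggregator = aggregator),
                     class = "vf_octree")
  jsonlite::write_json(
    list(levels = levels, channels = vol$channels, dtype = vol$dtype,
         aggregator = aggregator),
    file.path(out, "index.json"), auto_unbox = TRUE, digits = NA)
  index
}

#' Load an octree index from its store directory
#'
#' @param store store directory written by [build_octree()].
#' @return an `vf_octree` index.
#' @export
read_octree <- function(store) {
  j <- jsonlite::read_json(file.path(store, "index.json"),
                           simplifyVector = FALSE)
  levels <- lapply(j$levels, function(lv)
    list(dims = as.integer(unlist(lv$dims)),
         tile_size = as.integer(unlist(lv$tile_size)),
         tiles = lapply(lv$tiles, function(t)
           list(offset = as.integer(unlist(t$offset)), path = t$path))))
  structure(list(store = store, levels = levels,
                 channels = as.integer(j$channels), dtype = j$dtype,
                 aggregator = j$aggregator), class = "vf_octree")
}

#' Resolve a region of interest to tiles of a target level
#'
#' Scales a box expressed at one resolution level to another (doubling or
#' ceil-halving coordinates per level step so the scaled box always covers
#' the original region) and returns the minimal set of tiles of the
#' target level covering it.  The work depends only on the ROI size, not
#' on the total volume size — this is what makes gesture-driven
#' navigation of arbitrarily large stacks constant-time.
#'
#' @param index an `vf_octree`.
#' @param roi a [box3d] at level `level`.
#' @param level 1-based level of `roi` (1 = coarsest).
#' @param target_level 1-based level to resolve into.
#' @return list with `box` (the [box3d] at the target level) and `tiles`
#'   (list of `{offset, path}` entries).
#' @export
resolve_roi <- function(index, roi, level, target_level) {
  stopifnot(inherits(index, "vf_octree"))
  nlev <- length(index$levels)
  if (level < 1 || level > nlev || target_level < 1 || target_level > nlev)
    stop("no such octree level")
  dims_l <- index$levels[[level]]$dims
  if (any(roi$min < 0) || any(roi$max > dims_l))
    stop("roi out of bounds at level ", level)
  lo <- roi$min; hi <- roi$max
  steps <- target_level - level
  if (steps > 0) { # towards finer resolution: coordinates double
    lo <- lo * 2^steps
    hi <- hi * 2^steps
  } else if (steps < 0) { # towards coarser: cover by floor/ceil halving
    lo <- floor(lo / 2^(-steps))
    hi <- ceiling(hi / 2^(-steps))
  }
  dims_t <- index$levels[[target_level]]$dims
  lo <- pmax(lo, 0); hi <- pmin(hi, dims_t)
  box <- box3d(lo, hi)
  ts <- index$levels[[target_level]]$tile_size
  tiles <- Filter(function(t) {
    o <- t$offset
    all(o < hi & pmin(o + ts, dims_t) > lo)
  }, index$levels[[target_level]]$tiles)
  list(box = box, tiles = tiles, level = target_level)
}

#' Assemble a resolved region into a contiguous volume
#'
#' Reads the tiles named by [resolve_roi()], assembles them seamlessly and
#' crops to the requested box.
#'
#' @param index an `vf_octree`.
#' @param resolved a [resolve_roi()] result.
#' @return a [vf_volume] of dims `resolved$box$max - resolved$box$min`.
#' @export
load_block <- function(index, resolved) {
  box <- resolved$box
  d <- box_dims(box)
  out <- array(0, dim = c(d, index$channels))
  ts <- index$levels[[resolved$level]]$tile_size
  dims_t <- index$levels[[resolved$level]]$dims
  for (t in resolved$tiles) {
    fp <- file.path(index$store, t$path)
    if (!file.exists(fp)) stop("octree integrity error: missing tile ", t$path)
    tile <- read_volume(fp)
    o <- t$offset
    lo <- pmax(box$min, o)
    hi <- pmin(box$max, pmin(o + ts, dims_t))
    if (any(lo >= hi)) next
    out[(lo[1] - box$min[1] + 1):(hi[1] - box$min[1]),
        (lo[2] - box$min[2] + 1):(hi[2] - box$min[2]),
        (lo[3] - box$min[3] + 1):(hi[3] - box$min[3]), ] <-
      tile$data[(lo[1] - o[1] + 1):(hi[1] - o[1]),
                (lo[2] - o[2] + 1):(hi[2] - o[2]),
                (lo[3] - o[3] + 1):(hi[3] - o[3]), , drop = FALSE]
  }
  vf_volume(out, dtype = index$dtype)
}
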