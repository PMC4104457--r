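#' Construct a volumetric image
#'
#' A `vf_volume` wraps a 3D (optionally multi-channel) scalar grid with a
#' fixed coordinate convention: axes are (X, Y, Z), coordinates are 0-based
#' and voxel-centered, so voxel `(i,j,k)` occupies the half-open cube
#' `[i-0.5, i+0.5) x [j-0.5, j+0.5) x [k-0.5, k+0.5)`.  Continuous
#' (sub-voxel) coordinates are valid everywhere downstream.
#'
#' @param data numeric array with dims `(X, Y, Z)` or `(X, Y, Z, C)`.
#' @param voxel_size physical size per axis; length-3 positive numeric.
#' @param dtype scalar kind, one of `"uint8"`, `"uint16"`, `"float32"`.
#' @return object of class `vf_volume` with fields `data` (always 4D,
#'   `X x Y x Z x C`), `dims`, `channels`, `voxel_size`, `dtype`.
#' @export
vf_volume <- function(data, voxel_size = c(1, 1, 1), dtype = "uint8") {
  if (!is.array(data) && !is.matrix(data))
    stop("`data` must be a 3D or 4D array")
  d <- dim(data)
  if (length(d) == 3L) {
    dim(data) <- c(d, 1L)
    d <- dim(data)
  }
  if (length(d) != 4L) stop("`data` must have 3 or 4 dimensions (X,Y,Z[,C])")
  if (any(d < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  storage.mode(data) <- "double"
  if (!dtype %in% c("uint8", "uint16", "float32"))
    stop("unsupported dtype: ", dtype)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(data = data, dims = d[1:3], channels = d[4],
         voxel_size = as.numeric(voxel_size), dtype = dtype),
    class = "vf_volume")
}

#' @export
print.vf_volume <- function(x, ...) {
  cat(sprintf("<vf_volume> %d x %d x %d, %d channel(s), %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$channels, x$dtype))
  invisible(x)
}

#' Per-channel intensity range
#'
#' Exact minimum and maximum intensity of one channel, scanned over all
#' voxels.  Ranges are per channel (never pooled across channels) because
#' multi-channel pinpointing treats each channel independently.
#'
#' @param vol a [vf_volume].
#' @param channel 1-based channel index.
#' @return list with `i_min` and `i_max` (`i_min <= i_max`).
#' @export
intensity_range <- function(vol, channel = 1L) {
  stopifnot(inherits(vol, "vf_volume"))
  if (channel < 1L || channel > vol$channels)
    stop("channel index out of range: ", channel)
  ch <- vol$data[, , , channel, drop = FALSE]
  list(i_min = min(ch), i_max = max(ch))
}

dtype_max <- function(dtype) {
  switch(dtype, uint8 = 255, uint16 = 65535, float32 = 1, stop("bad dtype"))
}

#' Read a volume from disk
#'
#' Supported formats: multi-page TIFF (`.tif`/`.tiff`; pages are Z, page
#' rows are Y, columns are X, channels as samples per pixel), NRRD
#' (`.nrrd`, uncompressed attached raw), and raw little-endian with a JSON
#' sidecar header (`.raw` + `.json` holding `{dims, dtype, channels}`).
#' Axis order is normalized to `(X, Y, Z, C)` on read.
#'
#' @param path file path; format chosen by extension.
#' @return a [vf_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = read_volume_tiff(path),
    nrrd = read_volume_nrrd(path),
    raw = read_volume_raw(path),
    stop("unrecognized volume format for file: ", path))
}

#' Write a volume to disk
#'
#' Inverse of [read_volume()]; round trips are bit exact for every
#' supported dtype.
#'
#' @param vol a [vf_volume].
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vf_volume"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = write_volume_tiff(vol, path),
    nrrd = write_volume_nrrd(vol, path),
    raw = write_volume_raw(vol, path),
    stop("unrecognized volume format for file: ", path))
  invisible(path)
}

## --- TIFF ------------------------------------------------------------------

read_volume_tiff <- function(path) {
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE)),
    error = function(e) stop("unreadable TIFF file: ", path,
                             " (", conditionMessage(e), ")"))
  if (length(pages) == 0L) stop("empty TIFF file: ", path)
  info <- suppressWarnings(tiff::readTIFF(path, payload = FALSE))
  bps <- if (is.data.frame(info)) info$bits.per.sample[1]
         else attr(info, "bits.per.sample")
  p1 <- pages[[1]]
  nc <- if (length(dim(p1)) == 3L) dim(p1)[3] else 1L
  ny <- dim(p1)[1]; nx <- dim(p1)[2]; nz <- length(pages)
  arr <- array(0, dim = c(nx, ny, nz, nc))
  for (z in seq_len(nz)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
    if (!identical(dim(pg)[1:2], c(ny, nx)))
      stop("inconsistent page dimensions in TIFF file: ", path)
    # page is [Y, X, C]; transpose to [X, Y, C]
    arr[, , z, ] <- aperm(pg, c(2, 1, 3))
  }
  bps <- if (is.null(bps)) 8 else max(bps)
  dtype <- if (bps <= 8) "uint8"
           else if (bps <= 16) "uint16" else "float32"
  # multi-sample pages may come back rescaled to [0,1]; undo per bps
  if (dtype != "float32" && !is.integer(pages[[1]]))
    arr <- round(arr * (2^bps - 1))
  vf_volume(arr, dtype = dtype)
}

write_volume_tiff <- function(vol, path) {
  bps <- switch(vol$dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  scale <- if (vol$dtype == "float32") 1 else dtype_max(vol$dtype)
  pages <- lapply(seq_len(vol$dims[3]), function(z) {
    pg <- vol$data[, , z, , drop = FALSE]
    dim(pg) <- dim(pg)[c(1, 2, 4)]
    pg <- aperm(pg, c(2, 1, 3)) # [Y, X, C]
    if (dim(pg)[3] == 1L) dim(pg) <- dim(pg)[1:2]
    pg / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bps,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

## --- raw + JSON header -----------------------------------------------------

raw_header_path <- function(path) sub("\\.raw$", ".json", path)

read_volume_raw <- function(path) {
  hpath <- raw_header_path(path)
  if (!file.exists(hpath))
    stop("missing JSON header for raw volume: ", hpath)
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (is.null(hdr$dims) || length(hdr$dims) != 3L || is.null(hdr$dtype))
    stop("ambiguous raw header (need dims, dtype): ", hpath)
  nc <- if (is.null(hdr$channels)) 1L else as.integer(hdr$channels)
  dims <- as.integer(hdr$dims)
  n <- prod(dims) * nc
  con <- file(path, "rb"); on.exit(close(con))
  vals <- switch(hdr$dtype,
    uint8  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                                endian = "little")),
    uint16 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported dtype in raw header: ", hdr$dtype))
  if (length(vals) < n)
    stop("truncated raw volume file: ", path)
  vf_volume(array(vals, dim = c(dims, nc)), dtype = hdr$dtype)
}

write_volume_raw <- function(vol, path) {
  hdr <- list(dims = vol$dims, dtype = vol$dtype, channels = vol$channels)
  jsonlite::write_json(hdr, raw_header_path(path), auto_unbox = TRUE)
  con <- file(path, "wb"); on.exit(close(con))
  v <- as.vector(vol$data)
  switch(vol$dtype,
    uint8  = writeBin(as.integer(v), con, size = 1, endian = "little"),
    uint16 = writeBin(as.integer(v), con, size = 2, endian = "little"),
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"))
  invisible(path)
}

## --- NRRD (minimal, uncompressed attached raw) -----------------------------

nrrd_types <- c(uint8 = "uint8", uchar = "uint8",
                uint16 = "uint16", ushort = "uint16",
                float = "float32")

read_volume_nrrd <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0L) stop("truncated NRRD header: ", path)
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  if (is.null(fields$sizes) || is.null(fields$type))
    stop("ambiguous NRRD header (need sizes, type): ", path)
  if (!is.null(fields$encoding) && fields$encoding != "raw")
    stop("unsupported NRRD encoding '", fields$encoding, "' in: ", path)
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  dtype <- nrrd_types[[trimws(fields$type)]]
  if (is.null(dtype)) stop("unsupported NRRD type in: ", path)
  # axis convention: fastest axis first; 3 axes = X Y Z, 4 axes = C X Y Z
  if (!length(sizes) %in% c(3L, 4L))
    stop("ambiguous NRRD dimension count in: ", path)
  n <- prod(sizes)
  vals <- switch(dtype,
    uint8  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                                endian = "little")),
    uint16 = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"))
  if (length(vals) < n) stop("truncated NRRD data in: ", path)
  if (length(sizes) == 3L) {
    arr <- array(vals, dim = c(sizes, 1L))
  } else {
    arr <- aperm(array(vals, dim = sizes), c(2, 3, 4, 1))
  }
  vf_volume(arr, dtype = dtype)
}

write_volume_nrrd <- function(vol, path) {
  type <- switch(vol$dtype, uint8 = "uint8", uint16 = "uint16",
                 float32 = "float")
  multi <- vol$channels > 1L
  sizes <- if (multi) c(vol$channels, vol$dims) else vol$dims
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           paste0("dimension: ", length(sizes)),
           paste0("sizes: ", paste(sizes, collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(hdr, con)
  v <- if (multi) as.vector(aperm(vol$data, c(4, 1, 2, 3)))
       else as.vector(vol$data)
  switch(vol$dtype,
    uint8  = writeBin(as.integer(v), con, size = 1, endian = "little"),
    uint16 = writeBin(as.integer(v), con, size = 2, endian = "little"),
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"))
  invisible(path)
}

## --- sampling --------------------------------------------------------------

#' Trilinear intensity sampling at continuous coordinates
#'
#' Samples one channel at arbitrary 0-based voxel-centered coordinates.
#' Coordinates are clamped to the voxel-center range `[0, dim-1]` per axis,
#' so positions in the half-voxel border band take the edge value.
#'
#' @param vol a [vf_volume].
#' @param pts n x 3 matrix of (x, y, z) positions.
#' @param channel 1-based channel index.
#' @return numeric vector of n interpolated intensities.
#' @export
sample_trilinear <- function(vol, pts, channel = 1L) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- vol$dims
  x <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  y <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  z <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 1); x1 <- pmin(x0 + 1, d[1] - 1)
  y0 <- pmin(floor(y), d[2] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ch <- vol$data[, , , channel]
  if (is.null(dim(ch))) dim(ch) <- d
  at <- function(i, j, k) ch[cbind(i + 1, j + 1, k + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
        fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

#' Crop a volume to a half-open box
#'
#' @param vol a [vf_volume].
#' @param box a [box3d] (half-open, 0-based).
#' @return the cropped [vf_volume].
#' @export
crop_volume <- function(vol, box) {
  stopifnot(inherits(vol, "vf_volume"))
  lo <- box$min; hi <- box$max
  if (any(lo < 0) || any(hi > vol$dims) || any(lo >= hi))
    stop("crop box out of volume bounds")
  vf_volume(vol$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                     (lo[3] + 1):hi[3], , drop = FALSE],
            voxel_size = vol$voxel_size, dtype = vol$dtype)
}
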