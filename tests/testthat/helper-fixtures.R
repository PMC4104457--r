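# Shared fixtures, built in code at test time.

# A volume with a single Gaussian blob.
blob_volume <- function(centre = c(10, 10, 10), dims = c(21, 21, 21),
                        sigma = 2, peak = 200, background = 0,
                        noise_sigma = 0, seed = 1L) {
  ph <- make_phantom(
    phantom_spec("blob", list(centre = centre), peak = peak,
                 background = max(background, 0), sigma = sigma,
                 noise_sigma = noise_sigma, seed = seed),
    dims)
  ph
}

# A straight bright tube along x at fixed (y, z).
tube_volume <- function(y = 20, z = 20, dims = c(41, 41, 41), sigma = 1.5,
                        peak = 200, background = 20, noise_sigma = 0,
                        seed = 1L) {
  make_phantom(
    phantom_spec("straight-tube",
                 list(from = c(2, y, z), to = c(dims[1] - 3, y, z)),
                 peak = peak, background = background, sigma = sigma,
                 noise_sigma = noise_sigma, seed = seed),
    dims)
}

helix_phantom <- function(noise_sigma = 0, seed = 1L, pitch = 10,
                          radius = 8, dims = c(48, 48, 36),
                          z_range = c(6, 18)) {
  make_phantom(
    phantom_spec("helix-tube",
                 list(centre = c(24, 24), radius = radius, pitch = pitch,
                      z_range = z_range),
                 peak = 200, background = 20, sigma = 1.5,
                 noise_sigma = noise_sigma, seed = seed),
    dims)
}

random_volume <- function(dims, seed, vmax = 255) {
  withr::with_seed(seed,
    vf_volume(array(sample(0:vmax, prod(dims), TRUE), dims)))
}

# Independent shortest-path oracle on the explicit voxel graph (igraph).
oracle_geodesic_cost <- function(vol, src, snk, connectivity = 18,
                                 lambda_i = 10) {
  skip_if_not_installed("igraph")
  par <- geodesic_params(lambda_i = lambda_i, connectivity = connectivity)
  d <- vol$dims
  r <- intensity_range(vol, 1)
  gI <- g_intensity(as.vector(vol$data[, , , 1]), r, par)
  idx <- function(x, y, z) x + d[1] * (y + d[2] * z) + 1
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  edges <- integer(0); w <- numeric(0)
  for (z in 0:(d[3] - 1)) for (y in 0:(d[2] - 1)) for (x in 0:(d[1] - 1)) {
    i1 <- idx(x, y, z)
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (any(q < 0) || any(q >= d)) next
      i2 <- idx(q[1], q[2], q[3])
      if (i2 <= i1) next
      edges <- c(edges, i1, i2)
      w <- c(w, sqrt(sum(offs[k, ]^2)) * (gI[i1] + gI[i2]) / 2)
    }
  }
  g <- igraph::make_graph(edges, n = prod(d), directed = FALSE)
  igraph::distances(g, v = idx(src[1], src[2], src[3]),
                    to = idx(snk[1], snk[2], snk[3]), weights = w)[1, 1]
}

expect_close <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}

point_dist_to_poly <- function(pts, poly) {
  vfinger:::point_polyline_dist(pts, poly)
}

polyline_len <- function(p) vfinger:::polyline_length(p)
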