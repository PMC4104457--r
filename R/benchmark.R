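#' Synthetic tract set for curve-tracing validation
#'
#' Seven noisy tubular tracts — one gentle helix and six smooth bent
#' tubes — in 56-voxel cubes, emulating the regime of a noisy confocal
#' stack of neurite tracts: peak 200 over background 20, Gaussian
#' cross-section sigma 1.5, additive Gaussian noise sigma 30, 8-bit,
#' noise seeds 1 to 7.
#'
#' @param noise_sigma additive noise s.d.
#' @param dims volume dims per tract.
#' @return list of [make_phantom()] results.
#' @export
benchmark_tracts <- function(noise_sigma = 30, dims = c(56, 56, 56)) {
  geoms <- list(
    list(kind = "helix-tube",
         geometry = list(centre = c(28, 28), radius = 8, pitch = 24,
                         z_range = c(10, 46))),
    list(kind = "bent-tube",
         geometry = list(control = rbind(c(8, 16, 12), c(22, 26, 20),
                                         c(38, 28, 28), c(48, 38, 40)))),
    list(kind = "bent-tube",
         geometry = list(control = rbind(c(10, 46, 44), c(24, 36, 34),
                                         c(36, 28, 22), c(46, 12, 14)))),
    list(kind = "bent-tube",
         geometry = list(control = rbind(c(12, 10, 28), c(26, 20, 30),
                                         c(38, 34, 26), c(44, 46, 18)))),
    list(kind = "bent-tube",
         geometry = list(control = rbind(c(46, 10, 10), c(34, 22, 22),
                                         c(28, 34, 32), c(14, 44, 44)))),
    list(kind = "bent-tube",
         geometry = list(control = rbind(c(10, 28, 8), c(20, 24, 22),
                                         c(34, 30, 32), c(46, 26, 46)))),
    list(kind = "bent-tube",
         geometry = list(control = rbind(c(28, 8, 14), c(22, 22, 24),
                                         c(30, 36, 30), c(26, 48, 42)))))
  lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    make_phantom(phantom_spec(g$kind, g$geometry, peak = 200,
                              background = 20, sigma = 1.5,
                              noise_sigma = noise_sigma, seed = i),
                 dims)
  })
}

#' A random viewing rotation under which a tract is traceable
#'
#' Draws seeded random rotations and keeps the first under which the
#' tract can actually be traced on screen: the projected centerline must
#' retain at least `min_fraction` of its 3D arc length (no end-on views)
#' and no two parts of the tract that are far apart in 3D may project
#' onto the same screen location (no self-occluded views) — a user cannot
#' trace what the projection makes ambiguous.
#'
#' @param centerline n x 3 polyline.
#' @param seed integer seed.
#' @param min_fraction minimum projected/3D length ratio.
#' @param overlap_px screen distance below which two projected points
#'   count as overlapping.
#' @return 3x3 rotation matrix.
#' @export
visible_rotation <- function(centerline, seed, min_fraction = 0.6,
                             overlap_px = 2) {
  dense <- if (nrow(centerline) > 1) resample_polyline(centerline, 1)
           else centerline
  len3 <- polyline_length(dense)
  rot <- diag(3)
  for (try in 0:49) {
    rot <- random_rotation(seed + 1000L * try)
    proj <- dense %*% t(vf_camera(rot)$rotation[1:2, ])
    plen <- sum(sqrt(rowSums(diff(proj)^2)))
    if (plen < min_fraction * len3) next
    # self-occlusion: screen-close pairs that are 3D-far
    n <- nrow(dense)
    ambiguous <- FALSE
    for (i in seq_len(n)) {
      d2 <- sqrt(rowSums((proj - matrix(proj[i, ], n, 2, byrow = TRUE))^2))
      d3 <- sqrt(rowSums((dense - matrix(dense[i, ], n, 3,
                                         byrow = TRUE))^2))
      if (any(d2 < overlap_px & d3 > 4)) { ambiguous <- TRUE; break }
    }
    if (!ambiguous) break
  }
  rot
}

#' Multi-view curve-tracing accuracy experiment
#'
#' For each tract, draws simulated 20-point strokes along the projected
#' ground-truth centerline (2-pixel uniform hand jitter) under several
#' random-but-traceable viewing rotations and zooms, traces each stroke
#' with the globally optimal geodesic curve drawer at default parameters,
#' and scores every traced curve against the analytic centerline with the
#' spatial-divergence metric at 1-voxel resampling.  The curve scored is
#' the dense geodesic polyline (knots at ~1-voxel spacing, refined and
#' smoothed), the same density a live mouse stroke produces.
#'
#' @param base_seed seed driving cameras and jitter (phantom noise seeds
#'   are fixed by [benchmark_tracts()]).
#' @param n_cams rotations per tract.
#' @param zooms zoom factors per rotation.
#' @param n_jit jitter seeds per rotation/zoom.
#' @param n_points stroke points.
#' @param jitter_px uniform jitter half-width (screen pixels).
#' @param tracts tract list from [benchmark_tracts()].
#' @return data.frame with one row per traced curve: `tract`, `cam`,
#'   `zoom`, `jit`, `sd_mean`, `sd_max`, `fraction_visible`, `n_samples`.
#' @export
trace_benchmark <- function(base_seed = 1L, n_cams = 5L, zooms = c(1, 2),
                            n_jit = 3L, n_points = 20L, jitter_px = 2,
                            tracts = benchmark_tracts()) {
  rows <- list()
  for (ti in seq_along(tracts)) {
    ph <- tracts[[ti]]
    gt <- vf_curve(ph$centerline)
    for (ci in seq_len(n_cams)) {
      rot <- visible_rotation(ph$centerline,
                              base_seed * 101L + ti * 17L + ci)
      for (z in zooms) {
        cam <- vf_camera(rot, zoom = z)
        for (ji in seq_len(n_jit)) {
          sseed <- (base_seed * 7919L + ti * 131L + ci * 17L +
                    round(z * 5L) + ji) %% .Machine$integer.max
          s <- simulate_stroke(ph$centerline, cam, n_points, jitter_px,
                               seed = sseed)
          crv <- cda2_global(s, cam, ph$volume, keep_dense = TRUE)
          sd_ <- spatial_divergence(vf_curve(crv$dense_path), gt)
          rows[[length(rows) + 1L]] <- data.frame(
            tract = ti, cam = ci, zoom = z, jit = ji,
            sd_mean = sd_$mean, sd_max = sd_$max,
            fraction_visible = sd_$fraction_visible,
            n_samples = nrow(resample_polyline(crv$dense_path, 1)))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a tracing experiment into its headline accuracy numbers
#'
#' @param bench a [trace_benchmark()] data.frame.
#' @return list: `mean_sd` (voxels, curves weighted equally),
#'   `visible_pct` (percentage of resampled samples at >= 2 voxels),
#'   `mean_max_sd` (voxels, average over curves of the per-curve maximum),
#'   `n_curves`, `n_samples`.
#' @export
summarize_benchmark <- function(bench) {
  list(mean_sd = mean(bench$sd_mean),
       visible_pct = 100 * sum(bench$fraction_visible * bench$n_samples) /
         sum(bench$n_samples),
       mean_max_sd = mean(bench$sd_max),
       n_curves = nrow(bench),
       n_samples = sum(bench$n_samples))
}
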