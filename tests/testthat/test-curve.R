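test_that("stroke preprocessing keeps the brightest half, endpoints protected", {
  ph <- tube_volume()
  cam <- vf_camera()
  # 10 points along the tube's projection: half survive, order preserved
  s <- simulate_stroke(ph$centerline, cam, 10, 0)
  s2 <- preprocess_stroke(s, cam, ph$volume)
  expect_equal(nrow(s2$points), 5L)
  kept <- attr(s2, "kept")
  expect_true(all(diff(kept) > 0))
  expect_true(1L %in% kept && 10L %in% kept)
  # two points: both retained
  s3 <- preprocess_stroke(vf_stroke(s$points[c(1, 10), ]), cam, ph$volume)
  expect_equal(nrow(s3$points), 2L)
})

test_that("stroke preprocessing drops off-structure points", {
  ph <- tube_volume()
  cam <- vf_camera()
  on_tube <- simulate_stroke(ph$centerline, cam, 6, 0)$points
  off <- on_tube
  off[, 2] <- off[, 2] + 12 # projected well off the tube
  pts <- matrix(0, 12, 2)
  pts[seq(1, 12, 2), ] <- on_tube
  pts[seq(2, 12, 2), ] <- off
  s <- preprocess_stroke(vf_stroke(pts), cam, ph$volume)
  kept <- attr(s, "kept")
  # endpoints are always protected; every other kept point is on the tube
  expect_true(all(setdiff(kept, c(1L, 12L)) %in% seq(1, 12, 2)))
})

test_that("range-restricted chaining traces a straight tube", {
  ph <- tube_volume(y = 20, z = 20)
  cam <- vf_camera()
  s <- simulate_stroke(ph$centerline, cam, 12, 0)
  crv <- cda1(s, cam, ph$volume)
  expect_equal(nrow(crv$knots), 12L)
  d <- point_dist_to_poly(crv$knots, ph$centerline)
  expect_lt(max(d), 0.5)
})

test_that("chaining in a dark volume follows the stroke geometrically", {
  vol <- vf_volume(array(0, c(30, 30, 30)))
  cam <- vf_camera()
  s <- vf_stroke(cbind(seq(5, 25, length.out = 8), rep(15, 8)))
  crv <- cda1(s, cam, vol)
  expect_equal(nrow(crv$knots), 8L)
  # knots continue geometrically near the previous knot (nearest sample rule)
  expect_lt(max(abs(crv$knots[, 2] - 15)), 1)
  steps <- sqrt(rowSums(diff(crv$knots)^2))
  expect_lt(max(steps), 31)
})

test_that("the +-30 voxel range keeps chaining off a distant decoy", {
  dims <- c(60, 41, 90)
  # the first stroke point sees only the dim target; a brighter decoy sits
  # 50 voxels behind it for the rest of the gesture
  spec <- phantom_spec("two-tube-occlusion",
    list(target = list(kind = "straight-tube", from = c(5, 20, 20),
                       to = c(55, 20, 20), peak = 120),
         occluder = list(kind = "straight-tube", from = c(15, 20, 70),
                         to = c(55, 20, 70), peak = 255)),
    peak = 255, background = 0, sigma = 1.5)
  ph <- make_phantom(spec, dims)
  cam <- vf_camera()
  s <- simulate_stroke(ph$centerline, cam, 10, 0)
  crv <- cda1(s, cam, ph$volume)
  d <- point_dist_to_poly(crv$knots, ph$centerline)
  expect_lt(max(d), 2)
})

test_that("a two-point stroke yields exactly the two-ray geodesic termini", {
  ph <- tube_volume()
  cam <- vf_camera()
  pts <- simulate_stroke(ph$centerline, cam, 12, 0)$points[c(2, 9), ]
  crv <- cda2(vf_stroke(pts), cam, ph$volume, refine = FALSE, window = 1L)
  expect_equal(nrow(crv$knots), 2L)
  d <- point_dist_to_poly(crv$knots, ph$centerline)
  expect_lt(max(d), 1.5)
})

test_that("geodesic curve drawing follows a helix centerline", {
  ph <- helix_phantom(pitch = 10, z_range = c(6, 18), dims = c(48, 48, 26))
  cam <- vf_camera(random_rotation(12))
  s <- simulate_stroke(ph$centerline, cam, 20, 0)
  crv <- cda2(s, cam, ph$volume)
  sd_ <- spatial_divergence(crv, vf_curve(ph$centerline))
  expect_lt(sd_$mean, 1)
})

test_that("curve drawing stays on a dim tract occluded by a bright one", {
  dims <- c(60, 41, 41)
  # dim broken tract with a much brighter tract obscuring its middle from
  # the viewing direction
  spec <- phantom_spec("two-tube-occlusion",
    list(target = list(kind = "straight-tube", from = c(5, 20, 26),
                       to = c(55, 20, 26), peak = 80,
                       gaps = list(c(0.45, 0.55))),
         occluder = list(kind = "straight-tube", from = c(20, 20, 12),
                         to = c(40, 20, 12), peak = 240)),
    peak = 240, background = 10, sigma = 1.5)
  ph <- make_phantom(spec, dims)
  cam <- vf_camera() # bright tract in front along the view axis
  s <- simulate_stroke(ph$centerline, cam, 16, 0)
  crv <- cda2(s, cam, ph$volume)
  d <- point_dist_to_poly(crv$knots, ph$centerline)
  expect_lt(max(d), 2)
})

test_that("globally optimal drawing matches basic drawing on a clean tube", {
  ph <- tube_volume()
  cam <- vf_camera()
  s <- simulate_stroke(ph$centerline, cam, 12, 0)
  c_basic <- cda2(s, cam, ph$volume)
  c_glob <- cda2_global(s, cam, ph$volume)
  sd_ <- spatial_divergence(c_basic, c_glob)
  expect_lt(sd_$mean, 0.5)
})

test_that("globally optimal drawing shrugs off a jittered middle point", {
  ph <- tube_volume(y = 20, z = 20)
  cam <- vf_camera()
  pts <- simulate_stroke(ph$centerline, cam, 11, 0)$points
  pts[6, 2] <- pts[6, 2] + 10 # 10-pixel off-tube jitter
  crv <- cda2_global(vf_stroke(pts), cam, ph$volume)
  d <- point_dist_to_poly(crv$knots, ph$centerline)
  expect_lt(max(d), 2)
})

test_that("single-candidate mode degenerates to brightest-point chaining", {
  ph <- tube_volume()
  cam <- vf_camera()
  s <- simulate_stroke(ph$centerline, cam, 10, 0)
  crv <- cda2_global(s, cam, ph$volume, m = 1L, refine = FALSE,
                     window = 1L)
  # each knot must be the brightest sample of its ray
  s2 <- preprocess_stroke(s, cam, ph$volume)
  for (i in seq_len(nrow(crv$knots))) {
    ray <- screen_to_ray(s2$points[i, ], cam, ph$volume)
    best <- ray$samples[which.max(ray$intensity[, 1]), ]
    expect_close(crv$knots[i, ], best, 1e-9)
  }
})

test_that("dynamic-programming stitching is optimal over the candidate set", {
  # brute-force enumeration over all candidate chains on a tiny instance
  ph <- tube_volume(dims = c(25, 25, 25), y = 12, z = 12)
  cam <- vf_camera()
  s <- simulate_stroke(ph$centerline, cam, 8, 0)
  crv <- cda2_global(s, cam, ph$volume, m = 3L)
  expect_true(is.finite(attr(crv, "total_cost")))
  # independent check: exhaustive chain enumeration with fast_march costs
  s2 <- preprocess_stroke(s, cam, ph$volume)
  rays <- lapply(seq_len(nrow(s2$points)), function(i)
    screen_to_ray(s2$points[i, ], cam, ph$volume))
  cands <- lapply(rays, function(r) {
    ord <- order(r$intensity[, 1], decreasing = TRUE)
    picked <- integer(0)
    for (i in ord) {
      if (length(picked) >= 3) break
      if (!length(picked) ||
          min(sqrt(rowSums((r$samples[picked, , drop = FALSE] -
              matrix(r$samples[i, ], length(picked), 3, byrow = TRUE))^2))) >= 2)
        picked <- c(picked, i)
    }
    r$samples[picked, , drop = FALSE]
  })
  combos <- expand.grid(lapply(cands, function(x) seq_len(nrow(x))))
  best <- Inf
  for (ri in seq_len(nrow(combos))) {
    total <- 0
    for (k in 2:length(cands)) {
      a <- cands[[k - 1]][combos[ri, k - 1], ]
      b <- cands[[k]][combos[ri, k], ]
      total <- total + fast_march(a, b, ph$volume)$cost
      if (total > best) break
    }
    best <- min(best, total)
  }
  expect_lt(abs(attr(crv, "total_cost") - best), 1e-6)
})

test_that("box-restricted drawing matches the unrestricted curve cheaply", {
  ph <- tube_volume()
  cam <- vf_camera()
  s <- simulate_stroke(ph$centerline, cam, 10, 0)
  full <- cda2(s, cam, ph$volume)
  boxed <- cda2_bbox(s, cam, ph$volume, margin = 5)
  expect_close(boxed$knots, full$knots, 0.5)
  # restriction strictly reduces search effort; the allowed region itself
  # is a small fraction of the volume
  expect_lt(attr(boxed, "visited"), attr(full, "visited"))
})

test_that("box-restricted drawing reproduces the helix at the default margin", {
  ph <- helix_phantom(pitch = 10, z_range = c(6, 18), dims = c(48, 48, 26))
  cam <- vf_camera(random_rotation(12))
  s <- simulate_stroke(ph$centerline, cam, 20, 0)
  crv <- cda2_bbox(s, cam, ph$volume, margin = 5)
  sd_ <- spatial_divergence(crv, vf_curve(ph$centerline))
  expect_lt(sd_$mean, 1)
})

test_that("a zero margin on a curved tube raises no-path, never a wrong curve", {
  ph <- helix_phantom(pitch = 10, z_range = c(6, 18), dims = c(48, 48, 26))
  cam <- vf_camera(random_rotation(3))
  s <- simulate_stroke(ph$centerline, cam, 20, 0)
  res <- tryCatch(cda2_bbox(s, cam, ph$volume, margin = 0),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no curve|no path")
  } else {
    sd_ <- spatial_divergence(res, vf_curve(ph$centerline))
    expect_lt(sd_$mean, 1.5)
  }
})

test_that("smoothing leaves straight curves and endpoints fixed", {
  line <- vf_curve(cbind(0:10, 2 * (0:10), rep(3, 11)))
  sm <- smooth_curve(line, 5L)
  expect_close(sm$knots, line$knots, 1e-9)
  zig <- cbind(0:10, rep(5, 11) + rep(c(1, -1), length.out = 11), 0)
  crv <- vf_curve(zig)
  sm2 <- smooth_curve(crv, 5L)
  expect_equal(nrow(sm2$knots), 11L)
  expect_equal(sm2$knots[1, ], crv$knots[1, ])
  expect_equal(sm2$knots[11, ], crv$knots[11, ])
  # interior deviation from the line strictly decreases (ends are pinned)
  expect_lt(max(abs(sm2$knots[2:10, 2] - 5)), max(abs(zig[2:10, 2] - 5)))
  expect_identical(smooth_curve(crv, 1L)$knots, crv$knots)
  # idempotent on its own fixed points
  expect_close(smooth_curve(sm, 5L)$knots, sm$knots, 1e-9)
  expect_error(smooth_curve(crv, 4L), "odd")
})

test_that("rigid, similarity and mirror transforms act exactly on knots", {
  crv <- vf_curve(matrix(runif(30, 0, 20), 10))
  expect_close(transform_curve(crv)$knots, crv$knots, 1e-12)
  mm <- transform_curve(transform_curve(crv, mirror_axis = 2, mirror_at = 7),
                        mirror_axis = 2, mirror_at = 7)
  expect_close(mm$knots, crv$knots, 1e-9)
  z2 <- transform_curve(crv, scale = 2)
  d0 <- sqrt(rowSums(diff(crv$knots)^2))
  expect_close(sqrt(rowSums(diff(z2$knots)^2)), 2 * d0, 1e-9)
  rot <- rotation_about_axis("z", pi / 3)
  rr <- transform_curve(crv, rotation = rot, translation = c(1, 2, 3))
  expect_close(rr$knots, sweep(crv$knots %*% t(rot), 2, c(1, 2, 3), `+`),
               1e-9)
})

test_that("dragging a knot deforms the curve with a monotone falloff", {
  crv <- vf_curve(cbind(0:10, 0, 0))
  only <- drag_knot(crv, 6, c(0, 2, 0), radius = 0)
  expect_equal(only$knots[6, 2], 2)
  expect_equal(only$knots[-6, 2], rep(0, 10))
  none <- drag_knot(crv, 6, c(0, 0, 0), radius = 3)
  expect_equal(none$knots, crv$knots)
  dragged <- drag_knot(crv, 6, c(0, 4, 0), radius = 3)
  disp <- abs(dragged$knots[, 2])
  expect_equal(dragged$knots[6, 2], 4)
  expect_true(all(diff(disp[6:10]) <= 1e-12))
  expect_true(all(diff(disp[1:6]) >= -1e-12))
  expect_equal(disp[10], 0)
})

test_that("segments join within the inclusive 5-voxel threshold", {
  a <- vf_curve(cbind(0:10, 0, 0))
  b3 <- vf_curve(cbind(13:20, 0, 0))        # endpoint 3 voxels from a's end
  out <- join_segments(list(a, b3), threshold = 5)
  expect_length(out, 1L)
  b6 <- vf_curve(cbind(16:20, 0, 0))        # endpoint 6 voxels away
  expect_length(join_segments(list(a, b6), threshold = 5), 2L)
  b5 <- vf_curve(cbind(15:20, 0, 0))        # exactly 5: inclusive rule
  expect_length(join_segments(list(a, b5), threshold = 5), 1L)
})

test_that("joining inserts junctions without moving existing knots", {
  a <- vf_curve(cbind(0:20, 0, 0))
  t_seg <- vf_curve(cbind(5.5, 2:8, 0)) # endpoint 2 voxels above a's middle
  out <- join_segments(list(a, t_seg), threshold = 5)
  expect_length(out, 1L)
  merged <- out[[1]]$curves
  all_knots <- do.call(rbind, lapply(merged, function(c) c$knots))
  for (i in 0:20) # every original knot of a survives unmoved
    expect_true(any(rowSums(abs(all_knots -
      matrix(c(i, 0, 0), nrow(all_knots), 3, byrow = TRUE))) < 1e-9))
  expect_true(any(rowSums(abs(all_knots -
    matrix(c(5.5, 0, 0), nrow(all_knots), 3, byrow = TRUE))) < 1e-9))
})

test_that("spatial divergence is a symmetric premetric with exact offsets", {
  a <- vf_curve(cbind(0:20, 0, 0))
  expect_equal(spatial_divergence(a, a),
               list(mean = 0, max = 0, fraction_visible = 0))
  b <- vf_curve(cbind(0:20, 2, 0))
  sd_ <- spatial_divergence(a, b)
  expect_close(sd_$mean, 2, 1e-9)
  expect_close(sd_$max, 2, 1e-9)
  expect_equal(sd_$fraction_visible, 1)
  withr::with_seed(5, {
    for (k in 1:10) {
      x <- vf_curve(matrix(runif(18, 0, 30), 6))
      y <- vf_curve(matrix(runif(15, 0, 30), 5))
      f <- spatial_divergence(x, y); g <- spatial_divergence(y, x)
      expect_close(f$mean, g$mean, 1e-9)
      expect_close(f$max, g$max, 1e-9)
      expect_gte(f$mean, 0)
    }
  })
  expect_error(spatial_divergence(vf_curve(matrix(1, 2, 3)), a),
               "degenerate")
})

test_that("curves round trip through SWC", {
  c1 <- vf_curve(matrix(runif(30, 0, 40), 10))
  c2 <- vf_curve(matrix(runif(12, 0, 40), 4))
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(list(c1, c2), f)
  back <- read_swc(f)
  expect_length(back, 2L)
  expect_close(back[[1]]$knots, c1$knots, 1e-5)
  expect_close(back[[2]]$knots, c2$knots, 1e-5)
})
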