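make_ray <- function(intensity, spacing_axis = 3) {
  n <- length(intensity)
  s <- matrix(0, n, 3)
  s[, spacing_axis] <- 0:(n - 1)
  structure(list(origin = s[1, ], direction = c(0, 0, 1), samples = s,
                 t = 0:(n - 1), intensity = matrix(intensity, ncol = 1),
                 empty = FALSE), class = "vf_ray")
}

test_that("mean-shift pinpointing finds isolated and Gaussian peaks", {
  prof <- rep(0, 20); prof[8] <- 150 # single nonzero sample at depth 7
  p <- ppa_single(make_ray(prof))
  expect_equal(p$location, c(0, 0, 7))
  expect_true(p$confident)

  gauss <- 100 * exp(-((0:39) - 12)^2 / (2 * 2^2))
  p2 <- ppa_single(make_ray(gauss))
  expect_lt(abs(p2$location[3] - 12), 1)

  two <- 100 * exp(-((0:39) - 10)^2 / 8) + 50 * exp(-((0:39) - 30)^2 / 8)
  p3 <- ppa_single(make_ray(two))
  expect_lt(abs(p3$location[3] - 10), 1)
})

test_that("pinpointing a flat or empty ray is flagged", {
  p <- ppa_single(make_ray(rep(42, 15)))
  expect_false(p$confident)
  empty <- structure(list(samples = matrix(0, 0, 3), t = numeric(0),
                          intensity = matrix(0, 0, 1), empty = TRUE),
                     class = "vf_ray")
  expect_error(ppa_single(empty), "no point")
})

test_that("mean-shift location is invariant to affine intensity rescaling", {
  withr::with_seed(9, {
    for (k in 1:10) {
      prof <- pmax(rnorm(30, 50, 20), 0) +
        120 * exp(-((0:29) - runif(1, 8, 22))^2 / 6)
      base <- ppa_single(make_ray(prof))$location
      resc <- ppa_single(make_ray(3.7 * prof + 55))$location
      expect_equal(base, resc)
    }
  })
})

test_that("multi-channel pinpointing picks the brightest channel candidate", {
  dims <- c(15, 15, 15)
  a1 <- array(0, dims); a1[8, 8, 4] <- 200
  a2 <- array(0, dims); a2[8, 8, 11] <- 150
  v <- vf_volume(array(c(a1, a2), c(dims, 2)))
  p <- ppa_c(c(7, 7), vf_camera(), v)
  expect_equal(p$channel, 1L)
  expect_equal(p$location[3], 3)
  # fixed channel overrides the winner rule
  p2 <- ppa_c(c(7, 7), vf_camera(), v, channel = 2L)
  expect_equal(p2$location[3], 10)
  # exact tie goes to the lowest channel index
  a2[8, 8, 11] <- 200
  vt <- vf_volume(array(c(a1, a2), c(dims, 2)))
  expect_equal(ppa_c(c(7, 7), vf_camera(), vt)$channel, 1L)
  # single channel reduces to ppa_single on the ray
  v1 <- vf_volume(a1)
  ray <- screen_to_ray(c(7, 7), vf_camera(), v1)
  expect_equal(ppa_c(c(7, 7), vf_camera(), v1)$location,
               ppa_single(ray, 1L)$location)
  expect_error(ppa_c(c(40, 40), vf_camera(), v1), "no point")
})

test_that("noiseless blob pinpointing is sub-voxel over a camera sweep", {
  ph <- blob_volume(centre = c(10, 10, 10), dims = c(21, 21, 21))
  worst <- 0
  for (k in 1:100) {
    cam <- vf_camera(random_rotation(k), zoom = 1)
    p <- ppa_c(project_point(c(10, 10, 10), cam), cam, ph$volume)
    worst <- max(worst, sqrt(sum((p$location - c(10, 10, 10))^2)))
  }
  expect_lt(worst, 1)
})

test_that("micro-stroke pinpointing falls back to a click for one point", {
  ph <- blob_volume(centre = c(10, 10, 10))
  cam <- vf_camera()
  one <- vf_stroke(matrix(c(10, 10), 1))
  expect_equal(ppa_n(one, cam, ph$volume)$location,
               ppa_c(c(10, 10), cam, ph$volume)$location)
})

test_that("micro-stroke pinpointing equals the first curve knot", {
  ph <- tube_volume()
  cam <- vf_camera()
  # interior tube section (away from the end caps, whose asymmetric
  # intensity legitimately pulls the converged point inward)
  s <- simulate_stroke(ph$centerline[20:60, ], cam, 5, 0)
  crv <- cda2_global(s, cam, ph$volume)
  pin <- ppa_n(s, cam, ph$volume)
  # the returned point is the first curve knot, converged onto the local
  # intensity centre (sub-voxel agreement on a clean tube)
  expect_lt(sqrt(sum((pin$location - crv$knots[1, ])^2)), 0.5)
})

test_that("micro-stroke pinpointing beats the click on noisy blobs", {
  hits_n <- 0L; err_n <- numeric(0); err_c <- numeric(0)
  ctr <- c(12, 12, 12)
  for (k in 1:40) {
    ph <- blob_volume(centre = ctr, dims = c(25, 25, 25), sigma = 2,
                      peak = 200, background = 0, noise_sigma = 100,
                      seed = k)
    cam <- vf_camera(random_rotation(k + 40))
    p0 <- project_point(ctr, cam)
    jit <- withr::with_seed(k, runif(2, -1, 1))
    # press at the click, short flick away: the returned point is the
    # stroke start
    micro <- withr::with_seed(k, {
      ang <- runif(1, 0, 2 * pi)
      base <- p0 + jit
      u <- 0.5 * c(cos(ang), sin(ang))
      vf_stroke(rbind(base, base + u, base + 2 * u, base + 3 * u,
                      base + 4 * u))
    })
    pn <- ppa_n(micro, cam, ph$volume)
    pc <- ppa_c(p0 + jit, cam, ph$volume)
    err_n <- c(err_n, sqrt(sum((pn$location - ctr)^2)))
    err_c <- c(err_c, sqrt(sum((pc$location - ctr)^2)))
    if (err_n[k] <= 2) hits_n <- hits_n + 1L
  }
  expect_gte(hits_n / 40, 0.95)
  expect_lte(mean(err_n), mean(err_c))
})

test_that("markers export 1-based CSV rows", {
  p <- structure(list(location = c(3, 4, 5), channel = 2L, intensity = 9,
                      confident = TRUE, sample_index = 1L),
                 class = "vf_pinpoint")
  f <- withr::local_tempfile(fileext = ".csv")
  write_markers(p, f)
  df <- read.csv(f)
  expect_equal(df$x, 4); expect_equal(df$y, 5); expect_equal(df$z, 6)
  expect_equal(df$channel, 2)
})
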