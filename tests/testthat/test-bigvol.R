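test_that("pyramid level dims follow the ceil-halving rule to the cap", {
  lv <- octree_levels(c(2048, 2048, 1024), c(512, 512, 256))
  expect_length(lv, 3L)
  expect_equal(lv[[1]], c(512L, 512L, 256L))
  expect_equal(lv[[2]], c(1024L, 1024L, 512L))
  expect_equal(lv[[3]], c(2048L, 2048L, 1024L))
  expect_length(octree_levels(c(100, 80, 60), c(512, 512, 256)), 1L)
  # odd dims halve with ceiling
  expect_equal(octree_levels(c(1025, 1024, 512), c(512, 512, 256))[[2]],
               c(513L, 512L, 256L))
})

test_that("octree stores round trip bit-exactly at full resolution", {
  v <- random_volume(c(40, 36, 28), 7)
  store <- withr::local_tempdir()
  idx <- build_octree(v, store, leaf_cap = c(16, 16, 16),
                      tile_size = c(16, 16, 16))
  nlev <- length(idx$levels)
  withr::with_seed(8, {
    for (k in 1:6) {
      lo <- c(sample(0:30, 1), sample(0:26, 1), sample(0:20, 1))
      hi <- pmin(lo + c(sample(1:9, 1), sample(1:9, 1), sample(1:7, 1)),
                 v$dims)
      res <- resolve_roi(idx, box3d(lo, hi), nlev, nlev)
      blk <- load_block(idx, res)
      expect_identical(blk$data, crop_volume(v, box3d(lo, hi))$data)
    }
  })
  # re-read the JSON index from disk and load again
  idx2 <- read_octree(store)
  res <- resolve_roi(idx2, box3d(c(3, 3, 3), c(19, 17, 11)), nlev, nlev)
  expect_identical(load_block(idx2, res)$data,
                   crop_volume(v, box3d(c(3, 3, 3), c(19, 17, 11)))$data)
})

test_that("blocks straddling many tiles assemble seamlessly", {
  v <- random_volume(c(34, 34, 34), 17)
  store <- withr::local_tempdir()
  idx <- build_octree(v, store, leaf_cap = c(64, 64, 64),
                      tile_size = c(16, 16, 16))
  res <- resolve_roi(idx, box3d(c(10, 10, 10), c(30, 30, 30)), 1, 1)
  expect_equal(length(res$tiles), 8L)
  expect_identical(load_block(idx, res)$data,
                   crop_volume(v, box3d(c(10, 10, 10), c(30, 30, 30)))$data)
  tiny <- resolve_roi(idx, box3d(c(5, 5, 5), c(6, 6, 6)), 1, 1)
  expect_equal(length(tiny$tiles), 1L)
  expect_equal(load_block(idx, tiny)$dims, c(1L, 1L, 1L))
})

test_that("coarser levels are 2x2x2 block means at ~1/8 voxel ratio", {
  v <- random_volume(c(32, 32, 32), 9)
  store <- withr::local_tempdir()
  idx <- build_octree(v, store, leaf_cap = c(16, 16, 16),
                      tile_size = c(16, 16, 16))
  expect_length(idx$levels, 2L)
  ratio <- prod(idx$levels[[1]]$dims) / prod(idx$levels[[2]]$dims)
  expect_close(ratio, 1 / 8, 0.01)
  res <- resolve_roi(idx, box3d(c(0, 0, 0), c(16, 16, 16)), 1, 1)
  coarse <- load_block(idx, res)
  # spot-check block means with round-half-up quantization
  for (p in list(c(1, 1, 1), c(5, 9, 2), c(16, 16, 16))) {
    blk <- v$data[(2 * p[1] - 1):(2 * p[1]), (2 * p[2] - 1):(2 * p[2]),
                  (2 * p[3] - 1):(2 * p[3]), 1]
    expect_equal(coarse$data[p[1], p[2], p[3], 1], floor(mean(blk) + 0.5))
  }
  # constant volumes stay constant across levels
  cv <- vf_volume(array(99, c(20, 20, 20)))
  store2 <- withr::local_tempdir()
  idx2 <- build_octree(cv, store2, leaf_cap = c(8, 8, 8),
                       tile_size = c(16, 16, 16))
  for (k in seq_along(idx2$levels)) {
    res <- resolve_roi(idx2, box3d(c(0, 0, 0), idx2$levels[[k]]$dims), k, k)
    expect_true(all(load_block(idx2, res)$data == 99))
  }
})

test_that("ROIs scale across levels by doubling and covering halves", {
  v <- random_volume(c(64, 64, 64), 4)
  store <- withr::local_tempdir()
  idx <- build_octree(v, store, leaf_cap = c(16, 16, 16),
                      tile_size = c(16, 16, 16))
  nlev <- length(idx$levels) # 3 levels: 16, 32, 64
  up <- resolve_roi(idx, box3d(c(0, 0, 0), c(8, 8, 8)), 1, 2)
  expect_equal(up$box$min, c(0L, 0L, 0L))
  expect_equal(up$box$max, c(16L, 16L, 16L))
  down <- resolve_roi(idx, box3d(c(3, 3, 3), c(9, 9, 9)), 2, 1)
  expect_equal(down$box$min, c(1L, 1L, 1L))
  expect_equal(down$box$max, c(5L, 5L, 5L))
  expect_error(resolve_roi(idx, box3d(c(0, 0, 0), c(20, 8, 8)), 1, 1),
               "out of bounds")
})

test_that("ROI resolution work is independent of the total volume size", {
  small <- random_volume(c(32, 32, 32), 1)
  big <- random_volume(c(96, 96, 96), 2)
  s1 <- withr::local_tempdir(); s2 <- withr::local_tempdir()
  i1 <- build_octree(small, s1, leaf_cap = c(16, 16, 16),
                     tile_size = c(16, 16, 16))
  i2 <- build_octree(big, s2, leaf_cap = c(16, 16, 16),
                     tile_size = c(16, 16, 16))
  roi <- box3d(c(4, 4, 4), c(20, 20, 20))
  r1 <- resolve_roi(i1, roi, length(i1$levels), length(i1$levels))
  r2 <- resolve_roi(i2, roi, length(i2$levels), length(i2$levels))
  # same ROI size => same number of tiles touched, despite 27x the voxels
  expect_equal(length(r1$tiles), length(r2$tiles))
  # and the tile count is bounded by the ROI extent, not the volume
  expect_lte(length(r2$tiles), prod(ceiling(box_dims(roi) / 16) + 1))
})

test_that("missing tiles are reported as integrity errors", {
  v <- random_volume(c(20, 20, 20), 3)
  store <- withr::local_tempdir()
  idx <- build_octree(v, store, leaf_cap = c(32, 32, 32),
                      tile_size = c(16, 16, 16))
  res <- resolve_roi(idx, box3d(c(0, 0, 0), c(20, 20, 20)), 1, 1)
  file.remove(file.path(store, res$tiles[[1]]$path))
  expect_error(load_block(idx, res), "missing tile")
})
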