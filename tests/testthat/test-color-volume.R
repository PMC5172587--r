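test_that("saturation extraction follows (max-min)/max scaled to 0..255", {
  mk <- function(rgb) {
    a <- array(0L, dim = c(1, 1, 3))
    a[1, 1, ] <- as.integer(rgb)
    section_stack(list(a), 0.28, 7)
  }
  expect_equal(extract_saturation(mk(c(128, 128, 128)))$data[1, 1, 1], 0L)
  expect_equal(extract_saturation(mk(c(200, 100, 0)))$data[1, 1, 1], 255L)
  expect_equal(extract_saturation(mk(c(0, 0, 0)))$data[1, 1, 1], 0L)
  # DAB brown is strongly saturated, background weakly
  expect_gt(extract_saturation(mk(c(120, 70, 20)))$data[1, 1, 1], 180)
  expect_lt(extract_saturation(mk(c(235, 230, 225)))$data[1, 1, 1], 30)
  # spacing metadata: (z, xy, xy)
  sat <- extract_saturation(flat_stack(n = 2, size = 8, xy = 0.5, z = 7))
  expect_equal(sat$spacing, c(7, 0.5, 0.5))
})

test_that("interpolation emits (n-1) * z/target planes; 21 sections at 7 um give 140", {
  st <- flat_stack(n = 21, size = 32)
  ip <- interpolate_slices(extract_saturation(st), 1)
  expect_equal(dim(ip$data)[1], 140L)
  expect_equal(ip$spacing[1], 1)
  # plane-count formula holds across configurations
  for (cfg in list(c(n = 3, z = 6, t = 2), c(n = 5, z = 4, t = 1),
                   c(n = 2, z = 8, t = 4))) {
    vol <- scalar_volume(array(100L, dim = c(cfg[["n"]], 8, 8)),
                         c(cfg[["z"]], 1, 1))
    ip2 <- interpolate_slices(vol, cfg[["t"]])
    expect_equal(dim(ip2$data)[1],
                 (cfg[["n"]] - 1) * cfg[["z"]] / cfg[["t"]])
  }
  expect_error(interpolate_slices(
    scalar_volume(array(0L, dim = c(1, 8, 8)), c(7, 1, 1)), 1), "input error")
  expect_error(interpolate_slices(
    scalar_volume(array(0L, dim = c(3, 8, 8)), c(7, 1, 1)), 3), "divide")
})

test_that("zero flow between identical slices reproduces them exactly", {
  set.seed(8)
  plane <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  vol <- array(0L, dim = c(3, 40, 40))
  vol[1, , ] <- plane; vol[2, , ] <- plane; vol[3, , ] <- plane
  ip <- interpolate_slices(scalar_volume(vol, c(4, 1, 1)), 1)
  for (k in seq_len(dim(ip$data)[1]))
    expect_identical(ip$data[k, , ], plane)
})

test_that("flow interpolation moves a translated disk linearly", {
  mkdisk <- function(cx) {
    img <- matrix(0L, 64, 64)
    for (y in 1:64) for (x in 1:64)
      if ((x - cx)^2 + (y - 32)^2 <= 100) img[y, x] <- 200L
    img
  }
  vol <- array(0L, dim = c(2, 64, 64))
  vol[1, , ] <- mkdisk(20)
  vol[2, , ] <- mkdisk(34)
  ip <- interpolate_slices(scalar_volume(vol, c(14, 1, 1)), 7)
  mid <- ip$data[2, , ]
  centroid_x <- sum(col(mid) * (mid > 100)) / sum(mid > 100)
  expect_equal(centroid_x, 27, tolerance = 1.5 / 27 * 27)
  expect_lt(abs(centroid_x - 27), 1.5)
  # output intensity range within input range
  expect_gte(min(ip$data), 0)
  expect_lte(max(ip$data), 200)
})
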