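rand_volume <- function(seed, n = 20, density = 0.2) {
  set.seed(seed)
  a <- array(sample(0:255, n^3, TRUE) * rbinom(n^3, 1, density),
             dim = c(n, n, n))
  scalar_volume(a, c(1, 1, 1))
}

test_that("threshold keeps values at or above t and blanks those below", {
  v <- scalar_volume(array(c(69L, 70L, 71L, 0L, 255L, 1L, 100L, 200L),
                           dim = c(2, 2, 2)), c(1, 1, 1))
  th <- threshold_volume(v, 70)
  expect_equal(as.vector(th$data), c(0L, 70L, 71L, 0L, 255L, 0L, 100L, 200L))
  all255 <- scalar_volume(array(255L, dim = c(3, 3, 3)), c(1, 1, 1))
  expect_identical(threshold_volume(all255, 70)$data, all255$data)
})

test_that("dilation and erosion match the brute-force spherical oracle", {
  for (seed in 1:4) {
    v <- rand_volume(seed)
    for (r in c(1, 2, 3)) {
      expect_identical(grey_dilate(v, r)$data,
                       array(as.integer(oracle_morph(v$data, r, "dilate")),
                             dim(v$data)),
                       info = sprintf("dilate seed %d r %d", seed, r))
      expect_identical(grey_erode(v, r)$data,
                       array(as.integer(oracle_morph(v$data, r, "erode")),
                             dim(v$data)),
                       info = sprintf("erode seed %d r %d", seed, r))
    }
  }
})

test_that("dilation is extensive and monotone; single voxel becomes a ball", {
  v <- rand_volume(9)
  d <- grey_dilate(v, 3)
  expect_true(all(d$data >= v$data))
  v2 <- v; v2$data <- pmin(v$data + 20L, 255L)
  expect_true(all(grey_dilate(v2, 3)$data >= d$data))
  one <- array(0L, dim = c(15, 15, 15)); one[8, 8, 8] <- 255L
  db <- grey_dilate(scalar_volume(one, c(1, 1, 1)), 3)$data
  kk <- slice.index(one, 1); jj <- slice.index(one, 2); ii <- slice.index(one, 3)
  ball <- (kk - 8)^2 + (jj - 8)^2 + (ii - 8)^2 <= 9
  expect_true(all(db[ball] == 255L) && all(db[!ball] == 0L))
})

test_that("closing is idempotent, leaves uniform volumes alone, bridges wall gaps", {
  v <- rand_volume(12)
  c1 <- grey_close(v, 2)
  expect_identical(grey_close(c1, 2)$data, c1$data)
  u <- scalar_volume(array(200L, dim = c(10, 10, 10)), c(1, 1, 1))
  expect_identical(grey_close(u, 3)$data, u$data)
  # tube wall with an 8-voxel gap, closing r = 10 bridges it
  tube <- array(0L, dim = c(40, 40, 40))
  kk <- slice.index(tube, 1); jj <- slice.index(tube, 2)
  ii <- slice.index(tube, 3)
  rr <- sqrt((jj - 20)^2 + (ii - 20)^2)
  tube[rr >= 8 & rr <= 11] <- 200L
  tube[kk >= 17 & kk <= 24] <- 0L  # 8-plane gap
  cl <- grey_close(scalar_volume(tube, c(1, 1, 1)), 10)
  expect_identical(cl$data, array(as.integer(oracle_close(tube, 10)),
                                  dim(tube)))
  # the gap planes were empty before closing and are bridged after
  expect_equal(sum(tube[17:24, , ] > 0), 0L)
  expect_gt(sum(cl$data[20, , ] > 0), 50)
})

test_that("hole filling solidifies enclosed lumina but not border-connected ones", {
  # hollow sphere shell at 200 -> solid ball
  a <- array(0L, dim = c(30, 30, 30))
  kk <- slice.index(a, 1); jj <- slice.index(a, 2); ii <- slice.index(a, 3)
  dist <- sqrt((kk - 15)^2 + (jj - 15)^2 + (ii - 15)^2)
  a[dist >= 8 & dist <= 10] <- 200L
  fh <- fill_holes(scalar_volume(a, c(1, 1, 1)))
  expect_true(all(fh$data[dist < 8] == 200L))
  ext <- oracle_exterior_mask(a)
  expect_true(all(fh$data[ext] == 0L))
  # open-ended tube touching the border stays open
  tube <- array(0L, dim = c(20, 20, 20))
  jj2 <- slice.index(tube, 2); ii2 <- slice.index(tube, 3)
  rr <- sqrt((jj2 - 10)^2 + (ii2 - 10)^2)
  tube[rr >= 5 & rr <= 7] <- 150L
  ft <- fill_holes(scalar_volume(tube, c(1, 1, 1)))
  expect_true(all(ft$data[rr < 5] == 0L))
  # solid volume unchanged
  solid <- scalar_volume(array(90L, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_identical(fill_holes(solid)$data, solid$data)
})

test_that("Gaussian blur matches the separable oracle and conserves mass", {
  v <- rand_volume(3, n = 16)
  expect_identical(gaussian_blur(v, 0.33)$data,
                   array(as.integer(oracle_blur(v$data, 0.33)), dim(v$data)))
  u <- scalar_volume(array(137L, dim = c(10, 10, 10)), c(1, 1, 1))
  expect_true(all(abs(gaussian_blur(u, 0.33)$data - 137L) <= 1L))
  # interior-supported blob: total intensity conserved within 0.5%
  blob <- array(0L, dim = c(24, 24, 24))
  blob[10:14, 10:14, 10:14] <- 200L
  bl <- gaussian_blur(scalar_volume(blob, c(1, 1, 1)), 1.2)
  expect_lt(abs(sum(as.numeric(bl$data)) - sum(as.numeric(blob))) /
              sum(as.numeric(blob)), 0.005)
})

test_that("the six-stage chain runs in order, deterministically, preserving stained voxels", {
  z <- scalar_volume(array(0L, dim = c(10, 10, 10)), c(1, 1, 1))
  out <- apply_chain(z)
  expect_true(all(out$data == 0L))
  v <- rand_volume(21, n = 24, density = 0.1)
  chain <- list(threshold = 70, close1_r = 3, fill_holes = TRUE,
                dilate_r = 2, close2_r = 2, blur_sigma = 0.33)
  a <- apply_chain(v, chain)
  b <- apply_chain(v, chain)
  expect_identical(a$data, b$data)
  log <- attr(a, "stage_log")
  expect_named(log, c("input", "threshold", "close1", "fill_holes",
                      "dilate", "close2", "blur"))
  # every voxel >= 70 survives (nonzero) to the pre-blur stage:
  # threshold keeps them, closing/fill/dilate are extensive on the support
  pre <- grey_close(grey_dilate(fill_holes(grey_close(
    threshold_volume(v, 70), 3)), 2), 2)
  expect_true(all(pre$data[v$data >= 70] > 0))
})

test_that("stage-difference report flags exactly the changed voxels in six panels", {
  v <- rand_volume(5, n = 12)
  rep_same <- stage_difference_report(v, v)
  expect_false(any(rep_same[["1"]]$mask))
  expect_length(rep_same[["1"]]$panels, 6L)
  dil <- grey_dilate(v, 1)
  rep_dil <- stage_difference_report(v, dil, gaps = 1L)
  mid <- dim(v$data)[1] %/% 2 + 1L
  expect_identical(rep_dil[["1"]]$mask,
                   dil$data[mid, , ] != v$data[mid, , ])
  expect_error(stage_difference_report(
    v, scalar_volume(array(0L, dim = c(2, 2, 2)), c(1, 1, 1))),
    "shape mismatch")
})
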