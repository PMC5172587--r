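test_that("stacks read with metadata and reject malformed input", {
  dir <- withr::local_tempdir()
  st <- flat_stack(n = 3, size = 16)
  paths <- write_stack(st, dir, format = "png")
  rd <- read_stack(paths, 0.28, 7)
  expect_length(rd$slices, 3)
  expect_equal(dim(rd$slices[[1]]), c(16, 16, 3))
  expect_equal(rd$xy_spacing, 0.28)
  expect_equal(rd$z_spacing, 7)
  expect_equal(rd$slices[[1]], st$slices[[1]])

  # mismatched dimensions
  small <- array(0L, dim = c(8, 8, 3))
  png::writePNG(small / 255, file.path(dir, "odd.png"))
  expect_error(read_stack(c(paths[1], file.path(dir, "odd.png")), 0.28, 7),
               "dimension")
  expect_error(read_stack(character(0), 0.28, 7), "input error")
  expect_error(read_stack("does-not-exist.png", 0.28, 7), "I/O")
  expect_error(section_stack(st$slices, -1, 7), "xy_spacing")
})

test_that("volume TIFF round trip is lossless including spacing", {
  dir <- withr::local_tempdir()
  set.seed(4)
  vol <- scalar_volume(array(sample(0:255, 8^3, TRUE), dim = c(8, 8, 8)),
                       c(1, 0.28, 0.28), "test")
  p <- file.path(dir, "vol.tif")
  write_volume(vol, p)
  rt <- read_volume(p)
  expect_identical(rt$data, vol$data)
  expect_equal(rt$spacing, c(1, 0.28, 0.28))
  expect_equal(rt$provenance, "test")
  expect_error(read_volume(file.path(dir, "nope.tif")), "I/O")
})

test_that("PLY round trip preserves geometry, colors and attributes", {
  dir <- withr::local_tempdir()
  cube <- box_mesh(10, 20, 30)
  cube$colors <- matrix(as.integer((seq_len(8 * 3) * 9) %% 256), 8, 3)
  cube$attrs$sdf_um <- as.numeric(1:8)
  p <- file.path(dir, "cube.ply")
  write_mesh(cube, p)
  rt <- read_mesh(p)
  expect_equal(n_vertices(rt), 8)
  expect_equal(n_faces(rt), 12)
  expect_equal(rt$vertices, cube$vertices)
  expect_equal(rt$faces, cube$faces)
  expect_equal(rt$colors, unname(cube$colors))
  expect_equal(rt$attrs$sdf_um, cube$attrs$sdf_um)

  # empty mesh is a valid file
  p2 <- file.path(dir, "empty.ply")
  write_mesh(surface_mesh(), p2)
  rt2 <- read_mesh(p2)
  expect_equal(n_vertices(rt2), 0)

  # OBJ keeps geometry; STL drops colors with a warning
  p3 <- file.path(dir, "cube.obj")
  write_mesh(cube, p3)
  rt3 <- read_mesh(p3)
  expect_equal(rt3$vertices, cube$vertices)
  p4 <- file.path(dir, "cube.stl")
  expect_warning(write_mesh(cube, p4), "colors dropped")
  rt4 <- read_mesh(p4)
  expect_equal(n_faces(rt4), 12)

  # non-manifold mesh reads with a message
  nm <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                           c(1, 1, 1)),
                     rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  p5 <- file.path(dir, "nm.ply")
  write_mesh(nm, p5)
  expect_message(read_mesh(p5), "non-manifold")
})

test_that("voxel index to world position uses (k,j,i) * spacing", {
  vol <- scalar_volume(array(0L, dim = c(3, 4, 5)), c(7, 0.5, 0.25))
  ext <- volume_extent(vol)
  expect_equal(unname(ext), c(4 * 0.25, 3 * 0.5, 2 * 7))
  # a single lit voxel at (k=2, j=3, i=4) 1-based meshes around
  # world (x, y, z) = (3*0.25, 2*0.5, 1*7)
  v <- array(0L, dim = c(3, 4, 5))
  v[2, 3, 4] <- 255L
  m <- extract_isosurface(scalar_volume(v, c(7, 0.5, 0.25)), 127.5)
  cen <- colMeans(m$vertices)
  expect_equal(cen, c(3 * 0.25, 2 * 0.5, 1 * 7), tolerance = 0.3)
})
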