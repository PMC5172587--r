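test_that("isosurface of a smooth ball is closed, accurate and spacing-aware", {
  v <- ball_volume(64, 25)
  m <- extract_isosurface(v, 127.5)
  expect_true(mesh_is_watertight(m))
  expect_lt(abs(mesh_area(m) - 4 * pi * 25^2) / (4 * pi * 25^2), 0.03)
  # Euler characteristic of a sphere is 2
  n_edges <- n_faces(m) * 3 / 2
  expect_equal(n_vertices(m) - n_edges + n_faces(m), 2)
  # outward normals: positive enclosed volume
  expect_gt(mesh_volume(m), 0)
  # all-zero volume -> empty mesh, not an error
  z <- scalar_volume(array(0L, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_equal(n_faces(extract_isosurface(z, 127.5)), 0)
  # anisotropic spacing: same voxel ball becomes an ellipsoid 1 : 0.28
  v2 <- scalar_volume(v$data, c(1, 0.28, 0.28))
  m2 <- extract_isosurface(v2, 127.5)
  bb <- mesh_bbox(m2)
  expect_equal(unname((bb[2, 1] - bb[1, 1]) / (bb[2, 3] - bb[1, 3])), 0.28,
               tolerance = 0.01)
})

test_that("isosurface orientation mirrors under volume complement", {
  v <- ball_volume(32, 10)
  m <- extract_isosurface(v, 127.5)
  vc <- v
  vc$data <- 255L - vc$data
  mc <- extract_isosurface(vc, 255 - 127.5)
  expect_gt(mesh_volume(m), 0)
  expect_lt(mesh_volume(mc), 0)  # same surface, normals flipped
  expect_equal(abs(mesh_volume(mc)), mesh_volume(m), tolerance = 1e-6)
})

test_that("healing closes holes, merges duplicates and keeps watertight meshes intact", {
  s <- icosphere(20, 3)
  v0 <- mesh_volume(s)
  holed <- s
  holed$faces <- holed$faces[-(1:5), ]
  h <- heal_and_solidify(holed)
  expect_true(mesh_is_watertight(h))
  expect_lt(abs(mesh_volume(h) - v0) / v0, 0.01)
  # already watertight: unchanged counts (genus preserved)
  h2 <- heal_and_solidify(s)
  expect_equal(n_vertices(h2), n_vertices(s))
  expect_equal(n_faces(h2), n_faces(s))
  # coincident duplicated vertex merged, face count unchanged
  dup <- surface_mesh(rbind(s$vertices, s$vertices[1, ]), s$faces)
  h3 <- heal_and_solidify(dup)
  expect_equal(n_vertices(h3), n_vertices(s))
  expect_equal(n_faces(h3), n_faces(s))
  # every component closed with positive volume
  hollow <- hollow_sphere()
  hh <- heal_and_solidify(hollow)
  expect_true(mesh_is_watertight(hh))
  comp <- connected_components(hh)
  for (ci in seq_len(comp$n_components)) {
    sub <- subset_mesh_for_test(hh, comp$component_id == ci)
    expect_gt(mesh_volume(sub), 0)
  }
})

test_that("Taubin smoothing preserves volume and connectivity; pure Laplacian shrinks", {
  s <- icosphere(15, 2)
  expect_mesh_equal(taubin_smooth(s, 0), s)
  v0 <- mesh_volume(s)
  sm <- taubin_smooth(s, 10)
  expect_equal(n_vertices(sm), n_vertices(s))
  expect_equal(sm$faces, s$faces)
  expect_lt(abs(mesh_volume(sm) - v0) / v0, 0.03)
  lap <- taubin_smooth(s, 10, lambda = 0.5, mu = 0)
  shrink_taubin <- (v0 - mesh_volume(sm)) / v0
  shrink_laplace <- (v0 - mesh_volume(lap)) / v0
  expect_gt(shrink_laplace, shrink_taubin)
  expect_gt(shrink_laplace, 0.05)
})

test_that("cut-surface labeling flags exactly the vertices on the block faces", {
  bbox <- rbind(min = c(0, 0, 0), max = c(10, 10, 10))
  bx <- box_mesh(10, 10, 10)
  bx <- label_cut_surface(bx, bbox, tol = 0.5)
  expect_true(all(bx$attrs$cut_surface))
  s <- icosphere(2, 2, center = c(5, 5, 5))
  s <- label_cut_surface(s, bbox, tol = 0.5)
  expect_false(any(s$attrs$cut_surface))
  cyl <- cylinder_mesh(3, 10, center = c(5, 5, 5))  # spans z = 0..10
  cyl <- label_cut_surface(cyl, bbox, tol = 0.5)
  on_ends <- abs(cyl$vertices[, 3]) < 0.5 | abs(cyl$vertices[, 3] - 10) < 0.5
  expect_identical(cyl$attrs$cut_surface, on_ends)
})
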