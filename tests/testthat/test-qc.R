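test_that("surface distance is exact: identity, parallel plates, Hausdorff oracle", {
  s <- icosphere(10, 2)
  d0 <- surface_distance(s, s)
  expect_true(all(d0$distance_um == 0))
  # parallel unit plates 5 um apart: interior vertices at exactly 5
  p1 <- box_mesh(50, 50, 1)
  p2 <- box_mesh(50, 50, 1, origin = c(0, 0, 6))
  dm <- surface_distance(p2, p1)
  bottom <- p2$vertices[, 3] == 6
  expect_true(all(dm$distance_um[bottom] == 5))
  expect_equal(dm$summary$max, max(dm$distance_um))
  expect_error(surface_distance(s, surface_mesh()), "empty")
  # symmetric Hausdorff equals the all-pairs point-triangle oracle
  for (seed in c(3, 14)) {
    set.seed(seed)
    a <- icosphere(8, 1, center = runif(3, -5, 5))
    b <- icosphere(6, 1, center = runif(3, -5, 5))
    expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b),
                 tolerance = 1e-9)
  }
})

test_that("distance coloring ramps blue to red, saturating at 10 um", {
  rgb <- colorize_distance(c(0, 12, 5, 10))
  expect_equal(rgb[1, ], c(0L, 0L, 255L))
  expect_equal(rgb[2, ], c(255L, 0L, 0L))
  expect_equal(rgb[3, ], c(128L, 0L, 128L))
  expect_equal(rgb[4, ], c(255L, 0L, 0L))
})

test_that("repair restores components farther than 10 um and is idempotent", {
  near <- icosphere(10, 2)
  far <- icosphere(8, 2, center = c(50, 0, 0))
  reference <- surface_mesh(rbind(near$vertices, far$vertices),
                            rbind(near$faces, far$faces + n_vertices(near)))
  processed <- near  # the far sphere was lost in processing
  rep1 <- repair_missing(reference, processed, 10)
  expect_equal(connected_components(rep1)$n_components, 2L)
  expect_equal(attr(rep1, "repair_report")$n_added, 1L)
  expect_true(any(rep1$attrs$repaired))
  # postcondition: every reference component within threshold of output
  d <- surface_distance(reference, rep1)
  set <- connected_components(reference)
  for (ci in seq_len(set$n_components))
    expect_lte(min(d$distance_um[set$component_id == ci]), 10)
  # nothing to repair -> unchanged
  rep0 <- repair_missing(reference, rep1, 10)
  expect_equal(attr(rep0, "repair_report")$n_added, 0L)
  expect_equal(n_vertices(rep0), n_vertices(rep1))
  # idempotence
  rep2 <- repair_missing(reference, rep1, 10)
  expect_equal(rep2$vertices, rep1$vertices)
  expect_equal(rep2$faces, rep1$faces)
  # empty processed mesh: everything is restored
  repall <- repair_missing(reference, surface_mesh(), 10)
  expect_equal(connected_components(repall)$n_components, 2L)
})

test_that("repair on phantoms with an injected lost network recovers the count", {
  ph <- small_phantom(seed = 23)
  vol <- rasterize_truth(ph$truth, 1)
  mesh <- heal_and_solidify(extract_isosurface(gaussian_blur(vol, 1), 127.5))
  set <- connected_components(mesh, metrics = FALSE)
  expect_gte(set$n_components, 2L)
  # delete every component of one truth network (all are > 10 um from
  # the other network by the generator's clearance guarantee)
  segs <- vesselrecon:::truth_segments(ph$truth)
  centroids <- do.call(rbind, lapply(seq_len(set$n_components), function(ci)
    colMeans(mesh$vertices[set$component_id == ci, , drop = FALSE])))
  near <- vesselrecon:::cpp_nearest_segment(centroids, segs[, 1:6])
  net <- ph$truth$edges$network_id[near$index]
  lost_net <- net[1]
  damaged <- subset_mesh_for_test(mesh, net[set$component_id] != lost_net)
  expect_lt(connected_components(damaged, metrics = FALSE)$n_components,
            set$n_components)
  repaired <- repair_missing(mesh, damaged, 10)
  expect_equal(connected_components(repaired, metrics = FALSE)$n_components,
               set$n_components)
})

test_that("mesh-on-scan overlay draws the analytic cross-section", {
  st <- flat_stack(n = 5, size = 100, rgb = c(235, 230, 225), xy = 1, z = 7)
  # sphere centered on slice 3 (z = 14), radius 20
  s <- icosphere(20, 3, center = c(50, 50, 14))
  img <- overlay_mesh_on_slice(s, st, 3)
  red <- img[, , 1] == 255 & img[, , 2] == 0
  expect_gt(sum(red), 50)
  # red pixels lie on a circle of radius 20 (+- 1 px)
  ys <- row(img[, , 1])[red] - 1; xs <- col(img[, , 1])[red] - 1
  rr <- sqrt((xs - 50)^2 + (ys - 50)^2)
  expect_true(all(abs(rr - 20) <= 1.5))
  # mesh entirely above the slice: image unchanged
  high <- icosphere(5, 2, center = c(50, 50, 30))
  expect_identical(overlay_mesh_on_slice(high, st, 1), st$slices[[1]])
  # deterministic
  expect_identical(overlay_mesh_on_slice(s, st, 3), img)
  expect_error(overlay_mesh_on_slice(s, st, 99), "input error")
})

test_that("blind-end census finds free tube ends but not cut or closed shapes", {
  bbox <- rbind(min = c(0, 0, 0), max = c(100, 100, 100))
  # cylinder spanning the full z-range: both ends cut -> 0 blind ends
  span <- cylinder_mesh(8, 100, center = c(50, 50, 50))
  expect_equal(nrow(blind_end_census(span, bbox = bbox)), 0L)
  # half-cylinder ending mid-volume -> exactly 1 blind end
  half <- cylinder_mesh(8, 50, center = c(50, 50, 25))
  census <- blind_end_census(half, bbox = bbox)
  expect_equal(nrow(census), 1L)
  expect_equal(census$z, 50, tolerance = 2)
  # closed torus inside the volume -> 0 blind ends
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  ph <- seq(0, 2 * pi, length.out = 17)[-17]
  R <- 30; r <- 8
  verts <- do.call(rbind, lapply(th, function(t) cbind(
    (R + r * cos(ph)) * cos(t) + 50, (R + r * cos(ph)) * sin(t) + 50,
    r * sin(ph) + 50)))
  nt <- length(th); np <- length(ph)
  faces <- do.call(rbind, lapply(seq_len(nt), function(i) {
    i2 <- if (i == nt) 1L else i + 1L
    do.call(rbind, lapply(seq_len(np), function(j) {
      j2 <- if (j == np) 1L else j + 1L
      rbind(c((i - 1) * np + j, (i2 - 1) * np + j, (i - 1) * np + j2),
            c((i2 - 1) * np + j, (i2 - 1) * np + j2, (i - 1) * np + j2))
    }))
  }))
  torus <- surface_mesh(verts, faces)
  expect_equal(nrow(blind_end_census(torus, bbox = bbox)), 0L)
})
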