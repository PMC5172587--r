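test_that("component labeling matches the union-find oracle", {
  # two disjoint spheres
  a <- icosphere(5, 1)
  b <- icosphere(5, 1, center = c(30, 0, 0))
  two <- surface_mesh(rbind(a$vertices, b$vertices),
                      rbind(a$faces, b$faces + n_vertices(a)))
  set <- connected_components(two)
  expect_equal(set$n_components, 2L)
  # random triangle soups against brute-force union-find
  for (seed in c(2, 7, 19)) {
    set.seed(seed)
    nv <- 80L
    verts <- matrix(runif(nv * 3, 0, 100), nv, 3)
    faces <- matrix(sample.int(nv, 200 * 3, TRUE), ncol = 3)
    faces <- faces[faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
                     faces[, 1] != faces[, 3], , drop = FALSE]
    soup <- surface_mesh(verts, faces)
    got <- connected_components(soup)$component_id
    want <- oracle_components(faces, nv)
    # same partition up to label permutation
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1L))
  }
  expect_equal(connected_components(surface_mesh())$n_components, 0L)
})

test_that("largest diameter is the exact pairwise maximum", {
  bx <- box_mesh(10, 20, 30)
  expect_equal(largest_diameter(bx$vertices), sqrt(10^2 + 20^2 + 30^2),
               tolerance = 1e-12)
  s <- icosphere(35, 3)
  expect_equal(largest_diameter(s$vertices), 70, tolerance = 0.5)
  expect_equal(largest_diameter(matrix(c(1, 2, 3), 1, 3)), 0)
  # large-set directional-extremes path agrees with the exact path
  set.seed(5)
  pts <- matrix(rnorm(3000 * 3, sd = 40), ncol = 3)
  expect_equal(largest_diameter(pts, exact_max = 100L),
               largest_diameter(pts), tolerance = 1e-3)
})

test_that("component filtering removes exactly the sub-threshold components", {
  a <- icosphere(30, 2)                       # diameter 60
  b <- icosphere(40, 2, center = c(200, 0, 0))  # diameter 80
  two <- surface_mesh(rbind(a$vertices, b$vertices),
                      rbind(a$faces, b$faces + n_vertices(a)))
  kept <- filter_components(two, min_diam = 70)
  expect_equal(connected_components(kept)$n_components, 1L)
  expect_gt(min(kept$vertices[, 1]), 100)
  rep <- attr(kept, "removal_report")
  expect_equal(rep$n_removed, 1L)
  expect_equal(rep$removed_fraction,
               mesh_area(a) / (mesh_area(a) + mesh_area(b)),
               tolerance = 1e-9)
  # cutoff 0 is the identity
  expect_mesh_equal(filter_components(two, min_diam = 0), two)
  # many random blobs: survivors equal brute-force diameter filter
  set.seed(31)
  blobs <- list(); offs <- numeric(0)
  for (i in 1:12) {
    r <- runif(1, 10, 60)
    blobs[[i]] <- icosphere(r, 1, center = c(i * 150, 0, 0))
    offs[i] <- 2 * r
  }
  verts <- do.call(rbind, lapply(blobs, `[[`, "vertices"))
  nv <- cumsum(c(0, vapply(blobs, n_vertices, 1)))
  faces <- do.call(rbind, lapply(seq_along(blobs), function(i)
    blobs[[i]]$faces + nv[i]))
  scene <- surface_mesh(verts, faces)
  set <- connected_components(scene)
  kept <- filter_components(scene, set, min_diam = 70)
  set2 <- connected_components(kept)
  exact_diam <- vapply(blobs, function(b) largest_diameter(b$vertices),
                       numeric(1))
  expect_equal(set2$n_components, sum(exact_diam >= 70))
})

test_that("diagonal-fraction thresholds give 70 um and 7 um for the reference block", {
  expect_equal(diagonal_fraction_threshold(c(980, 980, 140), 0.05), 70)
  expect_equal(diagonal_fraction_threshold(c(980, 980, 140), 0.005), 7)
  expect_error(diagonal_fraction_threshold(c(1, 0, 1), 0.05), "positive")
  expect_error(diagonal_fraction_threshold(c(1, 1, 1), 1.5), "fraction")
})

test_that("obscurance separates enclosed from exposed vertices and drives interior removal", {
  s <- icosphere(20, 3)
  so <- volumetric_obscurance(s, 64)
  # half-space open at every point of a convex surface (a coarse
  # polyhedral vertex opens slightly more than half)
  expect_true(all(so$attrs$obscurance >= 0.4))
  expect_true(all(so$attrs$obscurance <= 0.65))
  expect_equal(mean(so$attrs$obscurance), 0.5, tolerance = 0.1)
  hollow <- hollow_sphere()
  ho <- volumetric_obscurance(hollow, 48)
  inner <- sqrt(rowSums(hollow$vertices^2)) < 15
  expect_true(all(ho$attrs$obscurance[inner] == 0))
  expect_true(all(ho$attrs$obscurance[!inner] > 0.3))
  # interior point of a flat isolated plate: open over half the sphere
  plate <- cylinder_mesh(20, 0.5, n_theta = 32, n_len = 1)
  po <- volumetric_obscurance(plate, 64)
  cap_centers <- which(plate$vertices[, 1] == 0 & plate$vertices[, 2] == 0)
  expect_true(all(abs(po$attrs$obscurance[cap_centers] - 0.5) < 0.15))
  # removal deletes the inner shell, keeps the outer shell intact
  rem <- remove_interior(ho, 0.05)
  expect_equal(n_vertices(rem), sum(!inner))
  expect_true(all(sqrt(rowSums(rem$vertices^2)) > 15))
  # solid single-shell sphere unchanged; threshold 0 is the identity
  expect_equal(n_vertices(remove_interior(so, 0.05)), n_vertices(s))
  expect_mesh_equal(remove_interior(hollow, 0), hollow)
  # cut-surface safety contract
  flagged <- ho
  flagged$attrs$cut_surface <- inner
  expect_error(remove_interior(flagged, 0.05), "validation failure")
})

test_that("shape diameter reads true caliber on analytic shapes and scales linearly", {
  s <- shape_diameter(icosphere(20, 3))
  expect_true(all(abs(s$attrs$sdf_um - 40) < 2))
  cyl <- shape_diameter(cylinder_mesh(10, 200, n_theta = 48, n_len = 40))
  mid <- abs(cyl$vertices[, 3]) < 50
  expect_true(all(abs(cyl$attrs$sdf_um[mid] - 20) < 2))
  # thin plate reads its thickness from the broad side (flat-sinus caveat)
  plate <- shape_diameter(box_mesh(40, 40, 4))
  facev <- plate$vertices[, 3] %in% c(0, 4) &
    plate$vertices[, 1] > 0 & plate$vertices[, 1] < 40
  expect_true(all(abs(plate$attrs$sdf_um[facev] - 4) < 1))
  # x2 scaling doubles the field within 1%
  s2 <- icosphere(40, 3)
  f2 <- shape_diameter(s2)$attrs$sdf_um
  expect_equal(median(f2), 2 * median(s$attrs$sdf_um), tolerance = 0.01)
  # robust variant also tracks the diameter
  sr <- shape_diameter(icosphere(20, 3), method = "robust")
  expect_true(all(abs(sr$attrs$sdf_um - 40) < 3))
})

test_that("SDF coloring maps the 12/16.5/30 um breakpoints as specified", {
  vals <- c(10, 35, 16.5, 12, 30, NA)
  rgb <- colorize_sdf(vals)
  expect_equal(rgb[1, ], c(255L, 0L, 0L))       # below 12: pure red
  expect_equal(rgb[2, ], c(0L, 255L, 0L))       # above 30: pure green
  expect_equal(rgb[3, ], c(128L, 128L, 0L))     # center: half blend
  expect_equal(rgb[4, ], c(255L, 0L, 0L))       # at low end of ramp
  expect_equal(rgb[5, ], c(0L, 255L, 0L))       # at high end of ramp
  # monotone red -> green along the ramp
  ramp <- colorize_sdf(seq(12, 30, by = 0.5))
  expect_true(all(diff(ramp[, 1]) <= 0))
  expect_true(all(diff(ramp[, 2]) >= 0))
  expect_error(colorize_sdf(vals, low = 20, high = 30, center = 16.5))
})

test_that("connectivity classification applies the 7/28 um band and area ranking", {
  mk <- function(d, x) icosphere(d / 2, 1, center = c(x, 0, 0))
  parts <- list(mk(5, 0), mk(15, 100), mk(100, 400), mk(400, 1000))
  verts <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  nv <- cumsum(c(0, vapply(parts, n_vertices, 1)))
  faces <- do.call(rbind, lapply(seq_along(parts), function(i)
    parts[[i]]$faces + nv[i]))
  scene <- surface_mesh(verts, faces)
  cls <- classify_connectivity(scene, small_min = 7, small_max = 28,
                               n_large = 1)
  tab <- attr(cls, "class_table")
  expect_equal(nrow(tab), 3L)  # 5 um sphere discarded
  tab <- tab[order(tab$diameter_um), ]
  expect_equal(tab$class, c(3L, 2L, 1L))  # red, green, light blue
  expect_equal(tab$rank[3], 1L)
  # ten similar networks with n_large = 10: 1 light blue + 9 dark blue
  many <- lapply(1:10, function(i) mk(100 + i, i * 300))
  verts <- do.call(rbind, lapply(many, `[[`, "vertices"))
  nv <- cumsum(c(0, vapply(many, n_vertices, 1)))
  faces <- do.call(rbind, lapply(seq_along(many), function(i)
    many[[i]]$faces + nv[i]))
  ten <- classify_connectivity(surface_mesh(verts, faces), n_large = 10)
  tab10 <- attr(ten, "class_table")
  expect_equal(sum(tab10$rank == 1), 1L)
  expect_equal(sum(tab10$rank %in% 2:10), 9L)
  cols <- unique(as.data.frame(ten$colors))
  expect_equal(nrow(cols), 2L)  # light blue + dark blue only
  # small_min = 0 keeps everything
  all_kept <- classify_connectivity(scene, small_min = 0)
  expect_equal(nrow(attr(all_kept, "class_table")), 4L)
  expect_error(classify_connectivity(scene, n_large = 0), "config error")
  # empty mesh passes through
  expect_equal(n_vertices(classify_connectivity(surface_mesh())), 0L)
})
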