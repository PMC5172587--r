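# Programmatic fixtures shared across test files.

# uniform-color RGB slice stack
flat_stack <- function(n = 21, size = 64, rgb = c(120, 70, 20),
                       xy = 0.28, z = 7) {
  sl <- replicate(n, {
    a <- array(0L, dim = c(size, size, 3))
    a[, , 1] <- rgb[1]; a[, , 2] <- rgb[2]; a[, , 3] <- rgb[3]
    a
  }, simplify = FALSE)
  section_stack(sl, xy, z)
}

# anti-aliased solid ball volume (smooth 2-voxel transition, as the blur
# stage of the pipeline produces); value 255 inside, 0 outside
ball_volume <- function(n = 64, radius = 25, center = (n + 1) / 2,
                        spacing = c(1, 1, 1), width = 2) {
  vol <- array(0L, dim = c(n, n, n))
  kk <- slice.index(vol, 1); jj <- slice.index(vol, 2)
  ii <- slice.index(vol, 3)
  dist <- sqrt((kk - center)^2 + (jj - center)^2 + (ii - center)^2)
  vol[] <- as.integer(round(255 * pmin(1, pmax(0, (radius - dist) / width + 0.5))))
  scalar_volume(vol, spacing)
}

# hollow sphere mesh: outer shell + inward-facing inner shell
hollow_sphere <- function(r_out = 20, r_in = 10, subdiv = 2) {
  outer <- icosphere(r_out, subdiv)
  inner <- icosphere(r_in, subdiv)
  inner$faces <- inner$faces[, c(1, 3, 2)]
  surface_mesh(rbind(outer$vertices, inner$vertices),
               rbind(outer$faces, inner$faces + n_vertices(outer)))
}

# small clean phantom rendered at desk scale (shared by pipeline tests)
small_phantom <- function(seed = 11) {
  spec <- phantom_spec(domain_size = c(140, 140, 84),
                       n_capillary_networks = 1, n_sinus_networks = 1,
                       sinus_diam_range = c(30, 36),
                       n_cross_connections = 0,
                       network_length_um = c(capillary = 250, sinus = 120),
                       defect_rates = list(wall_gap_per_100um = 0,
                                           collapse_fraction = 0,
                                           isolated_cells_per_mm3 = 0),
                       seed = seed)
  truth <- generate_network(spec)
  list(spec = spec, truth = truth)
}

expect_mesh_equal <- function(a, b, tol = 1e-12) {
  expect_equal(n_vertices(a), n_vertices(b))
  expect_equal(n_faces(a), n_faces(b))
  expect_equal(a$vertices, b$vertices, tolerance = tol)
  expect_equal(a$faces, b$faces)
}

subset_mesh_for_test <- function(mesh, keep) vesselrecon:::subset_mesh(mesh, keep)
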