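test_that("network generation is seeded-deterministic with requested topology", {
  ph <- small_phantom(seed = 1)
  t1 <- generate_network(ph$spec)
  t2 <- generate_network(ph$spec)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)
  # disjoint classes: component count equals network count without links
  spec0 <- phantom_spec(domain_size = c(140, 140, 120),
                        n_capillary_networks = 1, n_sinus_networks = 1,
                        sinus_diam_range = c(30, 40),
                        n_cross_connections = 0, seed = 3)
  expect_equal(n_true_networks(generate_network(spec0)), 2L)
  # one cross connection joins them (union-find over the edge graph)
  spec1 <- phantom_spec(domain_size = c(140, 140, 120),
                        n_capillary_networks = 1, n_sinus_networks = 1,
                        sinus_diam_range = c(30, 40),
                        n_cross_connections = 1, seed = 3)
  t3 <- generate_network(spec1)
  expect_equal(n_true_networks(t3), 1L)
  expect_true(any(t3$edges$cross_link))
  # oracle check on the same graph
  nv <- nrow(t3$nodes)
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(t3$edges)))
    parent[find(t3$edges$from[i])] <- find(t3$edges$to[i])
  used <- unique(c(t3$edges$from, t3$edges$to))
  expect_equal(length(unique(vapply(used, find, integer(1)))), 1L)
  # centerlines inside the domain; class diameters within their ranges
  expect_true(all(t3$nodes >= 0 &
                    t3$nodes <= rep(spec1$domain_size, each = nrow(t3$nodes))))
  caps <- t3$edges$class == "capillary"
  expect_true(all(t3$edges$diameter_um[caps] <= 12))
  expect_true(all(t3$edges$diameter_um[!caps] >= 30))
  # domain too small
  expect_error(generate_network(
    phantom_spec(domain_size = c(30, 30, 30), sinus_diam_range = c(30, 40))),
    "generation error")
})

test_that("rasterization produces the analytic wall shell and cell disks", {
  # single straight capillary, diameter 10: mid-slice ring of outer
  # diameter ~10 um
  nodes <- rbind(c(20, 20, 5), c(20, 20, 35))
  edges <- data.frame(from = 1, to = 2, diameter_um = 10,
                      class = "capillary", network_id = 1, flatness = 1,
                      e1x = 1, e1y = 0, e1z = 0, cross_link = FALSE)
  truth <- structure(list(nodes = nodes, edges = edges,
                          cells = data.frame(),
                          domain_size = c(40, 40, 40),
                          spec = list(wall_thickness = 1.5)),
                     class = "phantom_truth")
  vol <- rasterize_truth(truth, 0.5)
  mid <- vol$data[41, , ]  # z = 20 um
  on <- which(mid > 0, arr.ind = TRUE)
  rr <- sqrt(((on[, 1] - 1) * 0.5 - 20)^2 + ((on[, 2] - 1) * 0.5 - 20)^2)
  expect_equal(max(rr), 5, tolerance = 0.5)
  expect_equal(min(rr), 3.5, tolerance = 0.5)   # 5 - wall 1.5
  # empty truth -> all-zero volume
  empty <- truth; empty$edges <- edges[0, ]
  expect_true(all(rasterize_truth(empty, 1)$data == 0L))
  # 8 um sphere cell at 0.5 um spacing: filled equatorial disk ~16 voxels wide
  ct <- truth
  ct$edges <- edges[0, ]
  ct$cells <- data.frame(x = 20, y = 20, z = 20, diameter_um = 8)
  cv <- rasterize_truth(ct, 0.5, what = "solid", include_cells = TRUE)
  eq <- cv$data[41, , ]
  widths <- range(which(rowSums(eq > 0) > 0))
  expect_equal(diff(widths) + 1, 17, tolerance = 2)
  expect_true(all(eq[41, (41 - 7):(41 + 7)] > 0))  # filled, not a ring
})

test_that("rendered sections are deterministic, brown-on-light, and cover the truth", {
  ph <- small_phantom(seed = 5)
  st1 <- render_sections(ph$truth, ph$spec, xy_spacing = 1, z_spacing = 7)
  st2 <- render_sections(ph$truth, ph$spec, xy_spacing = 1, z_spacing = 7)
  expect_identical(st1$slices, st2$slices)
  expect_equal(length(st1$slices), ph$spec$domain_size[3] / 7 + 1)
  expect_error(render_sections(ph$truth, ph$spec, xy_spacing = 8,
                               z_spacing = 7))
  # thresholded saturation vs rasterized truth: IoU >= 0.85 at fine spacing
  st <- render_sections(ph$truth, ph$spec, xy_spacing = 0.5, z_spacing = 7)
  sat <- extract_saturation(st)
  pred <- sat$data >= 70
  want <- rasterize_truth(ph$truth, c(7, 0.5, 0.5))$data > 0
  iou <- sum(pred & want) / sum(pred | want)
  expect_gte(iou, 0.85)
})

test_that("defect rates shape the rendering: gaps erase stain, collapse thins capillaries", {
  base <- small_phantom(seed = 9)
  spec_def <- base$spec
  spec_def$defect_rates <- list(wall_gap_per_100um = 5,
                                collapse_fraction = 1,
                                isolated_cells_per_mm3 = 0)
  clean <- render_sections(base$truth, base$spec, xy_spacing = 1)
  defected <- render_sections(base$truth, spec_def, xy_spacing = 1)
  stain_px <- function(st) sum(extract_saturation(st)$data >= 70)
  expect_lt(stain_px(defected), stain_px(clean))
})

test_that("recovery evaluation scores a rasterized-truth mesh highly", {
  ph <- small_phantom(seed = 13)
  vol <- rasterize_truth(ph$truth, 1, what = "solid")
  mesh <- heal_and_solidify(extract_isosurface(gaussian_blur(vol, 1), 127.5))
  mesh <- shape_diameter(mesh)
  rep <- evaluate_recovery(ph$truth, mesh)
  expect_equal(rep$n_true_networks, 2L)
  expect_gte(rep$vertex_class_accuracy, 0.9)
  expect_true(rep$n_found_networks >= 2L)
  # empty mesh: zeroed report
  rep0 <- evaluate_recovery(ph$truth, surface_mesh())
  expect_equal(rep0$n_found_networks, 0L)
  expect_equal(rep0$vertex_class_accuracy, 0)
  expect_false(rep0$topology_match)
})

test_that("truth graphs round-trip through JSON", {
  dir <- withr::local_tempdir()
  ph <- small_phantom(seed = 2)
  p <- file.path(dir, "truth.json")
  write_truth(ph$truth, p)
  rt <- read_truth(p)
  expect_equal(unname(rt$nodes), unname(ph$truth$nodes), tolerance = 1e-12)
  expect_equal(rt$edges$diameter_um, ph$truth$edges$diameter_um)
  expect_equal(rt$edges$class, ph$truth$edges$class)
  expect_equal(rt$domain_size, ph$truth$domain_size)
})

test_that("increasing collapse fraction never merges capillary fragments (monotone fragmentation)", {
  ph <- small_phantom(seed = 17)
  counts <- vapply(c(0, 0.5, 1), function(cf) {
    spec <- ph$spec
    spec$defect_rates$collapse_fraction <- cf
    st <- render_sections(ph$truth, spec, xy_spacing = 1, z_spacing = 7)
    sat <- extract_saturation(st)
    ip <- interpolate_slices(sat, 1)
    chain <- pipeline_config()$filter_chain
    filt <- apply_chain(ip, chain)
    mesh <- heal_and_solidify(extract_isosurface(filt))
    connected_components(mesh)$n_components
  }, numeric(1))
  expect_true(all(diff(counts) >= 0) || counts[1] == counts[3])
})
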