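#' Specification of a synthetic microvessel phantom
#'
#' Describes a synthetic bone-marrow block: networks of narrow capillaries
#' and wide sinuses growing in segregated subdomains (mirroring capillary
#' networks in pure adipose tissue and sinus networks in haematopoietic
#' areas), optional end-to-side anastomoses between the two classes, and
#' the artefact taxonomy of stained serial sections — wall gaps, collapsed
#' capillaries and isolated stained cells.
#'
#' Networks are grown as biased random-walk trees (step 10 um, branching
#' probability 0.15) inside disjoint per-network boxes whose margins
#' guarantee a minimum surface clearance between distinct networks, so
#' morphological closing cannot fuse them. Sinus tubes are elliptical with
#' a per-network flatness ratio up to `sinus_flatness_max` : 1 (flat
#' sinuses extended along z are a prominent feature of real specimens).
#'
#' @param domain_size `(x, y, z)` block size in um.
#' @param n_capillary_networks,n_sinus_networks network counts.
#' @param capillary_diam_range,sinus_diam_range outer-diameter ranges in
#'   um; the class ranges must not overlap.
#' @param n_cross_connections number of capillary-to-sinus end-to-side
#'   anastomoses.
#' @param wall_thickness stained endothelial wall thickness in um.
#' @param defect_rates list with `wall_gap_per_100um` (gaps per 100 um of
#'   centerline), `collapse_fraction` (fraction of capillary edges
#'   rendered collapsed to ~2 um), `isolated_cells_per_mm3`.
#' @param seed integer seed; all generator operations are deterministic
#'   given the seed.
#' @param step_um random-walk step length.
#' @param branch_prob branching probability per step.
#' @param network_length_um target total centerline length per network,
#'   named by class.
#' @param clearance_um minimum surface-to-surface clearance between
#'   distinct networks (default 25 um: beyond the ~2r-voxel bridging
#'   reach of the radius-10 closing at 1 um voxels, so morphology cannot
#'   fuse separate networks).
#' @param sinus_flatness_max maximal flatness ratio of sinus
#'   cross-sections.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(domain_size = c(180, 180, 140),
                         n_capillary_networks = 1L,
                         n_sinus_networks = 2L,
                         capillary_diam_range = c(2, 12),
                         sinus_diam_range = c(30, 60),
                         n_cross_connections = 0L,
                         wall_thickness = 1.5,
                         defect_rates = list(wall_gap_per_100um = 0.5,
                                             collapse_fraction = 0.1,
                                             isolated_cells_per_mm3 = 5000),
                         seed = 1L,
                         step_um = 10,
                         branch_prob = 0.15,
                         network_length_um = c(capillary = 600, sinus = 250),
                         clearance_um = 25,
                         sinus_flatness_max = 3) {
  stopifnot(length(domain_size) == 3L, all(domain_size > 0),
            all(capillary_diam_range > 0), all(sinus_diam_range > 0),
            diff(capillary_diam_range) >= 0, diff(sinus_diam_range) >= 0)
  if (capillary_diam_range[2] >= sinus_diam_range[1])
    stop("capillary and sinus diameter ranges must not overlap")
  structure(as.list(environment()), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %g x %g x %g um, %d capillary + %d sinus networks, %d cross-links, seed %d\n",
    x$domain_size[1], x$domain_size[2], x$domain_size[3],
    x$n_capillary_networks, x$n_sinus_networks, x$n_cross_connections,
    x$seed))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

rand_unit <- function() unit(rnorm(3))

perp_axis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(c(d[2] * a[3] - d[3] * a[2], d[3] * a[1] - d[1] * a[3],
         d[1] * a[2] - d[2] * a[1]))
}

#' Generate a ground-truth microvessel network
#'
#' Deterministic given the spec seed. Produces the requested counts of
#' mutually disjoint capillary and sinus networks (capillaries and
#' sinuses occupy different subdomains and are at least partially
#' arranged in parallel), plus exactly `n_cross_connections` end-to-side
#' anastomoses from a capillary terminal onto a sinus side. All
#' centerlines lie inside the domain with full radial clearance from the
#' domain's x/y walls.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom_truth`: `nodes` (n x 3 um),
#'   `edges` (data.frame: `from`, `to`, `diameter_um`, `class`,
#'   `network_id`, `flatness`, `e1x..e1z`, `cross_link`), `cells`
#'   (isolated stained cells), and `domain_size`.
#' @export
generate_network <- function(spec) {
  with_seed(spec$seed, {
    X <- spec$domain_size[1]; Y <- spec$domain_size[2]; Z <- spec$domain_size[3]
    n_cap <- spec$n_capillary_networks; n_sin <- spec$n_sinus_networks
    regions <- list()
    if (n_cap > 0 && n_sin > 0) {
      split_x <- 0.45 * X
      regions$capillary <- c(0, split_x)
      regions$sinus <- c(split_x, X)
    } else if (n_cap > 0) regions$capillary <- c(0, X)
    else regions$sinus <- c(0, X)
    nodes <- matrix(numeric(0), 0, 3)
    edges <- list()
    net_id <- 0L
    plan <- c(rep("capillary", n_cap), rep("sinus", n_sin))
    class_count <- c(capillary = n_cap, sinus = n_sin)
    class_idx <- c(capillary = 0L, sinus = 0L)
    for (cls in plan) {
      net_id <- net_id + 1L
      class_idx[cls] <- class_idx[cls] + 1L
      drange <- if (cls == "capillary") spec$capillary_diam_range
                else spec$sinus_diam_range
      rmax <- drange[2] / 2
      margin <- rmax + spec$clearance_um / 2
      xr <- regions[[cls]]
      nb <- class_count[cls]
      yw <- Y / nb
      box <- rbind(
        lo = c(xr[1] + margin, (class_idx[cls] - 1) * yw + margin, margin),
        hi = c(xr[2] - margin, class_idx[cls] * yw - margin, Z - margin))
      if (any(box["hi", ] - box["lo", ] <= 0))
        stop("generation error: domain too small for requested diameters")
      flat_net <- if (cls == "sinus") runif(1, 1, spec$sinus_flatness_max) else 1
      bias <- if (cls == "sinus") c(0, 0, 0.5) * sample(c(-1, 1), 1) else c(0, 0, 0)
      target <- spec$network_length_um[[cls]]
      start <- box["lo", ] + runif(3) * (box["hi", ] - box["lo", ])
      nodes <- rbind(nodes, start)
      base_d <- runif(1, drange[1], drange[2])
      walkers <- list(list(node = nrow(nodes), dir = rand_unit(),
                           diam = base_d))
      total <- 0
      while (total < target && length(walkers)) {
        w <- walkers[[1]]
        walkers <- walkers[-1]
        nd <- unit(0.65 * w$dir + 0.35 * rand_unit() + bias)
        np <- nodes[w$node, ] + spec$step_um * nd
        for (a in 1:3) {  # reflect into the network box
          if (np[a] < box["lo", a]) { np[a] <- 2 * box["lo", a] - np[a]; nd[a] <- -nd[a] }
          if (np[a] > box["hi", a]) { np[a] <- 2 * box["hi", a] - np[a]; nd[a] <- -nd[a] }
          np[a] <- min(max(np[a], box["lo", a]), box["hi", a])
        }
        diam <- min(max(0.8 * w$diam + 0.2 * runif(1, drange[1], drange[2]),
                        drange[1]), drange[2])
        flat <- if (cls == "sinus")
          min(max(flat_net * runif(1, 0.9, 1.1), 1), spec$sinus_flatness_max)
        else 1
        seg_dir <- unit(np - nodes[w$node, ])
        e1 <- perp_axis(seg_dir)
        nodes <- rbind(nodes, np)
        edges[[length(edges) + 1L]] <- data.frame(
          from = w$node, to = nrow(nodes), diameter_um = diam, class = cls,
          network_id = net_id, flatness = flat, e1x = e1[1], e1y = e1[2],
          e1z = e1[3], cross_link = FALSE)
        total <- total + spec$step_um
        w2 <- list(node = nrow(nodes), dir = nd, diam = diam)
        walkers <- c(walkers, list(w2))
        if (runif(1) < spec$branch_prob)
          walkers <- c(walkers, list(list(node = nrow(nodes),
                                          dir = rand_unit(),
                                          diam = max(drange[1], 0.9 * diam))))
      }
    }
    edges <- do.call(rbind, edges)
    rownames(nodes) <- NULL
    # end-to-side cross connections capillary -> sinus
    if (spec$n_cross_connections > 0) {
      if (n_cap < 1 || n_sin < 1)
        stop("generation error: cross connections need both vessel classes")
      cap_edges <- edges[edges$class == "capillary", ]
      sin_edges <- edges[edges$class == "sinus", ]
      deg <- table(c(edges$from, edges$to))
      terminals <- intersect(
        as.integer(names(deg)[deg == 1L]),
        unique(c(cap_edges$from, cap_edges$to)))
      for (ci in seq_len(spec$n_cross_connections)) {
        term <- terminals[1 + (ci - 1) %% length(terminals)]
        p <- nodes[term, ]
        mids <- (nodes[sin_edges$from, , drop = FALSE] +
                   nodes[sin_edges$to, , drop = FALSE]) / 2
        dd <- sqrt(rowSums(sweep(mids, 2, p)^2))
        si <- which.min(dd)
        targetp <- mids[si, ] - unit(mids[si, ] - p) * sin_edges$diameter_um[si] / 4
        cap_net <- edges$network_id[edges$from == term | edges$to == term][1]
        cap_d <- edges$diameter_um[edges$from == term | edges$to == term][1]
        nsteps <- max(2L, ceiling(sqrt(sum((targetp - p)^2)) / spec$step_um))
        prev <- term
        for (s in seq_len(nsteps)) {
          q <- p + (targetp - p) * s / nsteps
          nodes <- rbind(nodes, q)
          e1 <- perp_axis(unit(targetp - p))
          edges <- rbind(edges, data.frame(
            from = prev, to = nrow(nodes), diameter_um = cap_d,
            class = "capillary", network_id = cap_net, flatness = 1,
            e1x = e1[1], e1y = e1[2], e1z = e1[3], cross_link = TRUE))
          prev <- nrow(nodes)
        }
        # land on the sinus axis so the graphs are truly joined
        edges$to[nrow(edges)] <- sin_edges$from[si]
        nodes <- nodes[-nrow(nodes), , drop = FALSE]
      }
    }
    vol_mm3 <- prod(spec$domain_size) * 1e-9
    n_cells <- rpois(1, spec$defect_rates$isolated_cells_per_mm3 * vol_mm3)
    cells <- data.frame(
      x = runif(n_cells, 5, X - 5), y = runif(n_cells, 5, Y - 5),
      z = runif(n_cells, 5, Z - 5), diameter_um = runif(n_cells, 6, 10))
    structure(list(nodes = nodes, edges = edges, cells = cells,
                   domain_size = spec$domain_size, spec = spec),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> %d nodes, %d edges, %d networks (%d connected), %d cells\n",
    nrow(x$nodes), nrow(x$edges), length(unique(x$edges$network_id)),
    n_true_networks(x), nrow(x$cells)))
  invisible(x)
}

#' Number of connected networks in the truth graph
#'
#' Connected components of the centerline graph, counting cross-link
#' anastomoses as connections.
#' @param truth a [phantom_truth][generate_network].
#' @return integer component count.
#' @export
n_true_networks <- function(truth) {
  if (!nrow(truth$edges)) return(0L)
  g <- igraph::graph_from_edgelist(
    cbind(truth$edges$from, truth$edges$to), directed = FALSE)
  memb <- igraph::components(g)$membership
  used <- unique(c(truth$edges$from, truth$edges$to))
  length(unique(memb[used]))
}

# edge-wise connected-component id (cross links merge networks)
edge_graph_components <- function(truth) {
  g <- igraph::graph_from_edgelist(
    cbind(truth$edges$from, truth$edges$to), directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[truth$edges$from]
}

truth_segments <- function(truth, wall = NULL, diam = NULL) {
  e <- truth$edges
  if (is.null(diam)) diam <- e$diameter_um
  if (is.null(wall)) wall <- truth$spec$wall_thickness
  cbind(truth$nodes[e$from, 1], truth$nodes[e$from, 2], truth$nodes[e$from, 3],
        truth$nodes[e$to, 1], truth$nodes[e$to, 2], truth$nodes[e$to, 3],
        diam / 2, wall, e$e1x, e$e1y, e$e1z, e$flatness)
}

grid_dims <- function(domain, spacing) {
  floor(domain / spacing + 1e-9) + 1L
}

#' Rasterize ground-truth vessel walls into a volume
#'
#' Binary occupancy of the stained wall shell (outer radius minus
#' `wall_thickness`) at 255; elliptical sinus cross-sections are honoured
#' and tube junctions keep clean lumina (solid union minus lumen union).
#'
#' @param truth a [phantom_truth][generate_network].
#' @param spacing voxel spacing `(z, y, x)` in um or a scalar.
#' @param what `"wall"` (default) or `"solid"` occupancy.
#' @param include_cells also rasterize isolated stained cells.
#' @return a [scalar_volume] with values 0/255.
#' @export
rasterize_truth <- function(truth, spacing, what = c("wall", "solid"),
                            include_cells = FALSE) {
  what <- match.arg(what)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0))
  d <- grid_dims(truth$domain_size[c(3, 2, 1)], spacing)
  segs <- if (nrow(truth$edges)) truth_segments(truth)
          else matrix(numeric(0), 0, 12)
  if (include_cells && nrow(truth$cells))
    segs <- rbind(segs, cell_segments(truth$cells))
  if (nrow(segs) == 0) {
    return(scalar_volume(array(0L, dim = d), spacing, "rasterized_truth"))
  }
  res <- cpp_rasterize_tubes(segs, d[1], d[2], d[3],
                             spacing[1], spacing[2], spacing[3])
  out <- if (what == "solid") res$solid
         else { x <- res$solid; x[res$lumen > 0L] <- 0L; x }
  dim(out) <- d
  scalar_volume(out, spacing, "rasterized_truth")
}

cell_segments <- function(cells) {
  n <- nrow(cells)
  cbind(cells$x, cells$y, cells$z, cells$x, cells$y, cells$z,
        cells$diameter_um / 2, cells$diameter_um / 2,  # solid spheres
        1, 0, 0, 1)
}

#' Render a phantom as a stained serial-section stack
#'
#' Samples one section every `z_spacing` um and renders a brown-on-light
#' DAB-like image: stained wall voxels around RGB(120, 70, 20), background
#' around RGB(235, 230, 225), with Gaussian pixel noise. Defects are
#' applied at the spec rates: unstained wall arcs (sectioning damage),
#' capillaries collapsed to about 2 um lumen, and isolated stained cells.
#' Deterministic for a given spec seed.
#'
#' @param truth a [phantom_truth][generate_network].
#' @param spec the [phantom_spec] (defect rates, wall thickness, seed).
#' @param xy_spacing rendered pixel spacing in um/px.
#' @param z_spacing section thickness in um (>= `xy_spacing`).
#' @return a [section_stack].
#' @export
render_sections <- function(truth, spec = truth$spec, xy_spacing,
                            z_spacing = 7) {
  stopifnot(z_spacing >= xy_spacing)
  with_seed(spec$seed + 1000L, {
    spacing <- c(z_spacing, xy_spacing, xy_spacing)
    d <- grid_dims(truth$domain_size[c(3, 2, 1)], spacing)
    diam <- truth$edges$diameter_um
    collapse <- truth$edges$class == "capillary" &
      runif(nrow(truth$edges)) < spec$defect_rates$collapse_fraction
    diam[collapse] <- 2
    segs <- truth_segments(truth, diam = diam)
    res <- cpp_rasterize_tubes(segs, d[1], d[2], d[3],
                               spacing[1], spacing[2], spacing[3])
    stain <- res$solid > 0L & !(res$lumen > 0L)
    if (nrow(truth$cells)) {
      cs <- cpp_rasterize_tubes(cell_segments(truth$cells),
                                d[1], d[2], d[3],
                                spacing[1], spacing[2], spacing[3])
      stain <- stain | cs$solid > 0L
    }
    # wall gaps: erase arc patches at random centerline positions
    rate <- spec$defect_rates$wall_gap_per_100um
    if (rate > 0 && nrow(truth$edges)) {
      erasers <- list()
      for (i in seq_len(nrow(truth$edges))) {
        p1 <- truth$nodes[truth$edges$from[i], ]
        p2 <- truth$nodes[truth$edges$to[i], ]
        len <- sqrt(sum((p2 - p1)^2))
        ng <- rpois(1, len * rate / 100)
        for (s in seq_len(ng)) {
          a <- runif(1)
          ax <- p1 + a * (p2 - p1)
          pd <- unit(rnorm(3))
          seg_d <- unit(p2 - p1)
          pd <- unit(pd - sum(pd * seg_d) * seg_d)
          r <- diam[i] / 2
          ctr <- ax + pd * r
          er <- 0.6 * r + 1
          erasers[[length(erasers) + 1L]] <-
            c(ctr, ctr, er, er, 1, 0, 0, 1)
        }
      }
      if (length(erasers)) {
        em <- do.call(rbind, erasers)
        ev <- cpp_rasterize_tubes(em, d[1], d[2], d[3],
                                  spacing[1], spacing[2], spacing[3])
        stain[ev$solid > 0L] <- FALSE
      }
    }
    dim(stain) <- d
    stain_rgb <- c(120, 70, 20)
    bg_rgb <- c(235, 230, 225)
    slices <- vector("list", d[1])
    for (k in seq_len(d[1])) {
      m <- stain[k, , ]
      img <- array(0, dim = c(d[2], d[3], 3))
      for (ch in 1:3) {
        base <- ifelse(m, stain_rgb[ch], bg_rgb[ch])
        img[, , ch] <- pmin(255, pmax(0, round(base + rnorm(length(base), 0, 4))))
      }
      slices[[k]] <- array(as.integer(img), dim = dim(img))
    }
    section_stack(slices, xy_spacing, z_spacing,
                  names = sprintf("phantom_%03d", seq_len(d[1])))
  })
}

#' Compare a reconstructed model against phantom ground truth
#'
#' Matches mesh components to truth networks by majority vote of each
#' component's vertices over their nearest centerline edge, and scores
#' the shape-diameter classification: a vertex is called capillary when
#' its SDF is below `sdf_center`, sinus otherwise, and is correct when
#' the call matches the class of its nearest truth edge. Vertices whose
#' nearest edge is a flat sinus (minor-axis diameter below `sdf_high`)
#' are exempt from the headline accuracy — the shape diameter genuinely
#' reads the thin dimension there — but a raw accuracy over all vertices
#' is reported alongside.
#'
#' @param truth a [phantom_truth][generate_network].
#' @param mesh the final [surface_mesh] with attribute `sdf_um`.
#' @param set optional precomputed [connected_components()].
#' @param sdf_center,sdf_high class boundary and sinus threshold in um.
#' @param max_sample cap on evaluated vertices (evenly subsampled).
#' @return an object of class `recovery_report`: `n_true_networks`,
#'   `n_found_networks`, `vertex_class_accuracy` (flat-sinus exempted),
#'   `vertex_class_accuracy_raw`, `component_diameter_errors` (um),
#'   `topology_match`.
#' @export
evaluate_recovery <- function(truth, mesh, set = NULL, sdf_center = 16.5,
                              sdf_high = 30, max_sample = 20000L) {
  n_true <- n_true_networks(truth)
  if (n_vertices(mesh) == 0 || n_faces(mesh) == 0) {
    return(structure(list(
      n_true_networks = n_true, n_found_networks = 0L,
      vertex_class_accuracy = 0, vertex_class_accuracy_raw = 0,
      component_diameter_errors = numeric(0), topology_match = FALSE),
      class = "recovery_report"))
  }
  if (is.null(set)) set <- connected_components(mesh, metrics = FALSE)
  nv <- n_vertices(mesh)
  idx <- unique(round(seq(1, nv, length.out = min(max_sample, nv))))
  pts <- mesh$vertices[idx, , drop = FALSE]
  segs <- truth_segments(truth)
  near <- cpp_nearest_segment(pts, segs[, 1:6, drop = FALSE])
  ecomp <- edge_graph_components(truth)
  truth_comp <- ecomp[near$index]
  truth_class <- truth$edges$class[near$index]
  minor_diam <- truth$edges$diameter_um[near$index] /
    truth$edges$flatness[near$index]
  # component matching by majority vote
  mesh_comp <- set$component_id[idx]
  match_map <- vapply(seq_len(set$n_components), function(ci) {
    tc <- truth_comp[mesh_comp == ci]
    if (!length(tc)) return(NA_integer_)
    as.integer(names(sort(table(tc), decreasing = TRUE))[1])
  }, integer(1))
  n_found <- set$n_components
  topology_match <- n_found == n_true && !anyNA(match_map) &&
    length(unique(match_map)) == n_true
  sdf <- mesh$attrs$sdf_um[idx]
  valid <- !is.na(sdf)
  pred_sinus <- sdf >= sdf_center
  true_sinus <- truth_class == "sinus"
  correct <- pred_sinus == true_sinus
  exempt <- true_sinus & minor_diam < sdf_high
  acc_raw <- if (any(valid)) mean(correct[valid]) else 0
  denom <- valid & !exempt
  acc <- if (any(denom)) mean(correct[denom]) else acc_raw
  diam_err <- vapply(seq_len(set$n_components), function(ci) {
    sel <- mesh_comp == ci & valid
    if (!any(sel) || is.na(match_map[ci])) return(NA_real_)
    truth_d <- truth$edges$diameter_um[ecomp == match_map[ci]]
    median(sdf[sel]) - mean(truth_d)
  }, numeric(1))
  structure(list(
    n_true_networks = n_true, n_found_networks = n_found,
    vertex_class_accuracy = acc, vertex_class_accuracy_raw = acc_raw,
    component_diameter_errors = diam_err, topology_match = topology_match),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> networks %d/%d, class accuracy %.3f (raw %.3f), topology %s\n",
    x$n_found_networks, x$n_true_networks, x$vertex_class_accuracy,
    x$vertex_class_accuracy_raw, x$topology_match))
  invisible(x)
}

#' Export / import a phantom truth graph as JSON
#'
#' @param truth a [phantom_truth][generate_network].
#' @param path JSON file.
#' @return `write_truth`: invisibly `path`; `read_truth`: the truth
#'   object (without the generating spec).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    domain_size = truth$domain_size,
    nodes = as.data.frame(truth$nodes),
    edges = truth$edges,
    cells = truth$cells,
    wall_thickness = truth$spec$wall_thickness),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    nodes = as.matrix(as.data.frame(j$nodes)),
    edges = as.data.frame(j$edges),
    cells = as.data.frame(j$cells),
    domain_size = as.numeric(j$domain_size),
    spec = list(wall_thickness = j$wall_thickness)),
    class = "phantom_truth")
}
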