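#' Nearest-surface distance from one mesh to another
#'
#' For every vertex of `source`, the exact distance to the nearest point
#' on the `target` surface (point-to-triangle, grid accelerated) — the
#' limit of casting rays in all directions and keeping the shortest. The
#' measure is unidirectional: structures present only in `source` show up
#' as large distances, so QC computes it in both directions by swapping
#' the arguments.
#'
#' @param source a [surface_mesh] whose vertices are measured.
#' @param target a nonempty [surface_mesh] measured against.
#' @param direction label stored in the result (`"forward"`/`"backward"`).
#' @return an object of class `distance_map`: list with `distance_um`
#'   (per source vertex), `direction`, and `summary` (max, mean, p95).
#' @export
surface_distance <- function(source, target, direction = "forward") {
  if (n_faces(target) == 0)
    stop("distance undefined: target mesh is empty")
  d <- cpp_closest_dist(source$vertices, target$vertices, target$faces)
  structure(list(
    distance_um = d,
    direction = direction,
    summary = list(max = max(d), mean = mean(d),
                   p95 = as.numeric(quantile(d, 0.95)))),
    class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %s: max %.2f um, mean %.2f um, p95 %.2f um\n",
              x$direction, x$summary$max, x$summary$mean, x$summary$p95))
  invisible(x)
}

#' Symmetric Hausdorff distance between two meshes
#'
#' Maximum of the two directed vertex-to-surface maxima.
#'
#' @param a,b nonempty [surface_mesh] objects.
#' @return distance in um.
#' @export
hausdorff_distance <- function(a, b) {
  max(surface_distance(a, b)$summary$max, surface_distance(b, a)$summary$max)
}

#' Color vertices by surface distance
#'
#' Blue at identity (0 um) ramping linearly to pure red at `saturation`
#' um or more — the coloring of the mesh-comparison QC figures.
#'
#' @param map a [surface_distance()] result or numeric distances in um.
#' @param saturation distance mapped to pure red (default 10 um).
#' @return `n x 3` integer RGB matrix.
#' @export
colorize_distance <- function(map, saturation = 10) {
  d <- if (inherits(map, "distance_map")) map$distance_um else map
  t <- pmin(d / saturation, 1)
  cbind(as.integer(floor(255 * t + 0.5)), 0L,
        as.integer(floor(255 * (1 - t) + 0.5)))
}

#' Restore structures lost during mesh processing
#'
#' Connected components of the `reference` mesh (the healed isosurface)
#' whose minimum vertex distance to the `processed` mesh exceeds
#' `threshold` were lost in processing; they are appended to the
#' processed mesh (flagged with vertex attribute `repaired`). After
#' repair, every reference component lies within `threshold` of the
#' output, so larger parts of microvessels are no longer missing.
#'
#' @param reference the healed reconstruction [surface_mesh].
#' @param processed the post-pipeline [surface_mesh].
#' @param threshold distance in um above which a component counts as
#'   missing (default 10).
#' @param distances optional precomputed per-vertex distances of
#'   `reference` to `processed` (e.g. from [surface_distance()]), to
#'   avoid recomputation.
#' @return the repaired [surface_mesh]; attribute `"repair_report"` lists
#'   the number of components re-added.
#' @export
repair_missing <- function(reference, processed, threshold = 10,
                           distances = NULL) {
  set <- connected_components(reference, metrics = FALSE)
  if (set$n_components == 0) return(processed)
  add <- logical(set$n_components)
  if (n_faces(processed) == 0) {
    add[] <- TRUE
  } else {
    d <- if (!is.null(distances)) {
      if (inherits(distances, "distance_map")) distances$distance_um
      else distances
    } else {
      cpp_closest_dist(reference$vertices, processed$vertices,
                       processed$faces)
    }
    for (ci in seq_len(set$n_components))
      add[ci] <- min(d[set$component_id == ci]) > threshold
  }
  if (!any(add)) {
    attr(processed, "repair_report") <- list(n_added = 0L)
    return(processed)
  }
  lost <- subset_mesh(reference, set$component_id %in% which(add))
  nv_old <- n_vertices(processed)
  verts <- rbind(processed$vertices, lost$vertices)
  faces <- rbind(processed$faces, lost$faces + nv_old)
  pad <- function(a, fill) c(a, rep(fill, n_vertices(lost)))
  attrs <- lapply(processed$attrs, pad, fill = NA)
  attrs$repaired <- c(rep(FALSE, nv_old), rep(TRUE, n_vertices(lost)))
  colors <- if (!is.null(processed$colors))
    rbind(processed$colors, matrix(255L, n_vertices(lost), 3)) else NULL
  out <- surface_mesh(verts, faces, attrs = attrs, colors = colors)
  attr(out, "repair_report") <- list(n_added = sum(add))
  out
}

#' Overlay the model cross-section on a section scan
#'
#' Intersects the mesh with the plane of the given section (optionally
#' tilted about the image x-axis, which lends a 3D impression when
#' stepping through the series) and draws the intersection contour in red
#' over the scan — the manual-QC check that modeled microvessels are
#' congruent with the stained vessels.
#'
#' @param mesh a [surface_mesh] in the stack's world coordinates.
#' @param stack the [section_stack].
#' @param slice_index 1-based section index.
#' @param view_tilt tilt angle in degrees (default 0: the section plane).
#' @param color RGB of the contour (default red).
#' @return RGB integer array `(height, width, 3)`.
#' @export
overlay_mesh_on_slice <- function(mesh, stack, slice_index, view_tilt = 0,
                                  color = c(255, 0, 0)) {
  if (slice_index < 1 || slice_index > length(stack$slices))
    stop("input error: slice_index out of range")
  img <- stack$slices[[slice_index]]
  if (n_faces(mesh) == 0) return(img)
  ny <- dim(img)[1]; nx <- dim(img)[2]
  z0 <- (slice_index - 1) * stack$z_spacing
  s <- tan(view_tilt * pi / 180)
  yc <- (ny - 1) / 2 * stack$xy_spacing
  # signed plane function: f(v) = z - (z0 + s * (y - yc))
  fv <- mesh$vertices[, 3] - (z0 + s * (mesh$vertices[, 2] - yc))
  segs <- list()
  f <- mesh$faces
  side <- fv > 0
  n_above <- side[f[, 1]] + side[f[, 2]] + side[f[, 3]]
  crossing <- which(n_above >= 1L & n_above <= 2L)
  for (fi in crossing) {
    vid <- f[fi, ]
    pts <- matrix(0, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- vid[e[1]]; b <- vid[e[2]]
      if ((fv[a] > 0) != (fv[b] > 0)) {
        t <- fv[a] / (fv[a] - fv[b])
        p <- mesh$vertices[a, 1:2] + t * (mesh$vertices[b, 1:2] -
                                            mesh$vertices[a, 1:2])
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) == 2) segs[[length(segs) + 1L]] <- pts
  }
  if (!length(segs)) return(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  for (sg in segs) {
    len <- sqrt(sum((sg[2, ] - sg[1, ])^2))
    nstep <- max(2L, ceiling(len / (stack$xy_spacing / 2)))
    tt <- seq(0, 1, length.out = nstep)
    px <- round((sg[1, 1] + tt * (sg[2, 1] - sg[1, 1])) / stack$xy_spacing) + 1
    py <- round((sg[1, 2] + tt * (sg[2, 2] - sg[1, 2])) / stack$xy_spacing) + 1
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
    idx <- cbind(py[ok], px[ok])
    r[idx] <- color[1]; g[idx] <- color[2]; b[idx] <- color[3]
  }
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

#' Census of candidate blind vessel ends
#'
#' Blind ends — vessel termini inside the model not explained by the
#' block boundary — are either reconstruction artefacts (registration,
#' filtering, mesh processing, collapsed capillaries) or, rarely, real.
#' This reviewing aid lists geometric terminal caps: directional extreme
#' points of each component whose surrounding surface slab is laterally
#' compact (a tube cap rather than a tube side), excluding caps at the
#' block's cut faces.
#'
#' @param mesh a [surface_mesh].
#' @param set optional precomputed [connected_components()].
#' @param bbox 2 x 3 block bounds in um (`min`/`max` rows).
#' @param bbox_tol distance to a bbox face counting as "cut" (um).
#' @param cap_extent_max maximal lateral extent of a terminal cap (um).
#' @return data.frame with one row per candidate blind end: component id,
#'   position, and cap extent.
#' @export
blind_end_census <- function(mesh, set = NULL, bbox, bbox_tol = 1.5,
                             cap_extent_max = 30) {
  if (n_vertices(mesh) == 0)
    return(data.frame(component = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), cap_extent_um = numeric(0)))
  if (is.null(set)) set <- connected_components(mesh)
  dirs <- fibonacci_directions(162L)
  rows <- list()
  for (ci in seq_len(set$n_components)) {
    vi <- which(set$component_id == ci)
    if (length(vi) > 20000L)  # keep the projection matrix small
      vi <- vi[unique(round(seq(1, length(vi), length.out = 20000L)))]
    pts <- mesh$vertices[vi, , drop = FALSE]
    proj <- pts %*% t(dirs)
    cand <- list()
    for (dc in seq_len(nrow(dirs))) {
      ahead <- proj[, dc]
      ei <- which.max(ahead)
      p <- pts[ei, ]
      # frontal slab behind the extreme point, measured laterally
      # (perpendicular to the probe direction): a tube cap stays compact,
      # a tube side or a convex crest spreads out
      slab <- which(ahead >= ahead[ei] - 10)
      lat <- pts[slab, , drop = FALSE] -
        outer(ahead[slab], dirs[dc, ])
      extent <- largest_diameter(lat)
      near_box <- any(abs(p - bbox[1, ]) <= bbox_tol |
                        abs(p - bbox[2, ]) <= bbox_tol)
      if (!near_box && extent <= cap_extent_max)
        cand[[length(cand) + 1L]] <- c(p, extent)
    }
    if (length(cand)) {
      m <- do.call(rbind, cand)
      # merge cap candidates of the same terminal
      kept <- rep(TRUE, nrow(m))
      if (nrow(m) > 1) for (i in 2:nrow(m)) {
        dd <- sqrt(rowSums((m[seq_len(i - 1), 1:3, drop = FALSE] -
                              matrix(m[i, 1:3], i - 1, 3, byrow = TRUE))^2))
        if (any(dd[kept[seq_len(i - 1)]] < 0.75 * cap_extent_max))
          kept[i] <- FALSE
      }
      m <- m[kept, , drop = FALSE]
      for (i in seq_len(nrow(m)))
        rows[[length(rows) + 1L]] <- data.frame(
          component = ci, x = m[i, 1], y = m[i, 2], z = m[i, 3],
          cap_extent_um = m[i, 4])
    }
  }
  if (!length(rows))
    return(data.frame(component = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), cap_extent_um = numeric(0)))
  do.call(rbind, rows)
}
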