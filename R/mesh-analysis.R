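#' Connected components of a mesh
#'
#' Components are equivalence classes of vertices under shared-triangle
#' adjacency ("the connectivity test basically detects connected
#' triangles"). Per component the vertex and triangle counts, surface
#' area, axis-aligned bounds and largest diameter (maximum pairwise
#' vertex distance) are tabulated.
#'
#' @param mesh a [surface_mesh].
#' @param metrics compute the per-component metric table (default TRUE);
#'   `FALSE` returns only the labeling, which is much cheaper on large
#'   meshes.
#' @return an object of class `component_set`: list with `component_id`
#'   (per vertex), `n_components`, and `table` (one row per component:
#'   `id`, `n_vertices`, `n_faces`, `area_um2`, `largest_diameter_um`,
#'   and bounds columns; empty when `metrics = FALSE`).
#' @export
connected_components <- function(mesh, metrics = TRUE) {
  nv <- n_vertices(mesh)
  if (nv == 0)
    return(structure(list(component_id = integer(0), n_components = 0L,
                          table = data.frame()), class = "component_set"))
  comp <- face_components(mesh$faces, nv)$vertex_comp
  # vertices not on any face become singleton components (kept distinct)
  ids <- sort(unique(comp))
  comp <- match(comp, ids)
  if (!metrics)
    return(structure(list(component_id = comp, n_components = length(ids),
                          table = data.frame()), class = "component_set"))
  fcomp <- if (nrow(mesh$faces)) comp[mesh$faces[, 1]] else integer(0)
  tab <- do.call(rbind, lapply(seq_along(ids), function(ci) {
    vi <- which(comp == ci)
    pts <- mesh$vertices[vi, , drop = FALSE]
    fi <- which(fcomp == ci)
    data.frame(
      id = ci,
      n_vertices = length(vi),
      n_faces = length(fi),
      area_um2 = mesh_area(mesh, fi),
      largest_diameter_um = largest_diameter(pts),
      xmin = min(pts[, 1]), xmax = max(pts[, 1]),
      ymin = min(pts[, 2]), ymax = max(pts[, 2]),
      zmin = min(pts[, 3]), zmax = max(pts[, 3]))
  }))
  structure(list(component_id = comp, n_components = length(ids), table = tab),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components\n", x$n_components))
  if (x$n_components > 0) print(utils::head(x$table, 10))
  invisible(x)
}

#' Largest diameter of a point set (maximum pairwise distance)
#'
#' Exact O(n^2) maximum for up to `exact_max` points. Larger sets are
#' reduced to their extreme vertices along 2562 well-spread directions
#' (these are convex-hull vertices, and the hull attains the diameter),
#' then the exact pairwise maximum is taken over that candidate set.
#'
#' @param pts numeric `n x 3` matrix of positions in um.
#' @param exact_max size limit for the exact path (default 20000).
#' @return diameter in um (0 for fewer than 2 points).
#' @export
largest_diameter <- function(pts, exact_max = 20000L) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  n <- nrow(pts)
  if (n < 2L) return(0)
  if (n <= exact_max) return(cpp_max_pairwise_dist(pts))
  dirs <- fibonacci_directions(2562L)
  cand <- unique(cpp_extreme_points(pts, dirs))
  cpp_max_pairwise_dist(pts[cand, , drop = FALSE])
}

fibonacci_directions <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Remove small non-connected components
#'
#' Drops every component whose largest diameter is below `min_diam` (the
#' production cutoff is 5% of the model space diagonal, 70 um for a
#' 980 x 980 x 140 um block). A removal report (component count, removed
#' area, and fraction of total surface) is attached as attribute
#' `"removal_report"` so the removed share can be checked against the
#' expectation that it stays a minor part of the model surface.
#'
#' @param mesh a [surface_mesh].
#' @param set optional precomputed [connected_components()] result.
#' @param min_diam diameter cutoff in um (default 70); 0 is the identity.
#' @return filtered [surface_mesh] with attribute `removal_report`.
#' @export
filter_components <- function(mesh, set = NULL, min_diam = 70) {
  if (is.null(set)) set <- connected_components(mesh)
  if (set$n_components == 0) return(mesh)
  drop_ids <- set$table$id[set$table$largest_diameter_um < min_diam]
  total_area <- sum(set$table$area_um2)
  removed_area <- sum(set$table$area_um2[set$table$id %in% drop_ids])
  out <- subset_mesh(mesh, !(set$component_id %in% drop_ids))
  attr(out, "removal_report") <- list(
    n_removed = length(drop_ids),
    removed_area_um2 = removed_area,
    removed_fraction = if (total_area > 0) removed_area / total_area else 0)
  out
}

# keep vertices where keep_vertex is TRUE, with all incident faces intact
subset_mesh <- function(mesh, keep_vertex) {
  idx <- which(keep_vertex)
  remap <- integer(n_vertices(mesh))
  remap[idx] <- seq_along(idx)
  fkeep <- rowSums(matrix(keep_vertex[mesh$faces], ncol = 3)) == 3L
  f <- mesh$faces[fkeep, , drop = FALSE]
  f[] <- remap[f]
  attrs <- lapply(mesh$attrs, function(a) a[idx])
  colors <- if (!is.null(mesh$colors)) mesh$colors[idx, , drop = FALSE]
  surface_mesh(mesh$vertices[idx, , drop = FALSE], f, attrs = attrs,
               colors = colors)
}

#' Component-size cutoff as a fraction of the model space diagonal
#'
#' `fraction * sqrt(x^2 + y^2 + z^2)`, rounded to the nearest um. For a
#' 980 x 980 x 140 um model, 5% gives 70 um and 0.5% gives 7 um.
#'
#' @param vol_extent numeric `(x, y, z)` model extents in um, all > 0.
#' @param fraction fraction of the diagonal, in (0, 1).
#' @return threshold in um.
#' @export
diagonal_fraction_threshold <- function(vol_extent, fraction) {
  if (length(vol_extent) != 3L || any(vol_extent <= 0))
    stop("vol_extent must be 3 positive lengths")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  round(fraction * sqrt(sum(as.numeric(vol_extent)^2)))
}

#' Per-vertex volumetric obscurance
#'
#' How visible a vertex is from the outside: the fraction of sphere-
#' sampled rays (deterministic low-discrepancy directions) that escape to
#' the bounds without hitting the mesh. 0 means fully enclosed (e.g. the
#' inner shell of a hollow vessel wall), about 0.5 an exposed point on a
#' locally flat surface, 1 fully exposed.
#'
#' @param mesh a [surface_mesh].
#' @param n_samples rays per vertex (default 48).
#' @return the mesh with numeric vertex attribute `obscurance`.
#' @export
volumetric_obscurance <- function(mesh, n_samples = 48L) {
  if (n_vertices(mesh) == 0) return(mesh)
  mesh$attrs$obscurance <- cpp_obscurance(mesh$vertices, mesh$faces,
                                          as.integer(n_samples))
  mesh
}

#' Delete interior (invisible) vertices
#'
#' Removes vertices with obscurance below `threshold` together with their
#' incident faces — the residual inner wall contours inside solidified
#' vessels. The threshold is chosen to never delete true outer-surface
#' points: if cut-surface flags are present, deleting any flagged vertex
#' is a validation failure.
#'
#' @param mesh a [surface_mesh] with attribute `obscurance` (computed on
#'   demand otherwise).
#' @param threshold obscurance cutoff (default 0.05); 0 is the identity.
#' @param n_samples passed to [volumetric_obscurance()] if needed.
#' @return filtered [surface_mesh].
#' @export
remove_interior <- function(mesh, threshold = 0.05, n_samples = 48L) {
  if (n_vertices(mesh) == 0 || threshold <= 0) return(mesh)
  if (is.null(mesh$attrs$obscurance))
    mesh <- volumetric_obscurance(mesh, n_samples)
  del <- mesh$attrs$obscurance < threshold
  if (!is.null(mesh$attrs$cut_surface) && any(del & mesh$attrs$cut_surface))
    stop("validation failure: interior removal would delete cut-surface vertices")
  subset_mesh(mesh, !del)
}

#' Shape diameter function (local vessel caliber)
#'
#' From each vertex, rays are cast into the mesh interior within a cone
#' around the inward normal; where a ray meets the surface it stops. The
#' recorded value is the shortest ray ("shortest" variant, the default)
#' or a robust variant (median of rays within one standard deviation).
#' With a solid vessel representation this reads the local diameter in
#' um. Note the caveat inherent to the method: broad flat sinuses read
#' their thin dimension when sampled from the broad side.
#'
#' @param mesh a [surface_mesh] (solid, outward-oriented).
#' @param cone_half_angle cone half-angle around the inward normal in
#'   degrees (default 15; narrow, so the shortest ray tracks the true
#'   diameter on tubes and spheres).
#' @param n_rays rays per vertex (default 30).
#' @param method `"shortest"` or `"robust"`.
#' @return the mesh with numeric vertex attributes `sdf_um` (NA where no
#'   ray hit: open meshes) and logical `sdf_valid`.
#' @export
shape_diameter <- function(mesh, cone_half_angle = 15, n_rays = 30L,
                           method = c("shortest", "robust")) {
  method <- match.arg(method)
  if (n_vertices(mesh) == 0) return(mesh)
  normals <- cpp_vertex_normals(mesh$vertices, mesh$faces)
  sdf <- cpp_sdf(mesh$vertices, mesh$faces, normals, cone_half_angle,
                 as.integer(n_rays), method == "robust")
  mesh$attrs$sdf_um <- sdf
  mesh$attrs$sdf_valid <- !is.na(sdf)
  mesh
}

#' Color vertices by shape diameter
#'
#' Pure red below `low` um, pure green above `high` um, and a two-ramp
#' gradient between: red to the 50/50 red-green blend on `[low, center]`,
#' then on to green on `[center, high]`. The defaults (12, 30, centred at
#' 16.5) highlight capillaries in red and sinuses in green.
#'
#' @param mesh a [surface_mesh] with attribute `sdf_um`, or a numeric
#'   vector of SDF values.
#' @param low,high,center gradient breakpoints in um.
#' @param cut_color RGB used for flagged cut-surface vertices (light
#'   grey).
#' @return the mesh with `colors` set (or an `n x 3` RGB matrix when a
#'   numeric vector was given).
#' @export
colorize_sdf <- function(mesh, low = 12, high = 30, center = 16.5,
                         cut_color = c(200, 200, 200)) {
  stopifnot(low < center, center < high)
  field <- if (inherits(mesh, "surface_mesh")) mesh$attrs$sdf_um else mesh
  if (is.null(field)) stop("no sdf_um attribute; run shape_diameter() first")
  n <- length(field)
  rgb <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    s <- field[i]
    col <- if (is.na(s)) c(80, 80, 80)
    else if (s < low) c(255, 0, 0)
    else if (s > high) c(0, 255, 0)
    else if (s <= center) {
      t <- (s - low) / (center - low)
      c(255 - 127.5 * t, 127.5 * t, 0)
    } else {
      t <- (s - center) / (high - center)
      c(127.5 * (1 - t), 127.5 + 127.5 * t, 0)
    }
    rgb[i, ] <- as.integer(floor(col + 0.5))
  }
  if (!inherits(mesh, "surface_mesh")) return(rgb)
  if (!is.null(mesh$attrs$cut_surface))
    rgb[mesh$attrs$cut_surface, ] <- rep(as.integer(cut_color),
                                         each = sum(mesh$attrs$cut_surface))
  mesh$colors <- rgb
  mesh
}

#' Classify and color mesh components by network connectivity
#'
#' Components smaller than `small_min` um in largest diameter are
#' discarded; components sized between `small_min` and `small_max` um are
#' "small structures" (red; mostly fused single cells, elongated along
#' z). The remaining networks are ranked by total surface area: the
#' largest is light blue, ranks 2..`n_large` dark blue (for specimens
#' with several similar large networks), the rest green. Cut-surface
#' flagged vertices are colored light blue by convention of the
#' connectivity models.
#'
#' @param mesh a [surface_mesh].
#' @param set optional precomputed [connected_components()].
#' @param small_min,small_max small-structure band in um (default 7-28).
#' @param n_large how many top-ranked networks count as "large"
#'   (default 1; must be >= 1).
#' @return a [surface_mesh] with colors and vertex attribute
#'   `connectivity_class` (integer: 1 largest network / dark blue ranks,
#'   2 other networks, 3 small structure), plus attribute
#'   `"class_table"` mapping component id to class and rank.
#' @export
classify_connectivity <- function(mesh, set = NULL, small_min = 7,
                                  small_max = 28, n_large = 1L) {
  if (n_large < 1L) stop("config error: n_large must be >= 1")
  if (n_vertices(mesh) == 0) return(mesh)
  if (is.null(set)) set <- connected_components(mesh)
  tab <- set$table
  keep_ids <- tab$id[tab$largest_diameter_um >= small_min]
  keep_v <- set$component_id %in% keep_ids
  mesh2 <- subset_mesh(mesh, keep_v)
  # relabel the surviving components instead of recomputing them
  tab2 <- tab[tab$id %in% keep_ids, , drop = FALSE]
  tab2$id <- match(tab2$id, keep_ids)
  set2 <- structure(list(
    component_id = match(set$component_id[keep_v], keep_ids),
    n_components = length(keep_ids), table = tab2),
    class = "component_set")
  small <- tab2$largest_diameter_um <= small_max
  nets <- tab2[!small, , drop = FALSE]
  rank <- integer(nrow(tab2))
  if (nrow(nets)) {
    ord <- nets$id[order(nets$area_um2, decreasing = TRUE)]
    rank[match(ord, tab2$id)] <- seq_along(ord)
  }
  light_blue <- c(110L, 190L, 255L)
  dark_blue <- c(0L, 0L, 139L)
  green <- c(0L, 200L, 0L)
  red <- c(255L, 0L, 0L)
  comp_color <- matrix(0L, nrow(tab2), 3)
  comp_class <- integer(nrow(tab2))
  for (i in seq_len(nrow(tab2))) {
    if (small[i]) { comp_color[i, ] <- red; comp_class[i] <- 3L }
    else if (rank[i] >= 1L && rank[i] <= n_large) {
      comp_color[i, ] <- if (rank[i] == 1L) light_blue else dark_blue
      comp_class[i] <- 1L
    } else { comp_color[i, ] <- green; comp_class[i] <- 2L }
  }
  cid <- set2$component_id
  mesh2$colors <- comp_color[cid, , drop = FALSE]
  mesh2$attrs$connectivity_class <- comp_class[cid]
  mesh2$attrs$component_id <- cid
  if (!is.null(mesh2$attrs$cut_surface)) {
    cs <- mesh2$attrs$cut_surface
    mesh2$colors[cs, ] <- rep(light_blue, each = sum(cs))
  }
  attr(mesh2, "class_table") <- data.frame(
    id = tab2$id, diameter_um = tab2$largest_diameter_um,
    area_um2 = tab2$area_um2, class = comp_class, rank = rank)
  mesh2
}

#' Export a component report as JSON
#'
#' @param set a [connected_components()] result or a classified mesh with
#'   a `class_table` attribute.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_component_report <- function(set, path) {
  tab <- if (inherits(set, "component_set")) set$table
         else attr(set, "class_table")
  jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
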