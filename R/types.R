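#' Ordered stack of registered serial-section images
#'
#' A `section_stack` holds the registered RGB scans of consecutive serial
#' sections together with their spatial metadata: in-plane pixel spacing
#' (typically 0.28 um/px for a 20x slide scan) and section thickness
#' (typically 7 um). All slices must share one width and height.
#'
#' @param slices list of RGB images, each an integer array
#'   `(height, width, 3)` with values in 0..255.
#' @param xy_spacing in-plane spacing in micrometres per pixel (> 0).
#' @param z_spacing section thickness in micrometres (> 0).
#' @param names optional per-slice identifiers.
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(slices, xy_spacing, z_spacing, names = NULL) {
  if (!is.list(slices) || length(slices) < 1L)
    stop("input error: need at least one slice")
  dims <- vapply(slices, function(s) dim(s)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension error: slices differ in size")
  if (!is.numeric(xy_spacing) || xy_spacing <= 0)
    stop("xy_spacing must be > 0")
  if (!is.numeric(z_spacing) || z_spacing <= 0)
    stop("z_spacing must be > 0")
  slices <- lapply(slices, function(s) {
    if (length(dim(s)) == 2L) s <- array(rep(s, 3L), dim = c(dim(s), 3L))
    storage.mode(s) <- "integer"
    s
  })
  if (is.null(names)) names <- sprintf("slice_%03d", seq_along(slices))
  structure(
    list(slices = slices, xy_spacing = xy_spacing, z_spacing = z_spacing,
         names = names),
    class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf(
    "<section_stack> %d slices of %d x %d px, %.3g um/px, %.3g um/section\n",
    length(x$slices), d[2], d[1], x$xy_spacing, x$z_spacing))
  invisible(x)
}

#' Scalar image volume with anisotropic voxel spacing
#'
#' A `scalar_volume` is a 3D 8-bit intensity field stored as an integer
#' array in `(z, y, x)` index order, with per-axis voxel spacing in
#' micrometres. World coordinates place voxel `(k, j, i)` (1-based) at
#' `((i-1)*sx, (j-1)*sy, (k-1)*sz)` um.
#'
#' @param data integer array with dim `(nz, ny, nx)`, values in 0..255.
#' @param spacing numeric length-3 `(z, y, x)` spacing in um, all > 0.
#' @param provenance label of the pipeline stage that produced the volume.
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing, provenance = "raw") {
  if (length(dim(data)) != 3L) stop("data must be a 3D array (z, y, x)")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (z, y, x)")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must lie in [0, 255]")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing),
                 provenance = provenance),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<scalar_volume> %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g um [%s]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$provenance))
  invisible(x)
}

#' Triangle surface mesh in micrometre coordinates
#'
#' Vertices are `N x 3` world positions `(x, y, z)` in um; faces are
#' `M x 3` 1-based vertex indices. Optional named per-vertex scalar
#' attributes (e.g. `sdf_um`, `obscurance`, `distance_um`, `component_id`)
#' and an `N x 3` RGB color matrix (0..255) travel with the mesh.
#'
#' @param vertices numeric `N x 3` matrix, no NA/NaN.
#' @param faces integer `M x 3` matrix of 1-based indices into `vertices`.
#' @param attrs named list of length-N vectors.
#' @param colors optional `N x 3` integer RGB matrix (0..255).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices = matrix(numeric(0), 0, 3),
                         faces = matrix(integer(0), 0, 3),
                         attrs = list(), colors = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (anyNA(vertices)) stop("vertex positions contain NA/NaN")
  n <- nrow(vertices)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > n))
    stop("face indices out of range")
  for (a in names(attrs))
    if (length(attrs[[a]]) != n)
      stop(sprintf("attribute '%s' must have one value per vertex", a))
  if (!is.null(colors)) {
    colors <- matrix(as.integer(colors), ncol = 3)
    if (nrow(colors) != n) stop("colors must have one row per vertex")
  }
  structure(list(vertices = vertices, faces = faces, attrs = attrs,
                 colors = colors),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (length(x$attrs)) cat(" | attrs:", paste(names(x$attrs), collapse = ", "))
  if (!is.null(x$colors)) cat(" | colored")
  cat("\n")
  invisible(x)
}

#' Number of mesh vertices / faces
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Total surface area of a mesh in um^2
#' @param mesh a `surface_mesh`.
#' @param faces optional subset of face rows.
#' @return numeric area.
#' @export
mesh_area <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed enclosed volume of a closed mesh in um^3
#'
#' Positive for consistently outward-oriented closed surfaces
#' (divergence-theorem sum of signed tetrahedron volumes).
#' @param mesh a `surface_mesh`.
#' @param faces optional subset of face rows.
#' @return numeric volume.
#' @export
mesh_volume <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Is every mesh edge shared by exactly two faces?
#' @param mesh a `surface_mesh`.
#' @return logical; `TRUE` for watertight (closed) meshes.
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  e <- mesh_edge_table(mesh)
  all(e$count == 2L)
}

# undirected edge table with incidence counts
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  ea <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  tab <- table(key)
  list(key = names(tab), count = as.integer(tab))
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a `surface_mesh`.
#' @return 2 x 3 matrix, rows `min`/`max`, columns x/y/z (um).
#' @export
mesh_bbox <- function(mesh) {
  if (nrow(mesh$vertices) == 0)
    return(matrix(0, 2, 3, dimnames = list(c("min", "max"), c("x", "y", "z"))))
  rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' World-extent of a scalar volume
#' @param vol a `scalar_volume`.
#' @return named numeric `(x, y, z)` extents in um (voxel-center span).
#' @export
volume_extent <- function(vol) {
  d <- dim(vol$data)
  c(x = (d[3] - 1) * vol$spacing[3], y = (d[2] - 1) * vol$spacing[2],
    z = (d[1] - 1) * vol$spacing[1])
}

#' Uncompressed size of an image volume in binary gigabytes
#'
#' Desk arithmetic for planning: `dims` voxels times `channels` times
#' `bytes_per_voxel`, expressed in 2^30-byte gigabytes. A 3500 x 3500 x 140
#' single-channel 8-bit volume is 1.60 GB; the same volume in RGB is
#' 4.79 GB.
#'
#' @param dims integer vector of voxel counts (any length).
#' @param channels number of channels (default 1).
#' @param bytes_per_voxel bytes per voxel and channel (default 1).
#' @return size in GB (2^30 bytes).
#' @export
volume_gigabytes <- function(dims, channels = 1, bytes_per_voxel = 1) {
  prod(as.numeric(dims)) * channels * bytes_per_voxel / 2^30
}
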