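#' Write a surface mesh to PLY, OBJ or STL
#'
#' PLY (binary little-endian) is the canonical attributed format: vertex
#' positions are stored as doubles, per-vertex RGB colors as `uchar
#' red/green/blue`, and every numeric vertex attribute as a double
#' property, so PLY round trips are lossless. OBJ keeps geometry only.
#' STL stores a triangle soup; colors, if present, are dropped with a
#' warning.
#'
#' @param mesh a [surface_mesh].
#' @param path output file.
#' @param format `"ply"`, `"obj"` or `"stl"`; default from the extension.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "obj", "stl"))
  switch(format,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path))
  invisible(path)
}

#' Read a surface mesh from PLY, OBJ or STL
#'
#' Non-manifold connectivity (an edge shared by more than two faces) is
#' reported with a message but does not fail the read.
#'
#' @param path mesh file (`.ply`, `.obj`, `.stl`).
#' @return a [surface_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 ply = read_ply(path),
                 obj = read_obj(path),
                 stl = read_stl(path),
                 stop("I/O error: unsupported mesh format: ", ext))
  if (nrow(mesh$faces) > 0) {
    e <- mesh_edge_table(mesh)
    if (any(e$count > 2L))
      message("read_mesh: non-manifold edges present in ", basename(path))
  }
  mesh
}

ply_type_size <- c(char = 1L, uchar = 1L, uint8 = 1L, int8 = 1L,
                   short = 2L, ushort = 2L, int = 4L, uint = 4L,
                   int32 = 4L, float = 4L, float32 = 4L, double = 8L,
                   float64 = 8L)

write_ply <- function(mesh, path) {
  n <- n_vertices(mesh); m <- n_faces(mesh)
  attrs <- mesh$attrs[vapply(mesh$attrs, is.numeric, TRUE) |
                        vapply(mesh$attrs, is.logical, TRUE)]
  has_col <- !is.null(mesh$colors)
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment vesselrecon attributed mesh",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (has_col)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  for (a in names(attrs)) hdr <- c(hdr, sprintf("property double %s", a))
  hdr <- c(hdr, sprintf("element face %d", m),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (n > 0) {
    rec <- 24L + (if (has_col) 3L else 0L) + 8L * length(attrs)
    raw_m <- matrix(as.raw(0), nrow = rec, ncol = n)
    raw_m[1:24, ] <- writeBin(as.numeric(t(mesh$vertices)), raw(), size = 8,
                              endian = "little")
    off <- 24L
    if (has_col) {
      raw_m[off + (1:3), ] <- as.raw(t(mesh$colors))
      off <- off + 3L
    }
    for (a in names(attrs)) {
      raw_m[off + (1:8), ] <- writeBin(as.numeric(attrs[[a]]), raw(),
                                       size = 8, endian = "little")
      off <- off + 8L
    }
    writeBin(as.vector(raw_m), con)
  }
  if (m > 0) {
    raw_f <- matrix(as.raw(0), nrow = 13L, ncol = m)
    raw_f[1, ] <- as.raw(3L)
    raw_f[2:13, ] <- writeBin(as.integer(t(mesh$faces) - 1L), raw(),
                              size = 4, endian = "little")
    writeBin(as.vector(raw_f), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("I/O error: truncated PLY header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (!any(grepl("^format binary_little_endian", hdr)))
    stop("I/O error: only binary little-endian PLY is supported")
  n <- 0L; m <- 0L; cur <- ""
  vprops <- list()
  for (line in hdr) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") n <- as.integer(tok[3])
      if (cur == "face") m <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex") {
      vprops[[tok[3]]] <- tok[2]
    }
  }
  sizes <- ply_type_size[unlist(vprops)]
  if (anyNA(sizes)) stop("I/O error: unsupported PLY property type")
  rec <- sum(sizes)
  vals <- list()
  if (n > 0) {
    raw_v <- readBin(con, "raw", n = n * rec)
    raw_m <- matrix(raw_v, nrow = rec, ncol = n)
    off <- 0L
    for (p in names(vprops)) {
      sz <- ply_type_size[[vprops[[p]]]]
      chunk <- as.vector(raw_m[off + seq_len(sz), , drop = FALSE])
      vals[[p]] <- switch(vprops[[p]],
        double = , float64 = readBin(chunk, "double", n = n, size = 8,
                                     endian = "little"),
        float = , float32 = readBin(chunk, "double", n = n, size = 4,
                                    endian = "little"),
        uchar = , uint8 = as.integer(chunk),
        int = , int32 = readBin(chunk, "integer", n = n, size = 4,
                                endian = "little"),
        stop("I/O error: unsupported PLY property type: ", vprops[[p]]))
      off <- off + sz
    }
  }
  faces <- matrix(integer(0), 0, 3)
  if (m > 0) {
    raw_f <- readBin(con, "raw", n = m * 13L)
    raw_m <- matrix(raw_f, nrow = 13L, ncol = m)
    if (any(as.integer(raw_m[1, ]) != 3L))
      stop("I/O error: non-triangular PLY faces")
    idx <- readBin(as.vector(raw_m[2:13, ]), "integer", n = 3L * m, size = 4,
                   endian = "little")
    faces <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
  }
  verts <- cbind(vals$x, vals$y, vals$z)
  if (n == 0) verts <- matrix(numeric(0), 0, 3)
  colors <- NULL
  if (all(c("red", "green", "blue") %in% names(vals)))
    colors <- cbind(vals$red, vals$green, vals$blue)
  extra <- setdiff(names(vals), c("x", "y", "z", "red", "green", "blue"))
  surface_mesh(verts, faces, attrs = vals[extra], colors = colors)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vesselrecon mesh", con)
  if (n_vertices(mesh) > 0)
    writeLines(sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (n_faces(mesh) > 0)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- if (length(vl)) {
    do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vl), "\\s+"), function(x)
      as.numeric(x[1:3])))
  } else matrix(numeric(0), 0, 3)
  faces <- if (length(fl)) {
    do.call(rbind, lapply(strsplit(sub("^f\\s+", "", fl), "\\s+"), function(x)
      as.integer(sub("/.*", "", x[1:3]))))
  } else matrix(integer(0), 0, 3)
  surface_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  if (!is.null(mesh$colors))
    warning("STL cannot carry vertex colors; colors dropped")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  m <- n_faces(mesh)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  for (i in seq_len(m)) {
    a <- mesh$vertices[mesh$faces[i, 1], ]
    b <- mesh$vertices[mesh$faces[i, 2], ]
    c_ <- mesh$vertices[mesh$faces[i, 3], ]
    nrm <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
             (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
             (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, a, b, c_)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  m <- readBin(con, "integer", n = 1L, size = 4, endian = "little")
  tri <- matrix(0, m * 3L, 3)
  for (i in seq_len(m)) {
    rec <- readBin(con, "double", n = 12L, size = 4, endian = "little")
    readBin(con, "raw", n = 2L)
    tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  key <- apply(tri, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}
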