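#' Read a registered serial-section stack from image files
#'
#' Reads PNG or TIFF slice images (8-bit RGB or grayscale) in the given
#' order. Row 1 of each image is the top of the slide scan; no flipping is
#' applied on input or output.
#'
#' @param paths character vector of image files, in section order.
#' @param xy_spacing in-plane spacing, um/pixel.
#' @param z_spacing section thickness, um.
#' @return a [section_stack].
#' @export
read_stack <- function(paths, xy_spacing, z_spacing) {
  if (length(paths) < 1L) stop("input error: empty path list")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("I/O error: file not found: ", paste(missing, collapse = ", "))
  slices <- lapply(paths, read_image)
  section_stack(slices, xy_spacing, z_spacing, names = basename(paths))
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("I/O error: unsupported image format: ", path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  arr <- array(as.integer(round(img * 255)), dim = dim(img))
  arr
}

#' Write a section stack as numbered image files
#'
#' @param stack a [section_stack].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, dir, prefix = "section", format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.%s", prefix, seq_along(stack$slices),
                                  if (format == "png") "png" else "tif"))
  for (i in seq_along(stack$slices)) {
    img <- stack$slices[[i]] / 255
    if (format == "png") png::writePNG(img, paths[i])
    else tiff::writeTIFF(img, paths[i], bits.per.sample = 8L)
  }
  invisible(paths)
}

#' Write / read a scalar volume as multi-page TIFF
#'
#' One TIFF page per z-plane. Voxel spacing and provenance are stored in a
#' JSON sidecar file `<path>.json`; the round trip reproduces data and
#' spacing exactly.
#'
#' @param vol a [scalar_volume].
#' @param path output `.tif` file.
#' @return `write_volume`: invisibly, `path`. `read_volume`: the volume.
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(k) {
    matrix(vol$data[k, , ] / 255, nrow = d[2], ncol = d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  jsonlite::write_json(
    list(spacing = vol$spacing, provenance = vol$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])[1:2]
  data <- array(0L, dim = c(length(pages), d2[1], d2[2]))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    data[k, , ] <- as.integer(round(pg * 255))
  }
  side <- paste0(path, ".json")
  spacing <- c(1, 1, 1); prov <- "loaded"
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    spacing <- as.numeric(meta$spacing)
    prov <- meta$provenance %||% "loaded"
  }
  scalar_volume(data, spacing, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
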