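#' The six-stage volume filter chain and its stages
#'
#' Segmentation of the interpolated stain-saturation volume uses six
#' grayscale operations in fixed order: threshold 70, closing (radius 10
#' voxels), hole filling, dilation (radius 3), a second closing (radius
#' 5), and a Gaussian blur (sigma 0.33). Structuring elements are digital
#' spheres in voxel units, so on anisotropic voxels the physical reach is
#' larger along the coarser axis; this is deliberate and documented.
#'
#' @name volume_filters
NULL

#' Threshold a volume: intensities below `t` become black
#'
#' Voxels with intensity strictly below the threshold are set to 0;
#' voxels at or above it are kept unchanged (coarse segmentation).
#'
#' @param vol a [scalar_volume].
#' @param t threshold in 0..255 (default 70).
#' @return filtered [scalar_volume].
#' @export
threshold_volume <- function(vol, t = 70) {
  stopifnot(t >= 0, t <= 255)
  d <- vol$data
  d[d < t] <- 0L
  scalar_volume(d, vol$spacing, "thresholded")
}

#' Grayscale 3D closing with a spherical structuring element
#'
#' Dilation followed by erosion with a digital sphere of radius `r`
#' voxels; bridges gaps in vessel walls up to about `2 r` voxels.
#'
#' @param vol a [scalar_volume].
#' @param r structuring-element radius in voxels (>= 1).
#' @return filtered [scalar_volume].
#' @export
grey_close <- function(vol, r) {
  stopifnot(r >= 1)
  d <- dim(vol$data)
  x <- cpp_grey_dilate(vol$data, d[1], d[2], d[3], as.integer(r))
  x <- cpp_grey_erode(x, d[1], d[2], d[3], as.integer(r))
  dim(x) <- d
  scalar_volume(x, vol$spacing, sprintf("closed_r%d", as.integer(r)))
}

#' Grayscale 3D dilation with a spherical structuring element
#'
#' @inheritParams grey_close
#' @return filtered [scalar_volume].
#' @export
grey_dilate <- function(vol, r = 3) {
  stopifnot(r >= 1)
  d <- dim(vol$data)
  x <- cpp_grey_dilate(vol$data, d[1], d[2], d[3], as.integer(r))
  dim(x) <- d
  scalar_volume(x, vol$spacing, sprintf("dilated_r%d", as.integer(r)))
}

#' Grayscale 3D erosion with a spherical structuring element
#'
#' @inheritParams grey_close
#' @return filtered [scalar_volume].
#' @export
grey_erode <- function(vol, r) {
  stopifnot(r >= 1)
  d <- dim(vol$data)
  x <- cpp_grey_erode(vol$data, d[1], d[2], d[3], as.integer(r))
  dim(x) <- d
  scalar_volume(x, vol$spacing, sprintf("eroded_r%d", as.integer(r)))
}

#' Fill enclosed background cavities (vessel lumina)
#'
#' Background voxels (value 0) that are not 6-connected to the volume
#' border are interior cavities: after wall closing these are the vessel
#' lumina, which must become solid so downstream diameter computation on
#' the mesh sees solid vessels. Each cavity is filled with the minimum
#' positive intensity of its enclosing shell. Open-ended lumina that reach
#' the volume border stay unfilled.
#'
#' @param vol a [scalar_volume] (thresholded: 0 = background).
#' @param per_slice fill per z-plane in 2D instead of in 3D.
#' @return filtered [scalar_volume].
#' @export
fill_holes <- function(vol, per_slice = FALSE) {
  d <- dim(vol$data)
  if (per_slice) {
    x <- vol$data
    for (k in seq_len(d[1]))
      x[k, , ] <- cpp_fill_holes(x[k, , , drop = TRUE], 1L, d[2], d[3])
  } else {
    x <- cpp_fill_holes(vol$data, d[1], d[2], d[3])
  }
  dim(x) <- d
  scalar_volume(x, vol$spacing, "holes_filled")
}

#' 3D Gaussian blur
#'
#' Separable Gaussian convolution (sigma in voxel units, reflect
#' boundary); the final chain stage, smoothing the surface fed to
#' isosurface extraction.
#'
#' @param vol a [scalar_volume].
#' @param sigma standard deviation in voxels (> 0; default 0.33).
#' @return filtered [scalar_volume].
#' @export
gaussian_blur <- function(vol, sigma = 0.33) {
  stopifnot(sigma > 0)
  d <- dim(vol$data)
  x <- cpp_gaussian_blur(vol$data, d[1], d[2], d[3], sigma)
  dim(x) <- d
  scalar_volume(x, vol$spacing, "blurred")
}

#' Apply the full six-filter segmentation chain
#'
#' Runs, in order: threshold, closing (radius `close1_r`), hole fill,
#' dilation, second closing (`close2_r`), Gaussian blur. A per-stage count
#' of nonzero voxels is attached as attribute `"stage_log"`.
#'
#' @param vol a [scalar_volume] (interpolated saturation volume).
#' @param chain named list with `threshold`, `close1_r`, `fill_holes`,
#'   `dilate_r`, `close2_r`, `blur_sigma` (see [pipeline_config()]).
#' @param verbose print per-stage voxel counts.
#' @return filtered [scalar_volume] with attribute `stage_log`.
#' @export
apply_chain <- function(vol, chain = pipeline_config()$filter_chain,
                        verbose = FALSE) {
  stages <- list()
  log_stage <- function(name, v) {
    stages[[name]] <<- sum(v$data > 0L)
    if (verbose)
      message(sprintf("  %-12s %d voxels > 0", name, stages[[name]]))
    v
  }
  v <- log_stage("input", vol)
  v <- log_stage("threshold", threshold_volume(v, chain$threshold))
  v <- log_stage("close1", grey_close(v, chain$close1_r))
  if (isTRUE(chain$fill_holes))
    v <- log_stage("fill_holes",
                   fill_holes(v, per_slice = isTRUE(chain$fill_per_slice)))
  v <- log_stage("dilate", grey_dilate(v, chain$dilate_r))
  v <- log_stage("close2", grey_close(v, chain$close2_r))
  v <- log_stage("blur", gaussian_blur(v, chain$blur_sigma))
  out <- scalar_volume(v$data, vol$spacing, "filtered")
  attr(out, "stage_log") <- unlist(stages)
  out
}

#' Stage-difference QC panels
#'
#' For each selected section gap, builds a six-panel montage mirroring the
#' volume-processing QC figure: the original scan, the saturation planes
#' of sections `i` and `i + 1`, an intermediate interpolated plane, the
#' filtered result, and the interpolated plane with every voxel changed by
#' filtering overlaid in red.
#'
#' @param interp interpolated [scalar_volume].
#' @param filtered filtered [scalar_volume] (same shape).
#' @param stack optional original [section_stack] for the scan panel.
#' @param sat optional saturation [scalar_volume] for the section panels.
#' @param gaps integer vector of section gaps to report (default: first).
#' @param tolerance intensity difference counted as "changed" (default 0,
#'   i.e. any change).
#' @param dir optional output directory; montages are written as PNG.
#' @return invisibly, a list per gap with the six `panels`, the logical
#'   difference `mask`, and the assembled `montage` RGB array.
#' @export
stage_difference_report <- function(interp, filtered, stack = NULL,
                                    sat = NULL, gaps = 1L, tolerance = 0,
                                    dir = NULL) {
  if (!all(dim(interp$data) == dim(filtered$data)))
    stop("shape mismatch between interpolated and filtered volumes")
  nz <- dim(interp$data)[1]
  m <- if (!is.null(sat)) nz %/% max(1L, dim(sat$data)[1] - 1L) else nz
  grey_rgb <- function(img) {
    a <- array(0L, dim = c(dim(img), 3L))
    a[, , 1] <- img; a[, , 2] <- img; a[, , 3] <- img
    a
  }
  out <- list()
  for (g in gaps) {
    mid <- min(nz, (g - 1L) * m + max(1L, m %/% 2L) + 1L)
    ip <- interp$data[mid, , ]
    fp <- filtered$data[mid, , ]
    mask <- abs(fp - ip) > tolerance
    overlay <- grey_rgb(ip)
    r <- overlay[, , 1]; gg <- overlay[, , 2]; b <- overlay[, , 3]
    r[mask] <- 255L; gg[mask] <- 0L; b[mask] <- 0L
    overlay[, , 1] <- r; overlay[, , 2] <- gg; overlay[, , 3] <- b
    panels <- list(
      scan = if (!is.null(stack)) stack$slices[[min(g, length(stack$slices))]]
             else grey_rgb(ip),
      saturation_i = grey_rgb(if (!is.null(sat)) sat$data[g, , ] else ip),
      saturation_i1 = grey_rgb(if (!is.null(sat))
        sat$data[min(g + 1L, dim(sat$data)[1]), , ] else ip),
      interpolated = grey_rgb(ip),
      filtered = grey_rgb(fp),
      difference = overlay)
    nr <- nrow(ip); nc <- ncol(ip)
    montage <- array(0L, dim = c(2L * nr, 3L * nc, 3L))
    for (p in seq_along(panels)) {
      ro <- ((p - 1L) %/% 3L) * nr
      co <- ((p - 1L) %% 3L) * nc
      montage[ro + seq_len(nr), co + seq_len(nc), ] <- panels[[p]]
    }
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      png::writePNG(montage / 255,
                    file.path(dir, sprintf("stage_diff_gap%03d.png", g)))
    }
    out[[as.character(g)]] <- list(panels = panels, mask = mask,
                                   montage = montage)
  }
  invisible(out)
}
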