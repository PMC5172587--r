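#' Pipeline configuration
#'
#' Collects every tunable of the reconstruction pipeline with the
#' production defaults: the six-filter chain (threshold 70, close 10,
#' hole fill, dilate 3, close 5, blur 0.33), interpolation target spacing
#' (1 um), iso-value (127.5), Taubin iterations (10), the shape-diameter
#' color breakpoints (red below 12 um, green above 30 um, gradient
#' centred at 16.5 um), the 70 um component cutoff and the 7-28 um
#' small-structure band of the connectivity models, and the 10 um
#' Hausdorff repair threshold.
#'
#' @param saturation_scale full-scale saturation intensity (0-255).
#' @param interp_target_z interpolated plane spacing, um.
#' @param filter_chain named list: `threshold`, `close1_r`, `fill_holes`,
#'   `fill_per_slice`, `dilate_r`, `close2_r`, `blur_sigma` (radii in
#'   voxels). Hole filling defaults to per-slice 2D: each closed wall
#'   ring fills its lumen in-plane, which stays robust when a vessel's
#'   end cap is lost between sections and a 3D fill would leak out
#'   through the open end.
#' @param iso_value marching iso-value (0-255). Default 35, the midpoint
#'   between background (0) and the smallest intensity the threshold
#'   stage retains (70): hole filling writes the shell *minimum* (>= 70)
#'   into vessel lumina, so any iso-value above the threshold would cut
#'   filled lumina back out and leave vessels hollow.
#' @param taubin_iters Taubin smoothing iterations.
#' @param sdf_low,sdf_high,sdf_center SDF color breakpoints, um
#'   (`low < center < high`).
#' @param sdf_cone_half_angle,sdf_n_rays shape-diameter ray parameters.
#' @param component_min_diam component-size cutoff, um.
#' @param small_min,small_max small-structure band, um
#'   (`small_min < small_max < component_min_diam`).
#' @param hausdorff_repair repair distance threshold, um.
#' @param n_large_networks how many largest networks get blue coloring.
#' @param obscurance_samples,obscurance_threshold interior-removal
#'   parameters.
#' @param xy_downsample integer in-plane downsampling factor for
#'   desk-scale runs (um thresholds are spacing-aware and unaffected).
#' @param seed seed for any stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(saturation_scale = 255,
                            interp_target_z = 1,
                            filter_chain = list(threshold = 70, close1_r = 10,
                                                fill_holes = TRUE,
                                                fill_per_slice = TRUE,
                                                dilate_r = 3, close2_r = 5,
                                                blur_sigma = 0.33),
                            iso_value = 35,
                            taubin_iters = 10L,
                            sdf_low = 12, sdf_high = 30, sdf_center = 16.5,
                            sdf_cone_half_angle = 15, sdf_n_rays = 30L,
                            component_min_diam = 70,
                            small_min = 7, small_max = 28,
                            hausdorff_repair = 10,
                            n_large_networks = 1L,
                            obscurance_samples = 32L,
                            obscurance_threshold = 0.05,
                            xy_downsample = 1L,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  um_pos <- c("interp_target_z", "sdf_low", "sdf_high", "sdf_center",
              "component_min_diam", "small_min", "small_max",
              "hausdorff_repair")
  for (f in um_pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config error: ", f, " must be > 0")
  if (!(cfg$sdf_low < cfg$sdf_center && cfg$sdf_center < cfg$sdf_high))
    stop("config error: need sdf_low < sdf_center < sdf_high")
  if (!(cfg$small_min < cfg$small_max &&
        cfg$small_max < cfg$component_min_diam))
    stop("config error: need small_min < small_max < component_min_diam")
  if (cfg$n_large_networks < 1L)
    stop("config error: n_large_networks must be >= 1")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  fc <- x$filter_chain
  cat(sprintf(
    "<pipeline_config> Threshold %g, Close %g, Fill hole %s, Dilate %g, Close %g, Blur %g | iso %g | cutoff %g um\n",
    fc$threshold, fc$close1_r, fc$fill_holes, fc$dilate_r, fc$close2_r,
    fc$blur_sigma, x$iso_value, x$component_min_diam))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_pipeline_config`: a validated [pipeline_config()];
#'   `write_pipeline_config`: invisibly, `path`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

checksum_of <- function(object) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(object, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full reconstruction pipeline on a section stack
#'
#' Executes saturation extraction, optical-flow interpolation, the
#' six-filter chain, isosurfacing, healing/solidification and Taubin
#' smoothing, then the two model branches — (A) interior removal, 70 um
#' component filtering, shape diameter and SDF coloring; (B) 7 um
#' small-component filtering and connectivity coloring — and the QC
#' stage: bidirectional surface distances between the healed
#' reconstruction and the final model, 10 um repair, and a
#' stage-difference report. A manifest of per-stage checksums and voxel /
#' vertex counts makes runs comparable: the configuration fully
#' determines all outputs.
#'
#' @param stack a [section_stack] (real scans or a rendered phantom).
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; meshes (PLY), reports (JSON) and
#'   QC panels are written there.
#' @param verbose print stage progress.
#' @return list with the stage artifacts: `saturation`, `interpolated`,
#'   `filtered`, `mesh_healed`, `mesh_smoothed`, `model_sdf`,
#'   `model_connectivity`, `qc` (distance maps, repaired mesh, stage
#'   report), and `manifest`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(),
                         output_dir = NULL, verbose = FALSE) {
  validate_config(config)
  manifest <- list(config_hash = checksum_of(unclass(config)))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  log_stage <- function(name, info) {
    if (verbose)
      message(sprintf("[%6.1fs] %-16s %s",
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      name, info))
  }
  if (config$xy_downsample > 1L)
    stack <- stage("downsample", downsample_stack(stack, config$xy_downsample))
  sat <- stage("saturation", extract_saturation(stack))
  log_stage("saturation", sprintf("%s voxels", paste(dim(sat$data), collapse = "x")))
  interp <- stage("interpolation",
                  interpolate_slices(sat, config$interp_target_z))
  log_stage("interpolation", sprintf("%d planes", dim(interp$data)[1]))
  filtered <- stage("filtering", apply_chain(interp, config$filter_chain))
  log_stage("filtering", sprintf("%d voxels > 0", sum(filtered$data > 0)))
  mesh_raw <- stage("isosurface", extract_isosurface(filtered, config$iso_value))
  log_stage("isosurface", sprintf("%d verts", n_vertices(mesh_raw)))
  mesh_healed <- stage("healing", heal_and_solidify(mesh_raw))
  mesh_smooth <- stage("smoothing",
                       taubin_smooth(mesh_healed, config$taubin_iters))
  ext <- volume_extent(interp)
  bbox <- rbind(min = c(0, 0, 0), max = ext[c("x", "y", "z")])
  log_stage("smoothing", sprintf("%d verts", n_vertices(mesh_smooth)))

  # branch A: shape-diameter model. Cut surfaces are labeled after
  # interior removal: enclosed inner contours can sit right at the block
  # faces, and only the visible cut surface should carry the flag.
  model_sdf <- stage("interior_removal", remove_interior(
    mesh_smooth, config$obscurance_threshold, config$obscurance_samples))
  model_sdf <- label_cut_surface(model_sdf, bbox)
  setA <- connected_components(model_sdf)
  model_sdf <- stage("component_filter",
                     filter_components(model_sdf, setA,
                                       config$component_min_diam))
  removalA <- attr(model_sdf, "removal_report")
  log_stage("component_filter",
            sprintf("removed %d comps (%.1f%% of surface)",
                    removalA$n_removed, 100 * removalA$removed_fraction))
  model_sdf <- stage("shape_diameter", shape_diameter(
    model_sdf, config$sdf_cone_half_angle, config$sdf_n_rays))
  model_sdf <- stage("sdf_colors", colorize_sdf(
    model_sdf, config$sdf_low, config$sdf_high, config$sdf_center))
  log_stage("shape_diameter",
            sprintf("median %.1f um", median(model_sdf$attrs$sdf_um, na.rm = TRUE)))

  # branch B: connectivity model
  model_conn <- stage("connectivity", classify_connectivity(
    label_cut_surface(mesh_smooth, bbox), small_min = config$small_min,
    small_max = config$small_max, n_large = config$n_large_networks))
  log_stage("connectivity",
            sprintf("%d comps kept", attr(model_conn, "class_table") |> nrow()))

  # QC: bidirectional distances + repair against the healed reconstruction
  qc <- list()
  if (n_faces(model_sdf) > 0 && n_faces(mesh_healed) > 0) {
    qc$forward <- stage("qc_distance",
                        surface_distance(mesh_healed, model_sdf, "forward"))
    qc$backward <- stage("qc_distance",
                         surface_distance(model_sdf, mesh_healed, "backward"))
    qc$repaired <- stage("qc_repair", repair_missing(
      mesh_healed, model_sdf, config$hausdorff_repair,
      distances = qc$forward))
    log_stage("qc", sprintf("fwd max %.1f um, %d comps re-added",
                            qc$forward$summary$max,
                            attr(qc$repaired, "repair_report")$n_added))
  }
  qc$stage_report <- stage("qc_stages",
                           stage_difference_report(interp, filtered,
                                                   stack = stack, sat = sat))
  artifacts <- list(saturation = sat, interpolated = interp,
                    filtered = filtered, mesh_healed = mesh_healed,
                    mesh_smoothed = mesh_smooth, model_sdf = model_sdf,
                    model_connectivity = model_conn, qc = qc)
  manifest$stages <- list(
    saturation = checksum_of(sat$data),
    interpolated = checksum_of(interp$data),
    filtered = checksum_of(filtered$data),
    mesh_healed = checksum_of(list(mesh_healed$vertices, mesh_healed$faces)),
    model_sdf = checksum_of(list(model_sdf$vertices, model_sdf$faces,
                                 model_sdf$colors)),
    model_connectivity = checksum_of(list(model_conn$vertices,
                                          model_conn$faces,
                                          model_conn$colors)))
  manifest$counts <- list(
    n_sections = length(stack$slices),
    n_planes = dim(interp$data)[1],
    n_vertices_final = n_vertices(model_sdf),
    removed_fraction = removalA$removed_fraction)
  artifacts$manifest <- manifest
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mesh(model_sdf, file.path(output_dir, "model_sdf.ply"))
    write_mesh(model_conn, file.path(output_dir, "model_connectivity.ply"))
    if (!is.null(qc$repaired))
      write_mesh(qc$repaired, file.path(output_dir, "model_repaired.ply"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  artifacts
}

downsample_stack <- function(stack, factor) {
  factor <- as.integer(factor)
  slices <- lapply(stack$slices, function(s) {
    d <- dim(s)
    ny <- d[1] %/% factor; nx <- d[2] %/% factor
    out <- array(0L, dim = c(ny, nx, 3))
    for (ch in 1:3) {
      m <- s[seq_len(ny * factor), seq_len(nx * factor), ch]
      blocks <- matrix(0, ny, nx)
      for (dy in seq_len(factor)) for (dx in seq_len(factor))
        blocks <- blocks + m[seq(dy, by = factor, length.out = ny),
                             seq(dx, by = factor, length.out = nx)]
      out[, , ch] <- as.integer(round(blocks / factor^2))
    }
    out
  })
  section_stack(slices, stack$xy_spacing * factor, stack$z_spacing,
                stack$names)
}
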