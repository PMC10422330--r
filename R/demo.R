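#' End-to-end synthetic two-epoch demo
#'
#' Runs the whole pipeline on a synthetic reef: generate a two-epoch scene
#' with prescribed growth and mortality, tile it, train a tiny model,
#' predict the epoch-2 mask, compute height change, VRM and point-cloud
#' roughness stratified by the predicted classes, and project the results
#' onto the height-field mesh. Deterministic for a fixed seed.
#'
#' @param out output directory
#' @param seed integer seed driving every random choice
#' @param extent_px scene size in cells (default 128)
#' @param n_colonies coral colonies in the scene
#' @param growth_mm prescribed live-coral growth between epochs (mm)
#' @param mortality_fraction fraction of live colonies dying between epochs
#' @param window,stride tiling parameters (must suit `extent_px`)
#' @param epochs training epochs for the tiny model
#' @return (invisibly) the summary list also written to `summary.json`
#' @export
reef_demo <- function(out, seed = 7L, extent_px = 128L, n_colonies = 4L,
                      growth_mm = 10, mortality_fraction = 0.25,
                      window = 64L, stride = 32L, epochs = 4L) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- scene_params(extent_px = c(extent_px, extent_px),
                    n_colonies = n_colonies,
                    colony_radius_range = c(0.010, 0.018) * extent_px / 128,
                    colony_height_range = c(0.02, 0.04),
                    seed = seed)
  s1 <- generate_scene(p)
  s2 <- evolve_scene(s1, epoch_delta(growth_mm = growth_mm,
                                     mortality_fraction = mortality_fraction,
                                     seed = seed + 1L))
  write_scene(s1, file.path(out, "epoch1"), cloud_density = 0L)
  write_scene(s2, file.path(out, "epoch2"), cloud_density = 0L)

  patches <- extract_patches(s2$ortho, s2$dsm, s2$labels, window, stride)
  model <- mmcs_fit(patches, mmcs_config("tiny"), epochs = epochs,
                    batch_size = 4L, seed = seed)
  pred <- predict(model, s2$ortho, s2$dsm)
  save_raster(pred$label, file.path(out, "predicted_mask.asc"))
  ev <- seg_eval(pred$label, s2$labels)

  change <- dsm_difference(s2$dsm, s1$dsm)
  save_raster(change, file.path(out, "height_change_mm.asc"))
  scene_med <- change_summary(change)$stats$median
  live_med <- change_summary(change, pred$label, class_id = 1L)$stats$median

  v <- vrm(s2$dsm, 21L)
  vrm_stats <- stratify_by_class(v$vrm, pred$label, scale = 21L)

  cloud <- sample_point_cloud(s2, 1L, jitter = FALSE)
  cloud <- transfer_labels(cloud, pred$label)
  cloud <- roughness(cloud, 0.02)
  rough_stats <- stratify_by_class(cloud, scale = 0.02,
                                   scalar_name = "roughness_r20")
  write_ply(cloud, file.path(out, "cloud_roughness.ply"))

  mesh <- build_mesh(s2)
  mesh <- project_raster_to_mesh(mesh, pred$label, "pred_class")
  mesh <- project_raster_to_mesh(mesh, change, "height_change_mm")
  mesh <- colorize(mesh, "height_change_mm", "diverging")
  write_ply(mesh, file.path(out, "mesh_change.ply"))

  summary <- list(
    seed = seed,
    scene = list(extent_px = extent_px, n_colonies = n_colonies,
                 growth_mm = growth_mm,
                 mortality_fraction = mortality_fraction),
    segmentation = list(val_mIoU = model$cv_mIoU, val_mPA = model$cv_mPA,
                        scene_mPA = ev$mPA, scene_mIoU = ev$mIoU),
    height_change_mm = list(scene_median = scene_med,
                            predicted_live_median = live_med),
    vrm_w21_median = stats::setNames(as.list(vrm_stats$median),
                                     class_scheme()$names),
    roughness_r20_median = stats::setNames(as.list(rough_stats$median),
                                           class_scheme()$names))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

cmd_demo <- function(opts) {
  seed <- cli_opt(opts, "seed", 7L, cli_int)
  out <- cli_opt(opts, "out")
  reef_demo(out, seed = seed,
            extent_px = cli_opt(opts, "extent", 128L, cli_int),
            epochs = cli_opt(opts, "epochs", 4L, cli_int),
            window = cli_opt(opts, "window", 64L, cli_int),
            stride = cli_opt(opts, "stride", 32L, cli_int))
  write_sidecar(out, "demo", opts, seed)
  0L
}
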