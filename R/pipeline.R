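#' Pipeline configuration
#'
#' A validated, YAML-round-trippable bundle of every knob in the end-to-end
#' flow: grid geometry, ROI decision threshold, detection thresholds, and
#' the convergence rule of the integrated histogram.
#'
#' @param grid_rows,grid_cols,tile_size_px Grid geometry (defaults 15, 20,
#'   512).
#' @param roi_threshold ROI decision threshold in `[0, 1]` (default 0.5).
#' @param conf_thr Detection class-probability cut (default 0.75).
#' @param iou_thr IoU threshold for evaluation matching (default 0.5).
#' @param min_tiles,tau,patience Convergence rule (defaults 80, 1e-5, 5).
#' @param include_bm_me Include the squashed myeloid-to-erythroid component
#'   in the convergence distance (default `TRUE`).
#' @param seed Master seed (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid_rows = 15L, grid_cols = 20L,
                            tile_size_px = 512L, roi_threshold = 0.5,
                            conf_thr = 0.75, iou_thr = 0.5, min_tiles = 80L,
                            tau = 1e-5, patience = 5L, include_bm_me = TRUE,
                            seed = 1L) {
  cfg <- list(
    grid = list(rows = as.integer(grid_rows), cols = as.integer(grid_cols),
                tile_size_px = as.integer(tile_size_px)),
    roi = list(threshold = roi_threshold),
    detect = list(conf_thr = conf_thr, iou_thr = iou_thr),
    hct = list(min_tiles = as.integer(min_tiles), tau = tau,
               patience = as.integer(patience),
               include_bm_me = isTRUE(include_bm_me)),
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$grid$rows >= 1, cfg$grid$cols >= 1, cfg$grid$tile_size_px >= 32,
    cfg$roi$threshold >= 0, cfg$roi$threshold <= 1,
    cfg$detect$conf_thr >= 0, cfg$detect$conf_thr <= 1,
    cfg$detect$iou_thr > 0, cfg$detect$iou_thr <= 1,
    cfg$hct$min_tiles >= 1, cfg$hct$tau > 0, cfg$hct$patience >= 1,
    is.logical(cfg$hct$include_bm_me)
  )
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Run the end-to-end pipeline on a synthetic slide
#'
#' The full flow on one seeded synthetic slide: simulate, grid, ROI
#' classification, per-ROI-tile detection, integrated-histogram convergence,
#' and a written report — deterministic under the configuration seed.
#'
#' @param profile_name Diagnostic preset name (see [diagnostic_profile()]).
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory; created if needed. The NDC report
#'   (JSON + CSVs), ROI predictions CSV and slide manifest JSON are written
#'   there.
#' @return The `ndc_report`, invisibly; artifact paths in
#'   `attr(, "paths")`.
#' @export
run_pipeline <- function(profile_name = "normal", cfg = pipeline_config(),
                         out_dir = tempfile("marrowhct_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profile <- diagnostic_profile(profile_name)
  grid <- grid_spec(cfg$grid$rows, cfg$grid$cols, cfg$grid$tile_size_px)
  slide <- render_slide(profile, grid, seed = cfg$seed)
  report <- run_ndc(
    slide,
    roi_threshold = cfg$roi$threshold, conf_thr = cfg$detect$conf_thr,
    min_tiles = cfg$hct$min_tiles, tau = cfg$hct$tau,
    patience = cfg$hct$patience, include_bm_me = cfg$hct$include_bm_me,
    grid = grid
  )
  paths <- list(
    report = file.path(out_dir, "ndc_report.json"),
    roi = file.path(out_dir, "roi_predictions.csv"),
    manifest = file.path(out_dir, "slide_manifest.json")
  )
  write_ndc_report(report, paths$report)
  utils::write.csv(report$roi_predictions, paths$roi, row.names = FALSE)
  write_slide_manifest(slide, paths$manifest)
  attr(report, "paths") <- paths
  invisible(report)
}

#' Write a synthetic slide's manifest as JSON
#'
#' Records everything needed to regenerate the slide bit-identically: the
#' seed, profile (name, mixture, per-tile mean, ROI fraction), grid, and
#' the per-tile appropriateness labels with tile seeds.
#'
#' @param slide A `synthetic_slide`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_slide_manifest <- function(slide, path) {
  jsonlite::write_json(
    list(
      seed = slide$seed,
      profile = list(name = slide$profile$name,
                     mixture = as.list(slide$profile$mixture),
                     cells_per_roi_tile_mean = slide$profile$cells_per_roi_tile_mean,
                     roi_fraction = slide$profile$roi_fraction),
      grid = unclass(slide$grid),
      roi_labels = slide$roi_labels
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_slide_manifest
#' @return `read_slide_manifest()` rebuilds the `synthetic_slide` from its
#'   manifest (annotations and tile images regenerate deterministically).
#' @export
read_slide_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- new_diagnostic_profile(
    m$profile$name, unlist(m$profile$mixture),
    m$profile$cells_per_roi_tile_mean, m$profile$roi_fraction
  )
  grid <- grid_spec(m$grid$rows, m$grid$cols, m$grid$tile_size_px)
  render_slide(profile, grid, seed = m$seed)
}
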