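#' Reference blob detector for synthetic aspirate tiles
#'
#' A transparent stand-in for a learned object detector, sufficient to run
#' the pipeline end-to-end on synthetic tiles. The algorithm is entirely
#' classical: (1) foreground = pixels whose colour departs from the tile's
#' median (background) colour by more than `fg_thr`; (2) connected
#' components, split by a distance-map watershed so touching cells separate;
#' (3) a tight bounding box, pixel area and mean colour per component;
#' (4) classification to the nearest class centroid in feature space
#' (mean RGB fill colour plus equivalent radius `sqrt(area / pi)`, radius
#' scaled by `radius_scale`); (5) confidence as a documented decreasing
#' function of the feature distance `d`: `exp(-(d / conf_scale)^2)`.
#'
#' Components smaller than `min_area` pixels are discarded as noise.
#'
#' @param image RGB tile array `[h, w, 3]` in `[0, 1]`.
#' @param classes Class table (default [bm_cell_classes()]).
#' @param fg_thr Foreground colour-distance threshold (default 0.15).
#' @param min_area Minimum component area in pixels (default 20).
#' @param conf_scale Scale of the confidence decay (default 0.25).
#' @param radius_scale Divisor bringing the radius feature onto the colour
#'   scale (default 30).
#' @param watershed_tolerance Minimum distance-map depth between split
#'   objects (default 2).
#' @return A detection tibble: `class_id`, `x0`, `y0`, `x1`, `y1`,
#'   `confidence`.
#' @export
detect_cells <- function(image, classes = bm_cell_classes(), fg_thr = 0.15,
                         min_area = 20, conf_scale = 0.25, radius_scale = 30,
                         watershed_tolerance = 2) {
  med <- apply(image, 3, median)
  dist <- sqrt((image[, , 1] - med[1])^2 + (image[, , 2] - med[2])^2 +
                 (image[, , 3] - med[3])^2)
  fg <- dist > fg_thr
  if (!any(fg)) return(detection_tbl())
  lab <- EBImage::watershed(EBImage::distmap(fg), tolerance = watershed_tolerance,
                            ext = 1)
  lab <- as.matrix(lab)
  n_lab <- max(lab)
  if (n_lab == 0) return(detection_tbl())
  centroids <- cbind(classes$fill_r, classes$fill_g, classes$fill_b) / 255
  centroids <- cbind(centroids, classes$mean_radius_px / radius_scale)
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(comp, n_lab)
  keep <- which(area >= min_area)
  if (length(keep) == 0) return(detection_tbl())
  r1 <- image[, , 1][idx]; g1 <- image[, , 2][idx]; b1 <- image[, , 3][idx]
  mean_r <- vapply(split(r1, comp), mean, numeric(1))[as.character(keep)]
  mean_g <- vapply(split(g1, comp), mean, numeric(1))[as.character(keep)]
  mean_b <- vapply(split(b1, comp), mean, numeric(1))[as.character(keep)]
  y0 <- vapply(split(rows, comp), min, numeric(1))[as.character(keep)] - 1
  y1 <- vapply(split(rows, comp), max, numeric(1))[as.character(keep)]
  x0 <- vapply(split(cols, comp), min, numeric(1))[as.character(keep)] - 1
  x1 <- vapply(split(cols, comp), max, numeric(1))[as.character(keep)]
  r_eq <- sqrt(area[keep] / pi) / radius_scale
  feats <- cbind(mean_r, mean_g, mean_b, r_eq)
  d2 <- outer(rowSums(feats^2), rowSums(centroids^2), `+`) -
    2 * feats %*% t(centroids)
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  d <- sqrt(d2[cbind(seq_along(best), best)])
  detection_tbl(
    class_id = classes$class_id[best],
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    confidence = exp(-(d / conf_scale)^2)
  )
}

#' Detector backend constructors
#'
#' `blob_detector_backend()` wraps [detect_cells()] with fixed settings into
#' the `function(image) -> detection tibble` contract that [run_ndc()] and
#' [classify_tiles()]-style drivers expect.
#'
#' @param ... Arguments forwarded to [detect_cells()].
#' @return A function of one argument (the tile image).
#' @export
blob_detector_backend <- function(...) {
  args <- list(...)
  function(image) do.call(detect_cells, c(list(image), args))
}

#' Write detections to CSV
#'
#' @param dets Detection tibble, optionally with a `tile` column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  utils::write.csv(dets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
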