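#' Tile grid specification
#'
#' The sampling grid laid over a slide: by default 15 rows by 20 columns of
#' 512-pixel tiles, so that tiles drawn from the cell centres sample the
#' whole slide evenly.
#'
#' @param rows,cols Positive integers (defaults 15 and 20).
#' @param tile_size_px Tile side in pixels (default 512, minimum 32).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(rows = 15L, cols = 20L, tile_size_px = 512L) {
  stopifnot(rows >= 1, cols >= 1, tile_size_px >= 32)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tile_size_px = as.integer(tile_size_px)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$rows, "x", x$cols, " tiles of ", x$tile_size_px,
      "px\n", sep = "")
  invisible(x)
}

#' Build the tile grid over a slide
#'
#' Places one tile per grid cell, centred at the cell centre
#' `((col + 0.5) * W / cols, (row + 0.5) * H / rows)` and clamped (never
#' padded) to the slide bounds. Coordinates are 0-based; tiles are half-open
#' pixel rectangles.
#'
#' @param slide_width,slide_height Slide dimensions in pixels.
#' @param grid A [grid_spec()].
#' @return A tibble of `rows * cols` tile references in row-major order:
#'   `row`, `col`, `x0`, `y0`, `width`, `height`.
#' @examples
#' build_grid(10240, 7680, grid_spec())
#' @export
build_grid <- function(slide_width, slide_height, grid = grid_spec()) {
  sz <- grid$tile_size_px
  if (slide_width < sz || slide_height < sz) {
    stop("slide (", slide_width, "x", slide_height,
         ") is smaller than one tile (", sz, ")", call. = FALSE)
  }
  tiles <- tidyr::expand_grid(row = seq_len(grid$rows) - 1L,
                              col = seq_len(grid$cols) - 1L)
  dplyr::mutate(
    tiles,
    x0 = pmin(pmax(round((.data$col + 0.5) * slide_width / grid$cols - sz / 2), 0),
              slide_width - sz),
    y0 = pmin(pmax(round((.data$row + 0.5) * slide_height / grid$rows - sz / 2), 0),
              slide_height - sz),
    width = sz, height = sz
  )
}

#' Score and label grid tiles with an ROI classifier backend
#'
#' Applies a pluggable backend — any function mapping an RGB tile array to a
#' score in `[0, 1]` — to every tile of the grid and labels tiles
#' `appropriate` when the score is at or above `threshold`.
#'
#' @param slide A slide object satisfying the reader contract
#'   ([slide_dims()] / [read_region()]).
#' @param tiles Tile tibble from [build_grid()].
#' @param backend `function(image) -> score in [0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A tibble: `row`, `col`, `x0`, `y0`, `score`,
#'   `label` (`"appropriate"` / `"inappropriate"`).
#' @export
classify_tiles <- function(slide, tiles, backend, threshold = 0.5) {
  scores <- purrr::pmap_dbl(tiles[, c("x0", "y0", "width", "height")],
    function(x0, y0, width, height) {
      s <- backend(read_region(slide, x0, y0, width, height))
      if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
        stop("ROI backend returned an invalid score (must be one number in [0, 1])",
             call. = FALSE)
      }
      s
    })
  dplyr::mutate(tiles[, c("row", "col", "x0", "y0")],
                score = scores,
                label = ifelse(scores >= threshold, "appropriate", "inappropriate"))
}

#' Reference heuristic ROI backend
#'
#' A transparent stand-in for a learned ROI classifier, scoring a tile from
#' three image features that mirror the cytological ROI criteria (thin,
#' well-spread, free of overstaining and clumping, with at least one
#' segmentable object):
#'
#' * foreground fraction — pixels whose colour departs from the tile's
#'   median (background) colour; the subscore is 1 inside the band
#'   `[lo, hi]` and falls off linearly outside it;
#' * clump fraction — the share of foreground in connected components
#'   larger than `max_blob_px` (smeared/agglutinated tiles); the subscore
#'   decreases monotonically in it;
#' * tint deviation — distance of the median colour from the reference
#'   background (overstained tiles); subscore decreases monotonically;
#' * component count — connected components within `[min_obj_px,
#'   max_blob_px]`; the subscore rises from 0 (no segmentable object) to 1
#'   at `n_ref` components.
#'
#' The final score is the product of the four subscores, hence in `[0, 1]`
#' and monotone in each feature in the documented direction.
#'
#' @param image RGB tile array.
#' @param lo,hi Foreground-fraction band (defaults 0.004 and 0.35).
#' @param min_obj_px,max_blob_px Component size band in pixels. The default
#'   `max_blob_px = 8000` is roughly twice the area of the largest
#'   legitimate single object (a megakaryocyte ellipse), so anything larger
#'   is read as a clump of overlapping cells.
#' @param n_ref Component count at which the count subscore saturates.
#' @return One score in `[0, 1]`.
#' @export
roi_reference_backend <- function(image, lo = 0.004, hi = 0.35,
                                  min_obj_px = 30, max_blob_px = 8000,
                                  n_ref = 4) {
  med <- apply(image, 3, median)
  dist <- sqrt((image[, , 1] - med[1])^2 + (image[, , 2] - med[2])^2 +
                 (image[, , 3] - med[3])^2)
  fg <- dist > 0.15
  p <- mean(fg)
  s_fg <- if (p < lo) p / lo else if (p <= hi) 1 else max(0, 1 - (p - hi) / hi)
  tint_dev <- sqrt(sum((med - tile_background_rgb())^2))
  s_tint <- max(0, 1 - tint_dev / 0.25)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab)
  n_comp <- sum(sizes >= min_obj_px & sizes <= max_blob_px)
  big_frac <- if (sum(sizes) > 0) sum(sizes[sizes > max_blob_px]) / sum(sizes) else 0
  s_blob <- 1 - big_frac
  s_count <- min(1, n_comp / n_ref)
  s_fg * s_tint * s_blob * s_count
}

#' Binary classification metrics from a confusion count
#'
#' The standard binary measures over true/false positive/negative counts,
#' with appropriate tiles as the positive class: accuracy
#' `(Tp+Tn)/(Tp+Tn+Fp+Fn)`, precision `Tp/(Tp+Fp)`, recall `Tp/(Tp+Fn)`,
#' specificity `Tn/(Tn+Fp)` and NPV `Tn/(Tn+Fn)`. A metric whose
#' denominator is zero is reported as `NA` (explicitly undefined), never
#' coerced to 0 or 1.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts; must not all be zero.
#' @return A one-row tibble: `accuracy`, `precision`, `recall`,
#'   `specificity`, `npv`.
#' @examples
#' binary_metrics(tp = 90, tn = 890, fp = 10, fn = 10)
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  stopifnot(length(counts) == 4, all(counts >= 0))
  if (sum(counts) == 0) stop("all counts are zero; metrics undefined", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    accuracy = (tp + tn) / sum(counts),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Tally ROI predictions against reference labels
#'
#' @param predictions Tibble from [classify_tiles()] (column `label`).
#' @param truth Logical vector (or tibble with column `appropriate`) of
#'   reference labels aligned with `predictions`.
#' @return A one-row tibble of counts `tp`, `tn`, `fp`, `fn` followed by the
#'   metrics of [binary_metrics()].
#' @export
roi_confusion <- function(predictions, truth) {
  if (is.data.frame(truth)) truth <- truth$appropriate
  stopifnot(length(truth) == nrow(predictions))
  pred_pos <- predictions$label == "appropriate"
  tp <- sum(pred_pos & truth); fp <- sum(pred_pos & !truth)
  fn <- sum(!pred_pos & truth); tn <- sum(!pred_pos & !truth)
  dplyr::bind_cols(tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn),
                   binary_metrics(tp, tn, fp, fn))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve over all score thresholds, with tied
#' scores handled by grouping (equivalent to the Mann-Whitney rank statistic
#' with midranks for ties).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or 0/1) reference labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc() needs both classes present", call. = FALSE)
  }
  # sweep thresholds at the unique scores, descending; ties move as a block
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp_last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(l)[grp_last] / n_pos)
  fpr <- c(0, cumsum(!l)[grp_last] / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Grouped k-fold split at the patient (slide) level
#'
#' Assigns each distinct group id (patient or slide) to one of `k` folds,
#' shuffling groups with an explicit seed, so that no group spans folds.
#'
#' @param group_ids Vector of group ids, one per observation.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return An integer fold assignment (1..k) per observation.
#' @export
patient_folds <- function(group_ids, k = 5L, seed = 1L) {
  groups <- unique(group_ids)
  stopifnot(k >= 2, length(groups) >= k)
  shuffled <- with_seed(seed, sample(groups))
  fold_of_group <- setNames(rep(seq_len(k), length.out = length(shuffled)),
                            as.character(shuffled))
  unname(fold_of_group[as.character(group_ids)])
}
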