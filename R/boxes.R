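#' Bounding-box containers
#'
#' Annotations and detections are plain tibbles so they compose with dplyr.
#' Boxes are 0-based, half-open pixel intervals: a box occupies
#' `[x0, x1) x [y0, y1)` with `x1 > x0`, `y1 > y0`. An annotation carries a
#' `class_id` (0-18); a detection additionally carries a `confidence` in
#' `[0, 1]`.
#'
#' @param x0,y0,x1,y1 Numeric box coordinates in pixels.
#' @param class_id Integer class ids (0-18).
#' @param confidence Numeric in `[0, 1]` (detections only).
#' @return A tibble with columns `class_id`, `x0`, `y0`, `x1`, `y1`
#'   (and `confidence` for detections).
#' @export
annotation_tbl <- function(class_id = integer(), x0 = numeric(), y0 = numeric(),
                           x1 = numeric(), y1 = numeric()) {
  out <- tibble::tibble(
    class_id = as.integer(class_id),
    x0 = as.numeric(x0), y0 = as.numeric(y0),
    x1 = as.numeric(x1), y1 = as.numeric(y1)
  )
  validate_boxes(out)
  out
}

#' @rdname annotation_tbl
#' @export
detection_tbl <- function(class_id = integer(), x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric(), confidence = numeric()) {
  out <- tibble::tibble(
    class_id = as.integer(class_id),
    x0 = as.numeric(x0), y0 = as.numeric(y0),
    x1 = as.numeric(x1), y1 = as.numeric(y1),
    confidence = as.numeric(confidence)
  )
  validate_boxes(out)
  if (any(out$confidence < 0 | out$confidence > 1)) {
    stop("`confidence` must lie in [0, 1]", call. = FALSE)
  }
  out
}

validate_boxes <- function(tbl) {
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (any(tbl$x1 <= tbl$x0) || any(tbl$y1 <= tbl$y0)) {
    stop("degenerate box: need x1 > x0 and y1 > y0", call. = FALSE)
  }
  if (any(!tbl$class_id %in% 0:18)) {
    stop("`class_id` must be in 0..18", call. = FALSE)
  }
  invisible(tbl)
}

#' Intersection over union of bounding boxes
#'
#' Computes `area(a intersect b) / area(a union b)` for half-open pixel
#' boxes. Vectorised: `a` and `b` are tibbles/data frames with columns
#' `x0, y0, x1, y1` and are recycled against each other row-wise.
#'
#' @param a,b Data frames with box columns `x0, y0, x1, y1`.
#' @return Numeric vector of IoU values in `[0, 1]`; 0 for disjoint boxes.
#' @examples
#' box_iou(data.frame(x0 = 0, y0 = 0, x1 = 2, y1 = 2),
#'         data.frame(x0 = 1, y0 = 0, x1 = 3, y1 = 2)) # 1/3
#' @export
box_iou <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(numeric(0))
  if (any(a$x1 <= a$x0) || any(a$y1 <= a$y0) ||
      any(b$x1 <= b$x0) || any(b$y1 <= b$y0)) {
    stop("degenerate box passed to box_iou()", call. = FALSE)
  }
  iw <- pmax(0, pmin(a$x1, b$x1) - pmax(a$x0, b$x0))
  ih <- pmax(0, pmin(a$y1, b$y1) - pmax(a$y0, b$y0))
  inter <- iw * ih
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) + (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

# IoU of one box (length-4 numeric x0,y0,x1,y1) against a matrix of boxes
iou_one_many <- function(box, mat) {
  if (nrow(mat) == 0) return(numeric(0))
  iw <- pmax(0, pmin(box[3], mat[, 3]) - pmax(box[1], mat[, 1]))
  ih <- pmax(0, pmin(box[4], mat[, 4]) - pmax(box[2], mat[, 2]))
  inter <- iw * ih
  union <- (box[3] - box[1]) * (box[4] - box[2]) +
    (mat[, 3] - mat[, 1]) * (mat[, 4] - mat[, 2]) - inter
  inter / union
}

#' Greedy confidence-ordered matching of detections to annotations
#'
#' Pascal-VOC style one-to-one assignment: detections below `conf_thr` are
#' discarded; the rest are sorted by descending confidence (ties broken by
#' input order) and each is greedily matched to the unmatched annotation
#' (of the same class when `class_aware = TRUE`) with the highest IoU at or
#' above `iou_thr` (IoU ties broken by lowest annotation index). Matched
#' pairs are true positives; unmatched retained detections are false
#' positives; unmatched annotations are false negatives.
#'
#' @param dets Detection tibble (see [detection_tbl()]).
#' @param anns Annotation tibble (see [annotation_tbl()]).
#' @param iou_thr Minimum IoU for a match (default 0.5).
#' @param conf_thr Minimum class-probability (confidence) for a detection to
#'   be retained (default 0.75).
#' @param class_aware Match only within the same class (default `TRUE`).
#' @return A list of class `match_result`: `tp` (tibble of matched pairs with
#'   `det_idx`, `ann_idx`, `class_id`, `pred_class_id`, `confidence`, `iou`),
#'   `fp` (retained unmatched detections), `fn` (unmatched annotations), and
#'   counts `n_tp`, `n_fp`, `n_fn`.
#' @export
match_detections <- function(dets, anns, iou_thr = 0.5, conf_thr = 0.75,
                             class_aware = TRUE) {
  keep <- which(dets$confidence >= conf_thr)
  ord <- keep[order(-dets$confidence[keep])] # stable: ties keep input order
  ann_mat <- as.matrix(anns[, c("x0", "y0", "x1", "y1")])
  matched_ann <- rep(FALSE, nrow(anns))
  tp_det <- integer(0); tp_ann <- integer(0); tp_iou <- numeric(0)
  for (d in ord) {
    cand <- which(!matched_ann)
    if (class_aware) cand <- cand[anns$class_id[cand] == dets$class_id[d]]
    if (length(cand) == 0) next
    ious <- iou_one_many(
      c(dets$x0[d], dets$y0[d], dets$x1[d], dets$y1[d]),
      ann_mat[cand, , drop = FALSE]
    )
    ok <- ious >= iou_thr
    if (!any(ok)) next
    best <- cand[ok][which.max(ious[ok])] # which.max takes first on ties
    matched_ann[best] <- TRUE
    tp_det <- c(tp_det, d); tp_ann <- c(tp_ann, best)
    tp_iou <- c(tp_iou, ious[ok][which.max(ious[ok])])
  }
  fp_idx <- setdiff(ord, tp_det)
  fn_idx <- which(!matched_ann)
  tp <- tibble::tibble(
    det_idx = tp_det,
    ann_idx = tp_ann,
    class_id = anns$class_id[tp_ann],
    pred_class_id = dets$class_id[tp_det],
    confidence = dets$confidence[tp_det],
    iou = tp_iou
  )
  structure(
    list(
      tp = tp,
      fp = dets[fp_idx, , drop = FALSE],
      fn = anns[fn_idx, , drop = FALSE],
      n_tp = nrow(tp), n_fp = length(fp_idx), n_fn = length(fn_idx)
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> TP:", x$n_tp, " FP:", x$n_fp, " FN:", x$n_fn, "\n")
  invisible(x)
}

#' Greedy non-maximum suppression
#'
#' Within each class, detections are visited in descending confidence order
#' and any lower-ranked detection overlapping a kept one with IoU above
#' `iou_thr` is suppressed.
#'
#' @param dets Detection tibble.
#' @param iou_thr Suppression threshold (default 0.5).
#' @return The surviving subset of `dets`, original order preserved.
#' @export
nms <- function(dets, iou_thr = 0.5) {
  if (nrow(dets) == 0) return(dets)
  keep <- logical(nrow(dets))
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    ord <- idx[order(-dets$confidence[idx])]
    mat <- as.matrix(dets[, c("x0", "y0", "x1", "y1")])
    kept <- integer(0)
    for (d in ord) {
      if (length(kept) > 0) {
        ious <- iou_one_many(mat[d, ], mat[kept, , drop = FALSE])
        if (any(ious > iou_thr)) next
      }
      kept <- c(kept, d)
    }
    keep[kept] <- TRUE
  }
  dets[keep, , drop = FALSE]
}

#' Read and write YOLO/LabelImg annotation files
#'
#' The plain-text dialect used by LabelImg-style tools: one line per object,
#' `class_id cx cy w h`, with centre and size normalised to `[0, 1]` by the
#' image dimensions. Reading converts to half-open pixel boxes
#' (`x0 = (cx - w/2) * width`, etc.); writing inverts the mapping, so a
#' write/read round trip is the identity to within about `1e-6` normalised
#' units.
#'
#' @param path File path.
#' @param image_width,image_height Pixel dimensions of the associated image.
#' @return `read_yolo()` returns an annotation tibble; an empty or missing
#'   final newline is tolerated, an empty file yields zero rows.
#' @export
read_yolo <- function(path, image_width, image_height) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(annotation_tbl())
  parse_line <- function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5) {
      stop("malformed YOLO line ", i, " in ", path, ": ", lines[i], call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      stop("non-numeric YOLO line ", i, " in ", path, call. = FALSE)
    }
    if (vals[1] != as.integer(vals[1]) || vals[1] < 0 || vals[1] > 18) {
      stop("class_id out of range (0-18) on line ", i, " in ", path, call. = FALSE)
    }
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1)) {
      stop("normalised coordinate outside [0, 1] on line ", i, " in ", path,
           call. = FALSE)
    }
    vals
  }
  m <- t(vapply(seq_along(lines), parse_line, numeric(5)))
  annotation_tbl(
    class_id = as.integer(m[, 1]),
    x0 = (m[, 2] - m[, 4] / 2) * image_width,
    y0 = (m[, 3] - m[, 5] / 2) * image_height,
    x1 = (m[, 2] + m[, 4] / 2) * image_width,
    y1 = (m[, 3] + m[, 5] / 2) * image_height
  )
}

#' @rdname read_yolo
#' @param anns Annotation tibble to write.
#' @export
write_yolo <- function(anns, path, image_width, image_height) {
  validate_boxes(anns)
  cx <- (anns$x0 + anns$x1) / 2 / image_width
  cy <- (anns$y0 + anns$y1) / 2 / image_height
  w <- (anns$x1 - anns$x0) / image_width
  h <- (anns$y1 - anns$y0) / image_height
  if (nrow(anns) > 0 && (any(c(cx - w / 2, cy - h / 2) < -1e-9) ||
                         any(c(cx + w / 2, cy + h / 2) > 1 + 1e-9))) {
    stop("box outside image bounds cannot be written in normalised form",
         call. = FALSE)
  }
  lines <- sprintf("%d %.8f %.8f %.8f %.8f", anns$class_id, cx, cy, w, h)
  writeLines(lines, path)
  invisible(path)
}
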