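split_by_tile <- function(tbl) {
  if (!"tile" %in% names(tbl)) tbl$tile <- "tile_0"
  tbl
}

#' Pooled precision-recall curve for one class
#'
#' Detections of one class are pooled over all tiles and ranked by
#' descending confidence (ties keep input order). Walking down the ranking,
#' each detection is greedily matched to the unmatched ground-truth
#' annotation of that class in its tile with the highest IoU at or above
#' `iou_thr`; cumulative precision and recall are recorded at every rank.
#'
#' @param dets Detection tibble with an optional `tile` column.
#' @param anns Annotation tibble with an optional `tile` column; must contain
#'   at least one object of `class_id` (otherwise AP is undefined and an
#'   error is raised).
#' @param class_id Class to evaluate.
#' @param iou_thr IoU threshold for a true positive (default 0.5).
#' @param conf_thr Discard detections below this confidence before ranking
#'   (default 0: the full ranking is used).
#' @return A `pr_curve` object: tibble `confidence`, `tp` (cumulative),
#'   `fp` (cumulative), `precision`, `recall`, with attribute `n_gt`.
#' @export
pr_curve <- function(dets, anns, class_id, iou_thr = 0.5, conf_thr = 0) {
  dets <- split_by_tile(dets); anns <- split_by_tile(anns)
  anns_c <- anns[anns$class_id == class_id, , drop = FALSE]
  n_gt <- nrow(anns_c)
  if (n_gt == 0) {
    stop("class ", class_id, " absent from ground truth; AP undefined",
         call. = FALSE)
  }
  dets_c <- dets[dets$class_id == class_id & dets$confidence >= conf_thr, ,
                 drop = FALSE]
  dets_c <- dets_c[order(-dets_c$confidence), , drop = FALSE]
  matched <- rep(FALSE, n_gt)
  is_tp <- logical(nrow(dets_c))
  ann_mat <- as.matrix(anns_c[, c("x0", "y0", "x1", "y1")])
  for (i in seq_len(nrow(dets_c))) {
    cand <- which(!matched & anns_c$tile == dets_c$tile[i])
    if (length(cand) > 0) {
      ious <- iou_one_many(
        c(dets_c$x0[i], dets_c$y0[i], dets_c$x1[i], dets_c$y1[i]),
        ann_mat[cand, , drop = FALSE]
      )
      if (any(ious >= iou_thr)) {
        matched[cand[which.max(ious)]] <- TRUE
        is_tp[i] <- TRUE
      }
    }
  }
  tp <- cumsum(is_tp); fp <- cumsum(!is_tp)
  curve <- tibble::tibble(
    confidence = dets_c$confidence,
    tp = tp, fp = fp,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), 0),
    recall = tp / n_gt
  )
  structure(curve, n_gt = n_gt, class_id = class_id,
            class = c("pr_curve", class(curve)))
}

#' Eleven-point interpolated average precision
#'
#' `AP = (1/11) * sum over r in {0, 0.1, ..., 1} of P_interp(r)` where
#' `P_interp(r) = max over achieved recalls r' >= r of precision(r')`;
#' recall levels never reached contribute 0.
#'
#' @param curve A [pr_curve()].
#' @return A list of class `ap_result`: `class_id`, `ap`,
#'   `interp_precisions` (the 11 interpolated precisions), `n_gt`.
#' @export
ap_11point <- function(curve) {
  r_grid <- seq(0, 1, by = 0.1)
  interp <- vapply(r_grid, function(r) {
    ok <- curve$recall >= r - 1e-12
    if (!any(ok)) 0 else max(curve$precision[ok])
  }, numeric(1))
  structure(
    list(class_id = attr(curve, "class_id"), ap = mean(interp),
         interp_precisions = setNames(interp, sprintf("r%.1f", r_grid)),
         n_gt = attr(curve, "n_gt")),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat("<ap_result> class", x$class_id, " AP =", format(x$ap, digits = 4), "\n")
  invisible(x)
}

#' Mean average precision
#'
#' Arithmetic mean of per-class AP values. Classes absent from the ground
#' truth should not be passed in (they are excluded from mAP, not scored 0).
#'
#' @param aps Numeric vector of APs, or a list of [ap_11point()] results.
#' @return The mean AP.
#' @export
mean_ap <- function(aps) {
  if (is.list(aps) && !is.numeric(aps)) {
    aps <- vapply(aps, function(a) a$ap, numeric(1))
  }
  stopifnot(length(aps) > 0, all(aps >= 0 & aps <= 1))
  mean(aps)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2 * p * r / (p + r)`.
#' Vectorised; requires `p + r > 0` elementwise.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(all(precision + recall > 0))
  2 * precision * recall / (precision + recall)
}

#' Miss rate versus false positives per image
#'
#' Sweeps the confidence threshold over all detection scores of a class and
#' records, at each threshold, the miss rate `FN / n_gt` and the false
#' positives per image `FP / n_images`.
#'
#' @inheritParams pr_curve
#' @param n_images Number of images the detections were produced on
#'   (default: distinct tiles in `anns`).
#' @return An `fppi_curve` object: tibble `confidence`, `fppi`, `miss_rate`,
#'   with attribute `n_images`.
#' @export
fppi_curve <- function(dets, anns, class_id, iou_thr = 0.5, n_images = NULL) {
  anns <- split_by_tile(anns)
  if (is.null(n_images)) n_images <- length(unique(anns$tile))
  stopifnot(n_images >= 1)
  pr <- pr_curve(dets, anns, class_id, iou_thr = iou_thr, conf_thr = 0)
  # threshold at each distinct confidence: include all detections >= it
  grp_last <- cumsum(rle(pr$confidence)$lengths)
  curve <- tibble::tibble(
    confidence = pr$confidence[grp_last],
    fppi = pr$fp[grp_last] / n_images,
    miss_rate = 1 - pr$recall[grp_last]
  )
  structure(curve, n_images = n_images, class_id = class_id,
            class = c("fppi_curve", class(curve)))
}

#' Log-average miss rate
#'
#' Geometric mean of the miss rates sampled at nine FPPI reference points
#' evenly spaced in log space between `1e-2` and `1`
#' (`10^(-2 + k/4), k = 0..8`). At each reference point the curve is sampled
#' as a step function: the miss rate at the largest achieved FPPI not
#' exceeding the point, or 1 if the curve never reaches that low an FPPI.
#' Miss rates are clamped to at least `1e-10` before taking logs.
#'
#' @param curve An [fppi_curve()].
#' @return The log-average miss rate in `[0, 1]`.
#' @export
lamr <- function(curve) {
  stopifnot(inherits(curve, "fppi_curve"))
  refs <- 10^(-2 + (0:8) / 4)
  a <- vapply(refs, function(ref) {
    cand <- which(curve$fppi <= ref + 1e-12)
    if (length(cand) == 0) return(1)
    best_fppi <- max(curve$fppi[cand])
    min(curve$miss_rate[cand][curve$fppi[cand] == best_fppi])
  }, numeric(1))
  exp(mean(log(pmax(a, 1e-10))))
}

#' Row-normalised confusion matrix of matched objects
#'
#' Detections are matched to ground truth class-agnostically (localisation
#' only, IoU at `iou_thr`, confidences at or above `conf_thr`); each matched
#' pair contributes one tally at (true class, predicted class). Rows are
#' normalised to percentages, so every row with any matched object sums
#' to 100.
#'
#' @inheritParams pr_curve
#' @param conf_thr Confidence cut for detections (default 0.75).
#' @param class_ids Classes to report (default: the 16 evaluated classes).
#' @return A numeric matrix (percent), rows = ground truth, columns =
#'   predicted class; rows with no matched objects are `NA`.
#' @export
confusion_matrix_pct <- function(dets, anns, iou_thr = 0.5, conf_thr = 0.75,
                                 class_ids = evaluated_class_ids()) {
  dets <- split_by_tile(dets); anns <- split_by_tile(anns)
  tallies <- matrix(0, length(class_ids), length(class_ids),
                    dimnames = list(bm_class_name(class_ids),
                                    bm_class_name(class_ids)))
  for (t in unique(anns$tile)) {
    m <- match_detections(dets[dets$tile == t, , drop = FALSE],
                          anns[anns$tile == t, , drop = FALSE],
                          iou_thr = iou_thr, conf_thr = conf_thr,
                          class_aware = FALSE)
    if (m$n_tp == 0) next
    keep <- m$tp$class_id %in% class_ids & m$tp$pred_class_id %in% class_ids
    for (i in which(keep)) {
      gi <- match(m$tp$class_id[i], class_ids)
      pi <- match(m$tp$pred_class_id[i], class_ids)
      tallies[gi, pi] <- tallies[gi, pi] + 1
    }
  }
  rs <- rowSums(tallies)
  out <- 100 * tallies / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters:
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' marginal-product expected agreement `p_e`. Identical lists give 1
#' (including the degenerate case where both raters are the same constant).
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  p_o <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  p_e <- sum(vapply(cats, function(k) mean(labels_a == k) * mean(labels_b == k),
                    numeric(1)))
  if (abs(1 - p_e) < 1e-15) return(if (p_o >= 1 - 1e-15) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Full detection evaluation summary
#'
#' The complete per-class evaluation over a set of tiles: precision, recall
#' and F1 at the operating confidence `conf_thr` (class-aware greedy
#' matching at `iou_thr`), 11-point AP from the full confidence ranking,
#' log-average miss rate, plus mAP, macro averages and the row-normalised
#' confusion matrix.
#'
#' @inheritParams confusion_matrix_pct
#' @param class_ids Classes to evaluate; classes absent from the ground
#'   truth are dropped (not scored 0).
#' @return A `detection_eval` object with fields `per_class` (tibble:
#'   `class_id`, `name`, `n_gt`, `precision`, `recall`, `f1`, `lamr`, `ap`),
#'   `map`, `macro` (one-row tibble of column means), `confusion`, and the
#'   thresholds used. Has [tidy()][generics::tidy] / [glance()][generics::glance]
#'   methods.
#' @export
evaluate_detections <- function(dets, anns, class_ids = evaluated_class_ids(),
                                iou_thr = 0.5, conf_thr = 0.75) {
  dets <- split_by_tile(dets); anns <- split_by_tile(anns)
  class_ids <- class_ids[class_ids %in% unique(anns$class_id)]
  if (length(class_ids) == 0) stop("no evaluated class present in ground truth",
                                   call. = FALSE)
  # one class-aware match per tile at the operating threshold
  tp <- fp <- fn <- setNames(rep(0, length(class_ids)), class_ids)
  for (t in unique(anns$tile)) {
    m <- match_detections(dets[dets$tile == t, , drop = FALSE],
                          anns[anns$tile == t, , drop = FALSE],
                          iou_thr = iou_thr, conf_thr = conf_thr,
                          class_aware = TRUE)
    add <- function(tab, ids) {
      cnt <- table(factor(ids, levels = class_ids))
      tab + as.numeric(cnt)
    }
    tp <- add(tp, m$tp$class_id)
    fp <- add(fp, m$fp$class_id)
    fn <- add(fn, m$fn$class_id)
  }
  per_class <- purrr::map_dfr(seq_along(class_ids), function(i) {
    cid <- class_ids[i]
    pr <- pr_curve(dets, anns, cid, iou_thr = iou_thr)
    ap <- ap_11point(pr)
    fc <- fppi_curve(dets, anns, cid, iou_thr = iou_thr)
    p <- if (tp[i] + fp[i] > 0) tp[i] / (tp[i] + fp[i]) else NA_real_
    r <- if (tp[i] + fn[i] > 0) tp[i] / (tp[i] + fn[i]) else NA_real_
    tibble::tibble(
      class_id = cid, name = bm_class_name(cid), n_gt = attr(pr, "n_gt"),
      precision = p, recall = r,
      f1 = if (!is.na(p) && !is.na(r) && p + r > 0) f1_score(p, r) else NA_real_,
      lamr = lamr(fc), ap = ap$ap
    )
  })
  structure(
    list(
      per_class = per_class,
      map = mean(per_class$ap),
      macro = tibble::tibble(
        precision = mean(per_class$precision, na.rm = TRUE),
        recall = mean(per_class$recall, na.rm = TRUE),
        f1 = mean(per_class$f1, na.rm = TRUE),
        lamr = mean(per_class$lamr),
        map = mean(per_class$ap)
      ),
      confusion = confusion_matrix_pct(dets, anns, iou_thr, conf_thr, class_ids),
      iou_thr = iou_thr, conf_thr = conf_thr
    ),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat("<detection_eval> ", nrow(x$per_class), " classes, mAP@",
      x$iou_thr, " = ", round(x$map, 2), "\n", sep = "")
  print(dplyr::mutate(x$per_class,
                      dplyr::across(c("precision", "recall", "f1", "lamr", "ap"),
                                    ~ round(.x, 2))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_detections
#' @param x A `detection_eval` object.
#' @param ... Unused.
#' @export
tidy.detection_eval <- function(x, ...) x$per_class

#' @rdname evaluate_detections
#' @export
glance.detection_eval <- function(x, ...) x$macro

#' @rdname evaluate_detections
#' @param object A `detection_eval` object.
#' @export
autoplot.detection_eval <- function(object, ...) {
  df <- object$per_class
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$name, .data$ap),
                                   y = .data$ap)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("AP@%.2g", object$iou_thr),
                  title = sprintf("mAP = %.2f", object$map)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write an evaluation summary to CSV
#'
#' Columns follow the conventional report order: class, Precision, Recall,
#' F1, log-average miss rate, AP; a final `Average` row holds the macro
#' means and mAP.
#'
#' @param eval A `detection_eval`.
#' @param path Output CSV path.
#' @param digits Rounding for report parity (default 2); use `NA` for full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(eval, path, digits = 2) {
  df <- eval$per_class[, c("name", "precision", "recall", "f1", "lamr", "ap")]
  names(df) <- c("class", "precision", "recall", "f1", "lamr", "ap")
  avg <- tibble::tibble(class = "Average",
                        precision = eval$macro$precision,
                        recall = eval$macro$recall, f1 = eval$macro$f1,
                        lamr = eval$macro$lamr, ap = eval$macro$map)
  out <- dplyr::bind_rows(df, avg)
  if (!is.na(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, digits)))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
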