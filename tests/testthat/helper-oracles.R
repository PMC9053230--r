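# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

oracle_chisq <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    denom <- x[i] + y[i]
    if (denom > 0) s <- s + (x[i] - y[i])^2 / denom
  }
  s / 2
}

oracle_iou_pair <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# greedy confidence-ordered one-to-one matcher, explicit loops
oracle_match <- function(dets, anns, iou_thr = 0.5, conf_thr = 0.75,
                         class_aware = TRUE) {
  keep <- which(dets$confidence >= conf_thr)
  if (length(keep) > 1) keep <- keep[order(-dets$confidence[keep])]
  used <- rep(FALSE, nrow(anns))
  pairs <- NULL
  for (d in keep) {
    best_iou <- -1; best_j <- NA
    for (j in seq_len(nrow(anns))) {
      if (used[j]) next
      if (class_aware && anns$class_id[j] != dets$class_id[d]) next
      v <- oracle_iou_pair(c(dets$x0[d], dets$y0[d], dets$x1[d], dets$y1[d]),
                           c(anns$x0[j], anns$y0[j], anns$x1[j], anns$y1[j]))
      if (v >= iou_thr && v > best_iou + 1e-15) { # strict: ties keep lowest j
        best_iou <- v; best_j <- j
      }
    }
    if (!is.na(best_j)) {
      used[best_j] <- TRUE
      pairs <- rbind(pairs, c(det = d, ann = best_j))
    }
  }
  n_tp <- if (is.null(pairs)) 0 else nrow(pairs)
  list(n_tp = n_tp, n_fp = length(keep) - n_tp, n_fn = sum(!used),
       pairs = pairs)
}

# 11-point AP by re-matching every top-k prefix from scratch (O(n^2))
oracle_ap <- function(dets, anns, class_id, iou_thr = 0.5) {
  dc <- dets[dets$class_id == class_id, , drop = FALSE]
  dc <- dc[order(-dc$confidence), , drop = FALSE]
  ac <- anns[anns$class_id == class_id, , drop = FALSE]
  n_gt <- nrow(ac)
  prec <- rec <- numeric(nrow(dc))
  for (k in seq_len(nrow(dc))) {
    tp <- 0
    used <- rep(FALSE, n_gt)
    for (i in seq_len(k)) {
      best <- -1; bj <- NA
      for (j in seq_len(n_gt)) {
        if (used[j] || ac$tile[j] != dc$tile[i]) next
        v <- oracle_iou_pair(c(dc$x0[i], dc$y0[i], dc$x1[i], dc$y1[i]),
                             c(ac$x0[j], ac$y0[j], ac$x1[j], ac$y1[j]))
        if (v >= iou_thr && v > best + 1e-15) { best <- v; bj <- j }
      }
      if (!is.na(bj)) { used[bj] <- TRUE; tp <- tp + 1 }
    }
    prec[k] <- tp / k
    rec[k] <- tp / n_gt
  }
  ap_terms <- numeric(11)
  for (m in 0:10) {
    r <- m / 10
    ok <- which(rec >= r - 1e-12)
    ap_terms[m + 1] <- if (length(ok) == 0) 0 else max(prec[ok])
  }
  mean(ap_terms)
}

# LAMR by direct sampling of an (fppi, miss_rate) table at the 9 points
oracle_lamr <- function(fppi, miss_rate) {
  total <- 0
  for (k in 0:8) {
    ref <- 10^(-2 + k / 4)
    best_fppi <- -Inf; a <- 1
    for (i in seq_along(fppi)) {
      if (fppi[i] <= ref + 1e-12) {
        if (fppi[i] > best_fppi + 1e-15) { best_fppi <- fppi[i]; a <- miss_rate[i] }
        else if (abs(fppi[i] - best_fppi) <= 1e-15) a <- min(a, miss_rate[i])
      }
    }
    total <- total + log(max(a, 1e-10))
  }
  exp(total / 9)
}

# AUC via the Mann-Whitney rank statistic with midranks
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

oracle_kappa <- function(a, b) {
  po <- mean(a == b)
  pe <- 0
  for (k in unique(c(a, b))) pe <- pe + mean(a == k) * mean(b == k)
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

# random box sets for property tests
rand_dets <- function(n, size = 100, n_classes = 3, tiles = 1) {
  x0 <- runif(n, 0, size - 12); y0 <- runif(n, 0, size - 12)
  detection_tbl(
    class_id = sample(0:(n_classes - 1), n, replace = TRUE),
    x0 = x0, y0 = y0,
    x1 = x0 + runif(n, 2, 12), y1 = y0 + runif(n, 2, 12),
    confidence = runif(n)
  ) |> dplyr::mutate(tile = sample(seq_len(tiles), n, replace = TRUE))
}

rand_anns <- function(n, size = 100, n_classes = 3, tiles = 1) {
  x0 <- runif(n, 0, size - 12); y0 <- runif(n, 0, size - 12)
  annotation_tbl(
    class_id = sample(0:(n_classes - 1), n, replace = TRUE),
    x0 = x0, y0 = y0,
    x1 = x0 + runif(n, 2, 12), y1 = y0 + runif(n, 2, 12)
  ) |> dplyr::mutate(tile = sample(seq_len(tiles), n, replace = TRUE))
}
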