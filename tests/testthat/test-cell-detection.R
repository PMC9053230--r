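box <- function(x0, y0, x1, y1) data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1)

test_that("box_iou satisfies the defining identities", {
  expect_equal(box_iou(box(0, 0, 2, 2), box(0, 0, 2, 2)), 1)
  expect_equal(box_iou(box(0, 0, 2, 2), box(5, 5, 7, 7)), 0)
  expect_equal(box_iou(box(0, 0, 2, 2), box(1, 0, 3, 2)), 1 / 3)
  expect_error(box_iou(box(0, 0, 0, 2), box(0, 0, 2, 2)), "degenerate")
  # symmetry, bounds, translation invariance on random pairs
  withr::with_seed(5, {
    for (i in 1:100) {
      a <- box(runif(1, 0, 50), runif(1, 0, 50), 0, 0)
      a$x1 <- a$x0 + runif(1, 1, 20); a$y1 <- a$y0 + runif(1, 1, 20)
      b <- box(runif(1, 0, 50), runif(1, 0, 50), 0, 0)
      b$x1 <- b$x0 + runif(1, 1, 20); b$y1 <- b$y0 + runif(1, 1, 20)
      v <- box_iou(a, b)
      expect_equal(v, box_iou(b, a))
      expect_true(v >= 0 && v <= 1)
      shift <- function(z, dx, dy) {
        z$x0 <- z$x0 + dx; z$x1 <- z$x1 + dx
        z$y0 <- z$y0 + dy; z$y1 <- z$y1 + dy
        z
      }
      expect_equal(box_iou(shift(a, 7, -3), shift(b, 7, -3)), v,
                   tolerance = 1e-12)
    }
  })
})

test_that("match_detections implements greedy one-to-one VOC matching", {
  ann <- annotation_tbl(class_id = 0L, x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  det1 <- detection_tbl(class_id = 0L, x0 = 1, y0 = 0, x1 = 11, y1 = 10,
                        confidence = 0.9)
  m <- match_detections(det1, ann)
  expect_equal(c(m$n_tp, m$n_fp, m$n_fn), c(1, 0, 0))
  # two detections on one annotation: higher confidence wins, other is FP
  det2 <- detection_tbl(class_id = c(0L, 0L), x0 = c(1, 0), y0 = 0,
                        x1 = c(11, 10), y1 = 10, confidence = c(0.8, 0.95))
  m2 <- match_detections(det2, ann)
  expect_equal(c(m2$n_tp, m2$n_fp, m2$n_fn), c(1, 1, 0))
  expect_equal(m2$tp$det_idx, 2L) # the 0.95 one
  # class-aware: wrong class never matches
  det3 <- detection_tbl(class_id = 5L, x0 = 0, y0 = 0, x1 = 10, y1 = 10,
                        confidence = 0.9)
  m3 <- match_detections(det3, ann)
  expect_equal(c(m3$n_tp, m3$n_fp, m3$n_fn), c(0, 1, 1))
  m4 <- match_detections(det3, ann, class_aware = FALSE)
  expect_equal(c(m4$n_tp, m4$n_fp, m4$n_fn), c(1, 0, 0))
  # confidence filter
  m5 <- match_detections(det1, ann, conf_thr = 0.95)
  expect_equal(c(m5$n_tp, m5$n_fp, m5$n_fn), c(0, 0, 1))
})

test_that("match_detections agrees with the brute-force matcher on random sets", {
  withr::with_seed(12, {
    for (i in 1:120) {
      dets <- rand_dets(sample(0:15, 1))
      anns <- rand_anns(sample(0:15, 1))
      got <- match_detections(dets, anns, iou_thr = 0.3, conf_thr = 0.4)
      want <- oracle_match(dets, anns, iou_thr = 0.3, conf_thr = 0.4)
      expect_equal(got$n_tp, want$n_tp)
      expect_equal(got$n_fp, want$n_fp)
      expect_equal(got$n_fn, want$n_fn)
      # counts conserve
      expect_equal(got$n_tp + got$n_fn, nrow(anns))
      expect_equal(got$n_tp + got$n_fp, sum(dets$confidence >= 0.4))
    }
  })
})

test_that("lowering the confidence threshold never shrinks the retained set", {
  withr::with_seed(13, {
    dets <- rand_dets(30)
    anns <- rand_anns(20)
    kept <- vapply(seq(0.9, 0.1, by = -0.2), function(ct) {
      m <- match_detections(dets, anns, conf_thr = ct)
      m$n_tp + m$n_fp
    }, numeric(1))
    expect_true(all(diff(kept) >= 0))
  })
})

test_that("YOLO text I/O round-trips and validates input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.txt")
  writeLines("4 0.5 0.5 0.25 0.25", f)
  a <- read_yolo(f, 512, 512)
  expect_equal(unlist(a[1, c("x0", "y0", "x1", "y1")]),
               c(x0 = 192, y0 = 192, x1 = 320, y1 = 320))
  expect_equal(bm_class_name(a$class_id), "blast")
  # round trip of a random set
  withr::with_seed(3, {
    anns <- rand_anns(25, size = 512)[, c("class_id", "x0", "y0", "x1", "y1")]
    write_yolo(anns, f, 512, 512)
    back <- read_yolo(f, 512, 512)
    expect_equal(as.data.frame(back), as.data.frame(anns), tolerance = 1e-5)
  })
  # empty file
  writeLines(character(0), f)
  expect_equal(nrow(read_yolo(f, 512, 512)), 0)
  # malformed inputs carry the line number
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.5 0.5"), f)
  expect_error(read_yolo(f, 512, 512), "line 2")
  writeLines("25 0.5 0.5 0.1 0.1", f)
  expect_error(read_yolo(f, 512, 512), "class_id")
  writeLines("3 1.5 0.5 0.1 0.1", f)
  expect_error(read_yolo(f, 512, 512), "outside")
})

test_that("nms keeps the highest-confidence box per overlapping cluster", {
  d <- detection_tbl(class_id = c(0L, 0L, 0L), x0 = c(0, 1, 50), y0 = c(0, 0, 50),
                     x1 = c(10, 11, 60), y1 = c(10, 10, 60),
                     confidence = c(0.8, 0.9, 0.5))
  kept <- nms(d, iou_thr = 0.5)
  expect_equal(nrow(kept), 2)
  expect_true(0.9 %in% kept$confidence && 0.5 %in% kept$confidence)
  # disjoint boxes all survive
  expect_equal(nrow(nms(d[c(1, 3), ], 0.5)), 2)
  # suppression is class-local
  d2 <- d; d2$class_id <- c(0L, 1L, 0L)
  expect_equal(nrow(nms(d2, 0.5)), 3)
  # agreement with an O(n^2) oracle on random sets
  withr::with_seed(8, {
    for (i in 1:40) {
      dets <- rand_dets(sample(2:20, 1), size = 40)
      got <- nms(dets, 0.4)
      keep <- logical(nrow(dets))
      for (cl in unique(dets$class_id)) {
        idx <- which(dets$class_id == cl)
        for (d_i in idx[order(-dets$confidence[idx])]) {
          ok <- TRUE
          for (k in idx[keep[idx]]) {
            v <- oracle_iou_pair(
              c(dets$x0[d_i], dets$y0[d_i], dets$x1[d_i], dets$y1[d_i]),
              c(dets$x0[k], dets$y0[k], dets$x1[k], dets$y1[k])
            )
            if (v > 0.4) { ok <- FALSE; break }
          }
          if (ok) keep[d_i] <- TRUE
        }
      }
      expect_equal(got, dets[keep, , drop = FALSE])
    }
  })
})

test_that("the blob detector finds nothing on a blank tile", {
  blank <- array(rep(marrowhct:::tile_background_rgb(), each = 64 * 64),
                 dim = c(64, 64, 3))
  expect_equal(nrow(detect_cells(blank)), 0)
})

test_that("the blob detector localises and classifies a single rendered cell", {
  p <- diagnostic_profile("normal")
  one <- new_diagnostic_profile("one_neutrophil", {
    m <- p$mixture * 0; m[["neutrophil"]] <- 1; m
  }, cells_per_roi_tile_mean = 1)
  found <- 0; good_iou <- 0; good_class <- 0; tries <- 0
  for (s in 1:12) {
    tl <- render_tile(one, TRUE, seed = 100 + s)
    if (nrow(tl$annotations) != 1) next
    tries <- tries + 1
    d <- detect_cells(tl$image)
    if (nrow(d) == 1) {
      found <- found + 1
      if (box_iou(d, tl$annotations) >= 0.7) good_iou <- good_iou + 1
      if (d$class_id == bm_class_id("neutrophil")) good_class <- good_class + 1
    }
  }
  expect_gte(tries, 3)
  expect_equal(found, tries)
  expect_equal(good_iou, tries)
  expect_equal(good_class, tries)
})

test_that("per-tile detector recall on appropriate tiles is at least 0.9", {
  p <- diagnostic_profile("normal")
  recalls <- vapply(1:8, function(s) {
    tl <- render_tile(p, TRUE, seed = 300 + s)
    if (nrow(tl$annotations) == 0) return(NA_real_)
    m <- match_detections(detect_cells(tl$image), tl$annotations)
    m$n_tp / nrow(tl$annotations)
  }, numeric(1))
  expect_gte(mean(recalls, na.rm = TRUE), 0.9)
})
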