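test_that("pr_curve reproduces hand-computable rankings", {
  ann <- rand_anns(1) |> dplyr::mutate(class_id = 0L)
  # one GT, one perfect detection
  det <- detection_tbl(class_id = 0L, x0 = ann$x0, y0 = ann$y0,
                       x1 = ann$x1, y1 = ann$y1, confidence = 0.9) |>
    dplyr::mutate(tile = ann$tile)
  pc <- pr_curve(det, ann, 0L)
  expect_equal(pc$precision, 1)
  expect_equal(pc$recall, 1)
  # ranked [TP, FP]
  det2 <- dplyr::bind_rows(det, dplyr::mutate(det, x0 = x0 + 500, x1 = x1 + 500,
                                              confidence = 0.5))
  pc2 <- pr_curve(det2, ann, 0L)
  expect_equal(pc2$precision, c(1, 0.5))
  expect_equal(pc2$recall, c(1, 1))
  expect_error(pr_curve(det, ann, 7L), "absent")
})

test_that("pr_curve recall is nondecreasing and matches the per-rank recount oracle", {
  withr::with_seed(21, {
    for (i in 1:30) {
      dets <- rand_dets(sample(3:15, 1), tiles = 3)
      anns <- rand_anns(sample(3:15, 1), tiles = 3)
      cid <- 0L
      if (!cid %in% anns$class_id) next
      pc <- pr_curve(dets, anns, cid, iou_thr = 0.3)
      expect_true(all(diff(pc$recall) >= -1e-12))
      got <- ap_11point(pc)$ap
      want <- oracle_ap(dets, anns, cid, iou_thr = 0.3)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("11-point AP handles the canonical cases", {
  ann2 <- annotation_tbl(class_id = c(0L, 0L), x0 = c(0, 100), y0 = 0,
                         x1 = c(10, 110), y1 = 10)
  # one perfect detection of a single GT
  d1 <- detection_tbl(class_id = 0L, x0 = 0, y0 = 0, x1 = 10, y1 = 10,
                      confidence = 0.9)
  expect_equal(ap_11point(pr_curve(d1, ann2[1, ], 0L))$ap, 1)
  # 2 GT, one TP and nothing else: P_interp = 1 for r <= 0.5, 0 beyond
  expect_equal(ap_11point(pr_curve(d1, ann2, 0L))$ap, 6 / 11)
  # all detections FP
  dfp <- detection_tbl(class_id = 0L, x0 = 50, y0 = 50, x1 = 60, y1 = 60,
                       confidence = 0.9)
  expect_equal(ap_11point(pr_curve(dfp, ann2, 0L))$ap, 0)
})

test_that("appending a lowest-rank FP never increases AP", {
  withr::with_seed(22, {
    for (i in 1:20) {
      dets <- rand_dets(sample(2:10, 1))
      anns <- rand_anns(sample(2:10, 1))
      if (!0L %in% anns$class_id) next
      base <- ap_11point(pr_curve(dets, anns, 0L, iou_thr = 0.3))$ap
      worse <- dplyr::bind_rows(
        dets,
        detection_tbl(class_id = 0L, x0 = 90, y0 = 90, x1 = 99, y1 = 99,
                      confidence = min(dets$confidence) / 2) |>
          dplyr::mutate(tile = 1L)
      )
      expect_lte(ap_11point(pr_curve(worse, anns, 0L, iou_thr = 0.3))$ap,
                 base + 1e-12)
    }
  })
})

test_that("mean_ap is a plain average with permutation invariance", {
  expect_equal(mean_ap(rep(0.4, 7)), 0.4)
  withr::with_seed(2, {
    aps <- runif(16)
    expect_equal(mean_ap(aps), mean_ap(sample(aps)))
    expect_equal(mean_ap(aps), mean(aps))
  })
})

test_that("f1_score is the harmonic mean", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_error(f1_score(0, 0))
})

test_that("lamr reduces to the constant on flat curves and 1 with no detections", {
  for (a in c(0.05, 0.2, 0.5, 0.9)) {
    flat <- structure(
      tibble::tibble(confidence = c(0.9, 0.5, 0.1),
                     fppi = c(0.005, 0.1, 1), miss_rate = a),
      n_images = 10, class_id = 0L,
      class = c("fppi_curve", class(tibble::tibble()))
    )
    expect_equal(lamr(flat), a, tolerance = 1e-12)
  }
  empty <- structure(
    tibble::tibble(confidence = numeric(), fppi = numeric(),
                   miss_rate = numeric()),
    n_images = 10, class_id = 0L,
    class = c("fppi_curve", class(tibble::tibble()))
  )
  expect_equal(lamr(empty), 1)
})

test_that("fppi_curve + lamr agree with the direct-formula oracle on random sweeps", {
  withr::with_seed(23, {
    for (i in 1:30) {
      dets <- rand_dets(sample(5:25, 1), tiles = 4)
      anns <- rand_anns(sample(5:25, 1), tiles = 4)
      if (!0L %in% anns$class_id) next
      fc <- fppi_curve(dets, anns, 0L, iou_thr = 0.3)
      expect_equal(lamr(fc), oracle_lamr(fc$fppi, fc$miss_rate),
                   tolerance = 1e-12)
      # miss rate falls (weakly) as the threshold drops down the ranking
      expect_true(all(diff(fc$miss_rate) <= 1e-12))
    }
  })
})

test_that("the confusion matrix is row-stochastic in percent and exact for a perfect detector", {
  anns <- rand_anns(40, n_classes = 4, tiles = 2)
  perfect <- detection_tbl(class_id = anns$class_id, x0 = anns$x0, y0 = anns$y0,
                           x1 = anns$x1, y1 = anns$y1,
                           confidence = 0.99) |>
    dplyr::mutate(tile = anns$tile)
  cm <- confusion_matrix_pct(perfect, anns, class_ids = 0:3)
  expect_equal(unname(diag(cm)), rep(100, 4))
  expect_equal(unname(rowSums(cm)), rep(100, 4))
  # tally oracle on a corrupted copy
  withr::with_seed(9, {
    noisy <- perfect
    flip <- runif(nrow(noisy)) < 0.3
    noisy$class_id[flip] <- (noisy$class_id[flip] + 1L) %% 4L
    cm2 <- confusion_matrix_pct(noisy, anns, class_ids = 0:3)
    tall <- table(factor(anns$class_id, 0:3), factor(noisy$class_id, 0:3))
    want <- 100 * sweep(unclass(tall), 1, rowSums(tall), "/")
    expect_equal(unname(cm2), unname(want))
  })
})

test_that("Cohen's kappa matches hand computations and its bounds", {
  x <- c("a", "b", "a", "b", "a")
  expect_equal(cohens_kappa(x, x), 1)
  # one rater constant
  expect_equal(cohens_kappa(rep("a", 10), rep(c("a", "b"), 5)), 0)
  # 2x2 case with p_o = 0.8, p_e = 0.5 -> 0.6
  a <- rep(c("x", "y"), each = 10)
  b <- c(rep("x", 8), rep("y", 2), rep("y", 8), rep("x", 2))
  expect_equal(cohens_kappa(a, b), 0.6)
  withr::with_seed(4, {
    for (i in 1:30) {
      u <- sample(letters[1:4], 30, replace = TRUE)
      v <- sample(letters[1:4], 30, replace = TRUE)
      k <- cohens_kappa(u, v)
      expect_equal(k, oracle_kappa(u, v), tolerance = 1e-12)
      expect_true(k >= -1 - 1e-12 && k <= 1 + 1e-12)
    }
  })
})

test_that("evaluate_detections assembles a coherent per-class summary", {
  withr::with_seed(17, {
    anns <- rand_anns(120, n_classes = 3, tiles = 6)
    # corrupt 20% of classes, drop 10% of objects, add a few FPs
    dets <- detection_tbl(class_id = anns$class_id, x0 = anns$x0, y0 = anns$y0,
                          x1 = anns$x1, y1 = anns$y1,
                          confidence = runif(nrow(anns), 0.8, 1)) |>
      dplyr::mutate(tile = anns$tile)
    flip <- runif(nrow(dets)) < 0.2
    dets$class_id[flip] <- (dets$class_id[flip] + 1L) %% 3L
    dets <- dets[runif(nrow(dets)) > 0.1, ]
    ev <- evaluate_detections(dets, anns, class_ids = 0:2)
    expect_equal(nrow(ev$per_class), 3)
    expect_equal(ev$map, mean(ev$per_class$ap))
    expect_true(all(ev$per_class$ap >= 0 & ev$per_class$ap <= 1))
    expect_equal(tidy(ev), ev$per_class)
    expect_equal(glance(ev)$map, ev$map)
    # CSV mirror has the Average row
    f <- withr::local_tempfile(fileext = ".csv")
    write_eval_csv(ev, f)
    out <- utils::read.csv(f)
    expect_equal(names(out), c("class", "precision", "recall", "f1", "lamr", "ap"))
    expect_equal(out$class[nrow(out)], "Average")
    expect_equal(out$ap[nrow(out)], round(ev$map, 2))
  })
})
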