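test_that("hct_from_detections counts per class above the confidence cut", {
  expect_equal(sum(hct_from_detections(detection_tbl())), 0)
  d <- detection_tbl(
    class_id = c(4L, 4L, 4L, 5L, 5L, 0L),
    x0 = 0, y0 = 0, x1 = 10, y1 = 10,
    confidence = c(0.9, 0.8, 0.76, 0.9, 0.8, 0.5)
  )
  h <- hct_from_detections(d)
  expect_equal(unname(h[["blast"]]), 3)
  expect_equal(unname(h[["erythroblast"]]), 2)
  expect_equal(unname(h[["neutrophil"]]), 0) # below 0.75
  expect_equal(sum(hct_from_detections(d, conf_thr = 1.01)), 0)
  # monotone data processing: raising the cut never raises any count
  for (ct in c(0, 0.5, 0.77, 0.85, 0.95)) {
    expect_true(all(hct_from_detections(d, ct) >= hct_from_detections(d, ct + 0.05)))
  }
})

test_that("chi-square distance follows its definition", {
  expect_equal(chi_square_distance(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(chi_square_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(chi_square_distance(c(0, 0), c(0, 0)), 0) # 0/0 terms drop
  expect_error(chi_square_distance(c(-1, 0), c(0, 1)), "nonnegative")
  withr::with_seed(6, {
    for (i in 1:60) {
      n <- sample(2:20, 1)
      x <- runif(n, 0, 5) * rbinom(n, 1, 0.8)
      y <- runif(n, 0, 5) * rbinom(n, 1, 0.8)
      expect_equal(chi_square_distance(x, y), oracle_chisq(x, y),
                   tolerance = 1e-12)
      expect_equal(chi_square_distance(x, y), chi_square_distance(y, x))
      expect_gte(chi_square_distance(x, y), 0)
    }
  })
})

test_that("the myeloid-to-erythroid ratio uses the six-class numerator", {
  counts <- rep(0, 19)
  names(counts) <- bm_cell_classes()$name
  counts[c("blast", "promyelocyte", "myelocyte", "metamyelocyte",
           "neutrophil", "eosinophil")] <- c(10, 2, 8, 4, 30, 2)
  counts[["erythroblast"]] <- 28
  expect_equal(bm_me_ratio(counts), 2)
  only_ery <- rep(0, 19); names(only_ery) <- names(counts)
  only_ery[["erythroblast"]] <- 5
  expect_equal(bm_me_ratio(only_ery), 0)
  counts[["erythroblast"]] <- 0
  expect_true(is.na(bm_me_ratio(counts)))
})

test_that("the convergence feature vector is proportions plus squashed BM_ME", {
  counts <- setNames(rep(0, 19), bm_cell_classes()$name)
  counts[c("neutrophil", "erythroblast", "blast", "debris", "platelet")] <-
    c(30, 20, 10, 100, 50) # non-NDC classes must not affect proportions
  fv <- ndc_feature_vector(counts)
  expect_equal(sum(fv[setdiff(names(fv), "bm_me")]), 1, tolerance = 1e-12)
  expect_equal(unname(fv[["neutrophil"]]), 0.5)
  r <- bm_me_ratio(counts)
  expect_equal(unname(fv[["bm_me"]]), r / (1 + r))
  # undefined ratio: component omitted, distance still works
  counts2 <- counts; counts2[["erythroblast"]] <- 0
  fv2 <- ndc_feature_vector(counts2)
  expect_false("bm_me" %in% names(fv2))
  expect_true(is.finite(feature_distance(fv, fv2)))
  fv3 <- ndc_feature_vector(counts, include_bm_me = FALSE)
  expect_false("bm_me" %in% names(fv3))
})

test_that("the convergence rule needs both the tile floor and a quiet run", {
  expect_true(check_convergence(rep(0, 100)))
  expect_false(check_convergence(rep(0, 79))) # below the 80-tile floor
  expect_false(check_convergence(c(rep(0, 99), 1))) # last step loud
  expect_false(check_convergence(c(rep(1, 96), rep(0, 4)))) # run too short
  expect_true(check_convergence(c(rep(1, 95), rep(0, 5))))
  trace <- c(rep(1, 90), rep(0, 30))
  expect_equal(tiles_to_convergence(trace), 95L)
  expect_true(is.na(tiles_to_convergence(rep(1, 200))))
})

test_that("IHCT accumulation conserves counts exactly", {
  p <- diagnostic_profile("mds_like")
  st <- simulate_hct_stream(p, 120, seed = 2)
  ih <- accumulate_hcts(st)
  expect_equal(unname(ih$counts), unname(colSums(st)))
  expect_equal(ih$n_cells, sum(st))
  expect_equal(ih$n_tiles, 120)
  expect_true(is.na(ih$distance_trace[1]))
  expect_true(all(ih$distance_trace[-1] >= 0))
})

test_that("stationary streams converge and the trace falls below tau", {
  p <- diagnostic_profile("normal")
  ih <- accumulate_hcts(simulate_hct_stream(p, 500, seed = 5))
  expect_true(ih$converged)
  expect_gte(ih$converged_at, 80)
  tail_dist <- ih$distance_trace[(ih$converged_at - 4):ih$converged_at]
  expect_true(all(tail_dist < 1e-5))
})

test_that("median tiles-to-convergence is non-increasing in tau", {
  p <- diagnostic_profile("normal")
  streams <- lapply(1:8, function(s) simulate_hct_stream(p, 600, seed = 40 + s))
  med <- vapply(c(3e-6, 1e-5, 3e-5, 1e-4), function(tau) {
    conv <- vapply(streams, function(st) {
      v <- tiles_to_convergence(accumulate_hcts(st, tau = tau)$distance_trace,
                                tau = tau)
      if (is.na(v)) 600 else as.numeric(v)
    }, numeric(1))
    median(conv)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("run_ndc is deterministic and honours degenerate settings", {
  p0 <- diagnostic_profile("normal")
  p <- new_diagnostic_profile("all_roi", p0$mixture, 10, roi_fraction = 1)
  slide <- render_slide(p, grid_spec(3, 4), seed = 31)
  r1 <- run_ndc(slide, max_tiles = 6, min_tiles = 4, patience = 2, tau = 1e-4)
  r2 <- run_ndc(slide, max_tiles = 6, min_tiles = 4, patience = 2, tau = 1e-4)
  expect_equal(glance(r1), glance(r2))
  expect_equal(r1$counts, r2$counts)
  # max_tiles below min_tiles warns and cannot converge
  expect_warning(r3 <- run_ndc(slide, max_tiles = 2, min_tiles = 80),
                 "cannot converge")
  expect_false(r3$converged)
  expect_equal(r3$n_tiles, 2)
  # a detector that returns nothing yields a non-converged zero-cell report
  r4 <- suppressWarnings(run_ndc(slide, detector_backend = function(img) detection_tbl(),
                                 max_tiles = 3, min_tiles = 80))
  expect_false(r4$converged)
  expect_equal(r4$n_cells, 0)
  # a slide with no appropriate tile errors
  expect_error(
    run_ndc(slide, roi_backend = function(img) 0),
    "no appropriate ROI tile"
  )
})

test_that("ndc reports serialise to JSON/CSV and expose tidy/glance", {
  p0 <- diagnostic_profile("normal")
  p <- new_diagnostic_profile("all_roi", p0$mixture, 10, roi_fraction = 1)
  slide <- render_slide(p, grid_spec(2, 3), seed = 8)
  rep <- suppressWarnings(run_ndc(slide, max_tiles = 4, min_tiles = 90))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(sum(tidy(rep)$count), rep$n_cells)
  g <- glance(rep)
  expect_equal(g$n_tiles, 4)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "report.json")
  write_ndc_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$n_cells, rep$n_cells)
  expect_true(file.exists(file.path(dir, "report_counts.csv")))
  expect_true(file.exists(file.path(dir, "report_trace.csv")))
})
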