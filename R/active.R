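#' Active-learning configuration
#'
#' @param batch_tiles Tiles selected per iteration (default 250).
#' @param rare_class_quantile Classes whose cumulative annotated count falls
#'   below this quantile of all class counts are treated as rare
#'   (default 0.25).
#' @param cost_full Cost of annotating one object from scratch (default 1).
#' @param cost_review Cost of reviewing/correcting one model-predicted
#'   object (default 0.25).
#' @return An `al_config` list.
#' @export
al_config <- function(batch_tiles = 250L, rare_class_quantile = 0.25,
                      cost_full = 1, cost_review = 0.25) {
  stopifnot(batch_tiles >= 1, rare_class_quantile > 0, rare_class_quantile < 1,
            cost_full >= 0, cost_review >= 0)
  structure(list(batch_tiles = as.integer(batch_tiles),
                 rare_class_quantile = rare_class_quantile,
                 cost_full = cost_full, cost_review = cost_review),
            class = "al_config")
}

#' Simulate a feature-level object pool
#'
#' Draws tiles of objects with class-dependent features (mean RGB fill and
#' scaled equivalent radius, i.e. the same feature space the reference blob
#' detector uses) plus isotropic Gaussian noise — the representation on
#' which a trainable classification backend can genuinely improve with more
#' labelled data. Boxes are synthesised at random non-degenerate positions;
#' localisation is taken as solved so that the loop isolates the
#' classification problem the annotation effort actually addresses.
#'
#' @param profile A [diagnostic_profile()].
#' @param n_tiles Number of tiles.
#' @param seed Integer seed.
#' @param feature_noise Feature noise standard deviation: a single value, or
#'   one value per class (length 19) to model class-dependent morphological
#'   heterogeneity — in real aspirates the rare object types (megakaryocyte
#'   nuclei, histiocytes) are also the cytologically most variable ones.
#'   Default 0.10.
#' @param tile_size Tile side in pixels (default 512).
#' @return A tibble: `tile`, `class_id` (ground truth), `x0`, `y0`, `x1`,
#'   `y1`, features `f_r`, `f_g`, `f_b`, `f_rad`.
#' @export
simulate_object_pool <- function(profile, n_tiles, seed = 1L,
                                 feature_noise = 0.10, tile_size = 512L) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  cls <- bm_cell_classes()
  centroids <- cbind(cls$fill_r, cls$fill_g, cls$fill_b) / 255
  centroids <- cbind(centroids, cls$mean_radius_px / 30)
  with_seed(seed, {
    n_per_tile <- rpois(n_tiles, profile$cells_per_roi_tile_mean)
    total <- sum(n_per_tile)
    if (total == 0) {
      return(dplyr::mutate(annotation_tbl(), tile = integer(),
                           f_r = numeric(), f_g = numeric(),
                           f_b = numeric(), f_rad = numeric()))
    }
    stopifnot(length(feature_noise) %in% c(1L, nrow(cls)))
    noise_of <- rep_len(feature_noise, nrow(cls))
    class_id <- sample(cls$class_id, total, replace = TRUE, prob = profile$mixture)
    feats <- centroids[class_id + 1L, , drop = FALSE] +
      matrix(rnorm(total * 4, 0, rep(noise_of[class_id + 1L], 4)), ncol = 4)
    r <- pmax(3, cls$mean_radius_px[class_id + 1L])
    cx <- runif(total, r + 1, tile_size - r - 1)
    cy <- runif(total, r + 1, tile_size - r - 1)
    tibble::tibble(
      tile = rep(seq_len(n_tiles), n_per_tile),
      class_id = as.integer(class_id),
      x0 = cx - r, y0 = cy - r, x1 = cx + r, y1 = cy + r,
      f_r = feats[, 1], f_g = feats[, 2], f_b = feats[, 3], f_rad = feats[, 4]
    )
  })
}

#' Canonical profiles for active-learning experiments
#'
#' `al_pool_profile()` is the unlabeled-reservoir mixture: a marrow-like
#' class distribution with a severely imbalanced tail — several evaluated
#' classes (megakaryocyte nucleus, megakaryocyte, histiocyte, plasma cell,
#' eosinophil) at frequencies of 0.1-0.4%, as in real aspirates where such
#' objects are orders of magnitude rarer than erythroblasts or debris.
#' Their examples therefore stay scarce for many 250-tile batches, which is
#' exactly the regime rare-class-targeted selection addresses.
#' `al_benchmark_profile()` is the frozen evaluation mixture: near-balanced
#' over the 16 evaluated classes so every per-class AP is estimated with
#' similar support (a stratified test set, standard practice when the
#' training distribution is long-tailed).
#'
#' @return A [diagnostic_profile()].
#' @export
al_pool_profile <- function() {
  mix <- diagnostic_profile("normal")$mixture
  # staggered rare tail: arrival rates of a few to a few dozen objects per
  # 250-tile batch keep these classes' example counts inside the regime
  # where the (heavily overlapping, see al_feature_noise) class boundaries
  # still respond to additional labels throughout a multi-batch run
  mix[["megakaryocyte nucleus"]] <- 0.0020
  mix[["megakaryocyte"]] <- 0.0030
  mix[["histiocyte"]] <- 0.0040
  mix[["plasma cell"]] <- 0.0050
  mix[["eosinophil"]] <- 0.0065
  mix[["promyelocyte"]] <- 0.0080
  mix[["monocyte"]] <- 0.0100
  mix[["platelet clump"]] <- 0.0130
  mix <- mix / sum(mix)
  new_diagnostic_profile("al_pool", mix, cells_per_roi_tile_mean = 10,
                         roi_fraction = 1)
}

#' @rdname al_pool_profile
#' @export
al_feature_noise <- function() {
  cls <- bm_cell_classes()
  noise <- setNames(rep(0.08, nrow(cls)), cls$name)
  noise[c("megakaryocyte nucleus", "megakaryocyte", "histiocyte",
          "plasma cell", "eosinophil", "promyelocyte", "monocyte",
          "platelet clump")] <- 0.30
  noise
}

#' @rdname al_pool_profile
#' @export
al_benchmark_profile <- function() {
  cls <- bm_cell_classes()
  mix <- setNames(rep(0, nrow(cls)), cls$name)
  mix[cls$evaluated] <- 1
  mix[!cls$evaluated] <- 0.05
  mix <- mix / sum(mix)
  new_diagnostic_profile("al_benchmark", mix, cells_per_roi_tile_mean = 10,
                         roi_fraction = 1)
}

#' Trainable nearest-centroid backend
#'
#' The reference trainable classifier for the active-learning loop: `fit()`
#' estimates one centroid per observed class from labelled object features;
#' `predict()` assigns each object to the nearest trained centroid with a
#' softmax-style confidence over squared feature distances. Classes never
#' seen in training cannot be predicted, which is precisely the weakness
#' rare-class-targeted selection addresses.
#'
#' @param conf_scale Bandwidth of the confidence softmax (default 0.15).
#' @return A list with elements `fit(objects)` (returns a model) and
#'   `predict(model, objects)` (returns a detection tibble with `tile`).
#' @export
centroid_backend <- function(conf_scale = 0.15) {
  feat_cols <- c("f_r", "f_g", "f_b", "f_rad")
  list(
    fit = function(objects) {
      stopifnot(nrow(objects) > 0)
      cents <- objects |>
        dplyr::group_by(.data$class_id) |>
        dplyr::summarise(dplyr::across(dplyr::all_of(feat_cols), mean),
                         .groups = "drop")
      list(classes = cents$class_id,
           centroids = as.matrix(cents[, feat_cols]))
    },
    predict = function(model, objects) {
      if (nrow(objects) == 0) {
        return(dplyr::mutate(detection_tbl(), tile = integer()))
      }
      feats <- as.matrix(objects[, feat_cols])
      d2 <- outer(rowSums(feats^2), rowSums(model$centroids^2), `+`) -
        2 * feats %*% t(model$centroids)
      d2[d2 < 0] <- 0
      w <- exp(-d2 / (2 * conf_scale^2))
      conf <- w / pmax(rowSums(w), 1e-300)
      best <- max.col(-d2, ties.method = "first")
      tibble::tibble(
        class_id = as.integer(model$classes[best]),
        x0 = objects$x0, y0 = objects$y0, x1 = objects$x1, y1 = objects$y1,
        confidence = conf[cbind(seq_along(best), best)],
        tile = objects$tile
      )
    }
  )
}

#' Rank and select pool tiles for annotation
#'
#' Tiles are ranked by their predicted content of rare classes — classes
#' whose cumulative annotated count lies strictly below the
#' `rare_class_quantile` quantile of all cumulative class counts. Ties are
#' broken by total predicted object count, then by tile id. When no class
#' is rare (perfectly balanced counts) the ranking falls back to total
#' predicted content.
#'
#' @param predictions Detection tibble over the unlabeled pool, with a
#'   `tile` column (model predictions).
#' @param cumulative_counts Named 19-vector of annotated objects per class
#'   so far.
#' @param config An [al_config()].
#' @param pool_tiles Vector of candidate tile ids (default: tiles appearing
#'   in `predictions`).
#' @param min_conf Only predictions with at least this class probability
#'   count towards a tile's content (default 0.75, the pipeline's
#'   class-probability convention). Low-confidence "rare-looking"
#'   predictions are mostly common-class outliers, and ranking on them
#'   floods the batches with contaminating boundary objects.
#' @return The selected tile ids (length `min(batch_tiles, pool size)`).
#' @export
select_tiles <- function(predictions, cumulative_counts, config = al_config(),
                         pool_tiles = NULL, min_conf = 0.75) {
  counts <- as_class_counts(cumulative_counts)
  if (is.null(pool_tiles)) pool_tiles <- sort(unique(predictions$tile))
  if (length(pool_tiles) < config$batch_tiles) {
    stop("pool (", length(pool_tiles), " tiles) smaller than the batch (",
         config$batch_tiles, ")", call. = FALSE)
  }
  thr <- quantile(counts, config$rare_class_quantile, names = FALSE)
  rare <- which(counts < thr) - 1L # class ids
  if ("confidence" %in% names(predictions)) {
    predictions <- predictions[predictions$confidence >= min_conf, , drop = FALSE]
  }
  scores <- predictions |>
    dplyr::group_by(tile = .data$tile) |>
    dplyr::summarise(rare_content = sum(.data$class_id %in% rare),
                     total = dplyr::n(), .groups = "drop")
  scores <- dplyr::left_join(tibble::tibble(tile = pool_tiles), scores,
                             by = "tile")
  scores$rare_content[is.na(scores$rare_content)] <- 0
  scores$total[is.na(scores$total)] <- 0
  ord <- order(-scores$rare_content, -scores$total, scores$tile)
  scores$tile[ord][seq_len(config$batch_tiles)]
}

#' Simulated expert review of model predictions
#'
#' The oracle reviewer replaces every wrong or missed label on the batch
#' with the ground truth; with `reviewer_error_rate > 0` a random fraction
#' of the corrected labels is flipped to a different class (seeded),
#' emulating imperfect review. Costs are accounted both ways: review mode
#' (`cost_review` per object) versus from-scratch annotation
#' (`cost_full` per object).
#'
#' @param truth Ground-truth object tibble for the batch tiles (class_id is
#'   the reference label).
#' @param reviewer_error_rate Fraction of labels corrupted by the reviewer
#'   (default 0).
#' @param seed Integer seed for the corruption draws.
#' @param config An [al_config()].
#' @return A list: `annotations` (corrected batch), `cost_review`,
#'   `cost_full`, `n_objects`.
#' @export
simulate_review <- function(truth, reviewer_error_rate = 0, seed = 1L,
                            config = al_config()) {
  stopifnot(reviewer_error_rate >= 0, reviewer_error_rate <= 1)
  out <- truth
  n <- nrow(out)
  if (reviewer_error_rate > 0 && n > 0) {
    out$class_id <- with_seed(seed, {
      flip <- runif(n) < reviewer_error_rate
      wrong <- vapply(out$class_id[flip], function(cid) {
        sample(setdiff(0:18, cid), 1)
      }, numeric(1))
      repl <- out$class_id
      repl[flip] <- as.integer(wrong)
      repl
    })
  }
  list(annotations = out,
       cost_review = config$cost_review * n,
       cost_full = config$cost_full * n,
       n_objects = n)
}

#' Run the active-learning annotation loop
#'
#' Simulates the iterative annotate-review-retrain cycle: a model is fitted
#' on a small fully annotated seed set; each iteration then (1) predicts on
#' the unlabeled pool, (2) selects a batch of tiles rich in rare classes
#' ([select_tiles()]), (3) passes the predictions through simulated expert
#' review ([simulate_review()]), (4) merges the corrected batch into the
#' training set, (5) refits, and (6) evaluates on a frozen held-out
#' benchmark, recording per-class annotated-object counts and AP. The run
#' is deterministic under a fixed seed; an exhausted pool stops the loop
#' early with the records so far.
#'
#' @param pool Object tibble from [simulate_object_pool()] (the unlabeled
#'   reservoir).
#' @param benchmark A list with `objects` (a pool-format tibble) used as the
#'   frozen evaluation set, or a pool-format tibble directly.
#' @param backend A trainable backend (default [centroid_backend()]).
#' @param iterations Number of active-learning iterations (default 8).
#' @param config An [al_config()].
#' @param seed Integer seed.
#' @param initial_tiles Size of the fully annotated seed set in tiles
#'   (default 50).
#' @param reviewer_error_rate Passed to [simulate_review()] (default 0).
#' @param class_ids Classes evaluated for mAP (default the 16 evaluated
#'   classes present in the benchmark).
#' @param selection One of `"rare_class"` (default) or `"random"` (ablation
#'   baseline: batches drawn uniformly at random).
#' @return An `al_run` object: `records` (long tibble: `iteration`,
#'   `class_id`, `name`, `count`, `ap`), `summary` (per-iteration tibble:
#'   `iteration`, `total_count`, `mean_ap`, `cost_review`, `cost_full`),
#'   and the settings. Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
run_active_learning <- function(pool, benchmark, backend = centroid_backend(),
                                iterations = 8L, config = al_config(),
                                seed = 1L, initial_tiles = 50L,
                                reviewer_error_rate = 0,
                                class_ids = evaluated_class_ids(),
                                selection = c("rare_class", "random")) {
  selection <- match.arg(selection)
  if (is.list(benchmark) && !is.data.frame(benchmark)) benchmark <- benchmark$objects
  bench_anns <- benchmark[, c("tile", "class_id", "x0", "y0", "x1", "y1")]
  pool_tiles <- sort(unique(pool$tile))
  init_ids <- with_seed(derive_seed(seed, 1),
                        sample(pool_tiles, min(initial_tiles, length(pool_tiles))))
  labeled <- pool[pool$tile %in% init_ids, , drop = FALSE]
  unlabeled_tiles <- setdiff(pool_tiles, init_ids)
  model <- backend$fit(labeled)
  records <- vector("list", iterations)
  summaries <- vector("list", iterations)
  cum_cost_review <- config$cost_full * nrow(labeled) # seed set is always manual
  cum_cost_full <- config$cost_full * nrow(labeled)
  for (iter in seq_len(iterations)) {
    if (length(unlabeled_tiles) < config$batch_tiles) break
    pool_rest <- pool[pool$tile %in% unlabeled_tiles, , drop = FALSE]
    preds <- backend$predict(model, pool_rest)
    counts <- tabulate(labeled$class_id + 1L, nbins = n_classes())
    batch_ids <- if (selection == "rare_class") {
      select_tiles(preds, setNames(counts, bm_cell_classes()$name), config,
                   pool_tiles = unlabeled_tiles)
    } else {
      with_seed(derive_seed(seed, 100 + iter),
                sample(unlabeled_tiles, config$batch_tiles))
    }
    review <- simulate_review(
      pool_rest[pool_rest$tile %in% batch_ids, , drop = FALSE],
      reviewer_error_rate, derive_seed(seed, 200 + iter), config
    )
    labeled <- dplyr::bind_rows(labeled, review$annotations)
    unlabeled_tiles <- setdiff(unlabeled_tiles, batch_ids)
    cum_cost_review <- cum_cost_review + review$cost_review
    cum_cost_full <- cum_cost_full + review$cost_full
    model <- backend$fit(labeled)
    bench_preds <- backend$predict(model, benchmark)
    eval_ids <- class_ids[class_ids %in% unique(bench_anns$class_id)]
    per_ap <- vapply(eval_ids, function(cid) {
      ap_11point(pr_curve(bench_preds, bench_anns, cid))$ap
    }, numeric(1))
    cum_counts <- tabulate(labeled$class_id + 1L, nbins = n_classes())
    records[[iter]] <- tibble::tibble(
      iteration = iter, class_id = eval_ids, name = bm_class_name(eval_ids),
      count = cum_counts[eval_ids + 1L], ap = per_ap
    )
    summaries[[iter]] <- tibble::tibble(
      iteration = iter, total_count = sum(cum_counts),
      mean_ap = mean(per_ap),
      cost_review = cum_cost_review, cost_full = cum_cost_full
    )
  }
  structure(
    list(records = dplyr::bind_rows(records),
         summary = dplyr::bind_rows(summaries),
         config = config, seed = seed, selection = selection,
         initial_tiles = initial_tiles),
    class = "al_run"
  )
}

#' @export
print.al_run <- function(x, ...) {
  cat("<al_run> ", nrow(x$summary), " iterations (", x$selection,
      " selection)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_active_learning
#' @param x,object An `al_run`.
#' @param ... Unused.
#' @export
tidy.al_run <- function(x, ...) x$records

#' @rdname run_active_learning
#' @export
glance.al_run <- function(x, ...) {
  last <- x$summary[nrow(x$summary), , drop = FALSE]
  tibble::tibble(iterations = nrow(x$summary),
                 final_mean_ap = last$mean_ap,
                 final_total_count = last$total_count,
                 cost_review = last$cost_review,
                 cost_full = last$cost_full)
}

#' @rdname run_active_learning
#' @export
autoplot.al_run <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$iteration, y = .data$mean_ap)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Iteration", y = "mean AP",
                  title = "Active-learning mAP trajectory") +
    ggplot2::theme_minimal()
}

#' Write active-learning records to CSV
#'
#' One row per (iteration, class) with cumulative count and AP, mirroring
#' the conventional iteration bookkeeping table.
#'
#' @param run An `al_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_al_records_csv <- function(run, path) {
  utils::write.csv(run$records, path, row.names = FALSE)
  invisible(path)
}
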