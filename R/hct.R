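#' Histogram of cell types from detections
#'
#' Counts detections with confidence at or above `conf_thr` per class,
#' yielding the per-tile Histogram of Cell Types (HCT).
#'
#' @param dets Detection tibble.
#' @param conf_thr Class-probability cut (default 0.75).
#' @return A named integer vector of length 19 (names are class names).
#' @export
hct_from_detections <- function(dets, conf_thr = 0.75) {
  cls <- bm_cell_classes()
  kept <- dets[dets$confidence >= conf_thr, , drop = FALSE]
  counts <- tabulate(kept$class_id + 1L, nbins = nrow(cls))
  setNames(as.integer(counts), cls$name)
}

#' Chi-square histogram distance
#'
#' `0.5 * sum((x - y)^2 / (x + y))`, with any 0/0 term contributing 0.
#' Symmetric, nonnegative, and zero exactly when the vectors are equal.
#'
#' @param x,y Equal-length nonnegative numeric vectors.
#' @return A nonnegative number.
#' @examples
#' chi_square_distance(c(1, 0), c(0, 1)) # 1
#' @export
chi_square_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) {
    stop("chi_square_distance() requires nonnegative entries", call. = FALSE)
  }
  s <- x + y
  d <- (x - y)^2
  sum(ifelse(s > 0, d / s, 0)) / 2
}

#' Myeloid-to-erythroid ratio from class counts
#'
#' `(blast + promyelocyte + myelocyte + metamyelocyte + neutrophil +
#' eosinophil) / erythroblast`. When the erythroblast count is zero the
#' ratio is undefined and `NA` is returned (never infinity, never an error).
#'
#' @param counts Numeric vector of 19 per-class counts (class-id order or
#'   named by class).
#' @return A nonnegative number, or `NA` when undefined.
#' @export
bm_me_ratio <- function(counts) {
  counts <- as_class_counts(counts)
  num <- sum(counts[bm_me_numerator_ids() + 1L])
  den <- counts[erythroblast_id() + 1L]
  if (den == 0) return(NA_real_)
  num / den
}

as_class_counts <- function(counts) {
  cls <- bm_cell_classes()
  if (!is.null(names(counts)) && all(cls$name %in% names(counts))) {
    counts <- counts[cls$name]
  }
  stopifnot(length(counts) == nrow(cls), all(counts >= 0))
  unname(as.numeric(counts))
}

#' Convergence feature vector of an accumulated histogram
#'
#' The vector compared between successive accumulation steps: the 12 NDC
#' class counts normalised to proportions, plus (optionally) the `BM_ME`
#' ratio squashed to `[0, 1)` as `s = r / (1 + r)` so that one unbounded
#' ratio cannot dominate twelve proportions. When the ratio is undefined
#' (no erythroblasts) the component is omitted; [feature_distance()] then
#' drops it from both vectors.
#'
#' @param counts 19 per-class counts.
#' @param include_bm_me Append the squashed ratio component (default `TRUE`).
#' @return A named numeric vector (12 proportions, optionally + `bm_me`).
#'   All-zero NDC counts yield zero proportions.
#' @export
ndc_feature_vector <- function(counts, include_bm_me = TRUE) {
  counts <- as_class_counts(counts)
  ids <- ndc_class_ids()
  ndc <- counts[ids + 1L]
  tot <- sum(ndc)
  props <- if (tot > 0) ndc / tot else rep(0, length(ndc))
  names(props) <- bm_class_name(ids)
  if (include_bm_me) {
    r <- bm_me_ratio(counts)
    if (!is.na(r)) props <- c(props, bm_me = r / (1 + r))
  }
  props
}

#' Chi-square distance between two convergence feature vectors
#'
#' Components present in only one vector (an undefined `BM_ME`) are omitted
#' from both before the distance is taken.
#'
#' @param a,b Feature vectors from [ndc_feature_vector()].
#' @return Nonnegative chi-square distance.
#' @export
feature_distance <- function(a, b) {
  common <- intersect(names(a), names(b))
  chi_square_distance(a[common], b[common])
}

#' Convergence rule for an accumulation trace
#'
#' The integrated histogram is converged when at least `min_tiles` tiles
#' have been accumulated and the last `patience` successive chi-square
#' distances are all below `tau`.
#'
#' @param trace Numeric vector of successive distances (entry `t` compares
#'   the accumulated histogram after tile `t` with that after `t - 1`; the
#'   first entry may be `NA`).
#' @param min_tiles Minimum tiles before convergence may trigger
#'   (default 80).
#' @param tau Distance threshold (default `1e-5`).
#' @param patience Number of consecutive sub-threshold distances required
#'   (default 5).
#' @return `TRUE` or `FALSE`.
#' @export
check_convergence <- function(trace, min_tiles = 80L, tau = 1e-5, patience = 5L) {
  stopifnot(tau > 0, patience >= 1)
  n <- length(trace)
  if (n < min_tiles || n < patience) return(FALSE)
  last <- trace[(n - patience + 1):n]
  all(!is.na(last) & last < tau)
}

#' First tile at which a distance trace converges
#'
#' @inheritParams check_convergence
#' @return The smallest `t` with `check_convergence(trace[1:t], ...)` true,
#'   or `NA` if the trace never converges.
#' @export
tiles_to_convergence <- function(trace, min_tiles = 80L, tau = 1e-5,
                                 patience = 5L) {
  ok <- !is.na(trace) & trace < tau
  run <- 0
  for (t in seq_along(trace)) {
    run <- if (ok[t]) run + 1 else 0
    if (t >= min_tiles && run >= patience) return(t)
  }
  NA_integer_
}

#' Accumulate per-tile histograms into an integrated histogram
#'
#' Sums per-tile HCTs into the Integrated Histogram of Cell Types (IHCT),
#' recording after every tile the chi-square distance between the current
#' and previous convergence feature vectors (proportions, not raw counts,
#' so the threshold is scale-free).
#'
#' @param hcts A matrix (tiles x 19) of per-tile class counts, or a list of
#'   19-vectors.
#' @inheritParams check_convergence
#' @param include_bm_me Include the squashed `BM_ME` component in the
#'   distance (default `TRUE`).
#' @return An `ihct` object: `counts` (named 19-vector), `n_tiles`,
#'   `n_cells`, `distance_trace` (length `n_tiles`, first entry `NA`),
#'   `converged`, `converged_at`.
#' @export
accumulate_hcts <- function(hcts, min_tiles = 80L, tau = 1e-5, patience = 5L,
                            include_bm_me = TRUE) {
  if (is.list(hcts)) hcts <- do.call(rbind, hcts)
  stopifnot(is.matrix(hcts), ncol(hcts) == n_classes())
  n_tiles <- nrow(hcts)
  counts <- rep(0, n_classes())
  trace <- rep(NA_real_, n_tiles)
  prev_fv <- NULL
  for (t in seq_len(n_tiles)) {
    counts <- counts + hcts[t, ]
    fv <- ndc_feature_vector(counts, include_bm_me)
    if (!is.null(prev_fv)) trace[t] <- feature_distance(fv, prev_fv)
    prev_fv <- fv
  }
  conv_at <- tiles_to_convergence(trace, min_tiles, tau, patience)
  structure(
    list(counts = setNames(counts, bm_cell_classes()$name),
         n_tiles = n_tiles, n_cells = sum(counts), distance_trace = trace,
         converged = !is.na(conv_at), converged_at = conv_at,
         tau = tau, min_tiles = min_tiles, patience = patience),
    class = "ihct"
  )
}

#' @export
print.ihct <- function(x, ...) {
  cat("<ihct> ", x$n_tiles, " tiles, ", x$n_cells, " objects, ",
      if (x$converged) paste0("converged at tile ", x$converged_at)
      else "not converged", "\n", sep = "")
  invisible(x)
}

#' Simulate a count-level HCT stream
#'
#' Draws per-tile class counts directly (Poisson tile totals, multinomial
#' classes) without rendering pixels — the statistical skeleton of a slide,
#' useful for convergence experiments. Optionally the mixture is
#' nonstationary, emulating regional heterogeneity across a slide (e.g.
#' erythroid islands versus blast-rich myeloid zones): with
#' `mode = "cycle"` it is interpolated linearly towards `mixture_end` and
#' back over `cycle_tiles` tiles; with `mode = "blocks"` it switches
#' between the two mixtures in solid blocks of `cycle_tiles / 2` tiles,
#' which keeps the deviation of the running mean from the current regime
#' near its maximum and so stresses the convergence rule hardest.
#'
#' @param profile A [diagnostic_profile()] (its mixture and per-tile mean
#'   are used).
#' @param n_tiles Number of tiles to draw.
#' @param seed Integer seed.
#' @param mixture_end Optional 19-vector: drift target mixture.
#' @param cycle_tiles Tiles per full drift cycle (default 200).
#' @param mode Drift shape: `"cycle"` (triangle wave) or `"blocks"`
#'   (square wave).
#' @return A `n_tiles x 19` integer matrix of counts.
#' @export
simulate_hct_stream <- function(profile, n_tiles, seed = 1L,
                                mixture_end = NULL, cycle_tiles = 200L,
                                mode = c("cycle", "blocks")) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  mode <- match.arg(mode)
  mix0 <- profile$mixture
  with_seed(seed, {
    out <- matrix(0L, n_tiles, n_classes())
    for (t in seq_len(n_tiles)) {
      mix <- if (is.null(mixture_end)) mix0 else {
        half <- cycle_tiles / 2
        phase <- (t - 1) %% cycle_tiles
        w <- if (mode == "blocks") as.numeric(phase >= half)
        else if (phase <= half) phase / half else 2 - phase / half
        (1 - w) * mix0 + w * mixture_end
      }
      n <- rpois(1, profile$cells_per_roi_tile_mean)
      if (n > 0) out[t, ] <- as.integer(rmultinom(1, n, mix))
    }
    colnames(out) <- bm_cell_classes()$name
    out
  })
}

#' Run the nucleated differential cell count on a slide
#'
#' The end-to-end loop: grid tiles are visited (row-major by default, or in
#' a seeded shuffled order), each is scored by the ROI backend, and every
#' appropriate tile is passed to the detector; its HCT is accumulated into
#' the IHCT and the chi-square distance between successive convergence
#' feature vectors is tracked. The loop stops at convergence or when the
#' grid is exhausted (exhaustion leaves `converged = FALSE` but still emits
#' a full report). A detector that never returns anything yields a
#' non-converged report with zero cells.
#'
#' @param slide A slide object ([render_slide()] output, or anything with
#'   [slide_dims()] / [read_region()] methods).
#' @param roi_backend `function(image) -> score in [0, 1]`
#'   (default [roi_reference_backend]).
#' @param detector_backend `function(image) -> detection tibble`
#'   (default [blob_detector_backend()]).
#' @param grid [grid_spec()]; defaults to the slide's own grid for synthetic
#'   slides.
#' @param roi_threshold ROI decision threshold (default 0.5).
#' @param conf_thr Detection class-probability cut (default 0.75).
#' @inheritParams check_convergence
#' @param include_bm_me Include the squashed `BM_ME` component in the
#'   convergence distance (default `TRUE`).
#' @param shuffle Visit tiles in a seeded random order instead of row-major.
#' @param order_seed Seed for the shuffle (default 1).
#' @param max_tiles Stop after accumulating this many ROI tiles (default
#'   unlimited; a value below `min_tiles` necessarily yields a non-converged
#'   report, with a warning).
#' @return An `ndc_report`: `counts` tibble (`class_id`, `name`, `count`,
#'   `pct_total`, `pct_ndc`), `bm_me`, `final_distance`, `n_tiles`
#'   (accumulated), `n_tiles_visited`, `n_cells`, `converged`,
#'   `converged_at`, `trace` tibble, `roi_predictions`, `slide_id`, and the
#'   parameters used. Errors if the grid contains no appropriate tile.
#' @export
run_ndc <- function(slide, roi_backend = roi_reference_backend,
                    detector_backend = blob_detector_backend(),
                    grid = NULL, roi_threshold = 0.5, conf_thr = 0.75,
                    min_tiles = 80L, tau = 1e-5, patience = 5L,
                    include_bm_me = TRUE, shuffle = FALSE, order_seed = 1L,
                    max_tiles = Inf) {
  if (is.null(grid)) {
    grid <- if (inherits(slide, "synthetic_slide")) slide$grid else grid_spec()
  }
  if (is.finite(max_tiles) && max_tiles < min_tiles) {
    warning("max_tiles (", max_tiles, ") < min_tiles (", min_tiles,
            "): the report cannot converge", call. = FALSE)
  }
  dims <- slide_dims(slide)
  tiles <- build_grid(dims[["width"]], dims[["height"]], grid)
  order_idx <- seq_len(nrow(tiles))
  if (shuffle) order_idx <- with_seed(order_seed, sample(order_idx))
  counts <- rep(0, n_classes())
  trace <- numeric(0)
  prev_fv <- NULL
  n_roi <- 0L
  visited <- 0L
  converged <- FALSE
  roi_rows <- vector("list", nrow(tiles))
  for (i in order_idx) {
    visited <- visited + 1L
    img <- read_region(slide, tiles$x0[i], tiles$y0[i],
                       tiles$width[i], tiles$height[i])
    score <- roi_backend(img)
    appropriate <- score >= roi_threshold
    roi_rows[[visited]] <- tibble::tibble(
      row = tiles$row[i], col = tiles$col[i], x0 = tiles$x0[i],
      y0 = tiles$y0[i], score = score,
      label = if (appropriate) "appropriate" else "inappropriate"
    )
    if (!appropriate) next
    dets <- detector_backend(img)
    counts <- counts + hct_from_detections(dets, conf_thr)
    n_roi <- n_roi + 1L
    fv <- ndc_feature_vector(counts, include_bm_me)
    trace <- c(trace, if (is.null(prev_fv)) NA_real_
               else feature_distance(fv, prev_fv))
    prev_fv <- fv
    if (check_convergence(trace, min_tiles, tau, patience)) {
      converged <- TRUE
      break
    }
    if (n_roi >= max_tiles) break
  }
  roi_predictions <- dplyr::bind_rows(roi_rows[seq_len(visited)])
  if (n_roi == 0) {
    stop("no appropriate ROI tile found on the slide", call. = FALSE)
  }
  cls <- bm_cell_classes()
  total <- sum(counts)
  ndc_total <- sum(counts[cls$ndc])
  counts_tbl <- tibble::tibble(
    class_id = cls$class_id, name = cls$name, count = as.integer(counts),
    pct_total = if (total > 0) 100 * counts / total else rep(NA_real_, nrow(cls)),
    pct_ndc = ifelse(cls$ndc,
                     if (ndc_total > 0) 100 * counts / ndc_total else NA_real_,
                     NA_real_)
  )
  structure(
    list(
      counts = counts_tbl,
      bm_me = bm_me_ratio(counts),
      final_distance = if (length(trace) > 0) trace[length(trace)] else NA_real_,
      n_tiles = n_roi, n_tiles_visited = visited, n_cells = as.integer(total),
      converged = converged,
      converged_at = if (converged) n_roi else NA_integer_,
      trace = tibble::tibble(tile_index = seq_along(trace), distance = trace),
      roi_predictions = roi_predictions,
      slide_id = if (inherits(slide, "synthetic_slide")) {
        paste0(slide$profile_name, "_seed", slide$seed)
      } else NA_character_,
      params = list(roi_threshold = roi_threshold, conf_thr = conf_thr,
                    min_tiles = min_tiles, tau = tau, patience = patience,
                    include_bm_me = include_bm_me, shuffle = shuffle,
                    order_seed = order_seed, max_tiles = max_tiles)
    ),
    class = "ndc_report"
  )
}

#' @export
print.ndc_report <- function(x, ...) {
  cat("<ndc_report> ", x$slide_id, "\n", sep = "")
  cat("  ", x$n_cells, " objects over ", x$n_tiles, " ROI tiles (",
      x$n_tiles_visited, " visited); ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("  BM_ME ratio: ",
      if (is.na(x$bm_me)) "undefined" else format(round(x$bm_me, 2)),
      "; final chi-square distance: ",
      format(signif(x$final_distance, 3)), "\n", sep = "")
  top <- dplyr::arrange(x$counts[x$counts$count > 0, ], dplyr::desc(.data$count))
  print(utils::head(top, 8))
  invisible(x)
}

#' @rdname run_ndc
#' @param x,object An `ndc_report`.
#' @param ... Unused.
#' @export
tidy.ndc_report <- function(x, ...) x$counts

#' @rdname run_ndc
#' @export
glance.ndc_report <- function(x, ...) {
  tibble::tibble(
    n_tiles = x$n_tiles, n_tiles_visited = x$n_tiles_visited,
    n_cells = x$n_cells, converged = x$converged,
    converged_at = x$converged_at, bm_me = x$bm_me,
    final_distance = x$final_distance
  )
}

#' @rdname run_ndc
#' @export
autoplot.ndc_report <- function(object, ...) {
  df <- object$trace[!is.na(object$trace$distance), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tile_index, y = .data$distance)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$params$tau, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ROI tiles accumulated",
                  y = expression(chi^2 ~ "distance"),
                  title = if (object$converged) {
                    sprintf("Converged at tile %d", object$converged_at)
                  } else "Not converged") +
    ggplot2::theme_minimal()
}

#' Write an NDC report to disk
#'
#' `write_ndc_report()` writes the full report as JSON plus the class table
#' and convergence trace as CSV next to it.
#'
#' @param report An `ndc_report`.
#' @param path JSON output path; `<stem>_counts.csv` and `<stem>_trace.csv`
#'   are written alongside.
#' @return `path`, invisibly.
#' @export
write_ndc_report <- function(report, path) {
  stem <- sub("\\.json$", "", path)
  jsonlite::write_json(
    list(slide_id = report$slide_id, converged = report$converged,
         converged_at = report$converged_at, n_tiles = report$n_tiles,
         n_tiles_visited = report$n_tiles_visited, n_cells = report$n_cells,
         bm_me = report$bm_me, final_distance = report$final_distance,
         counts = report$counts, params = report$params),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  utils::write.csv(report$counts, paste0(stem, "_counts.csv"), row.names = FALSE)
  utils::write.csv(report$trace, paste0(stem, "_trace.csv"), row.names = FALSE)
  invisible(path)
}
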