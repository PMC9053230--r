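#' Bundled reference benchmark tables
#'
#' Published headline results of a clinical-scale automated bone-marrow
#' cytology system, bundled as plain data so the package's report and
#' bookkeeping arithmetic (F1 from precision/recall, macro averages, mAP,
#' per-iteration totals, dataset accounting) can be validated against a
#' known table. These numbers describe that system's performance on its own
#' clinical slides; they are reference values for checking arithmetic, not
#' quantities this package claims to reproduce from images.
#'
#' * `reference_detection_metrics()` — 16 evaluated object classes with
#'   precision, recall, F1, log-average miss rate and AP at IoU 0.5
#'   (reported macro averages: precision 0.83, recall 0.75, F1 0.78,
#'   LAMR 0.32, mAP 0.75).
#' * `reference_active_learning()` — cumulative annotated-object counts and
#'   per-class AP over 8 annotation iterations (totals 6,128 at iteration 1
#'   to 24,735 at iteration 8).
#' * `reference_roi_dataset()` — diagnostic-category counts of whole-slide
#'   images used for ROI-model training and test-validation (204 + 46 = 250
#'   patients), plus the tile-level accounting (70,250 inappropriate +
#'   28,500 appropriate = 98,750 tiles after augmentation).
#'
#' @return Tibbles (see each description); `reference_roi_dataset()` returns
#'   a list with `wsi` (tibble) and `tiles` (named numeric).
#' @export
reference_detection_metrics <- function() {
  tibble::tribble(
    ~name, ~precision, ~recall, ~f1, ~lamr, ~ap,
    "neutrophil",            0.84, 0.91, 0.87, 0.21, 0.90,
    "metamyelocyte",         0.68, 0.79, 0.73, 0.37, 0.77,
    "myelocyte",             0.80, 0.82, 0.81, 0.34, 0.80,
    "promyelocyte",          0.60, 0.67, 0.64, 0.53, 0.62,
    "blast",                 0.87, 0.90, 0.88, 0.34, 0.84,
    "erythroblast",          0.86, 0.92, 0.89, 0.17, 0.92,
    "megakaryocyte nucleus", 0.80, 0.57, 0.67, 0.18, 0.60,
    "lymphocyte",            0.73, 0.65, 0.69, 0.49, 0.66,
    "monocyte",              0.84, 0.71, 0.77, 0.36, 0.72,
    "plasma cell",           0.75, 0.69, 0.72, 0.33, 0.72,
    "eosinophil",            0.93, 0.94, 0.93, 0.06, 0.97,
    "megakaryocyte",         1.00, 0.79, 0.88, 0.19, 0.82,
    "debris",                0.85, 0.80, 0.82, 0.34, 0.79,
    "histiocyte",            0.90, 0.53, 0.67, 0.50, 0.54,
    "platelet",              0.84, 0.64, 0.73, 0.33, 0.64,
    "platelet clump",        0.93, 0.61, 0.73, 0.41, 0.62
  )
}

#' @rdname reference_detection_metrics
#' @export
reference_active_learning <- function() {
  raw <- list(
    "neutrophil" = list(c(680, 1256, 1568, 1756, 1895, 2050, 2398, 2714),
                        c(.75, .82, .83, .85, .86, .89, .91, .90)),
    "metamyelocyte" = list(c(480, 605, 752, 785, 856, 925, 986, 1017),
                           c(.60, .66, .69, .72, .76, .75, .76, .77)),
    "myelocyte" = list(c(390, 589, 665, 720, 869, 950, 1015, 1199),
                       c(.53, .55, .59, .62, .70, .78, .79, .80)),
    "promyelocyte" = list(c(65, 102, 256, 285, 320, 326, 360, 409),
                          c(.44, .46, .52, .54, .59, .62, .64, .62)),
    "blast" = list(c(1050, 1785, 2029, 2590, 2896, 3268, 3526, 3950),
                   c(.69, .76, .78, .81, .80, .83, .84, .84)),
    "erythroblast" = list(c(620, 1150, 1390, 1580, 2028, 2295, 2480, 2668),
                          c(.72, .78, .80, .82, .89, .90, .92, .92)),
    "megakaryocyte nucleus" = list(c(5, 7, 18, 19, 19, 23, 23, 23),
                                   c(.32, .35, .52, .55, .55, .60, .59, .60)),
    "lymphocyte" = list(c(390, 530, 689, 706, 780, 1015, 1150, 1305),
                        c(.47, .48, .50, .51, .52, .59, .62, .66)),
    "monocyte" = list(c(62, 98, 295, 368, 423, 485, 520, 569),
                      c(.47, .51, .57, .61, .62, .65, .68, .72)),
    "plasma cell" = list(c(29, 45, 50, 82, 105, 135, 158, 176),
                         c(.57, .59, .61, .63, .67, .68, .71, .72)),
    "eosinophil" = list(c(31, 38, 135, 172, 185, 221, 228, 249),
                        c(.59, .63, .83, .86, .88, .95, .95, .97)),
    "megakaryocyte" = list(c(25, 30, 90, 90, 92, 95, 100, 106),
                           c(.49, .52, .77, .77, .78, .80, .81, .82)),
    "debris" = list(c(1380, 2680, 3450, 3920, 4490, 4901, 5260, 5603),
                    c(.58, .62, .65, .68, .73, .77, .77, .79)),
    "histiocyte" = list(c(38, 72, 147, 163, 168, 174, 182, 191),
                        c(.34, .42, .48, .48, .51, .52, .54, .54)),
    "platelet" = list(c(790, 1680, 2150, 2560, 2890, 3250, 3680, 3971),
                      c(.41, .46, .48, .52, .58, .65, .65, .64)),
    "platelet clump" = list(c(93, 146, 320, 409, 475, 536, 563, 585),
                            c(.37, .41, .54, .56, .57, .58, .61, .62))
  )
  purrr::imap_dfr(raw, function(v, nm) {
    tibble::tibble(name = nm, iteration = 1:8, count = v[[1]], ap = v[[2]])
  })
}

#' @rdname reference_detection_metrics
#' @export
reference_roi_dataset <- function() {
  wsi <- tibble::tribble(
    ~diagnostic_tag, ~training, ~test_validation, ~patients,
    "Normal",                            80, 18, 98,
    "Myelodysplastic syndrome (MDS)",    15,  3, 18,
    "Acute leukemia",                    23,  5, 28,
    "Lymphoproliferative disorder",      28,  7, 35,
    "Plasma cell neoplasm",              19,  4, 23,
    "Hypercellular",                      5,  1,  6,
    "Erythroid hyperplasia",              3,  0,  3,
    "Myeloproliferative neoplasm (MPN)",  4,  1,  5,
    "Inadequate",                        11,  3, 14,
    "Hypocellular",                       6,  2,  8,
    "MPN/MDS",                            2,  0,  2,
    "MPN (other)",                        3,  1,  4,
    "Necrosis",                           2,  1,  3,
    "Carcinoma",                          3,  0,  3
  )
  list(
    wsi = wsi,
    tiles = c(inappropriate = 70250, appropriate = 28500, total = 98750)
  )
}

#' Aggregate a per-class metrics table into macro summary rows
#'
#' Recomputes F1 from the table's own precision and recall columns via
#' [f1_score()], and the macro means of every metric column. Applied to a
#' bundled reference table this validates the summary arithmetic against
#' the published averages; applied to [tidy()] output of
#' [evaluate_detections()] it produces the same report row for a synthetic
#' benchmark.
#'
#' @param per_class A tibble with columns `precision`, `recall`, and any of
#'   `f1`, `lamr`, `ap`.
#' @param digits Rounding applied to the summary (default 2, the usual
#'   report precision); `NA` for none.
#' @return A list: `f1_recomputed` (vector aligned with the rows),
#'   `summary` (one-row tibble of macro means; `map` is the mean AP).
#' @export
summarize_metrics_table <- function(per_class, digits = 2) {
  f1r <- f1_score(per_class$precision, per_class$recall)
  cols <- intersect(c("precision", "recall", "f1", "lamr"), names(per_class))
  summ <- dplyr::summarise(per_class,
                           dplyr::across(dplyr::all_of(cols), mean))
  if ("ap" %in% names(per_class)) summ$map <- mean_ap(per_class$ap)
  if (!is.na(digits)) {
    summ <- dplyr::mutate(summ, dplyr::across(dplyr::everything(),
                                              ~ round(.x, digits)))
  }
  list(f1_recomputed = f1r, summary = summ)
}

#' Per-iteration totals of an active-learning bookkeeping table
#'
#' Sums cumulative per-class counts and averages per-class AP within each
#' iteration — the "Average" row of the iteration table.
#'
#' @param records Long tibble with columns `iteration`, `count`, `ap`
#'   (either [reference_active_learning()] or `tidy()` of an `al_run`).
#' @return A tibble: `iteration`, `total_count`, `mean_ap`.
#' @export
al_iteration_totals <- function(records) {
  records |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(total_count = sum(.data$count),
                     mean_ap = mean_ap(.data$ap), .groups = "drop")
}
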