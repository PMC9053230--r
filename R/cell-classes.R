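#' The 19-class bone marrow object taxonomy
#'
#' Returns the fixed table of cellular and non-cellular object classes used
#' throughout the pipeline: the twelve classes of the traditional nucleated
#' differential cell count (NDC), plus megakaryocytes' bare nuclei, debris,
#' histiocytes, platelets, platelet clumps and a catch-all "other" class for
#' objects that cannot be classified with certainty.
#'
#' Each class carries the morphology parameters the synthetic renderer uses
#' (equivalent circular radius in pixels, its spread, fill colour and
#' eccentricity) and three role flags:
#'
#' * `ndc` — counts toward the nucleated differential cell count and the
#'   convergence feature vector (12 classes);
#' * `bm_me_numerator` — belongs to the myeloid numerator of the
#'   myeloid-to-erythroid (`BM_ME`) ratio;
#' * `evaluated` — included in per-class detection evaluation and mAP
#'   (16 classes; basophil, mast cell and "other" are excluded by default,
#'   the first two for chronically low support, the last by definition).
#'
#' The fill colours are deliberately well separated in RGB space so that a
#' reference nearest-centroid detector can be exercised meaningfully; they
#' make no claim to stain realism.
#'
#' @return A tibble with one row per class: `class_id` (integer, 0-18),
#'   `name`, `mean_radius_px`, `radius_sd_px`, `fill_r`, `fill_g`, `fill_b`
#'   (0-255), `eccentricity`, `ndc`, `bm_me_numerator`, `evaluated`.
#' @examples
#' bm_cell_classes()
#' @export
bm_cell_classes <- function() {
  if (!is.null(.marrowhct_cache$classes)) return(.marrowhct_cache$classes)
  cls <- tibble::tribble(
    ~class_id, ~name,                   ~mean_radius_px, ~radius_sd_px, ~fill_r, ~fill_g, ~fill_b, ~eccentricity,
    0L, "neutrophil",            13,  1.3, 220L,  40L, 220L, 0.30,
    1L, "metamyelocyte",         14,  1.4, 220L,  40L, 130L, 0.35,
    2L, "myelocyte",             15,  1.5, 220L,  40L,  40L, 0.25,
    3L, "promyelocyte",          17,  1.7, 220L, 130L,  40L, 0.20,
    4L, "blast",                 16,  1.6, 130L,  40L, 220L, 0.15,
    5L, "erythroblast",          10,  1.0,  40L,  40L, 220L, 0.10,
    6L, "megakaryocyte nucleus", 28,  2.8,  40L, 130L, 220L, 0.40,
    7L, "lymphocyte",            11,  1.1,  40L, 220L, 220L, 0.10,
    8L, "monocyte",              16,  1.6,  40L, 220L, 130L, 0.45,
    9L, "plasma cell",           13,  1.3,  40L, 220L,  40L, 0.50,
    10L, "eosinophil",           13,  1.3, 130L, 220L,  40L, 0.20,
    11L, "basophil",             13,  1.3, 220L, 220L,  40L, 0.20,
    12L, "megakaryocyte",        40,  4.0, 130L,  40L, 130L, 0.30,
    13L, "debris",                8,  2.0, 130L, 130L, 130L, 0.60,
    14L, "histiocyte",           20,  2.0,  40L, 130L,  40L, 0.40,
    15L, "mast cell",            14,  1.4,  40L,  40L, 130L, 0.25,
    16L, "platelet",              4,  0.5, 220L, 130L, 130L, 0.20,
    17L, "platelet clump",       12,  2.0, 130L,  40L,  40L, 0.55,
    18L, "other",                12,  1.5, 130L, 130L, 220L, 0.30
  )
  ndc_names <- c(
    "neutrophil", "metamyelocyte", "myelocyte", "promyelocyte", "blast",
    "erythroblast", "lymphocyte", "monocyte", "plasma cell", "eosinophil",
    "basophil", "megakaryocyte"
  )
  myeloid_names <- c(
    "blast", "promyelocyte", "myelocyte", "metamyelocyte", "neutrophil",
    "eosinophil"
  )
  excluded_eval <- c("basophil", "mast cell", "other")
  .marrowhct_cache$classes <- dplyr::mutate(
    cls,
    ndc = .data$name %in% ndc_names,
    bm_me_numerator = .data$name %in% myeloid_names,
    evaluated = !(.data$name %in% excluded_eval)
  )
  .marrowhct_cache$classes
}

# per-session cache for the fixed class table
.marrowhct_cache <- new.env(parent = emptyenv())

#' @rdname bm_cell_classes
#' @param class_id Integer vector of class ids (0-18).
#' @export
bm_class_name <- function(class_id) {
  cls <- bm_cell_classes()
  stopifnot(all(class_id %in% cls$class_id))
  cls$name[match(class_id, cls$class_id)]
}

#' @rdname bm_cell_classes
#' @param name Character vector of class names.
#' @export
bm_class_id <- function(name) {
  cls <- bm_cell_classes()
  stopifnot(all(name %in% cls$name))
  cls$class_id[match(name, cls$name)]
}

# internal: ids of the three class roles, computed once per call site
ndc_class_ids <- function() bm_cell_classes()$class_id[bm_cell_classes()$ndc]
evaluated_class_ids <- function() {
  cls <- bm_cell_classes()
  cls$class_id[cls$evaluated]
}
bm_me_numerator_ids <- function() {
  cls <- bm_cell_classes()
  cls$class_id[cls$bm_me_numerator]
}
erythroblast_id <- function() bm_class_id("erythroblast")
n_classes <- function() 19L
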