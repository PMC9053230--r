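#' Diagnostic mixture profiles for synthetic slides
#'
#' A diagnostic profile fixes the statistical structure of a synthetic
#' aspirate slide: the class mixture from which objects are drawn, the mean
#' number of objects per appropriate (ROI) tile, and the fraction of grid
#' tiles that are appropriate at all. Three presets are provided that mimic
#' the broad regimes seen in clinical marrow: `"normal"` (blast fraction
#' 0.02, myeloid-rich), `"mds_like"` (erythroid hyperplasia with modestly
#' elevated blasts) and `"aml_like"` (blast fraction 0.38).
#'
#' The preset mixtures are fixed, documented constants chosen to be broadly
#' plausible for each regime; they are not calibrated against any clinical
#' per-class frequency table and must not be read as such.
#'
#' @param name One of `"normal"`, `"mds_like"`, `"aml_like"`.
#' @return An object of class `diagnostic_profile`: a list with `name`,
#'   `mixture` (named numeric, length 19, sums to 1), `cells_per_roi_tile_mean`
#'   and `roi_fraction`.
#' @examples
#' p <- diagnostic_profile("aml_like")
#' p$mixture[["blast"]]
#' @export
diagnostic_profile <- function(name = c("normal", "mds_like", "aml_like")) {
  name <- match.arg(name)
  cls <- bm_cell_classes()
  mix <- switch(name,
    normal = c(
      0.25, 0.04, 0.05, 0.025, 0.02, 0.22, 0.002, 0.12, 0.03, 0.012,
      0.015, 0.004, 0.004, 0.07, 0.006, 0.002, 0.10, 0.02, 0.01
    ),
    mds_like = c(
      0.16, 0.04, 0.05, 0.03, 0.08, 0.30, 0.004, 0.09, 0.03, 0.015,
      0.012, 0.004, 0.005, 0.07, 0.008, 0.002, 0.07, 0.02, 0.01
    ),
    aml_like = c(
      0.08, 0.02, 0.03, 0.03, 0.38, 0.18, 0.002, 0.07, 0.04, 0.01,
      0.008, 0.004, 0.003, 0.05, 0.006, 0.002, 0.06, 0.015, 0.01
    )
  )
  names(mix) <- cls$name
  roi_frac <- switch(name, normal = 0.20, mds_like = 0.15, aml_like = 0.15)
  new_diagnostic_profile(name, mix, cells_per_roi_tile_mean = 10, roi_fraction = roi_frac)
}

#' Construct a custom diagnostic profile
#'
#' @param name Profile label.
#' @param mixture Named (or 19-long) nonnegative numeric vector of class
#'   probabilities over the taxonomy of [bm_cell_classes()]; must sum to 1
#'   within `1e-9`.
#' @param cells_per_roi_tile_mean Mean number of objects per appropriate tile
#'   (Poisson mean), positive.
#' @param roi_fraction Fraction of grid tiles that are appropriate, in (0, 1].
#' @return A `diagnostic_profile` object.
#' @export
new_diagnostic_profile <- function(name, mixture, cells_per_roi_tile_mean = 10,
                                   roi_fraction = 0.2) {
  cls <- bm_cell_classes()
  if (length(mixture) != nrow(cls)) {
    stop("`mixture` must have one entry per class (", nrow(cls), ")", call. = FALSE)
  }
  if (any(mixture < 0)) stop("`mixture` entries must be nonnegative", call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-9) {
    stop("`mixture` must sum to 1 (got ", format(sum(mixture)), ")", call. = FALSE)
  }
  if (is.null(names(mixture))) names(mixture) <- cls$name
  stopifnot(identical(names(mixture), cls$name))
  if (!(is.numeric(cells_per_roi_tile_mean) && cells_per_roi_tile_mean > 0)) {
    stop("`cells_per_roi_tile_mean` must be positive", call. = FALSE)
  }
  if (!(roi_fraction > 0 && roi_fraction <= 1)) {
    stop("`roi_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      name = name,
      mixture = mixture,
      cells_per_roi_tile_mean = cells_per_roi_tile_mean,
      roi_fraction = roi_fraction
    ),
    class = "diagnostic_profile"
  )
}

#' @export
print.diagnostic_profile <- function(x, ...) {
  cat("<diagnostic_profile> ", x$name, "\n", sep = "")
  cat("  cells per ROI tile (mean): ", x$cells_per_roi_tile_mean, "\n", sep = "")
  cat("  ROI fraction: ", x$roi_fraction, "\n", sep = "")
  top <- sort(x$mixture, decreasing = TRUE)[1:5]
  cat("  top classes: ",
      paste0(names(top), " (", format(top, digits = 2), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Mixture-implied myeloid-to-erythroid ratio of a profile
#'
#' The `BM_ME` ratio implied by a class mixture: the summed probability of
#' blast, promyelocyte, myelocyte, metamyelocyte, neutrophil and eosinophil,
#' divided by the erythroblast probability.
#'
#' @param profile A `diagnostic_profile`.
#' @return A single number (`NA` if the erythroblast probability is 0).
#' @export
profile_bm_me <- function(profile) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  cls <- bm_cell_classes()
  num <- sum(profile$mixture[cls$bm_me_numerator])
  den <- profile$mixture[["erythroblast"]]
  if (den == 0) return(NA_real_)
  num / den
}
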