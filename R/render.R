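#' @importFrom stats rnorm runif rpois rbinom qnorm rmultinom median quantile setNames
#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive child seeds (kept below 2^31) from a parent seed and an index;
# vectorised over `idx`.
derive_seed <- function(seed, idx) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 %% m
  as.integer((s + as.double(idx) * 2654435 + 1) %% m)
}

# background colour of synthetic aspirate tiles (pale smear), in [0,1]
tile_background_rgb <- function() c(245, 230, 235) / 255

# --- stochastic layout (all RNG draws happen here, before any painting) ----

# Sample one cell's geometry for a class row; returns c(a, b) semi-axes such
# that sqrt(a*b) equals the sampled equivalent radius.
sample_axes <- function(cls_row) {
  r <- max(3, rnorm(1, cls_row$mean_radius_px, cls_row$radius_sd_px))
  e <- cls_row$eccentricity
  f <- (1 - e^2)^0.25
  ab <- c(r / f, r * f)
  if (runif(1) < 0.5) ab <- rev(ab)
  ab
}

place_cells <- function(n, class_ids, tile_size, cls, max_overlap_iou,
                        max_rejects, cluster_centers = NULL) {
  out <- vector("list", n)
  boxes <- matrix(numeric(0), ncol = 4)
  kept <- 0
  for (i in seq_len(n)) {
    row <- cls[cls$class_id == class_ids[i], ]
    ab <- sample_axes(row)
    a <- ab[1]; b <- ab[2]
    if (2 * a + 2 >= tile_size || 2 * b + 2 >= tile_size) next
    placed <- FALSE
    for (try in seq_len(max_rejects + 1)) {
      if (is.null(cluster_centers)) {
        cx <- runif(1, a + 1, tile_size - a - 1)
        cy <- runif(1, b + 1, tile_size - b - 1)
      } else {
        ctr <- cluster_centers[sample.int(nrow(cluster_centers), 1), ]
        cx <- min(max(ctr[1] + rnorm(1, 0, 25), a + 1), tile_size - a - 1)
        cy <- min(max(ctr[2] + rnorm(1, 0, 25), b + 1), tile_size - b - 1)
      }
      box <- c(cx - a, cy - b, cx + a, cy + b)
      if (nrow(boxes) == 0 ||
          all(iou_one_many(box, boxes) <= max_overlap_iou) ||
          try > max_rejects) {
        kept <- kept + 1
        boxes <- rbind(boxes, box)
        jit <- rnorm(3, 0, 0.015)
        out[[kept]] <- list(
          class_id = row$class_id, cx = cx, cy = cy, a = a, b = b,
          col = pmin(1, pmax(0, c(row$fill_r, row$fill_g, row$fill_b) / 255 + jit))
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  out[seq_len(kept)]
}

# Draw the stochastic content of one tile. Must be called inside with_seed().
layout_tile_impl <- function(profile, appropriate, tile_size, max_overlap_iou,
                             max_rejects) {
  cls <- bm_cell_classes()
  mode <- NA_character_
  cluster_centers <- NULL
  tint <- NULL
  if (appropriate) {
    n <- rpois(1, profile$cells_per_roi_tile_mean)
    class_ids <- if (n > 0) {
      sample(cls$class_id, n, replace = TRUE, prob = profile$mixture)
    } else integer(0)
    iou_cap <- max_overlap_iou
  } else {
    mode <- sample(c("overlap", "overstain", "empty"), 1)
    if (mode == "overlap") {
      n <- rpois(1, profile$cells_per_roi_tile_mean * 12) + 40
      class_ids <- sample(cls$class_id, n, replace = TRUE, prob = profile$mixture)
      iou_cap <- 1
      k <- sample(1:2, 1)
      cluster_centers <- cbind(runif(k, 120, tile_size - 120),
                               runif(k, 120, tile_size - 120))
    } else if (mode == "overstain") {
      n <- rpois(1, profile$cells_per_roi_tile_mean)
      class_ids <- if (n > 0) {
        sample(cls$class_id, n, replace = TRUE, prob = profile$mixture)
      } else integer(0)
      iou_cap <- max_overlap_iou
      tint <- c(110, 50, 130) / 255
    } else { # empty: at most a couple of debris objects
      n <- sample(0:2, 1)
      class_ids <- rep(bm_class_id("debris"), n)
      iou_cap <- max_overlap_iou
    }
  }
  cells <- place_cells(length(class_ids), class_ids, tile_size, cls,
                       iou_cap, max_rejects, cluster_centers)
  anns <- if (length(cells) == 0) annotation_tbl() else annotation_tbl(
    class_id = vapply(cells, `[[`, integer(1), "class_id"),
    x0 = vapply(cells, function(c) c$cx - c$a, numeric(1)),
    y0 = vapply(cells, function(c) c$cy - c$b, numeric(1)),
    x1 = vapply(cells, function(c) c$cx + c$a, numeric(1)),
    y1 = vapply(cells, function(c) c$cy + c$b, numeric(1))
  )
  list(cells = cells, annotations = anns, mode = mode, tint = tint,
       tile_size = tile_size)
}

# Paint a layout into an RGB array [height, width, 3]. Uses RNG (pixel noise);
# must run inside the same with_seed() call as the layout for reproducibility.
paint_layout <- function(layout) {
  sz <- layout$tile_size
  bg <- tile_background_rgb()
  img <- array(rep(bg, each = sz * sz), dim = c(sz, sz, 3))
  img <- img + array(rnorm(sz * sz * 3, 0, 0.02), dim = c(sz, sz, 3))
  for (cell in layout$cells) {
    xs <- max(1L, floor(cell$cx - cell$a)):min(sz, ceiling(cell$cx + cell$a))
    ys <- max(1L, floor(cell$cy - cell$b)):min(sz, ceiling(cell$cy + cell$b))
    px <- xs - 0.5; py <- ys - 0.5
    mask <- outer((py - cell$cy)^2 / cell$b^2, (px - cell$cx)^2 / cell$a^2, `+`) <= 1
    if (!any(mask)) next
    for (ch in 1:3) {
      sub <- img[ys, xs, ch, drop = FALSE]
      dim(sub) <- dim(mask)
      sub[mask] <- cell$col[ch] + rnorm(sum(mask), 0, 0.02)
      img[ys, xs, ch] <- sub
    }
  }
  if (!is.null(layout$tint)) {
    for (ch in 1:3) img[, , ch] <- img[, , ch] * 0.45 + layout$tint[ch] * 0.55
  }
  clamp01(img)
}

# clamp values to [0, 1] without dropping array dims
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Render one synthetic aspirate tile
#'
#' Draws a 512x512 (by default) synthetic bone marrow aspirate tile.
#' Appropriate tiles contain a Poisson number of elliptical "cells" sampled
#' from the profile's class mixture, placed by rejection sampling so that
#' pairwise bounding-box IoU stays at or below `max_overlap_iou` (after
#' `max_rejects` failed placements a cell is accepted anyway). Each cell gets
#' a tight bounding-box annotation. Inappropriate tiles violate the ROI
#' criteria in one of three documented failure modes chosen uniformly at
#' random: `"overlap"` (a dense, clumped smear), `"overstain"` (a global
#' stain tint) or `"empty"` (debris only).
#'
#' Output is bit-identical for identical `(profile, appropriate, seed)`;
#' the caller's RNG state is left untouched.
#'
#' @param profile A [diagnostic_profile()].
#' @param appropriate Logical: render an ROI-quality tile?
#' @param seed Integer seed.
#' @param tile_size Tile side in pixels (default 512).
#' @param max_overlap_iou Maximum pairwise box IoU tolerated when placing
#'   cells in appropriate tiles (default 0.1).
#' @param max_rejects Placement attempts before accepting an overlapping
#'   position (default 100).
#' @return A list with `image` (array `[tile_size, tile_size, 3]`, values in
#'   `[0, 1]`), `annotations` (annotation tibble in tile pixel coordinates)
#'   and `mode` (`NA` for appropriate tiles, else the failure mode).
#' @export
render_tile <- function(profile, appropriate = TRUE, seed = 1L,
                        tile_size = 512L, max_overlap_iou = 0.1,
                        max_rejects = 100L) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  with_seed(seed, {
    layout <- layout_tile_impl(profile, appropriate, tile_size,
                               max_overlap_iou, max_rejects)
    list(image = paint_layout(layout), annotations = layout$annotations,
         mode = layout$mode)
  })
}

# Annotations of a tile without painting pixels (same RNG path as render_tile).
layout_tile <- function(profile, appropriate, seed, tile_size = 512L,
                        max_overlap_iou = 0.1, max_rejects = 100L) {
  with_seed(seed, layout_tile_impl(profile, appropriate, tile_size,
                                   max_overlap_iou, max_rejects))
}

#' Generate a synthetic whole-slide image with ground truth
#'
#' Lays a `grid$rows x grid$cols` grid of `grid$tile_size_px` tiles over a
#' virtual slide of exactly that extent. Each grid tile is independently
#' appropriate with probability `profile$roi_fraction`; appropriate tiles are
#' populated from the profile mixture, inappropriate ones drawn in a random
#' failure mode. Tile pixel data are rendered lazily (deterministically from
#' per-tile seeds derived from `seed`), so large slides never materialise a
#' full raster; use [slide_tile_image()] or [read_region()] to obtain pixels.
#'
#' @param profile A [diagnostic_profile()].
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @inheritParams render_tile
#' @return A `synthetic_slide` object: fields `profile`, `grid`, `seed`,
#'   `width`, `height`, `roi_labels` (tibble `row`, `col`, `x0`, `y0`,
#'   `appropriate`, `mode`, `tile_seed`) and `annotations` (slide-coordinate
#'   annotation tibble with `row`, `col` columns).
#' @export
render_slide <- function(profile, grid = grid_spec(), seed = 1L,
                         max_overlap_iou = 0.1, max_rejects = 100L) {
  stopifnot(inherits(profile, "diagnostic_profile"), inherits(grid, "grid_spec"))
  sz <- grid$tile_size_px
  width <- grid$cols * sz
  height <- grid$rows * sz
  cells <- tidyr::expand_grid(row = seq_len(grid$rows) - 1L,
                              col = seq_len(grid$cols) - 1L)
  appropriate <- with_seed(seed, runif(nrow(cells)) < profile$roi_fraction)
  labels <- dplyr::mutate(
    cells,
    x0 = .data$col * sz, y0 = .data$row * sz,
    appropriate = appropriate,
    tile_seed = derive_seed(seed, .data$row * grid$cols + .data$col)
  )
  layouts <- purrr::pmap(labels, function(row, col, x0, y0, appropriate, tile_seed) {
    layout_tile(profile, appropriate, tile_seed, sz, max_overlap_iou, max_rejects)
  })
  labels$mode <- vapply(layouts, function(l) l$mode, character(1))
  anns <- purrr::map2_dfr(layouts, seq_len(nrow(labels)), function(l, i) {
    if (nrow(l$annotations) == 0) return(NULL)
    dplyr::mutate(l$annotations,
                  x0 = .data$x0 + labels$x0[i], x1 = .data$x1 + labels$x0[i],
                  y0 = .data$y0 + labels$y0[i], y1 = .data$y1 + labels$y0[i],
                  row = labels$row[i], col = labels$col[i])
  })
  if (is.null(anns) || nrow(anns) == 0) {
    anns <- dplyr::mutate(annotation_tbl(), row = integer(), col = integer())
  }
  structure(
    list(
      profile = profile, profile_name = profile$name, grid = grid, seed = seed,
      width = width, height = height, roi_labels = labels, annotations = anns,
      max_overlap_iou = max_overlap_iou, max_rejects = max_rejects
    ),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat("<synthetic_slide> ", x$profile_name, ", ", x$grid$rows, "x", x$grid$cols,
      " grid of ", x$grid$tile_size_px, "px tiles (",
      sum(x$roi_labels$appropriate), " appropriate), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Pixels of one grid tile of a slide
#'
#' @param slide A `synthetic_slide` (or `raster_slide`).
#' @param row,col 0-based grid indices.
#' @return RGB array `[tile_size, tile_size, 3]`.
#' @export
slide_tile_image <- function(slide, row, col) {
  UseMethod("slide_tile_image")
}

#' @export
slide_tile_image.synthetic_slide <- function(slide, row, col) {
  lab <- slide$roi_labels[slide$roi_labels$row == row & slide$roi_labels$col == col, ]
  if (nrow(lab) != 1) stop("no such grid tile (", row, ", ", col, ")", call. = FALSE)
  render_tile(slide$profile, lab$appropriate, lab$tile_seed,
              slide$grid$tile_size_px, slide$max_overlap_iou,
              slide$max_rejects)$image
}

#' Slide reader contract
#'
#' Every slide-like object answers `slide_dims()` (width, height in pixels)
#' and `read_region()` (an RGB array for an arbitrary rectangle). Synthetic
#' slides render regions on demand; [raster_slide()] wraps an in-memory
#' array (e.g. a PNG/TIFF read with \pkg{png} or \pkg{EBImage}) so that flat
#' images satisfy the same contract. Adapters for proprietary scanner
#' formats only need methods for these two generics.
#'
#' @param slide A slide object.
#' @return `slide_dims()`: named numeric `c(width, height)`.
#' @export
slide_dims <- function(slide) UseMethod("slide_dims")

#' @export
slide_dims.synthetic_slide <- function(slide) c(width = slide$width, height = slide$height)

#' @rdname slide_dims
#' @param x0,y0 Top-left corner of the region (0-based pixels).
#' @param w,h Region width and height in pixels.
#' @export
read_region <- function(slide, x0, y0, w, h) UseMethod("read_region")

#' @export
read_region.synthetic_slide <- function(slide, x0, y0, w, h) {
  sz <- slide$grid$tile_size_px
  stopifnot(x0 >= 0, y0 >= 0, x0 + w <= slide$width, y0 + h <= slide$height)
  out <- array(0, dim = c(h, w, 3))
  rows <- floor(y0 / sz):floor((y0 + h - 1) / sz)
  cols <- floor(x0 / sz):floor((x0 + w - 1) / sz)
  for (r in rows) {
    for (cc in cols) {
      img <- slide_tile_image(slide, r, cc)
      ty <- max(y0, r * sz):min(y0 + h - 1, (r + 1) * sz - 1)
      tx <- max(x0, cc * sz):min(x0 + w - 1, (cc + 1) * sz - 1)
      out[ty - y0 + 1, tx - x0 + 1, ] <- img[ty - r * sz + 1, tx - cc * sz + 1, ]
    }
  }
  out
}

#' @rdname slide_dims
#' @param image RGB array `[height, width, 3]` with values in `[0, 1]`.
#' @export
raster_slide <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  structure(list(image = image), class = "raster_slide")
}

#' @export
slide_dims.raster_slide <- function(slide) {
  c(width = dim(slide$image)[2], height = dim(slide$image)[1])
}

#' @export
read_region.raster_slide <- function(slide, x0, y0, w, h) {
  d <- dim(slide$image)
  stopifnot(x0 >= 0, y0 >= 0, x0 + w <= d[2], y0 + h <= d[1])
  slide$image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
}

#' Geometric and photometric tile augmentation
#'
#' Geometric operations (`hflip`, `vflip`, `rot90` — a clockwise quarter
#' turn) transform pixels and bounding boxes consistently; photometric
#' operations (`brightness`, `contrast`) change pixels only. `hflip` and
#' `vflip` are involutions and four `rot90`s are the identity, exactly, on
#' both pixels and boxes.
#'
#' @param image RGB array `[h, w, 3]`.
#' @param annotations Annotation tibble in the image's pixel coordinates.
#' @param op One of `"hflip"`, `"vflip"`, `"rot90"`, `"brightness"`,
#'   `"contrast"`.
#' @param delta Brightness shift in `[-0.5, 0.5]` (for `op = "brightness"`).
#' @param gamma Contrast factor in `[0.1, 3]` (for `op = "contrast"`).
#' @return A list with transformed `image` and `annotations`.
#' @export
augment_tile <- function(image, annotations, op, delta = 0, gamma = 1) {
  h <- dim(image)[1]; w <- dim(image)[2]
  anns <- annotations
  switch(op,
    hflip = {
      image <- image[, w:1, , drop = FALSE]
      if (nrow(anns) > 0) {
        new_x0 <- w - anns$x1; new_x1 <- w - anns$x0
        anns$x0 <- new_x0; anns$x1 <- new_x1
      }
    },
    vflip = {
      image <- image[h:1, , , drop = FALSE]
      if (nrow(anns) > 0) {
        new_y0 <- h - anns$y1; new_y1 <- h - anns$y0
        anns$y0 <- new_y0; anns$y1 <- new_y1
      }
    },
    rot90 = {
      image <- aperm(image, c(2, 1, 3))[, h:1, , drop = FALSE]
      if (nrow(anns) > 0) {
        nx0 <- h - anns$y1; nx1 <- h - anns$y0
        ny0 <- anns$x0; ny1 <- anns$x1
        anns$x0 <- nx0; anns$x1 <- nx1; anns$y0 <- ny0; anns$y1 <- ny1
      }
    },
    brightness = {
      stopifnot(delta >= -0.5, delta <= 0.5)
      image <- clamp01(image + delta)
    },
    contrast = {
      stopifnot(gamma >= 0.1, gamma <= 3)
      image <- clamp01((image - 0.5) * gamma + 0.5)
    },
    stop("unknown augmentation op: ", op, call. = FALSE)
  )
  list(image = image, annotations = anns)
}

#' Write a tile dataset to disk in PNG + YOLO text form
#'
#' Renders `n_tiles` appropriate tiles from a profile and writes each as
#' `{stem}_r{row}_c{col}.png` alongside a YOLO annotation file with the same
#' stem, plus a JSON manifest recording the seed, profile and per-tile
#' appropriateness.
#'
#' @param profile A [diagnostic_profile()].
#' @param dir Output directory (created if needed).
#' @param n_tiles Number of tiles.
#' @param seed Integer seed.
#' @param stem Filename stem (default the profile name).
#' @param tile_size Tile side in pixels.
#' @return Invisibly, a tibble with `png`, `txt` and annotation counts.
#' @export
write_tile_dataset <- function(profile, dir, n_tiles = 10, seed = 1L,
                               stem = profile$name, tile_size = 512L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(seq_len(n_tiles), function(i) {
    tl <- render_tile(profile, TRUE, derive_seed(seed, i), tile_size)
    base <- sprintf("%s_r0_c%d", stem, i - 1)
    png_path <- file.path(dir, paste0(base, ".png"))
    txt_path <- file.path(dir, paste0(base, ".txt"))
    png::writePNG(tl$image, png_path)
    write_yolo(tl$annotations, txt_path, tile_size, tile_size)
    tibble::tibble(png = png_path, txt = txt_path, n_objects = nrow(tl$annotations))
  })
  manifest <- list(seed = seed, profile = profile$name, n_tiles = n_tiles,
                   tile_size = tile_size, files = rows$png)
  jsonlite::write_json(manifest, file.path(dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(rows)
}
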