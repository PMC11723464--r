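#' Canopy segmentation configuration
#'
#' @param ndvi_threshold Pixels with NDVI strictly below this value are
#'   treated as soil (default 0.2; a pixel exactly at the threshold is
#'   retained).
#' @param min_canopy_fraction Slices whose canopy fraction falls strictly
#'   below this value are dropped as "mostly soil" (default 0.5; a slice
#'   exactly at the threshold is retained).
#' @param connectivity Pixel connectivity for connected components, 4 or 8
#'   (default 8).
#' @param grid_rows,grid_cols Slicing grid dimensions (default 3 x 3).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(ndvi_threshold = 0.2,
                                min_canopy_fraction = 0.5,
                                connectivity = 8L,
                                grid_rows = 3L, grid_cols = 3L) {
  stopifnot(ndvi_threshold >= 0, ndvi_threshold <= 1,
            min_canopy_fraction >= 0, min_canopy_fraction <= 1,
            connectivity %in% c(4L, 8L),
            grid_rows >= 1L, grid_cols >= 1L)
  structure(list(ndvi_threshold = ndvi_threshold,
                 min_canopy_fraction = min_canopy_fraction,
                 connectivity = as.integer(connectivity),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "segmentation_config")
}

#' Geometric crop around a trunk position
#'
#' Crops a square window of side `round(spacing_m * 100 / gsd)` pixels
#' centred on the trunk, the planting-geometry route used for mature plants
#' with overlapping canopies. Window parts outside the scene are zero-padded
#' with a warning.
#'
#' @param scene A [bandstack()].
#' @param trunk_rc Length-2 integer vector `(row, col)`, 0-based, of the
#'   trunk pixel.
#' @param spacing_m Planting distance in metres (default 4).
#' @return A [bandstack()] crop.
#' @export
geometric_crop <- function(scene, trunk_rc, spacing_m = 4) {
  stopifnot(inherits(scene, "bandstack"), length(trunk_rc) == 2L)
  tr <- as.integer(trunk_rc[1]); tc <- as.integer(trunk_rc[2])
  if (tr < 0L || tr >= scene$height || tc < 0L || tc >= scene$width) {
    stop("trunk position (", tr, ", ", tc, ") outside scene", call. = FALSE)
  }
  side <- as.integer(round(spacing_m * 100 / scene$gsd_cm_per_px))
  r0 <- tr - side %/% 2L; c0 <- tc - side %/% 2L
  r1 <- r0 + side; c1 <- c0 + side
  padded <- r0 < 0L || c0 < 0L || r1 > scene$height || c1 > scene$width
  if (padded) {
    warning("crop window extends beyond the scene; zero-padding the margin")
  }
  crop_band <- function(b) {
    out <- matrix(0, side, side)
    sr <- max(r0, 0L):(min(r1, scene$height) - 1L)
    sc <- max(c0, 0L):(min(c1, scene$width) - 1L)
    out[sr - r0 + 1L, sc - c0 + 1L] <- b[sr + 1L, sc + 1L]
    out
  }
  bandstack(lapply(scene$bands, crop_band),
            gsd_cm_per_px = scene$gsd_cm_per_px,
            provenance = c(scene$provenance,
                           list(crop = c(r0, c0, r1, c1), padded = padded)))
}

#' Per-pixel NDVI map
#'
#' @param stack A [bandstack()] with `NIR` and `RED`.
#' @param epsilon Pixels with `NIR + RED < epsilon` are returned as `NA`
#'   (invalid).
#' @return Numeric matrix of NDVI values in \[-1, 1\] (with `NA` where
#'   invalid).
#' @export
ndvi_map <- function(stack, epsilon = 1e-9) {
  stopifnot(inherits(stack, "bandstack"))
  n <- stack$bands$NIR; r <- stack$bands$RED
  v <- (n - r) / (n + r)
  v[abs(n + r) < epsilon] <- NA_real_
  v
}

#' Soil mask from an NDVI map
#'
#' Marks canopy pixels by thresholding NDVI: soil pixels (NDVI strictly
#' below the threshold, mirroring the "NDVI < threshold excluded" rule) and
#' invalid pixels are `FALSE`.
#'
#' @param ndvi NDVI matrix from [ndvi_map()].
#' @param cfg A [segmentation_config()].
#' @return A `canopy_mask`: logical matrix with attribute `canopy_fraction`.
#' @export
soil_mask <- function(ndvi, cfg = segmentation_config()) {
  m <- !is.na(ndvi) & ndvi >= cfg$ndvi_threshold
  attr(m, "canopy_fraction") <- mean(m)
  class(m) <- c("canopy_mask", class(m))
  m
}

# Connected-component labelling of a logical matrix via row-run merging
# (union-find over runs). connectivity 4: runs on adjacent rows must share a
# column; connectivity 8: column ranges may touch diagonally (overlap +/- 1).
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  # row-wise runs of TRUE, extracted from the transition points of the
  # row-major pixel sequence (rows padded so runs never span rows)
  padded <- rbind(matrix(FALSE, 1L, nr), matrix(as.logical(t(mask)), nc, nr))
  v <- as.vector(padded)
  d <- diff(c(FALSE, v))
  up <- which(d == 1L); down <- which(d == -1L)
  if (length(down) < length(up)) down <- c(down, length(v) + 1L)
  if (length(up) == 0L) return(matrix(0L, nr, nc))
  per <- nc + 1L
  run_row <- (up - 1L) %/% per + 1L
  run_start <- (up - 1L) %% per       # 1-based column (padding occupies 0)
  run_end <- run_start + (down - up) - 1L
  nruns <- length(up)

  parent <- seq_len(nruns)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  slack <- if (connectivity == 8L) 1L else 0L
  # interval join between consecutive rows: runs are sorted and disjoint
  # within a row, so overlap candidates form a contiguous index range
  row_first <- match(seq_len(nr), run_row)
  row_count <- tabulate(run_row, nbins = nr)
  for (i in which(row_count[-nr] > 0L & row_count[-1L] > 0L)) {
    ai <- row_first[i] + seq_len(row_count[i]) - 1L
    bi <- row_first[i + 1L] + seq_len(row_count[i + 1L]) - 1L
    hi <- findInterval(run_end[bi] + slack, run_start[ai])
    lo <- 1L + findInterval(run_start[bi] - slack - 1L, run_end[ai])
    for (k in which(hi >= lo)) {
      for (j in lo[k]:hi[k]) {
        ra <- find(ai[j]); rb <- find(bi[k])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(nruns), find, integer(1))
  relabel <- match(roots, unique(roots))
  # paint runs back: pixel index (column-major) of run cells
  lens <- run_end - run_start + 1L
  px <- sequence(lens, from = run_row + (run_start - 1L) * nr, by = nr)
  out <- matrix(0L, nr, nc)
  out[px] <- rep.int(relabel, lens)
  out
}

# Union of one-pixel shifts of a logical matrix (4- or 8-neighbourhood)
shift_union <- function(m, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[, -nc] <- out[, -nc] | m[, -1]
  out[, -1] <- out[, -1] | m[, -nc]
  if (connectivity == 8L) {
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
  }
  out
}

# Fill holes: background components (complementary connectivity) that do not
# touch the image border are interior holes.
fill_holes <- function(mask, connectivity = 8L) {
  bg_conn <- if (connectivity == 8L) 4L else 8L
  bg <- label_components(!mask, bg_conn)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border != 0L]
  mask | (bg != 0L & !(bg %in% border))
}

#' Contour-hierarchy filter on a canopy mask
#'
#' Builds the two-level containment hierarchy of connected components:
#' components lying strictly inside the filled region of another component
#' (inner contours) are removed, and the retained outer components are
#' filled (holes closed). The result is a union of solid canopy regions.
#' The operation is idempotent.
#'
#' @param mask A logical matrix or `canopy_mask`.
#' @param cfg A [segmentation_config()] (supplies connectivity).
#' @return A filled `canopy_mask`.
#' @export
hierarchical_filter <- function(mask, cfg = segmentation_config()) {
  m <- unclass(mask)
  attr(m, "canopy_fraction") <- NULL
  if (!any(m)) {
    warning("empty canopy mask; returned unchanged")
    out <- m
  } else {
    lab <- label_components(m, cfg$connectivity)
    # background regions, labelled with the complementary connectivity;
    # regions reachable from the image border are "outside", the rest are
    # holes of some contour
    bg_conn <- if (cfg$connectivity == 8L) 4L else 8L
    bg <- label_components(!m, bg_conn)
    border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    outside <- matrix(bg %in% setdiff(border_ids, 0L), nrow(m), ncol(m))
    # a component is an outer contour iff it touches the image border or is
    # adjacent to the outside background; components only adjacent to holes
    # are inner contours and get removed
    nbr <- shift_union(outside, cfg$connectivity)
    outer_ids <- unique(c(lab[nbr & lab > 0L],
                          lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- matrix(lab %in% setdiff(outer_ids, 0L), nrow(m), ncol(m))
    out <- fill_holes(keep, cfg$connectivity)
  }
  attr(out, "canopy_fraction") <- mean(out)
  class(out) <- c("canopy_mask", class(out))
  out
}

#' Sub-image of a plant
#'
#' One cell of the slicing grid: band data and canopy mask restricted to a
#' half-open pixel window, plus grid position and an optional health label.
#'
#' @param bands Named list of band matrices restricted to the window.
#' @param mask Logical matrix restricted to the window.
#' @param plant_id Plant identifier.
#' @param grid_row,grid_col 0-based grid position.
#' @param window Integer vector `(r0, r1, c0, c1)`, half-open.
#' @param label Optional 0/1 health label (NA when unknown).
#' @return An object of class `sub_image`.
#' @export
sub_image <- function(bands, mask, plant_id, grid_row, grid_col, window,
                      label = NA_integer_) {
  structure(list(bands = bands, mask = mask, plant_id = plant_id,
                 grid_row = as.integer(grid_row),
                 grid_col = as.integer(grid_col),
                 window = as.integer(window),
                 slice_id = sprintf("%s_r%dc%d", plant_id, grid_row, grid_col),
                 label = as.integer(label),
                 canopy_fraction = mean(mask)),
            class = "sub_image")
}

#' Partition a plant image into a grid of sub-images
#'
#' Row boundaries at `floor(i * H / grid_rows)` (columns analogous), so the
#' windows tile the frame exactly and side lengths differ by at most one
#' pixel; the remainder is absorbed by the last row/column. Slices are
#' returned in row-major order.
#'
#' @param plant A [bandstack()].
#' @param mask Canopy mask matrix of the same shape.
#' @param cfg A [segmentation_config()].
#' @param plant_id Identifier carried into slice ids.
#' @param labels Optional `grid_rows x grid_cols` 0/1 matrix of slice labels.
#' @return List of [sub_image()] objects.
#' @export
slice_grid <- function(plant, mask, cfg = segmentation_config(),
                       plant_id = "plant", labels = NULL) {
  stopifnot(inherits(plant, "bandstack"),
            all(dim(mask) == c(plant$height, plant$width)))
  h <- plant$height; w <- plant$width
  if (h < cfg$grid_rows || w < cfg$grid_cols) {
    stop("image (", h, " x ", w, ") smaller than the slicing grid",
         call. = FALSE)
  }
  rb <- floor((0:cfg$grid_rows) * h / cfg$grid_rows)
  cb <- floor((0:cfg$grid_cols) * w / cfg$grid_cols)
  out <- list()
  for (i in seq_len(cfg$grid_rows)) {
    for (j in seq_len(cfg$grid_cols)) {
      rsel <- (rb[i] + 1L):rb[i + 1L]
      csel <- (cb[j] + 1L):cb[j + 1L]
      lab <- if (is.null(labels)) NA_integer_ else labels[i, j]
      out[[length(out) + 1L]] <- sub_image(
        bands = lapply(plant$bands, function(b) b[rsel, csel, drop = FALSE]),
        mask = unclass(mask)[rsel, csel, drop = FALSE],
        plant_id = plant_id, grid_row = i - 1L, grid_col = j - 1L,
        window = c(rb[i], rb[i + 1L], cb[j], cb[j + 1L]),
        label = lab)
    }
  }
  out
}

#' Drop slices that are mostly soil
#'
#' Retains slices whose canopy fraction is at least `min_canopy_fraction`
#' and reports the dropped count via a message.
#'
#' @param slices List of [sub_image()] objects.
#' @param cfg A [segmentation_config()].
#' @return Filtered list of sub-images.
#' @export
drop_soil_slices <- function(slices, cfg = segmentation_config()) {
  keep <- vapply(slices, function(s) {
    s$canopy_fraction >= cfg$min_canopy_fraction
  }, logical(1))
  if (any(!keep)) {
    message("drop_soil_slices: dropped ", sum(!keep), " of ", length(slices),
            " slices as mostly soil")
  }
  slices[keep]
}

#' Segment one plant image into labelled slices
#'
#' Convenience composition of the per-plant stages: NDVI soil masking,
#' contour-hierarchy filtering, grid slicing and soil-slice dropping.
#'
#' @param plant A [bandstack()].
#' @param cfg A [segmentation_config()].
#' @param plant_id Identifier for slice ids.
#' @param labels Optional slice label matrix.
#' @return List with `mask` (filtered canopy mask), `slices` (retained),
#'   `n_slices_total`, `n_slices_dropped`.
#' @export
segment_plant <- function(plant, cfg = segmentation_config(),
                          plant_id = "plant", labels = NULL) {
  nd <- ndvi_map(plant)
  m0 <- soil_mask(nd, cfg)
  m <- hierarchical_filter(m0, cfg)
  slices <- slice_grid(plant, m, cfg, plant_id = plant_id, labels = labels)
  kept <- suppressMessages(drop_soil_slices(slices, cfg))
  list(mask = m, slices = kept,
       n_slices_total = length(slices),
       n_slices_dropped = length(slices) - length(kept))
}
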