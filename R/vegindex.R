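#' Vegetation-index configuration
#'
#' Settings shared by all vegetation-index (VI) computations: the SAVI soil
#' correction factor `L`, the denominator guard `epsilon` below which a pixel
#' is flagged invalid, the TCARI formula variant, and whether slice averages
#' are restricted to canopy-mask pixels.
#'
#' @param L Soil-adjustment factor for SAVI, in \[0, 1\]. `L = 0` reduces SAVI
#'   to NDVI; 0.5 is the customary intermediate-cover value and the default.
#' @param epsilon Positive guard: a pixel whose VI denominator has magnitude
#'   below `epsilon` is marked invalid and dropped from slice means.
#' @param tcari_variant `"standard"` uses the literature form
#'   3\[(RE - R) - 0.2 (RE - G) (RE / R)\]; `"paper_literal"` uses
#'   3\[(RE - R) - 0.2 (R - G) (RE / R)\].
#' @param use_mask If `TRUE` (default) slice means are taken over canopy-mask
#'   pixels only; if `FALSE`, over all pixels of the slice.
#' @return An object of class `vi_config`.
#' @export
vi_config <- function(L = 0.5, epsilon = 1e-9,
                      tcari_variant = c("standard", "paper_literal"),
                      use_mask = TRUE) {
  tcari_variant <- match.arg(tcari_variant)
  stopifnot(is.numeric(L), length(L) == 1L, L >= 0, L <= 1,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.logical(use_mask), length(use_mask) == 1L)
  structure(list(L = L, epsilon = epsilon, tcari_variant = tcari_variant,
                 use_mask = use_mask),
            class = "vi_config")
}

#' Names of the nine supported vegetation indices
#'
#' @return Character vector, lower case, in canonical order.
#' @export
vi_names <- function() {
  c("ndvi", "gndvi", "gci", "ndrei", "reci", "nri", "gi", "tcari", "savi")
}

#' Compute one vegetation index per pixel
#'
#' Vectorised over pixels: the band arguments may be scalars, vectors or
#' matrices of identical shape. Pixels whose denominator magnitude falls
#' below `cfg$epsilon` are returned as `NA` (invalid) rather than clamped.
#'
#' The nine indices are
#' \describe{
#'   \item{ndvi}{(NIR - RED) / (NIR + RED)}
#'   \item{gndvi}{(NIR - GREEN) / (NIR + GREEN)}
#'   \item{gci}{NIR / GREEN - 1}
#'   \item{ndrei}{(NIR - RED_EDGE) / (NIR + RED_EDGE)}
#'   \item{reci}{NIR / RED_EDGE - 1}
#'   \item{nri}{(GREEN - RED) / (GREEN + RED)}
#'   \item{gi}{GREEN / RED}
#'   \item{tcari}{3 \[(RE - R) - 0.2 (RE - G) (RE / R)\] (standard variant)}
#'   \item{savi}{(1 + L) (NIR - RED) / (NIR + RED + L)}
#' }
#'
#' @param name One of [vi_names()] (case-insensitive).
#' @param g,r,re,n GREEN, RED, RED_EDGE and NIR reflectances in \[0, 1\].
#' @param cfg A [vi_config()].
#' @return Numeric of the same shape as the inputs; `NA` marks invalid pixels.
#' @export
compute_vi_pixel <- function(name, g = NULL, r = NULL, re = NULL, n = NULL,
                             cfg = vi_config()) {
  name <- tolower(name)
  eps <- cfg$epsilon
  guard <- function(x, den) {
    x[abs(den) < eps] <- NA_real_
    x
  }
  switch(name,
    ndvi  = guard((n - r) / (n + r), n + r),
    gndvi = guard((n - g) / (n + g), n + g),
    gci   = guard(n / g - 1, g),
    ndrei = guard((n - re) / (n + re), n + re),
    reci  = guard(n / re - 1, re),
    nri   = guard((g - r) / (g + r), g + r),
    gi    = guard(g / r, r),
    tcari = {
      v <- if (cfg$tcari_variant == "standard") {
        3 * ((re - r) - 0.2 * (re - g) * (re / r))
      } else {
        3 * ((re - r) - 0.2 * (r - g) * (re / r))
      }
      guard(v, r)
    },
    savi  = guard((1 + cfg$L) * (n - r) / (n + r + cfg$L), n + r + cfg$L),
    stop("unknown vegetation index: ", name, call. = FALSE)
  )
}

#' Mean vegetation index over one sub-image
#'
#' Averages the per-pixel index over the slice, restricted to canopy-mask
#' pixels when `cfg$use_mask` is `TRUE`, and excluding pixels with invalid
#' (guarded) denominators. Returns the count of pixels actually averaged so
#' that the exclusion is auditable.
#'
#' @param sub A [sub_image] as produced by [slice_grid()].
#' @param name One of [vi_names()].
#' @param cfg A [vi_config()].
#' @return List with `mean` (NA when no valid pixel) and `n_valid`.
#' @export
compute_vi_slice <- function(sub, name, cfg = vi_config()) {
  stopifnot(inherits(sub, "sub_image"))
  v <- compute_vi_pixel(name,
                        g = sub$bands$GREEN, r = sub$bands$RED,
                        re = sub$bands$RED_EDGE, n = sub$bands$NIR,
                        cfg = cfg)
  keep <- !is.na(v)
  if (isTRUE(cfg$use_mask)) keep <- keep & sub$mask
  n_valid <- sum(keep)
  list(mean = if (n_valid > 0L) mean(v[keep]) else NA_real_,
       n_valid = as.integer(n_valid))
}

#' All nine vegetation indices for one sub-image
#'
#' @param sub A [sub_image].
#' @param cfg A [vi_config()].
#' @return A one-row data frame: `slice_id`, `plant_id`, `grid_row`,
#'   `grid_col`, one column per VI (slice mean), and `n_valid_min`, the
#'   smallest valid-pixel count across the nine indices.
#' @export
compute_all_vi <- function(sub, cfg = vi_config()) {
  vals <- lapply(vi_names(), function(nm) compute_vi_slice(sub, nm, cfg))
  means <- vapply(vals, `[[`, numeric(1), "mean")
  nv <- vapply(vals, `[[`, integer(1), "n_valid")
  out <- data.frame(slice_id = sub$slice_id, plant_id = sub$plant_id,
                    grid_row = sub$grid_row, grid_col = sub$grid_col,
                    stringsAsFactors = FALSE)
  out[vi_names()] <- as.list(means)
  out$n_valid_min <- min(nv)
  out
}

#' Class-separation report for vegetation indices
#'
#' Quantifies, for each VI, how well slice-level means separate healthy
#' (label 0) from unhealthy (label 1) slices, using the standardised mean
#' difference (Cohen's d with pooled standard deviation, healthy minus
#' unhealthy). A VI passes the separation threshold when |d| >= `threshold_d`.
#' Because SAVI is an NDVI rescaling, NDVI is additionally deselected
#' whenever SAVI fails the threshold, even if NDVI itself passes.
#'
#' @param records Data frame with one column per VI (as from
#'   [compute_all_vi()] rows bound together).
#' @param labels Integer vector of 0/1 slice labels, same length as
#'   `nrow(records)`; both classes must be present.
#' @param threshold_d Selection threshold on |d| (default 0.5).
#' @return A `separation_report`: data frame with one row per VI and columns
#'   `vi`, class quartiles (`q25_0`, `q50_0`, `q75_0`, `q25_1`, `q50_1`,
#'   `q75_1`), `d`, `sign` (+1 healthy higher, -1 unhealthy higher),
#'   `passes_threshold`, `selected`; `threshold_d` kept as an attribute.
#' @export
separation_report <- function(records, labels, threshold_d = 0.5) {
  stopifnot(is.data.frame(records), nrow(records) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a separation report",
         call. = FALSE)
  }
  present <- intersect(vi_names(), names(records))
  rows <- lapply(present, function(nm) {
    x0 <- records[[nm]][labels == 0L]
    x1 <- records[[nm]][labels == 1L]
    x0 <- x0[is.finite(x0)]; x1 <- x1[is.finite(x1)]
    n0 <- length(x0); n1 <- length(x1)
    sp <- sqrt(((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) /
                 (n0 + n1 - 2))
    d <- if (sp > 0) (mean(x0) - mean(x1)) / sp else 0
    q0 <- stats::quantile(x0, c(.25, .5, .75), names = FALSE)
    q1 <- stats::quantile(x1, c(.25, .5, .75), names = FALSE)
    data.frame(vi = nm, q25_0 = q0[1], q50_0 = q0[2], q75_0 = q0[3],
               q25_1 = q1[1], q50_1 = q1[2], q75_1 = q1[3],
               d = d, sign = sign(d), passes_threshold = abs(d) >= threshold_d,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$selected <- rep$passes_threshold
  # SAVI is NDVI with an additive soil correction: if SAVI is uninformative,
  # NDVI is deselected with it.
  if ("savi" %in% rep$vi && "ndvi" %in% rep$vi &&
      !rep$passes_threshold[rep$vi == "savi"]) {
    rep$selected[rep$vi == "ndvi"] <- FALSE
  }
  attr(rep, "threshold_d") <- threshold_d
  class(rep) <- c("separation_report", class(rep))
  rep
}

#' Selected vegetation indices from a separation report
#'
#' @param report A [separation_report()].
#' @return Character vector of selected VI names.
#' @export
selected_vis <- function(report) {
  stopifnot(inherits(report, "separation_report"))
  report$vi[report$selected]
}
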