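#' Construct a band stack of co-registered reflectance grids
#'
#' A `bandstack` holds one reflectance matrix per spectral band for a scene
#' or a single plant. All bands share the same pixel grid (row-major,
#' 0-based indexing convention for windows, origin top-left). Reflectance is
#' stored as floats in \[0, 1\]; out-of-range or non-finite values are
#' clipped with a message reporting the count.
#'
#' @param bands Named list of numeric matrices; names drawn from
#'   `BLUE, GREEN, RED, RED_EDGE, NIR`. `GREEN`, `RED`, `RED_EDGE` and `NIR`
#'   are required (no index uses `BLUE`, but it is carried if present).
#' @param gsd_cm_per_px Ground sample distance, centimetres per pixel (> 0).
#' @param provenance Optional list of free-form metadata (source path,
#'   rescale factor applied at load time, ...).
#' @return An object of class `bandstack` with elements `bands`, `width`,
#'   `height`, `gsd_cm_per_px`, `provenance`.
#' @export
bandstack <- function(bands, gsd_cm_per_px = 1, provenance = list()) {
  required <- c("GREEN", "RED", "RED_EDGE", "NIR")
  allowed <- c("BLUE", required)
  if (!is.list(bands) || is.null(names(bands)) ||
      !all(names(bands) %in% allowed)) {
    stop("bands must be a named list with names in {",
         paste(allowed, collapse = ", "), "}", call. = FALSE)
  }
  missing <- setdiff(required, names(bands))
  if (length(missing) > 0L) {
    stop("required band(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dims <- lapply(bands, dim)
  if (any(!vapply(bands, is.matrix, logical(1)))) {
    stop("every band must be a numeric matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("band grids differ in shape", call. = FALSE)
  }
  if (!is.numeric(gsd_cm_per_px) || length(gsd_cm_per_px) != 1L ||
      gsd_cm_per_px <= 0) {
    stop("gsd_cm_per_px must be a single positive number", call. = FALSE)
  }
  n_clipped <- 0L
  bands <- lapply(bands, function(b) {
    bad <- !is.finite(b)
    b[bad] <- 0
    oob <- b < 0 | b > 1
    n_clipped <<- n_clipped + sum(bad) + sum(oob)
    pmin(pmax(b, 0), 1)
  })
  if (n_clipped > 0L) {
    message("bandstack: clipped ", n_clipped,
            " non-finite or out-of-range values to [0, 1]")
  }
  structure(list(bands = bands,
                 width = ncol(bands[[1]]),
                 height = nrow(bands[[1]]),
                 gsd_cm_per_px = gsd_cm_per_px,
                 provenance = provenance),
            class = "bandstack")
}

#' @export
print.bandstack <- function(x, ...) {
  cat("bandstack:", x$height, "x", x$width, "px,",
      length(x$bands), "bands (", paste(names(x$bands), collapse = ", "),
      "), gsd", x$gsd_cm_per_px, "cm/px\n")
  invisible(x)
}

#' Read a multiband reflectance image
#'
#' Accepts either a band-sequential multi-page TIFF (one single-band page
#' per spectral band) or a directory holding one file per band, named
#' `<BAND>.tif` or `<BAND>.csv` (plain numeric matrix, no header). Integer
#' TIFF digital numbers are rescaled to \[0, 1\] by the file's bit depth;
#' the scale factor is recorded in the stack's provenance.
#'
#' @param path File path of a multiband TIFF, or a directory of per-band
#'   files.
#' @param band_map Character vector mapping band index (page order) to band
#'   name, e.g. `c("BLUE", "GREEN", "RED", "RED_EDGE", "NIR")`. Must cover
#'   `GREEN`, `RED`, `RED_EDGE`, `NIR`. Ignored for directory input, where
#'   file names carry the band names.
#' @param gsd Ground sample distance in cm/pixel.
#' @return A [bandstack()].
#' @export
read_bandstack <- function(path, band_map = c("GREEN", "RED", "RED_EDGE", "NIR"),
                           gsd = 1) {
  required <- c("GREEN", "RED", "RED_EDGE", "NIR")
  if (dir.exists(path)) {
    bands <- list()
    for (nm in c("BLUE", required)) {
      tif <- file.path(path, paste0(nm, ".tif"))
      csv <- file.path(path, paste0(nm, ".csv"))
      if (file.exists(tif)) {
        bands[[nm]] <- as.matrix(tiff::readTIFF(tif))
      } else if (file.exists(csv)) {
        bands[[nm]] <- as.matrix(utils::read.csv(csv, header = FALSE))
      }
    }
    missing <- setdiff(required, names(bands))
    if (length(missing) > 0L) {
      stop("directory ", path, " lacks required band file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    bands <- lapply(bands, unname)
    return(bandstack(bands, gsd_cm_per_px = gsd,
                     provenance = list(source = path, format = "per-band files")))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  missing <- setdiff(required, band_map)
  if (length(missing) > 0L) {
    stop("band_map lacks required band(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < length(band_map)) {
    stop("file has ", length(pages), " band page(s) but band_map names ",
         length(band_map), call. = FALSE)
  }
  bands <- list()
  for (i in seq_along(band_map)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      if (dim(pg)[3] != 1L) {
        stop("band page ", i, " is not single-band", call. = FALSE)
      }
      pg <- pg[, , 1]
    }
    bands[[band_map[i]]] <- pg
  }
  shapes <- unique(vapply(bands, function(b) paste(dim(b), collapse = "x"),
                          character(1)))
  if (length(shapes) != 1L) {
    stop("band pages differ in shape: ", paste(shapes, collapse = " vs "),
         call. = FALSE)
  }
  # tiff::readTIFF already divides integer samples by (2^bits - 1)
  bits <- attr(pages[[1]], "info")$bits.per.sample
  bandstack(bands, gsd_cm_per_px = gsd,
            provenance = list(source = path, format = "multipage TIFF",
                              bits_per_sample = bits,
                              scale = if (!is.null(bits)) 2^bits - 1 else NA))
}

#' Write a band stack as a band-sequential multiband TIFF
#'
#' One single-band 16-bit page per band, in the band order given by
#' `names(stack$bands)`. The written file round-trips through
#' [read_bandstack()] within one 16-bit quantisation step.
#'
#' @param stack A [bandstack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bandstack <- function(stack, path) {
  stopifnot(inherits(stack, "bandstack"))
  ok <- try(tiff::writeTIFF(unname(stack$bands), path,
                            bits.per.sample = 16L), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write TIFF to ", path, ": ", attr(ok, "condition")$message,
         call. = FALSE)
  }
  invisible(path)
}

#' Read a per-slice feature table
#'
#' Expects an RFC-4180 CSV with header columns `slice_id`, `plant_id`,
#' `grid_row`, `grid_col`, one column per vegetation index, and optionally
#' `label` (binary 0/1) and `n_valid_min`.
#'
#' @param path CSV file path.
#' @param required_vis Character vector of VI columns that must be present
#'   (default: all nine).
#' @return Data frame with typed columns; `label`, if present, as integer.
#' @export
read_feature_table <- function(path, required_vis = vi_names()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_vis, names(tab))
  if (length(missing) > 0L) {
    stop("feature table lacks configured VI column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("label" %in% names(tab)) {
    lab <- suppressWarnings(as.integer(tab$label))
    if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
      stop("label column must be binary 0/1", call. = FALSE)
    }
    tab$label <- lab
  }
  tab
}

#' Write a per-slice feature table
#'
#' @param table Data frame of slice features.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
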