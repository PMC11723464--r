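# uniform-band stack: every band constant
uniform_stack <- function(g, r, re, n, side = 8, gsd = 1) {
  bandstack(list(GREEN = matrix(g, side, side),
                 RED = matrix(r, side, side),
                 RED_EDGE = matrix(re, side, side),
                 NIR = matrix(n, side, side)),
            gsd_cm_per_px = gsd)
}

# random-band sub-image with full canopy mask
random_sub_image <- function(side = 16, seed = 1, mask = NULL) {
  withr::with_seed(seed, {
    bands <- lapply(c(GREEN = 1, RED = 2, RED_EDGE = 3, NIR = 4),
                    function(i) matrix(runif(side * side, 0.02, 1), side, side))
    names(bands) <- c("GREEN", "RED", "RED_EDGE", "NIR")
    if (is.null(mask)) mask <- matrix(TRUE, side, side)
    sub_image(bands, mask, "fix", 0, 0, c(0, side, 0, side))
  })
}

# independent slice-mean oracle: explicit per-pixel loop over the formulas
oracle_vi_slice_mean <- function(sub, name, L = 0.5, eps = 1e-9,
                                 use_mask = TRUE) {
  vals <- c()
  for (i in seq_len(nrow(sub$mask))) {
    for (j in seq_len(ncol(sub$mask))) {
      if (use_mask && !sub$mask[i, j]) next
      g <- sub$bands$GREEN[i, j]; r <- sub$bands$RED[i, j]
      re <- sub$bands$RED_EDGE[i, j]; n <- sub$bands$NIR[i, j]
      v <- switch(name,
        ndvi = if (abs(n + r) < eps) NA else (n - r) / (n + r),
        gndvi = if (abs(n + g) < eps) NA else (n - g) / (n + g),
        gci = if (abs(g) < eps) NA else n / g - 1,
        ndrei = if (abs(n + re) < eps) NA else (n - re) / (n + re),
        reci = if (abs(re) < eps) NA else n / re - 1,
        nri = if (abs(g + r) < eps) NA else (g - r) / (g + r),
        gi = if (abs(r) < eps) NA else g / r,
        tcari = if (abs(r) < eps) NA else
          3 * ((re - r) - 0.2 * (re - g) * (re / r)),
        savi = if (abs(n + r + L) < eps) NA else
          (1 + L) * (n - r) / (n + r + L))
      if (!is.na(v)) vals <- c(vals, v)
    }
  }
  list(mean = mean(vals), n_valid = length(vals))
}

# scenario used in small rendering tests
tiny_scenario <- function(...) {
  orchard_scenario(n_plants = 2, seed = 1, ...)
}
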