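test_that("ndvi_map matches the closed form and flags invalid pixels", {
  st <- uniform_stack(0.1, 0.1, 0.3, 0.5, side = 4)
  expect_equal(ndvi_map(st)[1, 1], 2 / 3, tolerance = 1e-6)
  z <- uniform_stack(0.1, 0.02, 0.3, 0.02, side = 4)
  z$bands$RED[] <- 0; z$bands$NIR[] <- 0
  expect_true(all(is.na(ndvi_map(z))))
})

test_that("soil_mask applies the strict-less-than exclusion rule", {
  nd <- matrix(c(0.19, 0.2, 0.21, NA), 2, 2)
  m <- soil_mask(nd, segmentation_config(ndvi_threshold = 0.2))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(attr(m, "canopy_fraction"), 0.5)
})

test_that("raising the NDVI threshold never increases canopy fraction", {
  nd <- withr::with_seed(21, matrix(runif(400, -0.2, 0.9), 20, 20))
  fracs <- vapply(seq(0, 0.8, by = 0.1), function(th) {
    attr(soil_mask(nd, segmentation_config(ndvi_threshold = th)),
         "canopy_fraction")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("hierarchical_filter closes holes and removes nested contours", {
  f <- matrix(FALSE, 32, 32)
  rr <- row(f); cc <- col(f)
  # disc with a small hole: hole is closed
  disc <- (rr - 16)^2 + (cc - 16)^2 <= 10^2
  holey <- disc & !((rr - 16)^2 + (cc - 16)^2 <= 2^2)
  out <- hierarchical_filter(holey)
  expect_identical(unclass(out)[, ], disc)
  # two disjoint discs: both retained
  two <- ((rr - 8)^2 + (cc - 8)^2 <= 4^2) |
    ((rr - 24)^2 + (cc - 24)^2 <= 4^2)
  expect_identical(unclass(hierarchical_filter(two))[, ], two)
  # ring B strictly inside the hole of annulus A: B removed, A filled
  A <- (rr - 16)^2 + (cc - 16)^2 <= 14^2 & (rr - 16)^2 + (cc - 16)^2 >= 9^2
  B <- (rr - 16)^2 + (cc - 16)^2 <= 6^2 & (rr - 16)^2 + (cc - 16)^2 >= 4^2
  expected <- (rr - 16)^2 + (cc - 16)^2 <= 14^2
  expect_identical(unclass(hierarchical_filter(A | B))[, ], expected)
  # containment oracle: brute-force labelling confirms B is inside A's fill
  lab <- hazelhealth:::label_components(A | B, 8L)
  fillA <- hazelhealth:::fill_holes(lab == lab[16, 3], 8L)
  expect_true(all(fillA[B]))
  # empty mask returned unchanged with a warning
  expect_warning(e <- hierarchical_filter(matrix(FALSE, 4, 4)), "empty")
  expect_false(any(e))
})

test_that("hierarchical_filter is idempotent on random blob masks", {
  withr::with_seed(22, {
    for (i in 1:5) {
      m <- matrix(runif(900) < 0.35, 30, 30)
      h1 <- suppressWarnings(hierarchical_filter(m))
      h2 <- suppressWarnings(hierarchical_filter(h1))
      expect_identical(unclass(h1)[, ], unclass(h2)[, ])
    }
  })
})

test_that("connected-component labelling agrees with EBImage (4-conn)", {
  skip_if_not_installed("EBImage")
  withr::with_seed(23, {
    for (i in 1:10) {
      m <- matrix(runif(32 * 32) < 0.4, 32, 32)
      mine <- hazelhealth:::label_components(m, 4L)
      ref <- EBImage::bwlabel(m * 1)
      expect_identical(max(mine), as.integer(max(ref)))
      # identical partition: each reference component maps to one label
      expect_true(all(tapply(ref[m], mine[m],
                             function(x) length(unique(x))) == 1))
    }
  })
})

test_that("slice_grid tiles the frame exactly with floor boundaries", {
  st <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = 400)
  mask <- matrix(TRUE, 400, 400)
  slices <- slice_grid(st, mask, segmentation_config())
  expect_length(slices, 9L)
  rb <- unique(unlist(lapply(slices, function(s) s$window[1:2])))
  expect_identical(sort(rb), c(0L, 133L, 266L, 400L))
  # windows are disjoint and their union is the full frame
  cover <- matrix(0L, 400, 400)
  for (s in slices) {
    cover[(s$window[1] + 1):s$window[2], (s$window[3] + 1):s$window[4]] <-
      cover[(s$window[1] + 1):s$window[2],
            (s$window[3] + 1):s$window[4]] + 1L
  }
  expect_true(all(cover == 1L))
  sizes <- vapply(slices, function(s) diff(s$window[1:2]), integer(1))
  expect_true(all(sizes %in% c(133L, 134L)))
  # divisible case: all slices equal
  st2 <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = 402)
  s2 <- slice_grid(st2, matrix(TRUE, 402, 402), segmentation_config())
  expect_true(all(vapply(s2, function(s) diff(s$window[1:2]), integer(1)) ==
                    134L))
  # grid larger than image is an input error
  st3 <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = 2)
  expect_error(slice_grid(st3, matrix(TRUE, 2, 2), segmentation_config()),
               "smaller")
})

test_that("tiling exactness holds for odd sizes and non-square grids", {
  for (side in c(10, 41, 100)) {
    st <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = side)
    cfg <- segmentation_config(grid_rows = 3L, grid_cols = 4L)
    slices <- slice_grid(st, matrix(TRUE, side, side), cfg)
    cover <- matrix(0L, side, side)
    for (s in slices) {
      cover[(s$window[1] + 1):s$window[2], (s$window[3] + 1):s$window[4]] <-
        cover[(s$window[1] + 1):s$window[2],
              (s$window[3] + 1):s$window[4]] + 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("drop_soil_slices keeps the >= boundary and is monotone", {
  st <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = 30)
  mask <- matrix(FALSE, 30, 30)
  mask[1:15, ] <- TRUE            # top half canopy
  slices <- slice_grid(st, mask, segmentation_config())
  # slice canopy fractions are 1, 1, 1, .5, .5, .5, 0, 0, 0
  kept <- suppressMessages(drop_soil_slices(slices, segmentation_config()))
  expect_length(kept, 6L)   # 0.5 slices retained under the >= rule
  counts <- vapply(c(0, 0.3, 0.5, 0.8, 1), function(th) {
    length(suppressMessages(drop_soil_slices(
      slices, segmentation_config(min_canopy_fraction = th))))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("geometric_crop windows, pads and validates", {
  st <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = 400)
  # trunk at centre of a 400 px scene at 4 m spacing, 1 cm/px: identity
  crop <- geometric_crop(st, c(200, 200), spacing_m = 4)
  expect_identical(c(crop$height, crop$width), c(400L, 400L))
  expect_equal(crop$bands$NIR, st$bands$NIR)
  # trunk near the edge: zero-padded margin with a warning
  expect_warning(near <- geometric_crop(st, c(10, 200), spacing_m = 4),
                 "padding")
  expect_identical(c(near$height, near$width), c(400L, 400L))
  expect_true(all(near$bands$NIR[1:10, ] == 0))
  expect_error(geometric_crop(st, c(500, 200)), "outside")
  # side length follows round(spacing * 100 / gsd)
  st2 <- uniform_stack(0.1, 0.06, 0.3, 0.5, side = 250, gsd = 2)
  crop2 <- geometric_crop(st2, c(125, 125), spacing_m = 4)
  expect_identical(crop2$height, 200L)
})

test_that("soil precision: >= 99% of ground-truth soil pixels are masked out", {
  rp <- render_plant(tiny_scenario(), matrix(0L, 3, 3),
                     make_default_profiles(), seed = 7)
  mask <- soil_mask(ndvi_map(rp$stack), segmentation_config())
  soil_px <- rp$truth$class_map == 0L
  expect_gte(mean(!mask[soil_px]), 0.99)
})
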