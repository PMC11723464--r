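test_that("per-pixel index formulas match hand-computed values", {
  cfg <- vi_config()
  expect_equal(compute_vi_pixel("ndvi", r = 0.1, n = 0.5, cfg = cfg),
               0.666667, tolerance = 1e-6)
  expect_equal(compute_vi_pixel("ndvi", r = 0.3, n = 0.3, cfg = cfg), 0)
  expect_equal(compute_vi_pixel("ndvi", r = 0, n = 0.5, cfg = cfg), 1)
  expect_equal(compute_vi_pixel("gci", g = 0.1, n = 0.5, cfg = cfg), 4)
  expect_equal(compute_vi_pixel("gi", g = 0.2, r = 0.2, cfg = cfg), 1)
  expect_equal(compute_vi_pixel("nri", g = 0.2, r = 0.2, cfg = cfg), 0)
  expect_equal(compute_vi_pixel("ndrei", re = 0.4, n = 0.4, cfg = cfg), 0)
  expect_error(compute_vi_pixel("evi", g = 1, r = 1, re = 1, n = 1, cfg = cfg),
               "unknown")
})

test_that("denominator guard flags invalid pixels instead of clamping", {
  cfg <- vi_config(epsilon = 1e-9)
  expect_true(is.na(compute_vi_pixel("gi", g = 0.5, r = 0, cfg = cfg)))
  expect_true(is.na(compute_vi_pixel("gci", g = 0, n = 0.5, cfg = cfg)))
  expect_true(is.na(compute_vi_pixel("ndvi", r = 0, n = 0, cfg = cfg)))
  # guard threshold honours configured epsilon
  cfg2 <- vi_config(epsilon = 0.01)
  expect_true(is.na(compute_vi_pixel("gi", g = 0.5, r = 0.005, cfg = cfg2)))
  expect_false(is.na(compute_vi_pixel("gi", g = 0.5, r = 0.05, cfg = cfg2)))
})

test_that("SAVI with L = 0 equals NDVI pixel-wise", {
  cfg <- vi_config(L = 0)
  withr::with_seed(4, {
    for (i in 1:50) {
      n <- runif(1); r <- runif(1)
      expect_equal(compute_vi_pixel("savi", r = r, n = n, cfg = cfg),
                   compute_vi_pixel("ndvi", r = r, n = n, cfg = cfg),
                   tolerance = 1e-12)
    }
  })
})

test_that("normalized-difference indices are antisymmetric under band swap", {
  withr::with_seed(5, {
    a <- runif(20, 0.05, 1); b <- runif(20, 0.05, 1)
  })
  cfg <- vi_config()
  expect_equal(compute_vi_pixel("ndvi", r = b, n = a, cfg = cfg),
               -compute_vi_pixel("ndvi", r = a, n = b, cfg = cfg))
  expect_equal(compute_vi_pixel("gndvi", g = b, n = a, cfg = cfg),
               -compute_vi_pixel("gndvi", g = a, n = b, cfg = cfg))
  expect_equal(compute_vi_pixel("ndrei", re = b, n = a, cfg = cfg),
               -compute_vi_pixel("ndrei", re = a, n = b, cfg = cfg))
  expect_equal(compute_vi_pixel("nri", g = a, r = b, cfg = cfg),
               -compute_vi_pixel("nri", g = b, r = a, cfg = cfg))
})

test_that("ratio and normalized indices are scale invariant; SAVI is not", {
  withr::with_seed(6, {
    g <- runif(10, 0.05, 0.5); r <- runif(10, 0.05, 0.5)
    re <- runif(10, 0.05, 0.5); n <- runif(10, 0.05, 0.5)
  })
  cfg <- vi_config(L = 0.5)
  for (vi in c("ndvi", "gndvi", "gci", "ndrei", "reci", "nri", "gi")) {
    expect_equal(
      compute_vi_pixel(vi, 1.7 * g, 1.7 * r, 1.7 * re, 1.7 * n, cfg),
      compute_vi_pixel(vi, g, r, re, n, cfg), tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(
    compute_vi_pixel("savi", 1.7 * g, 1.7 * r, 1.7 * re, 1.7 * n, cfg),
    compute_vi_pixel("savi", g, r, re, n, cfg))))
})

test_that("both TCARI variants agree with their closed forms", {
  g <- 0.1; r <- 0.06; re <- 0.3
  std <- compute_vi_pixel("tcari", g, r, re, 0.5, vi_config())
  expect_equal(std, 3 * ((re - r) - 0.2 * (re - g) * (re / r)))
  lit <- compute_vi_pixel("tcari", g, r, re, 0.5,
                          vi_config(tcari_variant = "paper_literal"))
  expect_equal(lit, 3 * ((re - r) - 0.2 * (r - g) * (re / r)))
})

test_that("slice means equal the brute-force pixel-loop oracle", {
  for (seed in 1:4) {
    mask <- withr::with_seed(100 + seed,
                             matrix(runif(256) > 0.3, 16, 16))
    sub <- random_sub_image(16, seed = seed, mask = mask)
    for (vi in vi_names()) {
      got <- compute_vi_slice(sub, vi, vi_config())
      exp <- oracle_vi_slice_mean(sub, vi)
      expect_equal(got$mean, exp$mean, tolerance = 1e-10,
                   label = paste(vi, "mean"))
      expect_identical(got$n_valid, as.integer(exp$n_valid))
    }
  }
})

test_that("uniform and degenerate slices aggregate as specified", {
  sub <- random_sub_image(8, seed = 1)
  for (b in names(sub$bands)) sub$bands[[b]][] <- c(GREEN = 0.1, RED = 0.1,
                                                    RED_EDGE = 0.3,
                                                    NIR = 0.5)[b]
  got <- compute_vi_slice(sub, "ndvi", vi_config())
  expect_equal(got$mean, 2 / 3, tolerance = 1e-6)
  expect_identical(got$n_valid, 64L)
  # fully soil-masked slice: no valid pixel, flagged mean
  sub$mask[] <- FALSE
  got2 <- compute_vi_slice(sub, "ndvi", vi_config(use_mask = TRUE))
  expect_identical(got2$n_valid, 0L)
  expect_true(is.na(got2$mean))
  # use_mask = FALSE averages over all pixels regardless
  got3 <- compute_vi_slice(sub, "ndvi", vi_config(use_mask = FALSE))
  expect_identical(got3$n_valid, 64L)
})

test_that("checkerboard slice mean is the average of the two pixel values", {
  side <- 8
  chk <- outer(1:side, 1:side, function(i, j) (i + j) %% 2 == 0)
  bands <- list(GREEN = ifelse(chk, 0.1, 0.2), RED = ifelse(chk, 0.05, 0.1),
                RED_EDGE = ifelse(chk, 0.3, 0.25),
                NIR = ifelse(chk, 0.5, 0.4))
  sub <- sub_image(bands, matrix(TRUE, side, side), "chk", 0, 0,
                   c(0, side, 0, side))
  for (vi in vi_names()) {
    v1 <- compute_vi_pixel(vi, 0.1, 0.05, 0.3, 0.5, vi_config())
    v2 <- compute_vi_pixel(vi, 0.2, 0.1, 0.25, 0.4, vi_config())
    expect_equal(compute_vi_slice(sub, vi, vi_config())$mean, (v1 + v2) / 2,
                 tolerance = 1e-10)
  }
})

test_that("compute_all_vi is pure and satisfies the record invariants", {
  sub <- random_sub_image(8, seed = 2)
  expect_identical(compute_all_vi(sub), compute_all_vi(sub))
  withr::with_seed(11, {
    for (i in 1:300) {
      s <- random_sub_image(3, seed = i + 1000)
      rec <- compute_all_vi(s)
      expect_true(all(abs(unlist(rec[c("ndvi", "gndvi", "ndrei", "nri")])) <= 1))
      expect_true(rec$gci >= -1 && rec$reci >= -1)
      expect_true(rec$gi > 0)
      expect_true(rec$n_valid_min <= 9L)
    }
  })
})

test_that("separation report computes quartiles, d and selection correctly", {
  withr::with_seed(12, {
    n <- 200
    recs <- data.frame(ndvi = rnorm(n), gndvi = c(rnorm(n / 2, 2),
                                                  rnorm(n / 2, 0)))
    labels <- rep(c(0L, 1L), each = n / 2)
  })
  rep <- separation_report(recs, labels, threshold_d = 0.5)
  # identical distributions: |d| small, not selected
  expect_lt(abs(rep$d[rep$vi == "ndvi"]), 0.3)
  expect_false(rep$selected[rep$vi == "ndvi"])
  # strongly separated feature: large positive d (healthy higher), selected
  expect_gt(rep$d[rep$vi == "gndvi"], 1.5)
  expect_true(rep$selected[rep$vi == "gndvi"])
  # quartiles match stats::quantile per class
  expect_equal(rep$q50_0[rep$vi == "gndvi"],
               median(recs$gndvi[labels == 0]))
  expect_error(separation_report(recs, rep(0L, n)), "both classes")
})

test_that("NDVI is deselected along with SAVI even when its own d passes", {
  withr::with_seed(13, {
    n <- 400
    base <- rep(c(1, 0), each = n / 2)
    recs <- data.frame(ndvi = base + rnorm(n, 0, 0.8),   # d ~ 1.2
                       savi = rnorm(n))                  # d ~ 0
    labels <- rep(c(0L, 1L), each = n / 2)
  })
  rep <- separation_report(recs, labels, threshold_d = 0.5)
  expect_true(rep$passes_threshold[rep$vi == "ndvi"])
  expect_false(rep$selected[rep$vi == "ndvi"])
  expect_false("ndvi" %in% selected_vis(rep))
})
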