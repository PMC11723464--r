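#' Spectral profile of a ground-cover class
#'
#' Mean reflectance per band plus the pixel-level noise model for one of the
#' three rendered classes (soil, healthy canopy, unhealthy canopy). Pixel
#' noise has two components: a multiplicative log-normal speckle shared
#' across bands (brightness texture: shadow, leaf angle, soil roughness) and
#' an independent additive Gaussian term per band. A `contamination_fraction`
#' of pixels is drawn with both noise standard deviations inflated threefold,
#' giving heavy-tailed pixel noise.
#'
#' @param name One of `"soil"`, `"healthy"`, `"unhealthy"`.
#' @param means Named numeric vector of mean reflectances for `GREEN`,
#'   `RED`, `RED_EDGE`, `NIR`, each in (0, 1).
#' @param band_sd Additive per-band noise standard deviation (>= 0).
#' @param speckle_sd Standard deviation of the log-normal multiplicative
#'   speckle (>= 0).
#' @param contamination_fraction Fraction of pixels with x3 inflated noise,
#'   in \[0, 0.5\].
#' @return An object of class `spectral_profile`.
#' @export
spectral_profile <- function(name, means, band_sd = 0.03, speckle_sd = 0.04,
                             contamination_fraction = 0.05) {
  stopifnot(name %in% c("soil", "healthy", "unhealthy"),
            all(c("GREEN", "RED", "RED_EDGE", "NIR") %in% names(means)),
            all(means > 0 & means < 1),
            band_sd >= 0, speckle_sd >= 0,
            contamination_fraction >= 0, contamination_fraction <= 0.5)
  ndvi <- (means[["NIR"]] - means[["RED"]]) / (means[["NIR"]] + means[["RED"]])
  if (name == "soil" && ndvi >= 0.2) {
    stop("soil profile must have NDVI(means) < 0.2, got ", round(ndvi, 3),
         call. = FALSE)
  }
  if (name != "soil" && ndvi <= 0.3) {
    stop("canopy profile must have NDVI(means) > 0.3, got ", round(ndvi, 3),
         call. = FALSE)
  }
  structure(list(name = name, means = means, band_sd = band_sd,
                 speckle_sd = speckle_sd,
                 contamination_fraction = contamination_fraction),
            class = "spectral_profile")
}

#' Default soil / healthy / unhealthy spectral profiles
#'
#' The default class means are chosen so that soil NDVI (0.149) falls below
#' the 0.2 soil-masking threshold, both canopy classes exceed NDVI 0.3, the
#' healthy canopy has the higher NIR plateau and red edge, and the unhealthy
#' canopy shows the raised green / lowered red reflectance of chlorotic,
#' wilting foliage (hence higher NRI and GI). Together with the rendering
#' heterogeneity in [orchard_scenario()], these defaults are calibrated so
#' that on a default synthetic dataset the slice-level distributions of
#' GNDVI, GCI, NDREI, NRI and GI separate the classes strongly
#' (|Cohen's d| >= 0.8) while NDVI, SAVI, RECI and TCARI do not (<= 0.4).
#'
#' @return Named list with elements `soil`, `healthy`, `unhealthy`.
#' @export
make_default_profiles <- function() {
  list(
    soil = spectral_profile(
      "soil",
      means = c(GREEN = 0.18, RED = 0.20, RED_EDGE = 0.25, NIR = 0.27),
      band_sd = 0.004, speckle_sd = 0.03, contamination_fraction = 0.05),
    healthy = spectral_profile(
      "healthy",
      means = c(GREEN = 0.10, RED = 0.06, RED_EDGE = 0.32, NIR = 0.50),
      band_sd = 0.04, speckle_sd = 0.05, contamination_fraction = 0.05),
    unhealthy = spectral_profile(
      "unhealthy",
      means = c(GREEN = 0.24, RED = 0.10, RED_EDGE = 0.63, NIR = 0.64),
      band_sd = 0.04, speckle_sd = 0.05, contamination_fraction = 0.05)
  )
}

#' Synthetic orchard scenario
#'
#' Describes the geometry and statistical structure of a simulated orchard:
#' planting density and image scale, canopy size, the prevalence of
#' unhealthy quadrants (optionally one value per acquisition time point),
#' and the slice-level heterogeneity that real orchard imagery exhibits on
#' top of pixel noise. The heterogeneity mechanisms are:
#' \itemize{
#'   \item canopy gaps: interior holes exposing soil through the crown
#'     (fraction per quadrant, Gaussian-jittered around `gap_mean`);
#'   \item canopy condition: per-quadrant mixing of the canopy spectrum
#'     toward the soil spectrum (sparse or dusty foliage);
#'   \item per-plant brightness: a log-normal illumination factor;
#'   \item red-edge stress: a random subset of quadrants with suppressed
#'     red-edge reflectance, affecting both classes alike;
#'   \item severity: unhealthy patches interpolate a random distance
#'     between the healthy and unhealthy spectral endpoints.
#' }
#' `heterogeneity` scales all five mechanisms jointly (0 = deterministic
#' class spectra, 1 = calibrated default).
#'
#' @param n_plants Number of plants per time point (> 0).
#' @param spacing_m Trunk spacing in metres (default 4; one image covers one
#'   spacing cell).
#' @param gsd_cm_per_px Ground sample distance (default 1 cm/px).
#' @param canopy_radius_m,canopy_radius_sd_m Mean and sd of the main crown
#'   radius in metres.
#' @param prevalence_unhealthy Probability that a quadrant is unhealthy;
#'   a vector gives one acquisition time point per value.
#' @param single_quadrant_fraction Fraction of plants forced to have exactly
#'   one unhealthy quadrant (default 0.1).
#' @param seed Integer seed; fixes the full dataset.
#' @param heterogeneity Scale factor on slice-level variability (default 1).
#' @param patch_fraction Fraction of a labelled quadrant's canopy rendered
#'   as the unhealthy patch (default 0.6).
#' @param gap_mean,gap_sd Per-quadrant canopy gap fraction: mean and sd.
#' @param condition_mean,condition_sd Per-quadrant soil-mixing weight of the
#'   canopy spectrum: mean and sd.
#' @param brightness_sd Log-scale sd of the per-plant brightness factor.
#' @param shade_sd Half-normal log-scale spread of the per-quadrant shading
#'   factor (crown self-shading darkens quadrants multiplicatively across
#'   all bands).
#' @param re_stress_prob Probability a quadrant is red-edge stressed.
#' @param re_stress_range Two-element range of the red-edge suppression
#'   factor for stressed quadrants.
#' @param severity_range Two-element range of the unhealthy severity draw.
#' @return An object of class `orchard_scenario`.
#' @export
orchard_scenario <- function(n_plants,
                             spacing_m = 4,
                             gsd_cm_per_px = 1,
                             canopy_radius_m = 2.0,
                             canopy_radius_sd_m = 0.15,
                             prevalence_unhealthy = 0.5,
                             single_quadrant_fraction = 0.1,
                             seed = 0L,
                             heterogeneity = 1,
                             patch_fraction = 0.6,
                             gap_mean = 0.32,
                             gap_sd = 0.26,
                             condition_mean = 0.10,
                             condition_sd = 0.07,
                             brightness_sd = 0.25,
                             shade_sd = 0,
                             re_stress_prob = 0.02,
                             re_stress_range = c(0.05, 0.15),
                             severity_range = c(0.7, 1),
                             grid_rows = 3L, grid_cols = 3L) {
  stopifnot(n_plants > 0, spacing_m > 0, gsd_cm_per_px > 0,
            canopy_radius_m > 0,
            all(prevalence_unhealthy >= 0 & prevalence_unhealthy <= 1),
            single_quadrant_fraction >= 0, single_quadrant_fraction <= 1,
            heterogeneity >= 0, patch_fraction > 0, patch_fraction <= 1)
  structure(list(n_plants = as.integer(n_plants), spacing_m = spacing_m,
                 gsd_cm_per_px = gsd_cm_per_px,
                 canopy_radius_m = canopy_radius_m,
                 canopy_radius_sd_m = canopy_radius_sd_m,
                 prevalence_unhealthy = prevalence_unhealthy,
                 single_quadrant_fraction = single_quadrant_fraction,
                 seed = as.integer(seed), heterogeneity = heterogeneity,
                 patch_fraction = patch_fraction,
                 gap_mean = gap_mean, gap_sd = gap_sd,
                 condition_mean = condition_mean, condition_sd = condition_sd,
                 brightness_sd = brightness_sd,
                 shade_sd = shade_sd,
                 re_stress_prob = re_stress_prob,
                 re_stress_range = re_stress_range,
                 severity_range = severity_range,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "orchard_scenario")
}

#' Plant image side length implied by a scenario
#' @param scenario An [orchard_scenario()].
#' @return Side length in pixels.
#' @export
scenario_side_px <- function(scenario) {
  as.integer(round(scenario$spacing_m * 100 / scenario$gsd_cm_per_px))
}

# quadrant index matrix (1..rows*cols, row-major) for a side x side image
quadrant_index <- function(nrow, ncol, rows, cols) {
  rb <- floor((0:rows) * nrow / rows)
  cb <- floor((0:cols) * ncol / cols)
  qi <- findInterval(seq_len(nrow) - 1L, rb, rightmost.closed = FALSE)
  qj <- findInterval(seq_len(ncol) - 1L, cb, rightmost.closed = FALSE)
  qi <- pmin(qi, rows); qj <- pmin(qj, cols)
  outer(qi - 1L, qj - 1L, function(a, b) a * cols + b + 1L)
}

#' Draw per-quadrant health labels for an orchard
#'
#' Quadrant labels are i.i.d. Bernoulli(`prevalence`) except for a
#' `single_quadrant_fraction` subset of plants, which receive exactly one
#' unhealthy quadrant at a uniformly random grid position (the
#' localized-symptom case that motivates slicing whole-tree images).
#'
#' @param n_plants Number of plants.
#' @param prevalence Scalar Bernoulli probability.
#' @param single_quadrant_fraction Fraction of plants with exactly one
#'   unhealthy quadrant.
#' @param seed Integer seed.
#' @param grid_rows,grid_cols Label grid dimensions (default 3 x 3).
#' @return List of `grid_rows x grid_cols` 0/1 integer matrices.
#' @export
draw_quadrant_labels <- function(n_plants, prevalence,
                                 single_quadrant_fraction = 0,
                                 seed = 0L, grid_rows = 3L, grid_cols = 3L) {
  nq <- grid_rows * grid_cols
  withr::with_seed(seed, {
    n_single <- round(single_quadrant_fraction * n_plants)
    singles <- if (n_single > 0) sample.int(n_plants, n_single) else integer(0)
    lapply(seq_len(n_plants), function(i) {
      lab <- if (i %in% singles) {
        v <- integer(nq); v[sample.int(nq, 1L)] <- 1L; v
      } else {
        stats::rbinom(nq, 1L, prevalence)
      }
      matrix(lab, grid_rows, grid_cols, byrow = TRUE)
    })
  })
}

#' Render one synthetic plant image with ground truth
#'
#' Produces a square multispectral image of side
#' `round(spacing_m * 100 / gsd_cm_per_px)` pixels: soil background, a
#' bush-like compound canopy (union of a central disc and several satellite
#' discs), interior canopy gaps, and a contiguous unhealthy patch in every
#' quadrant labelled 1. Pixel values are the class spectra modulated by the
#' scenario's slice-level heterogeneity plus speckle and band noise, clipped
#' to \[0.02, 1\] (a small reflectance floor mimicking the sensor dark
#' level and keeping band ratios bounded).
#'
#' @param scenario An [orchard_scenario()].
#' @param quadrant_labels 3 x 3 (or `grid_rows x grid_cols`) 0/1 matrix.
#' @param profiles As from [make_default_profiles()].
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return List with `stack` (a [bandstack()]) and `truth` (class
#'   `ground_truth`: `class_map` with 0 = soil, 1 = healthy, 2 = unhealthy;
#'   `quadrant_labels`; `plant_label`).
#' @export
render_plant <- function(scenario, quadrant_labels,
                         profiles = make_default_profiles(), seed = 0L) {
  stopifnot(inherits(scenario, "orchard_scenario"),
            all(quadrant_labels %in% c(0L, 1L)))
  side <- scenario_side_px(scenario)
  rows <- scenario$grid_rows; cols <- scenario$grid_cols
  het <- scenario$heterogeneity
  bandn <- c("GREEN", "RED", "RED_EDGE", "NIR")
  withr::with_seed(seed, {
    rr <- matrix(seq_len(side), side, side)
    cc <- matrix(seq_len(side), side, side, byrow = TRUE)
    ctr <- (side + 1) / 2

    # compound canopy: central disc + 4-8 satellites
    r0 <- max(scenario$canopy_radius_m +
                stats::rnorm(1, 0, scenario$canopy_radius_sd_m), 1.0) *
      100 / scenario$gsd_cm_per_px
    if (r0 > 0.75 * side) {
      warning("canopy radius far exceeds the image frame; canopy clipped")
    }
    cy <- ctr + stats::rnorm(1, 0, 4); cx <- ctr + stats::rnorm(1, 0, 4)
    canopy <- (rr - cy)^2 + (cc - cx)^2 <= r0^2
    for (k in seq_len(sample(4:8, 1))) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 0.3, 0.6) * r0
      rk <- stats::runif(1, 0.35, 0.6) * r0
      oy <- cy + off * sin(ang); ox <- cx + off * cos(ang)
      canopy <- canopy | ((rr - oy)^2 + (cc - ox)^2 <= rk^2)
    }

    qidx <- quadrant_index(side, side, rows, cols)
    nq <- rows * cols
    lab_vec <- as.integer(t(quadrant_labels))  # row-major quadrant order

    # per-quadrant heterogeneity draws
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    gap_q <- clamp(stats::rnorm(nq, scenario$gap_mean,
                                scenario$gap_sd * het), 0, 0.45)
    cond_q <- clamp(stats::rnorm(nq, scenario$condition_mean,
                                 scenario$condition_sd * het), 0, 0.7)
    stressed <- stats::runif(nq) < scenario$re_stress_prob
    e_q <- ifelse(stressed,
                  stats::runif(nq, scenario$re_stress_range[1],
                               scenario$re_stress_range[2]), 1)
    e_q <- clamp(1 - (1 - e_q) * het, 0.02, 1)
    sev_q <- stats::runif(nq, scenario$severity_range[1],
                          scenario$severity_range[2])
    sev_q <- clamp(1 - (1 - sev_q) * het, 0, 1)
    bright <- clamp(exp(stats::rnorm(1, 0, scenario$brightness_sd * het)),
                    0.5, 2)
    shade_q <- exp(-abs(stats::rnorm(nq, 0, scenario$shade_sd * het)))

    # canopy gaps: soil-filled holes inside the crown, per quadrant
    gap <- matrix(FALSE, side, side)
    for (q in seq_len(nq)) {
      in_q <- which(canopy & qidx == q)
      target <- round(gap_q[q] * length(in_q))
      if (target < 1L || length(in_q) < 50L) next
      tries <- 0L
      while (sum(gap[in_q]) < target && tries < 200L) {
        ci <- in_q[sample.int(length(in_q), 1L)]
        gy <- (ci - 1L) %% side + 1L; gx <- (ci - 1L) %/% side + 1L
        gr <- stats::runif(1, 2, 6)
        ys <- max(1L, gy - 6L):min(side, gy + 6L)
        xs <- max(1L, gx - 6L):min(side, gx + 6L)
        gap[ys, xs] <- gap[ys, xs] |
          (outer((ys - gy)^2, (xs - gx)^2, `+`) <= gr^2)
        tries <- tries + 1L
      }
    }
    gap <- gap & canopy
    veg <- canopy & !gap

    # unhealthy patches: nearest patch_fraction of a quadrant's vegetation
    # pixels to a random seed pixel -> one contiguous patch per quadrant
    unhealthy <- matrix(FALSE, side, side)
    realized <- integer(nq)
    for (q in which(lab_vec == 1L)) {
      in_q <- which(veg & qidx == q)
      if (length(in_q) == 0L) next
      sp <- in_q[sample.int(length(in_q), 1L)]
      sy <- (sp - 1L) %% side + 1L; sx <- (sp - 1L) %/% side + 1L
      d2 <- (((in_q - 1L) %% side + 1L) - sy)^2 +
        (((in_q - 1L) %/% side + 1L) - sx)^2
      take <- in_q[order(d2)][seq_len(max(1L,
                round(scenario$patch_fraction * length(in_q))))]
      unhealthy[take] <- TRUE
      realized[q] <- 1L
    }
    if (any(lab_vec == 1L & realized == 0L)) {
      warning("quadrant(s) labelled unhealthy contain no canopy; ",
              "label reset to 0 in ground truth")
    }
    lab_out <- matrix(ifelse(lab_vec == 1L & realized == 1L, 1L, 0L),
                      rows, cols, byrow = TRUE)

    class_map <- matrix(0L, side, side)
    class_map[veg] <- 1L
    class_map[unhealthy] <- 2L

    # per-pixel spectral means, then noise
    soil_m <- profiles$soil$means
    h_m <- profiles$healthy$means
    u_m <- profiles$unhealthy$means
    is_soil <- class_map == 0L
    is_unh <- class_map == 2L
    contam_p <- matrix(profiles$healthy$contamination_fraction, side, side)
    contam_p[is_soil] <- profiles$soil$contamination_fraction
    contam <- matrix(stats::runif(side * side), side, side) < contam_p
    infl <- matrix(1, side, side); infl[contam] <- 3
    sp_sd <- matrix(profiles$healthy$speckle_sd, side, side)
    sp_sd[is_soil] <- profiles$soil$speckle_sd
    speckle <- exp(stats::rnorm(side * side, 0, 1) * sp_sd * infl)

    cond_px <- matrix(cond_q[qidx], side, side)
    sev_px <- matrix(sev_q[qidx], side, side)
    e_px <- matrix(e_q[qidx], side, side)
    shade_px <- matrix(shade_q[qidx], side, side)
    bands <- list()
    for (b in bandn) {
      class_mean <- matrix(h_m[[b]], side, side)
      class_mean[is_unh] <- h_m[[b]] +
        sev_px[is_unh] * (u_m[[b]] - h_m[[b]])
      if (b == "RED_EDGE") class_mean <- class_mean * e_px
      mu <- (1 - cond_px) * class_mean + cond_px * soil_m[[b]]
      mu[is_soil] <- soil_m[[b]]
      b_sd <- matrix(profiles$healthy$band_sd, side, side)
      b_sd[is_soil] <- profiles$soil$band_sd
      v <- bright * shade_px * mu * speckle +
        stats::rnorm(side * side, 0, 1) * b_sd * infl
      bands[[b]] <- matrix(pmin(pmax(v, 0.02), 1), side, side)
    }
    truth <- structure(list(class_map = class_map,
                            quadrant_labels = lab_out,
                            plant_label = as.integer(any(lab_out == 1L))),
                       class = "ground_truth")
    list(stack = bandstack(bands, gsd_cm_per_px = scenario$gsd_cm_per_px,
                           provenance = list(source = "synthetic",
                                             seed = seed)),
         truth = truth)
  })
}

#' Generate a full synthetic orchard dataset
#'
#' One rendered plant per `n_plants` and per prevalence value (a prevalence
#' vector models repeated acquisitions with seasonal drift in the
#' healthy:unhealthy ratio). Per-plant seeds are derived deterministically
#' from `scenario$seed`.
#'
#' @param scenario An [orchard_scenario()].
#' @param profiles As from [make_default_profiles()].
#' @return List of per-plant records: `plant_id`, `time_point`, `stack`,
#'   `truth`.
#' @export
generate_dataset <- function(scenario, profiles = make_default_profiles()) {
  stopifnot(inherits(scenario, "orchard_scenario"))
  if (scenario$n_plants <= 0L) stop("n_plants must be positive", call. = FALSE)
  out <- list()
  pid <- 0L
  for (tp in seq_along(scenario$prevalence_unhealthy)) {
    prev <- scenario$prevalence_unhealthy[tp]
    labels <- draw_quadrant_labels(scenario$n_plants, prev,
                                   scenario$single_quadrant_fraction,
                                   seed = scenario$seed + 7919L * tp,
                                   grid_rows = scenario$grid_rows,
                                   grid_cols = scenario$grid_cols)
    for (i in seq_len(scenario$n_plants)) {
      pid <- pid + 1L
      rp <- render_plant(scenario, labels[[i]], profiles,
                         seed = scenario$seed + 7919L * tp + 31L * i)
      out[[pid]] <- list(plant_id = pid, time_point = tp,
                         stack = rp$stack, truth = rp$truth)
    }
  }
  out
}
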