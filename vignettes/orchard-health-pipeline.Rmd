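---
title: "Vegetation-index screening of orchard tree health from drone imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vegetation-index screening of orchard tree health from drone imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazelhealth)
```

## The problem

Hazelnut orchards are increasingly monitored with small drones carrying
multispectral cameras (green, red, red edge ~730 nm, near-infrared ~840 nm)
flown low enough to resolve individual crowns at about 1 cm per pixel.
The monitoring question is binary and operational: is this part of this
tree healthy or not? Symptoms of abiotic stress and pathogen attack
(chlorosis, leaf scorch, wilting, branch collapse) are often confined to a
portion of a bushy crown, so whole-tree averaging of spectral signals
dilutes localized damage and produces false negatives — the costliest error
for a grower, because a missed sick tree goes untreated.

`hazelhealth` implements the full analysis chain for this setting:

1. **Plant isolation** — geometric cropping around the trunk (one 4 m x 4 m
   planting cell per image) and/or soil removal by NDVI thresholding
   followed by a contour-hierarchy cleanup.
2. **Slicing** — each plant image is partitioned into a 3 x 3 grid of
   sub-images ("quadrants"), each covering slightly more than 1 m^2 of
   ground; sub-images that are mostly soil are excluded.
3. **Vegetation indices** — nine per-pixel indices (NDVI, GNDVI, GCI,
   NDREI, RECI, NRI, GI, TCARI, SAVI) averaged per slice.
4. **Index selection** — per-index class separation between healthy and
   unhealthy slices, quantified by Cohen's d.
5. **Classification** — random forest, k-nearest neighbours and penalised
   logistic regression on the selected indices, evaluated with
   false-negative-oriented reports.
6. **Simulation** — a calibrated synthetic orchard generator, so that every
   stage is testable end-to-end without access to field data.

## Segmentation conventions

Soil masking uses the standard observation that bare soil has much lower
NDVI than canopy. The rule is kept in its conventional strict form: pixels
with NDVI *strictly below* the threshold (default 0.2) are excluded, so a
pixel exactly at the threshold is retained. The raw mask is then cleaned by
a two-level contour hierarchy: connected components that are only adjacent
to *enclosed* background (holes of other components) are inner contours and
are removed; retained outer components are hole-filled. The result is a
union of solid crown regions. The operation is idempotent and is O(image)
via run-merging connected-component labelling (4- or 8-connectivity,
default 8).

Slicing uses half-open, 0-based windows with boundaries at
`floor(i * H / 3)`; the remainder pixel goes to the last row/column, so a
400 px image slices into 133/133/134. Windows tile the frame exactly — this
is asserted, not assumed. A slice is dropped as "mostly soil" when its
canopy fraction falls below 0.5; the threshold is configurable because
"mostly" is a judgment call, and the retained-at-exactly-0.5 boundary
convention mirrors the NDVI rule. At the simulator's defaults this drops
roughly 15–20% of slices, comparable to the exclusion rate reported for
real surveys of this design.

Two isolation routes exist because orchards mix habits: geometric cropping
(`geometric_crop()`) for mature plants whose canopies overlap, and
NDVI-based isolation for young, well-separated plants. They compose: the
pipeline applies the NDVI mask within each cropped cell.

## Vegetation indices

All indices are computed per pixel from reflectances in [0, 1] and averaged
per slice. Normalized differences (NDVI, GNDVI, NDREI, NRI) are bounded in
[-1, 1]; ratio indices (GCI, RECI, GI) are unbounded above, which matters
for their noise behaviour. SAVI adds the soil-correction constant L
(default 0.5) to the NDVI denominator; at L = 0 it *is* NDVI, which the
test suite asserts to 1e-12. Pixels whose denominator magnitude falls below
`epsilon` (default 1e-9) are flagged invalid and dropped from the slice
mean rather than clamped — clamping would bias the unbounded ratio indices;
the per-slice `n_valid` count keeps the exclusion auditable.

TCARI is typeset ambiguously in parts of the literature; the default
`standard` variant computes `3[(RE - R) - 0.2 (RE - G)(RE / R)]` and a
`paper_literal` variant computes `3[(RE - R) - 0.2 (R - G)(RE / R)]`. Both
are implemented and tested; since TCARI is not selected downstream, the
choice does not propagate.

Whether the slice mean should run over all pixels or canopy pixels only is
genuinely underdetermined in this analysis tradition; both modes exist
(`use_mask` in `vi_config()`), and canopy-only is the default because
retaining soil pixels inside a slice mixes two populations the soil mask
was introduced to separate.

Index selection replaces visual boxplot judgment with Cohen's d on pooled
standard deviations (healthy minus unhealthy), with selection at
|d| >= 0.5. One linked rule: because SAVI is a rescaled NDVI, NDVI is
deselected whenever SAVI fails the threshold, even if NDVI itself passes.

## Classification protocol

The feature set is the selected index set (by default GNDVI, GCI, NDREI,
NRI, GI). The data are split 80/20 with stratified random sampling; the
three classifiers use fixed, conventional hyperparameters — random forest
with 100 trees, Gini splits and unbounded depth; KNN with k = 5, uniform
weights and the Euclidean metric; logistic regression with an l2 penalty
(`glmnet` ridge at lambda = 1/(C n), C = 1, i.e. a quasi-Newton-quality
convex fit to tolerance 1e-10). Seeded random search over documented spaces
(trees in {50..500}, k in 1..15, C log-uniform in 10^±3) with stratified
5-fold cross-validation is available but off by default, since the fixed
values above are the protocol of record. Features enter raw; a
`standardize` flag exists because KNN is scale-sensitive.

Evaluation treats *unhealthy* (label 1) as the positive class and reports
the confusion matrix, accuracy, per-class precision/recall/F1, macro and
support-weighted averages, and false negatives both as a count and as a
rate over the whole test set — the convention under which "132 false
negatives out of 823 data points" is 16%. Internal consistency of this
algebra is property-tested against brute-force recomputation on 1000
random confusion matrices.

## The synthetic orchard generator

No public dataset accompanies this problem setting, so the generator is a
first-class, tested component, not a fixture. It emulates:

* **Geometry**: one plant per 4 m x 4 m cell at 1 cm/px (400 x 400 px
  images); a bush-like crown built from a central disc (radius ~2.0 ± 0.15
  m — at this spacing mature crowns nearly close, and smaller crowns would
  drop every corner slice as soil) plus 4–8 satellite discs; interior
  canopy gaps punched as small soil-filled holes.
* **Spectra**: three class profiles (soil / healthy / unhealthy). Soil has
  NDVI 0.149, safely below the 0.2 masking threshold; both canopy classes
  exceed 0.3. The healthy profile is classic green vegetation (high NIR
  plateau, strong red absorption). The unhealthy profile is brighter
  across bands with a flattened red-edge shoulder — the spectroscopy of
  dry, chlorotic foliage: higher green and red-edge reflectance, NIR no
  longer dominating the red edge. Its band *ratios* give NDVI 0.730,
  GNDVI 0.455 and NRI 0.412 against healthy 0.786, 0.667 and 0.25.
* **Labels**: per-quadrant Bernoulli draws at a configurable prevalence
  (optionally one prevalence per acquisition date to model seasonal drift:
  the default study uses 0.305/0.521/0.719, i.e. healthy:unhealthy ratios
  2.28/0.92/0.39), plus a fraction of plants (default 10%) forced to have
  exactly one unhealthy quadrant — the localized-symptom case that
  motivates slicing. Unhealthy quadrants are rendered as one contiguous
  patch covering ~60% of the quadrant's canopy, not salt-and-pepper.
* **Noise**: per-pixel log-normal speckle shared across bands (brightness
  texture) plus independent per-band Gaussian noise, with 5% of pixels at
  3x inflated noise (heavy tails); values clipped to [0.02, 1] — the small
  floor mimics a sensor dark level and keeps band ratios bounded. Soil
  noise is mostly multiplicative: soil colour variation is brightness-like,
  and this is also what keeps >= 99% of soil pixels below the NDVI mask
  threshold (a seeded test).

Pixel noise alone cannot make slice-level statistics realistic: a slice
mean averages ~17 000 pixels, so independent pixel noise collapses and
every index with any class gap would separate almost perfectly. Real
orchard slices vary for structural reasons, which the generator models as
slice-level random effects applied per quadrant and per plant:

* canopy **gap fraction** (soil visible through the crown after hole
  filling) — spreads every soil-contrasting index, NDVI most strongly
  relative to its class gap;
* canopy **condition** (mild mixing of the canopy spectrum toward soil —
  sparse or dusty foliage);
* per-plant **brightness** (log-normal illumination factor) — only the
  non-scale-invariant indices respond;
* rare deep **red-edge stress** (2% of quadrants at 0.05–0.15 of the
  normal red-edge level, both classes alike): because RECI is an unbounded
  ratio while NDREI saturates, rare deep events inflate RECI's variance
  far more than NDREI's — this is what separates two indices that are
  monotone transforms of the same band ratio;
* unhealthy **severity** (each unhealthy quadrant sits a uniform random
  fraction 0.7–1 of the way from the healthy to the unhealthy endpoint).

A single `heterogeneity` dial scales all five mechanisms; the
noise-degradation tests couple it to the band noise level
(`heterogeneity = band_sd / 0.04`) so that "low noise" genuinely means a
cleaner orchard, and classifier accuracy falls monotonically as the dial
rises.

### Calibration

The generator's defaults are calibrated so that, on a default dataset of
at least 200 slices per class (80 plants, prevalence 0.5, seed 0), the
slice-level distributions reproduce the qualitative selection pattern that
motivates the pipeline: |d| >= 0.8 for GNDVI, GCI, NDREI, NRI and GI
(healthy higher for the first three, unhealthy higher for the last two)
and |d| <= 0.4 for NDVI, SAVI, RECI and TCARI. This pattern is
structurally demanding — SAVI alone would match the unhealthy class gap
only if unhealthy canopies were ~1.8x brighter, while TCARI alone would
want them ~0.6x darker — and is resolved by the flattened red-edge
shoulder of the unhealthy profile, which simultaneously closes the TCARI
gap, closes the SAVI gap at 2x brightness, and widens the NDREI gap. The
calibration is enforced as an executable test, not a claim.

What the generator does **not** emulate: radiative transfer, shadows and
directional illumination, spatially correlated noise, georeferencing
error, specific pathogens or phenological stages. Passing tests on
synthetic data therefore demonstrate that the pipeline's logic and
statistics behave as specified — not that any particular accuracy will be
attained on real orchard imagery, where class separations are far weaker.
The `reproduce_study()` summary carries published reference ranges for
real drone surveys of this crop (accuracy 0.64–0.66, 13–16% false
negatives) purely as context; synthetic results are expected to exceed
them and are labelled as non-comparable.

## Numerical choices and degenerate inputs

* Reflectance is normalised to [0, 1] floats at load time (integer digital
  numbers divided by their bit-depth maximum, with the factor recorded in
  provenance); every index except SAVI is scale-invariant, and SAVI's L is
  defined on reflectance, so normalisation must precede it.
* Multiband imagery is written as band-sequential multi-page 16-bit TIFF
  (one single-band page per band); round-trips are bit-stable within one
  quantisation step (2^-16).
* Denominator guards return invalid (dropped) pixels, never clamped
  values; a fully masked slice reports `n_valid = 0` and a flagged mean.
* Empty canopy masks pass through the hierarchy filter unchanged with a
  warning; trunks outside the scene and grids larger than the image are
  errors; crop windows extending beyond the scene are zero-padded with a
  warning.
* All stochastic stages take explicit integer seeds, and every dataset,
  split, fit and study is bit-reproducible under a fixed seed.

## Problem sizes

The test suite renders small orchards (2–80 plants) chosen so the full
suite runs in a few minutes: the calibration-recovery test uses 80 plants
(~600 slices, >= 200 per class), the noise-degradation test 30 plants per
noise level with two replicates, and the end-to-end study check 10 plants
per time point. The acceptance script runs the full default study at 135
plants per time point (405 plants, ~3300 slices). These sizes are the
package's reporting choices; all of them are parameters.

## Known limitations

* The synthetic class separations are, by design, stronger than field
  reality; synthetic accuracies (~0.9+) say nothing quantitative about
  real surveys.
* Trunk positions are inputs, not detected; there is no orthomosaicking,
  radiometric panel calibration or 3D crown reconstruction.
* The contour hierarchy is two-level (outer/inner), which matches the
  cleanup its source procedure describes but is not a general topological
  contour tree.
* Binary labels only; severity grading is out of scope.
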