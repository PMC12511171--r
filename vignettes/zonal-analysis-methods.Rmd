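---
title: "Methods: zonal tumor-immune quantification in glioblastoma tissue sections"
author: "glioSpatial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zonal tumor-immune quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioSpatial)
```

## The analysis

Glioblastoma, IDH-wildtype infiltrates brain parenchyma: histologically one
distinguishes a dense **tumor core**, a **transition zone** of decreasing
tumor-cell density, and a **periphery** with single-cell infiltration into
near-normal brain. glioSpatial quantifies how tumor cells (P53+ in
TP53-mutant tumors), tumor-associated microglia/macrophages (IBA1+),
cytotoxic T cells (CD8+) and regulatory T cells (FOXP3+) distribute over
these zones, starting from the output of an upstream cell classifier: one
row per cell with micrometer coordinates and a phenotype class. The package
never touches images; classified cell tables, ROI polygons and a clinical
table are its complete input surface.

The pipeline computes, per patient:

* **Densities** `count / net ROI area` (cells/mm²) per zone and class, with
  artifact areas (bleeding, necrosis, folds, background staining) removed
  from both counts and area via exclusion polygons.
* **Ratios** of immune to tumor density (IBA1/tumor, CD8/tumor,
  FOXP3/tumor) and the immunosuppression index FOXP3/CD8. Because numerator
  and denominator share the ROI area, these equal count ratios; a zero
  denominator gives a missing value, never an infinity. Cohort summaries
  take the median of per-patient ratios — not the ratio of cohort medians,
  which is a different (and generally misleading) quantity.
* **Waterfall differences** (core − periphery, transition − periphery,
  core − transition) per class, exposing interpatient heterogeneity: most
  patients show positive differences, a minority shows sign flips.
* **Proximity fractions**: for each reference tumor cell, the number of
  immune cells of a class within a 30 µm radius (Euclidean,
  center-to-center, boundary inclusive), binned as 1–4, 5–9, ≥10 neighbors.
  Reported per zone as the fraction of reference cells per bin, plus the
  un-normalized variant (reference cells per bin divided by zone area).
* **Cohort inference**: Wilcoxon signed-rank comparisons of any metric
  between zone pairs (pairwise exclusion of patients missing a zone), and a
  univariate survival screen in which each per-patient feature is split at
  the cohort median (strictly above = high) and fed into a Cox
  proportional-hazards fit with Efron tie handling; Kaplan–Meier curves
  support visualization. Raw p-values are reported without multiplicity
  adjustment (a Benjamini–Hochberg column is available via `adjust = "BH"`).

## Key conventions and why

* **Geometry.** Coordinates are micrometers in slide space with y pointing
  down (image convention); only relative distances matter, so orientation is
  inert. Boundary points belong to the polygon (closed polygons); where two
  zones share an edge the assignment is deterministic in CORE, TRANSITION,
  PERIPHERY order. Zone polygons with positive-area overlap are rejected.
  Exclusions are intersected with the zone geometry before area
  subtraction, so an exclusion outside a zone has no effect. Polygon
  intersection areas are computed exactly by ear-clipping both polygons
  into triangles and clipping triangle pairs (triangles are convex, so
  Sutherland–Hodgman clipping is exact); this supports arbitrary simple
  polygons and multipolygon zones without a geometry dependency.
* **Proximity.** Neighbors are counted across zone boundaries; only the
  reference cell's own position decides which zone the observation belongs
  to. Clipping neighbors at ROI lines would bias narrow zones, and cells do
  not respect annotation lines. No edge correction is applied at tissue
  boundaries (naive counting, as commercial counting tools report); the
  resulting bias is small for zones much larger than the radius and can be
  quantified against the analytic Poisson oracle. Cells in exclusion zones
  are dropped both as references and as neighbors. A zero-neighbor bin
  (`b0`) is tracked explicitly so the four bin fractions always sum to one.
* **Core criterion.** The quantitative core definition — more than 60 % of
  the total cell population (unstained cells included) being tumor cells —
  is available as an advisory tile-grid tool (`tumorFractionGrid()` +
  `suggestCoreMask()`, strict `> 0.60`, tiles with fewer than 20 cells
  undefined). Analyses always use the supplied, expert-approved ROIs.
* **Statistics.** The signed-rank test drops zero differences, uses average
  ranks for ties, and is exact (signed-rank distribution, equivalent to
  enumerating all 2ⁿ sign assignments) for n ≤ 25 without ties; otherwise a
  normal approximation with tie and continuity correction. The median split
  sends ties to the low group, a deterministic and common convention. The
  survival screen reports non-convergent fits (e.g. complete separation
  with no events in a group) explicitly instead of a number.

## The synthetic cohort generator

Because classified patient slides cannot be redistributed, the generator is
a first-class module that reproduces the statistical structure the analysis
assumes, so every stage is testable at desk scale:

* **Intensities.** Per class and zone, interpatient intensities are
  log-normal around calibrated cohort medians — tumor 2301/1141/250,
  IBA1 512/419/179, CD8 14/10/3, FOXP3 1.7/1.2/0.1 cells/mm² for
  core/transition/periphery — with log-scale σ = 0.6 and cross-zone
  correlation ρ = 0.5 (equicorrelated construction, valid up to ρ = 1).
  This makes most, not all, patients core-dominant, reproducing waterfall
  sign flips. The published cohort reports medians only, so σ and ρ are
  calibration choices, not estimates.
* **Unstained background** medians 800/1000/1500 cells/mm² rise toward the
  periphery (neurons and glia of infiltrated brain), keeping the core just
  above the 60 % tumor-fraction criterion and the periphery far below it.
* **Geometry.** Concentric square bands (core square, two surrounding
  bands) with exact net areas, 6/6/8 mm² by default — the scale of
  whole-zone ROIs on a tissue section. Any polygon set is accepted.
* **Cell placement.** Homogeneous Poisson per class and zone
  (count ~ Poisson(λ·area), uniform positions). Optional Thomas-process
  recruitment places a configured proportion of an immune class as Gaussian
  offspring (σ = 15 µm default) of uniformly chosen tumor parents,
  preserving total intensity while raising 30 µm co-occurrence above the
  independence null — a test fixture for the proximity statistic, not a
  biological claim.
* **Survival.** Exponential event times with baseline median OS 14 and PFS
  7.6 months; progression is an additional competing exponential so
  PFS ≤ OS by construction. A binary covariate — the indicator that a
  patient's latent core tumor intensity exceeds the configured median —
  scales the hazard by exp(log HR), default log(0.46), i.e. longer survival
  for the high group. Administrative censoring is uniform over 57–236
  months of potential follow-up, emulating a multi-year accrual window
  censored at a fixed date; with a 14-month median OS this leaves only a
  few percent of patients alive, as in the cohort the defaults emulate.
* **Reproducibility.** One master seed; each patient consumes an
  arithmetically derived substream, so cohorts are bit-reproducible and
  stable under partial regeneration.

### What passing tests do and do not show

The generator emulates first-order zonal structure (intensity medians,
heterogeneity, censoring) and one specific second-order mechanism (Thomas
clustering). It does not emulate anisotropy, tissue folds, necrosis
geometry, classifier error, or spatial inhomogeneity within a zone. Tests
passing on synthetic cohorts therefore validate the *pipeline arithmetic
and inference machinery*, not the biology of any real cohort.

## Numerical and testing choices

* The analytic oracle for proximity is the Poisson thinning identity: under
  independence the neighbor count within radius r is Poisson with mean
  λ·10⁻⁶·π·r². Null-model tests compare observed bin fractions on
  generated slides (clustering off) against this closed form; a mean
  absolute deviation below 0.02 at ≥ 5·10⁴ reference cells is the bar,
  leaving room for the small edge bias of naive counting on a 5 × 5 mm
  slide.
* The fixed-radius neighbor search uses a uniform grid (cell size = radius,
  3 × 3 block lookup) implemented in C++; an O(n²) brute-force
  implementation with the identical contract serves as its oracle and must
  agree exactly, not approximately.
* Type-I error of the paired zonal comparison is measured on the
  generator's null (equal intensity medians in all zones) at the count
  level: per-region counts are drawn as Poisson(λ·area) directly, which is
  exactly the distribution the spatial generator induces on the density
  table, skipping only the uniform positions that the density statistics
  never see. 500 simulated cohorts of 54 patients must reject within the
  95 % binomial envelope of the nominal α = 0.05.
* Cox recovery uses 200 simulated cohorts of n = 216 with true HR 0.5 and
  roughly one-third censoring; the mean estimated log-HR must sit within
  ±0.1 of log 0.5. The group-relabeling identity (HR → 1/HR) is checked
  exactly.
* Zonal ordering (core > transition > periphery for all four class
  densities, immune-to-tumor ratios rising toward the periphery) must hold
  in at least 19 of 20 default-configuration cohorts.
* Problem sizes used in the routine test suite (smaller areas for unit
  tests, full defaults for the end-to-end ordering check) were chosen so
  the whole suite runs in minutes on a laptop while keeping every check at
  the statistical resolution stated above.

## Known limitations

* Density recovery at very low intensities is quantized by the area: with
  8 mm² of periphery, FOXP3 at 0.1 cells/mm² yields 0–2 cells, so
  per-patient estimates are coarse (0, 0.125, …). Cohort medians of such
  combinations inherit that granularity; recovery tests therefore assert
  tight agreement only where the expected count resolves it.
* Polygon holes are not supported in GeoJSON input; model holes as EXCLUDE
  features, which subtract from both area and counts.
* The transition zone and periphery have no numeric delineation rule (their
  histological definitions are qualitative); the package assigns cells to
  supplied ROIs and offers the tumor-fraction grid only for the core
  criterion.
* The survival screen is univariate by design; no multivariable adjustment
  or competing-risks handling is attempted.
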