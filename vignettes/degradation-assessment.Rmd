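---
title: "Mapping degraded ecosystem hotspots: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping degraded ecosystem hotspots: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodegrade)
```

# The assessment model

`ecodegrade` operationalizes a multicriteria, GIS-style national ecosystem
degradation assessment. Every mapped feature — a grassland parcel, a lake
or coastal polygon, a river reach, a cave — is scored against ecosystem-
specific degradation criteria and assigned one of three classes: natural,
semi-degraded, degraded. Degraded features are then converted to density
surfaces on a common grid, combined, and screened for statistically
significant spatial concentrations (hotspots). Forests are handled
differently: degradation is inferred from the temporal trend of percent
canopy cover rather than from static attributes.

The pipeline therefore has five analytic layers, each an exported module
surface:

1. **composite scoring** (`apply_scheme`, `batch_score`, `score_grassland`),
2. **canopy trend analysis** (`pixel_trend`, `detect_conversion`),
3. **density + hotspot mapping** (`rasterize_density`, `classify_density`,
   `sum_layers`, `gi_star`, `natural_breaks`),
4. **validation** (`extract_model_at_points`, `confusion_matrix`,
   `roc_auc`, `validate_map`),
5. **reporting** (`class_percentages`, `summarize_classes`,
   `zonal_summary`).

## Composite scoring

All static-attribute ecosystems run through one declarative engine. A
`scoring_scheme` is an ordered list of criteria; each criterion bands an
attribute into a class score 0/1/2 using two thresholds and a direction
(`higher_is_worse` for pressures such as invasive cover,
`lower_is_worse` for protective quantities such as distance to
settlements or riparian vegetation). The aggregate is the weighted sum of
scores, classed by two cut-points: at most the lower cut-point is natural,
at least the upper is degraded.

The boundary convention is a *closed middle interval*: printed bands such
as ">4 km / 2–4 km / <2 km" leave the endpoints ambiguous, and the
dash-written middle band is read as closed, so a value equal to either
threshold is semi-degraded. One convention is applied uniformly across all
schemes.

The bundled configurations (`inst/schemes/`, loadable with
`eco_scheme()`) encode:

* **grassland** — weights (5, 20, 5, 10, 50, 100) over proximity to
  localities, proximity to sheepfolds, slope, livestock-density deviation,
  invasive species and bare soil; aggregate cut-points 30/65. The
  livestock criterion is banded on the absolute deviation with thresholds
  10 and 30; its printed description is self-contradictory ("±10–50%"
  semi-degraded yet ">±30%" degraded), and the degraded trigger at 30 is
  honored, treating the 50 as a typographical inconsistency.
* **cave** — two *raw-mode* criteria (pre-aggregated impact and
  vulnerability form totals, each 0–100) summed and classed at 34/85. The
  internal item content of the underlying field forms is out of scope; the
  engine consumes their totals.
* **river** — 13 criteria in four indicator classes. The source method
  names the six most important criteria but prints no weights; the bundled
  scheme gives those six double weight and the remaining seven unit
  weight, normalized to sum 1 — an explicitly documented stand-in that
  preserves the stated importance ordering without inventing false
  precision. The printed class lists name only 12 criteria; a dam-density
  criterion (the river data inventory includes a dams-on-rivers layer)
  completes the stated count of 13. Every number is overridable in the
  YAML file.
* **lake** — eight unit-weight components (wastewater, recreation,
  agriculture, size, transport, industry, land cover, vulnerability)
  mirroring a composite pollutant-load-plus-vulnerability index whose
  component formulas live in external references; cut-points 4/12 so that
  all-natural, all-middle and all-degraded bands land in the three
  classes.
* **coastal** — eight summed indicators. Terrestrial bands are ≤4 / 5–12 /
  ≥13 (the printed bands skip 13 exactly; it is closed upward into
  degraded so the classification is exhaustive). Marine bands are printed
  overlapping and are implemented as ≤5 / 6–15 / >15.

The grassland index is additionally exposed as dedicated functions
(`score_criterion`, `compute_di`, `classify_di`); an exhaustive test over
all 3^6 = 729 score combinations confirms the generic engine reproduces
them exactly, that the index is always a multiple of 5 in [0, 380], and
that the unreachable gap values (31–34, 61–64) are never produced. The
printed degraded range "65 to 180" understates the attainable maximum of
380; only the lower bound is load-bearing and only it is used.

## Forest canopy trend

The trend fit is unweighted ordinary least squares of percent canopy on
year — the simplest estimator compatible with "linear trend per pixel" —
and the degradation rule is a fitted *total* change below −10 percentage
points over the observed span. The threshold is absolute, not relative:
the input is already a percentage, and a relative option would be a
configuration choice. Pixels with fewer than 3 valid epochs become nodata
rather than errors. An optional canopy-range mask (default 30–80%,
applied to the per-pixel mean, `NULL` to disable) restricts analysis to
the band in which forests are mapped; whether the source method masked
before or after trend analysis is unstated, so the mask is explicit and
optional.

## Density, hotspots and classes

Density is the per-cell amount of degraded features — point count, line
length exactly clipped to the cell (Liang–Barsky), or polygon area exactly
clipped to the cell (Sutherland–Hodgman) — divided by cell area in km².
No kernel smoothing is applied. Cells with no ecosystem present score 0;
positive cells are classed 1–5 (very low to very high), by quantiles by
default with ties broken toward the lower class, or by equal intervals
(degenerate ranges collapse to class 1). Scoring absent cells 0 rather
than 1 matters for the combined layer: summed scores then range 0–30 over
six ecosystems, and observed combined maxima stay well below the ceiling,
consistent with the zero-for-absent convention.

The Gi\* statistic follows the standard Getis–Ord formulation (the printed
equation in the source is typographically garbled; the standard formula it
evidently transcribes is implemented and checked against an independently
coded brute-force double loop to 1e-10). Weights are binary
fixed-distance-band including self — the conventional "star" choice — with
the radius a configuration parameter, since the source used a GIS-tool
default without stating it. A constant field is defined to give z = 0
everywhere. Confidence bins use the two-sided normal cut-offs 1.645,
1.960, 2.576.

Natural breaks are computed by an exact Fisher–Jenks dynamic program
(O(k·n²)) minimizing within-class sum of squared deviations, verified
against exhaustive enumeration of all partitions for n ≤ 12. Interior
breaks are reported as class maxima. The per-ecosystem density step uses
quantile classes (the classification method for that step is unstated in
the source); the combined map uses natural breaks, matching the published
zonal table's construction. Both are explicit options.

## Validation

Validation points receive the *worst* class and maximum aggregate score
among features intersecting a 300 m buffer (the source protocol's
radius); points with empty buffers are flagged and excluded. The binary
reduction is degraded vs not-degraded (semi-degraded counts as not
degraded, matching "presence or absence of degradation"); a
degraded-plus-semi option exists. The ROC ranks by the continuous
aggregate score (the source does not say whether it ranked by score or
class; the continuous score is the default and the richer choice), groups
tied scores into single threshold steps, and integrates by trapezoid —
provably equal to the normalized Mann–Whitney statistic, asserted to
1e-12 against a pairwise loop and cross-checked against an established
ROC implementation. The 0.8 AUC convention is reported as a
strong/moderate-vs-weak verdict, never enforced.

# The synthetic landscape generator

No national datasets accompany the method, so the generator supplies
landscapes with the statistical structure the analysis assumes, with
known ground truth:

* **class-conditional attributes** — the hidden true class is drawn first
  (Bernoulli at the ecosystem's prevalence), then attributes are drawn
  uniformly inside criterion bands chosen to guarantee that class (a
  seeded random walk over band assignments keeps within-class variety).
  Prevalence is therefore a direct, recoverable parameter, and every
  threshold band is exercised.
* **clustered placement** — degraded features scatter around
  `cluster_count` Gaussian centers (sd `cluster_sd`), the simplest
  process that produces genuine hotspots; `cluster_count = 0` disables
  clustering for null studies.
* **canopy series** — degraded pixels decline linearly by 12–25
  percentage points over the span; others hold a constant 35–75% level;
  Gaussian noise (sd 2) everywhere.
* **validation truth** — points drawn uniformly over the extent inherit
  the hidden label of the nearest feature within the buffer radius.

Defaults, chosen once as field-realistic study conditions: a 100 km ×
100 km extent; 300 grassland parcels of 0.4–1.2 km side, 150 caves, 200
river reaches of 2–6 km, 200 lakes, 150 coastal polygons; 3 clusters of
sd 5 km; 14 annual canopy epochs; prevalences 0.3 (grassland, river,
coastal), 0.15 (lake), 0.1 (cave), 0.2 (forest). Each `simulate_*`
function seeds its own stream from the global seed plus a fixed offset,
so stages are individually reproducible.

What the generator does *not* emulate — real geography, land-cover
taxonomies, satellite radiometry, spatially correlated attribute noise,
or genuinely ambiguous borderline features (generated features are
class-consistent by construction). Passing tests therefore demonstrate
the pipeline's internal correctness and calibration, not field accuracy;
the published field AUCs (0.916 grassland, 0.918 lakes) depend on
unavailable national data and are deliberately not reproduction targets.

# Numerical and degenerate-input choices

* Banding boundaries: closed middle interval, everywhere.
* Aggregate classing: natural at or below the lower cut-point, degraded
  at or above the upper.
* Quantile ties break toward the lower class; an all-equal positive field
  is all class 1; equal-interval on a zero-width range collapses to
  class 1; an all-zero grid warns and scores 0.
* Gi\* on a constant field is z = 0 by definition; non-finite z bins as
  not significant with a warning.
* Percentages round half-up to 2 decimals (the printed-table convention;
  base R's round-half-even would disagree on boundary cases), with
  unrounded values available.
* Geographic (lon/lat) input is rejected rather than silently
  reprojected: densities, buffers and areas are metric.
* Vector exchange is GeoJSON (single-ring polygons, named planar CRS);
  rasters are plain-text ESRI ASCII grids; schemes are YAML. These are
  the standard text formats the toolchain reads and writes directly.

# Calibration properties and problem sizes

The test suite exercises, at fixed seeds: Gi\* equality with the
brute-force oracle on random 10×10 grids (1e-10); the 729-case grassland
enumeration; AUC-equals-Mann-Whitney to 1e-12; Jenks-equals-exhaustive
for n ≤ 12; a 1000-permutation Gi\* null whose mean significant fraction
at |z| > 1.96 must lie in [0.03, 0.08]; prevalence recovery at n = 1000
per ecosystem within exact binomial 95% intervals; and a single-cluster
landscape yielding hot99 cells while a uniform landscape stays at the
nominal significance rate (20×20 grid of 5 km cells, 7.5 km radius, 400
parcels).

One calibration subtlety is worth recording: under spatial uniformity the
*expected* fraction of cells with |z| > 1.96 is the nominal ~5%, so any
single landscape fluctuates around that value and a strict "below 5%"
reading holds only about half the time. The permutation-band check is the
statistically well-posed version; the single-landscape check is asserted
at the canonical seed. Likewise, single-draw prevalence checks are
asserted as binomial coverage across 20 seeds rather than one lucky draw.

Problem sizes (40×40 combined grids, n = 1000 feature sets, 1000
permutations on 10×10 grids) were chosen so the full suite and the
acceptance script each complete in about a minute on one CPU while
keeping every statistical check well-powered.

# Known limitations

* Polygons are single-ring (no holes, no multipolygons); rivers are
  simple polylines.
* No reprojection: all inputs must already share one planar metric CRS.
* The river and lake scheme weights/thresholds are documented stand-ins
  pending published values; results depending on them should be read as
  methodology demonstrations, not ecological estimates.
* No false-discovery-rate correction of Gi\* p-values is applied (the
  source applies none), so multiple testing across cells inflates the
  count of nominally significant cells under the null exactly as the
  calibration tests quantify.
* Point features are assigned to the cell containing them; lines and
  polygons are clipped exactly, but a feature lying exactly on a cell
  boundary is attributed deterministically to the upper/right cell.
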