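---
title: "From suitability surface to conservation priorities: the coreconn workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From suitability surface to conservation priorities: the coreconn workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreconn)
```

## The problem this package addresses

National-scale conservation assessments for elusive species — here modelled
on the situation of a small Andean felid — typically have to work from
indirect evidence: a compiled occurrence dataset of mixed quality, a
continuous habitat-suitability surface from a distribution model, a land
cover map, a human-footprint index, published density estimates from a
related taxon, and the national protected-area cadastre. `coreconn` turns
those inputs into the standard chain of products: cleaned records, discrete
habitat cores, a corridor network with circuit-theory importance scores, an
ordinal conservation priority per core, potential population sizes, and a
protected-area gap and temporal-coverage analysis.

Because real national rasters are large, proprietary or unavailable, the
package ships a seeded synthetic-landscape generator that reproduces the
*statistical structure* the analysis assumes, so every stage is testable
end-to-end without external data.

## The synthetic world

`generate_landscape()` builds three co-registered rasters on one projected
grid (square cells; the default CRS label is the Colombian national
projection, but nothing depends on it):

* **Suitability** in [0, 1]: Gaussian-smoothed white noise (smoothing scale
  `autocorr_length`, default 5 km on a 1-km grid — landscape-scale
  autocorrelation) rescaled to `[0, background_max]`, with
  `n_planted_patches` rectangular patches of known geometry assigned values
  in `patch_suitability`. Planted patches always exceed the generator's
  `design_threshold` (0.5) and the background never does
  (`background_max = 0.45`), which is what makes planted-structure
  recovery an exact, checkable property rather than a statistical one.
* **Land cover**: four classes (montane forest, paramo/shrub, cropland,
  built-up); the first two carry the natural flag. About 60% of the
  background is natural, and planted patches are always natural forest.
* **Human footprint** in [0, 100]: an independent smoothed field centred on
  `footprint_background["mean"]` (default 40 ± 25, a heavily intervened
  Andean landscape); inside planted patches the footprint is reduced to
  20% of its background value, reflecting that intact habitat and low
  human influence co-occur.

Occurrence records are sampled with probability proportional to
suitability, jittered within their cell, and attributed with evidence /
source / precision categories drawn from configurable frequencies; a
configurable fraction has blank coordinates. Protected areas are
axis-aligned rectangles — a deliberate simplification: with no geometry
library in the supported stack, rectangles let every intersection and
union be computed *exactly* (analytic clipping plus coordinate-compression
union), so the gap-analysis tests assert equalities, not approximations.

Draws happen in one documented stream order (landscape, then records, then
protected areas), each stage seeded at `seed + {0, 1, 2}`, so a stage can
be regenerated alone and two runs with one configuration are
bit-identical.

What a green synthetic test does **not** establish: realism of spatial
covariance between footprint and land cover, georeferencing error
structure, irregular protected-area shapes, or any property of a real
suitability model. The generator's defaults are a stated world, not a
fitted one.

## Record quality control

`classify_reliability()` maps the three criteria to High/Medium/Low;
`filter_records()` applies, in order: drop records without coordinates;
apply the *moderate* filter (exclude any record with at least one Low —
the *strict* variant, all-High, is exposed as an option); collapse exact
coordinate duplicates; and thin to one record per 1-km grid cell. Every
input row receives exactly one fate code, so attrition is fully auditable.

The survivor rule among duplicated or cell-sharing records is not part of
the published protocol and had to be fixed here: best reliability triple
(lexicographic over evidence, source, precision), then earliest year, then
lowest record id. The thinning grid is anchored at the raster origin so
the QC stage and the raster stages share cell boundaries; points exactly
on a boundary go to the cell on the increasing-x / decreasing-y side
(floor convention).

`screen_collinear_variables()` computes Spearman rank correlations
(average ranks on ties — the tie rule is also unstated in the source
protocol and is fixed here) and greedily keeps variables in importance
order, dropping any candidate correlated at |rho| >= 0.70 with an
already-kept variable. Constant columns have undefined rank correlation;
they are flagged and treated as uncorrelated rather than silently dropped.

## Habitat cores

`ten_percentile_threshold()` implements the 10-percentile
training-presence rule as the k-th smallest presence suitability with
k = ceiling(0.10 n) and a `>=` comparison — the common MaxEnt-tooling
convention; a linearly interpolated percentile is available via
`method = "interp"` since the convention is not universal.
`binarize()` and `mask_natural()` are cellwise; `extract_cores()` labels
connected components (queen adjacency by default, so diagonally touching
habitat stays joined, consistent with diagonal corridor moves) and applies
the minimum-area rule, **inclusive** at 17 km² — one maximum reported home
range, i.e. the smallest patch viable for at least one individual.
Areas are always projected km² (cells are square metres); geographic
inputs must be projected beforehand, never silently reprojected.
Area SDs are sample SDs (n − 1). Whether a published threshold should be
applied to a replicate-mean surface or averaged across per-replicate
thresholds is ambiguous in common usage; this package thresholds a single
surface and leaves replicate averaging upstream.

## Corridor network and circuit theory

The human footprint is rescaled linearly to the 1–100 resistance scale
(`footprint_to_resistance()`); a constant footprint degenerates to R = 1
everywhere (frictionless but traversable), and nodata is impassable.

`cost_distance()` runs multi-source Dijkstra on the 8-neighbour lattice
with step cost = mean endpoint resistance × centre distance (√2 × cell on
diagonals) — the convention of the common GIS corridor tools, which do not
publish a formula; it is therefore asserted here against brute-force path
enumeration on small grids. Core interiors are traversed at zero cost when
routing between cores, so cost-weighted distance (CWD) measures the
intervening matrix, not patch size.

`build_network()` takes candidate pairs at minimum edge-to-edge Euclidean
distance <= 15 km (the dispersal reach of an individual with the median
home range of 4.5 km²; whether the published 15 km was Euclidean or
cost-weighted is unstated — Euclidean is used because the pruning is
described as a *dispersal distance*), traces each least-cost path, and
drops links whose path crosses a third core: that pair is connected
transitively, which is the standard adjacent-pair pruning that corridor
tools apply implicitly.

`current_flow()` models the corridor graph as a resistor network with
edge resistance = CWD. For every unordered pair in a component, a unit
current is injected and extracted by solving the graph Laplacian (one
grounded node, all right-hand sides factored at once); per-pair edge
current is conductance × potential difference. Aggregation uses absolute
currents. The centrality convention matters and is documented so
alternatives can be diffed: **terminal cores count the full injected
unit**, interior cores half the sum of absolute incident currents. A
two-core network therefore has centrality 1 at both ends rather than 0,
matching the reading of centrality as importance for keeping the network
connected. Currents are per-unit-injection sums over pairs; they are
comparable within a network but not across tools that scale currents
differently.

`corridor_surface()` maps the swath `cwd_a + cwd_b − lcp_cost <= cutoff`.
No published width rule exists; the cutoff is an explicit argument, and
the orchestrated run leaves surfaces to be computed on demand rather than
materialising one raster per link.

## Prioritization

Three criteria per core: log10 area, log10 (centrality + 1), and mean
human footprint. Published descriptions of such schemes sum "the three
categories" without stating commensuration; summing raw log-km², current
units and a 0–100 index would be dominated by the footprint, so each
criterion is min–max normalized to [0, 1] first (an unnormalized mode is
kept behind a flag for sensitivity analysis). The footprint enters
inverted — lower human influence is better — which the category semantics
imply ("best existing conditions" down to "severely affected"). The +1
inside the centrality log places isolated cores at the bottom of that
axis without producing −Inf. Degenerate axes (all cores equal) score 1
for every core rather than dropping the axis silently.

`assign_priority()` splits the observed score range into k = 5 equal
intervals, category 1 = best. Interval upper boundaries belong to the
better category (so the maximum score is always category 1 and a score
exactly at an interval edge is not pushed down by float noise — a 1e-9
guard absorbs representation error). All scores equal puts everything in
category 1.

`area_centrality_regression()` fits OLS of centrality on area over all
cores and over nested subsets below decreasing size thresholds (the
decremental / chained-regression design), reporting slope, t, p and
adjusted R². Raw scales are the default because the relationship of
interest is stated on raw size; a log–log option exists. Subsets with
n < 3 or zero predictor variance are skipped with an explicit note.

## Population extrapolation

Each published density estimate is reduced to a representative density
(range midpoint, or the mean of a mean ± SD form) and a spread
(half-range, or the SD). Population = density × total core area, rounded
to whole individuals for headline values only; per-core populations stay
unrounded. Pooling is the unweighted mean of representative densities,
and the pooled population mean and SD are the means of the **per-estimate
integer populations** — pooling on the same rounded-individuals scale on
which each estimate is reported. This choice is deliberate: pooling the
unrounded spreads and then rounding differs by one individual in the SD,
and the rounded-scale convention is the one consistent with the published
tabulation this module is verified against. The density sources are from
a closely related congener (likely *L. guttulus*); the `source_tag`
column carries that caveat into outputs.

## Protection gap analysis

`overlay_protection()` computes exact per-(core, protected-area)
intersection areas, and per-core coverage p_i from the geometric union of
protected areas, so overlapping designations are never double-counted in
coverage. The category/level/regime breakdown, by contrast, counts each
protected area's intersection independently, so category rows sum to the
column total — the dual convention of national protected-area accounting
tables, where the same hectare may appear under two designations. Both
totals are reported (`union_km2` vs `breakdown$total_km2`) rather than
reconciled.

Percentages are reported with half-up rounding to two decimals (raw
values are kept alongside); a geometric tolerance of 1e-6 km² discards
sliver intersections. `temporal_protection()` replays the overlay
cumulatively by establishment year; both series (area, cores touched) are
monotone by construction since unions only grow.

## Numerical and engineering choices

* No R spatial stack is assumed: rasters are matrix-backed with ESRI
  ASCII grid I/O, vectors are GeoJSON via `jsonlite`, and the only
  compiled code is the Dijkstra kernel (Rcpp), where the field's packages
  also use compiled code.
* Laplacian systems are solved dense with one grounded node and all
  right-hand sides at once; networks here have at most a few hundred
  cores, far below where sparse or preconditioned solvers pay off.
* Determinism contract: a `sim_config` plus a `run_config` fully
  determine every artifact byte; the orchestrated run writes a resolved
  configuration copy next to its outputs.
* The pipeline report contains only quantities recomputed at run time;
  nothing is cached between runs.

## Known limitations

* The circuit analysis operates on the core graph (one node per core),
  not on a full raster-resolution current map; within-corridor current
  density is out of scope.
* Synthetic protected areas are rectangles; irregular boundary effects on
  the overlay are untested (though the overlay code is shape-agnostic for
  any set of rectangles).
* The generator does not simulate bioclimatic covariates or a
  distribution-model fit; the suitability surface is produced directly,
  so model-calibration questions cannot be studied with it.
* Published aggregate figures that were printed with truncation or from
  unrounded intermediates can differ from recomputation in the last
  printed digit; the package reports recomputed values and does not chase
  printed rounding.
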