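---
title: "Estimating stand height increments from two-epoch airborne laser scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stand height increments from two-epoch airborne laser scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Forest management plans record, for every forest unit (sub-compartment), a
stand height: the representative height of the dominant species, measured in
the field on roughly ten representative trees and recorded in whole meters.
Airborne laser scanning (ALS) surveys of national mapping programmes cover
the same forests at typically 4 pulses/m² with a vertical accuracy of
0.15–0.25 m. When two ALS epochs a decade apart exist, the difference of
ALS-derived stand heights is a candidate replacement for the inventory's
height-increment bookkeeping. `standgrowth` implements that comparison end
to end and quantifies how well the two increment sources agree.

## The processing model

Per epoch, the chain is:

1. **Class filtering.** ALS returns carry ASPRS class codes; unclassified
   (0), noise (7), water (8) and multi-overlap (12) points are dropped
   before any surface is built. The drop set is configurable
   (`filter_classes()`).
2. **TIN rasterization.** The digital surface model interpolates the
   *first* returns, the terrain model the classified ground returns
   (class 2; farthest returns as a fallback), both through a Delaunay
   triangulation with linear (barycentric) interpolation, sampled at cell
   centers of a 0.5 m grid (`make_dsm()`, `make_dtm()`). 1 m is supported
   as a coarse alternative. Cells outside the convex hull are `NA` — the
   TIN never extrapolates.
3. **Canopy height model.** `CHM = DSM − DTM`, cellwise, `NA`-propagating.
   Negative cells (vertical noise over open ground) are clamped to 0 so
   that the later mask does not convert noise into no-data.
4. **Smoothing.** One pass of the 3×3 Gaussian kernel
   (1/16, 1/8, 1/16 / 1/8, 1/4, 1/8 / 1/16, 1/8, 1/16). The kernel sums to
   one, so constant rasters are preserved exactly. At borders and next to
   `NA` cells, the weights over the valid neighbors are renormalized
   rather than padding — padding would bias stand edges downward.
5. **Masking.** Canopy below 7 m becomes `NA` (`mask_below()`); the value
   7.0 itself is kept. This removes young growth and understorey before
   detection. A *separate* rule excludes inventory records at or below
   6 m (growth tabulations start above 6 m); the two thresholds are
   distinct, deliberately, and both configurable.
6. **Tree-top detection.** A cell is a top when it is the maximum of a
   circular window of radius `f(h) = 0.16 h + 0.8` m centered on it, where
   `h` is its own *post-smoothing* height (`detect_treetops()`). The
   linear window reflects the near-linear crown-diameter/height relation
   of Scots pine. Ties are broken lexicographically by (row, col), which
   keeps exactly one top per plateau given that the window is wider than
   one cell (guaranteed above the 7 m mask at resolutions up to 1 m). No
   mutual-suppression second pass is applied: the contract is exactly
   "greatest within its own radius", which an exhaustive oracle can check.
7. **Spatial filtering.** Tops outside forest-stand units are dropped, as
   are tops inside non-exclusive areas (NEAs) dilated by 2 m — half the
   crown width of a mature pine, absorbing the consumer-GNSS positional
   error of NEA digitization. Survivors inherit the unit's forest address.
8. **Stand height.** Top heights are rounded to whole meters, occurrences
   of each rounded height counted, and the stand height is the
   occurrence-weighted mean, rounded again to whole meters
   (`stand_height()`). The weighted form is algebraically the arithmetic
   mean of the rounded heights; it is kept because the histogram is the
   per-unit audit artifact. "Rounded to full meters" is implemented as
   round-half-up, not ceiling: inventory heights are recorded
   round-to-nearest, and a ceiling would bias LiDAR-minus-inventory
   differences by about +0.5 m. Ceiling is available via
   `round_height(mode = "ceiling")`.

Across epochs, forest units are matched **spatially, never by address**:
management-plan revisions merge and re-address units. All polygon
intersections are formed and a fragment is kept only when it contains the
pole of inaccessibility of the current-epoch unit (computed by iterative
grid refinement to 0.1 m). This single containment rule also discards the
sliver fragments that overlay produces along redrawn boundaries, with no ad
hoc area threshold. Pairs with a negative age difference (clear-cuts) or a
treeless first epoch are removed; units whose LiDAR-minus-inventory
difference is +8 m or more in either epoch are flagged gross errors
(misplaced NEAs, wrong contours, residual trees, multi-tier stands) and
excluded from agreement statistics. Large *negative* differences are kept —
they are informative (deciduous leaf-off underestimation), not errors.

Agreement between the increment series is summarized by the weighted
Pearson correlation (weights = cross-tabulation cell counts; identical to
expanding the table to unit-level pairs), bias, RMSE, relative bias
(percent of the mean inventory increment) and two R² variants. Two,
because the conventional definitions genuinely diverge here: squared
Pearson measures agreement up to linear recalibration, while
`1 − SS_res/SS_tot` about the identity line `x = y` measures agreement with
the reference as-is and can be negative. Both are reported
(`agreement_stats()`). Jenks natural breaks (`jenks_breaks()`, exact
Fisher dynamic programming, deterministic and order-invariant) classify
within-unit top heights for site-potential mapping. Detection quality
against digitized reference tops uses greedy nearest-first one-to-one
matching within a radius; with zero detections, precision (0/0) is
reported as 0 by convention.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| raster resolution | 0.5 | m | reference resolution; 1 m supported for the coarser variant |
| mask threshold | 7 | m | canopy floor for detection |
| inventory exclusion | ≤ 6 | m | growth tables start above 6 m |
| window slope, intercept | 0.16, 0.8 | –, m | crown radius vs height, pine |
| NEA buffer | 2 | m | half a mature pine crown width |
| drop classes | 0, 7, 8, 12 | – | unclassified, noise, water, overlap |
| rounding | half-up | – | matches whole-meter inventory records |

## What the synthetic generator emulates — and what it does not

`simulate_study()` produces a complete two-epoch scene: smooth bounded
terrain (sum of random cosine waves, exactly rescaled to the configured
amplitude); a rectangular grid of forest units with pine-dominated species
shares; Poisson-distributed stems scattered uniformly per unit; cone
crowns for conifers and paraboloid crowns for deciduous trees (distinct
apexes for the detector, configurable); a jittered-square-grid pulse
pattern (locally uniform, like flight-line ALS, rather than Poisson);
two returns per crowned pulse (crown surface + ground) and one per open
pulse, with independent Gaussian vertical noise; height-band vegetation
classes; optional class-7 noise points; optional downward bias of
deciduous first returns to emulate leaf-off acquisition; NEA clusters of
taller residual trees excluded from inventory sampling; and an inventory
of ~10 sampled dominant-species trees per unit with 0.3 m per-tree error,
rounded to whole meters. Per-unit true mean heights and growth are kept as
a sidecar truth table for parameter-recovery tests.

Between epochs, each unit grows at a rate drawn once from U(0.05, 0.45)
m/yr. No growth-rate distribution is published for the target stands; this
range was chosen a priori so that nine growing seasons span roughly 0.5–4 m
increments — the bulk of what the reference case study tabulates — and it
is not tuned against test outcomes.

Not emulated: radiometric intensity, multi-return waveforms within crowns,
real flight-line geometry, understorey vegetation structure, occlusion,
and terrain-correlated stand properties. A green parameter-recovery test
therefore establishes that the *pipeline* recovers known increments under
the stated noise model — not that the noise model captures every failure
mode of real ALS forestry data (leaf-off deciduous crowns being the known
dominant one, available as an explicit bias knob but off by default).

## Numerical choices

* The published smoothing formula indexes neighbors as `(i+m−1, j+n−1)`,
  which taken literally shifts the raster diagonally; it is read as an
  ordinary centered 3×3 convolution, since a shift contradicts the
  filter's stated smoothing purpose.
* Delaunay triangulation is incremental Bowyer–Watson with walk-based
  location and a tolerance-guarded in-circle predicate; cocircular points
  (regular grids) fall outside the strict in-circle and yield one of the
  valid triangulations — linear interpolation of affine fields is exact
  either way, which the tests assert at 1e−9.
* Both epochs snap their raster origins to multiples of the resolution, so
  the two CHMs land on one lattice and are cellwise comparable; whether to
  resample between epochs never arises.
* Increments are differences of *rounded* whole-meter stand heights, for
  comparability with the whole-meter inventory increments (the alternative
  — rounding after differencing — is not what field records support).
* The window radius in cells is `floor(radius/res)` cells with the exact
  circular-distance check on cell centers; a top must beat every non-NA
  cell whose center lies inside its own radius.
* `pole_of_inaccessibility()` refines quadtree cells best-first until the
  possible improvement is below the precision (default 0.1 m).
* Degenerate NEA rings are repaired (convex hull; segments dilate to
  capsules) with a warning rather than erroring, mirroring a zero-width
  buffer repair.

## Known limitations

* Polygon clipping (Sutherland–Hodgman) requires the current-epoch clip
  ring to be convex; arbitrary concave-vs-concave unit overlays would need
  a full boolean-ops engine, which this package deliberately does not
  ship.
* The headline full-dataset statistics of the reference case study
  (r = 0.6 on unrounded increments, bias 0.2 m, RMSE 0.7 m, field CHM
  accuracies) require the original non-public unit-level data; the package
  reproduces every aggregate computable from the published class-level
  tables and property-tests the formulas instead.
* The text point-cloud dialect trades file size for a text-only,
  dependency-free exchange format; binary LAS support would be an external
  conversion step.
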