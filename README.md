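# standgrowth

Estimates forest-stand height increments from two epochs of classified
airborne laser scanning (ALS) and quantifies their agreement with
field-inventory stand heights.

Forest documentation records, per forest unit, the height of the dominant
species in whole meters, traditionally averaged over ~10 representative
trees. National ALS programmes (≈4 pts/m², vertical accuracy 0.15–0.25 m)
revisit the same forests roughly once a decade. `standgrowth` turns two such
point-cloud epochs into per-unit stand heights and increments, and asks how
far ALS can stand in for the field inventory.

The processing chain per epoch:

1. drop unclassified / noise / water / overlap returns (classes {0,7,8,12});
2. DSM from first returns and DTM from ground returns, each by Delaunay-TIN
   linear interpolation onto a snapped 0.5 m grid:
   `DSM(i,j) = TIN(H_first; i,j,r)`, `DTM(i,j) = TIN(H_last; i,j,r)`;
3. `CHM = DSM − DTM`, smoothed with the 3×3 Gaussian kernel
   (1/16 1/8 1/16 / 1/8 1/4 1/8 / 1/16 1/8 1/16), masked below 7 m;
4. tree tops as local maxima within a height-dependent circular window of
   radius `f(h) = 0.16·h + 0.8` m, filtered against forest-unit polygons and
   2 m-buffered non-exclusive areas (NEAs);
5. stand height per unit as the occurrence-weighted mean of whole-meter top
   heights, `h̄ = Σ wᵢhᵢ / Σ wᵢ` with `wᵢ = count(unit, round(hᵢ))`,
   reported in whole meters.

Units are then matched across epochs spatially (polygon intersection kept
only where it contains the current unit's pole of inaccessibility),
clear-cuts and gross errors (difference ≥ +8 m) are excluded, and LiDAR vs
inventory increments are compared by weighted Pearson correlation, bias,
RMSE, R² and relative bias. A synthetic-forest generator (terrain, stems,
crowns, pulses, inventory) makes the whole pipeline runnable and testable
with no external data.

## Worked example

```r
library(standgrowth)

cfg   <- scene_config(extent = c(xmin = 0, xmax = 100, ymin = 0, ymax = 100),
                      seed = 42)          # 1 ha, 4 pts/m², noise sd 0.2 m
study <- simulate_study(cfg, nx = 2, ny = 2)   # 4 units, 2 epochs, 9 years
run   <- run_pipeline(study, run_config())

run$pairs[, .(address_new, lidar_old, lidar_new,
              lidar_increment, inventory_increment)]
#>    address_new lidar_old lidar_new lidar_increment inventory_increment
#> 1:        U001        14        15               1                   1
#> 2:        U002        17        17               0                   1
#> 3:        U003        19        20               1                   1
#> 4:        U004        14        18               4                   4

str(run$stats)
#> $ n          : int 4
#> $ r          : num 0.962
#> $ bias       : num -0.25
#> $ rmse       : num 0.5
#> $ r2_pearson : num 0.926
#> $ r2_identity: num 0.852
#> $ rbias      : num -14.3
```

Reading this: per unit, the whole-meter ALS stand heights of both epochs,
their difference (`lidar_increment`), and the increment the synthetic
inventory recorded. Here the two sources agree within 1 m everywhere
(r = 0.96, RMSE 0.5 m); the −0.25 m bias is the ALS increments sitting
slightly below the inventory ones. `run$counts` keeps the full filter
bookkeeping (returns kept, tops detected/kept, units matched and analysed
at every stage).

The package also ships the class-level summary tables of the pine-dominated
Zbrzyca (northern Poland) two-epoch case study as plain-CSV fixtures
(`zbrzyca_table()`); the acceptance tests recompute that study's published
aggregates from them — e.g. 216 compared stands, restricted increment
correlation 0.8, and the −5…−2 m class area of 142.11 ha.

Inventory uncertainty is negligible at stand level: with a 0.3 m per-tree
error and ~1000 trees per stand,

```r
mc_height_uncertainty(sigma = 0.3, n_trees = 1000, n_reps = 1000, seed = 1)
#> MC SE: 0.0093 m  (analytic sigma/sqrt(n) = 0.0095 m)
```

## Command line

```sh
Rscript -e 'standgrowth::standgrowth_cli()' simulate --seed 7 --out scene/
Rscript -e 'standgrowth::standgrowth_cli()' all      --seed 7 --out results/
```

`simulate` writes the synthetic scene (text point clouds, GeoJSON layers,
CSV inventories and truth table); `all` runs the full pipeline and writes
per-stage artifacts plus `report.json`.

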