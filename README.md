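# blueberrymap

Quantifying an invasive highbush blueberry (*Vaccinium corymbosum x
angustifolium*) incursion in wetlands from annotated UAV orthomosaics.

Feral blueberries escape plantations into rewetted moorland, form dense
shrub stands and displace ground vegetation. Given a UAV orthomosaic with
six-class pixel annotations (blueberries, trees, yellow bushes, soil,
water, dead trees), a co-registered DEM and annotated ground points, this
package computes:

* **Per-bush allometry** — bushes as 8-connected components of the
  annotation mask, area in m², and per-bush height as
  `stat(DEM over bush) − elevation(nearest ground point)` with
  `stat ∈ {max, median}`, negative estimates clamped to 0 m and flagged.
* **Spread statistics** — transitive single-linkage clustering at 3 m /
  6 m; quartic-kernel density K(d) = 3/(πr²)(1 − d²/r²)²; Getis-Ord Gi*
  hotspots with fixed-distance binary weights,
  `z_i = (Σ_j w_ij x_j − x̄ Σ_j w_ij) / (s √[(n Σ w_ij² − (Σ w_ij)²)/(n−1)])`,
  binned at 90/95/99% confidence; and 0-dimensional persistent homology of
  the annotated regions — the radius at which growing disks first connect
  two regions, with fused-fraction radii at 1/10/50/90%.
* **Automatic detection** — multi-label classification of 100 px patches
  under extreme class imbalance (blueberry loss weighted 8× soil and 4×
  the other classes, 12 augmented copies per blueberry patch, soil
  downsampled to 50%), a dual loss (presence + blueberry pixel fraction),
  leave-one-mosaic-out evaluation, and coarse-to-fine refinement of every
  positive patch into 4×4 sub-patches of 25 px.
* **Evaluation** — TPR = TP/(TP+FN), ACC = (TP+TN)/total at patch level;
  Dice = 2TP/(2TP+FP+FN) and ground-truth cover = |truth ∩ mask|/|truth|
  at pixel level, for the coarse and refined masks.

Because the original survey imagery is not publicly deposited, the package
ships a seeded synthetic wetland scene generator (`generate_scene()`) that
reproduces the survey's statistical structure — soil-dominated scenes,
blueberry at 1-1.5% of area, bush radii 20-100 px, clustered centroids,
heights mostly below 0.5 m with a tail to 3 m, reddish-soil confounders,
hassock elevation noise — with full ground truth, so every stage is
testable end to end.

## Worked example

```r
library(blueberrymap)

scene <- generate_scene(scene_config(seed = 1), site_id = "A1")
scene
#> orthomosaic_scene 'A1': 1000 x 1000 px @ 0.050 m/px
#>   class fractions: blueberry 1.2%, tree 5.0%, yellow_bush 3.0%, soil 87.3%, water 3.0%, dead_tree 0.5%

bushes  <- label_bushes(scene$masks$blueberry, scene$pixel_size_m)
heights <- compute_bush_heights(scene$dem, bushes, scene$ground_points,
                                "max", pixel_size_m = scene$pixel_size_m)
head(cbind(bushes[, c("component_id", "pixel_count", "area_m2")],
           height_m = round(heights$height_m, 2)), 4)
#>   component_id pixel_count area_m2 height_m
#> 1            1        1257  3.1425     1.05
#> 2            2        1862  4.6550     0.85
#> 3            3        1257  3.1425     0.27
#> 4            4        1760  4.4000     1.00

summarize_inventory(bushes, site_area_ha = 0.25)
#>   site_area_ha bush_count bushes_per_ha total_bush_area_m2 mean_area_per_bush_m2
#> 1         0.25          8            32                 30                  3.75

pp <- scene_centroids(scene)
cluster_points(pp, 6)
#> cluster_table @ 6.0 m: 8 points, 75.00% grouped >=3, 2 singletons, largest 6

h0_persistence(sample_regions(scene$masks$blueberry, 5),
               pixel_size_m = scene$pixel_size_m)
#> persistence_result: 8 regions, 7 inter-region merges (half-distance)
#>  0.01   0.1   0.5   0.9
#> 17.50 17.50 31.32 65.19
```

The inventory says: 8 bushes on the 0.25 ha site (32 bushes/ha, the
density of the sparser surveyed sites), covering 30 m² in total, 3.75 m²
per bush, with canopy heights between 0.27 m and 1.56 m. At a 6 m grouping
distance 75% of bushes sit in clusters of three or more; half of all
region merges have happened once disks grow to a 31 px (1.6 m) radius,
while connecting 90% of regions takes 65 px (3.3 m) — a compact, strongly
clustered incursion front.

The classifier study runs over a three-mosaic corpus:

```r
scenes <- scene_corpus(seed = 1)
res <- leave_one_mosaic_out(scenes, train_config(seed = 1))
res
#> leave-one-mosaic-out over 3 sites
#>   fold 1 (test S1): TPR 1.000 ACC 1.000 | Dice 0.197 -> 0.571 | cover 1.000 -> 1.000
#>   fold 2 (test S2): TPR 1.000 ACC 1.000 | Dice 0.169 -> 0.518 | cover 1.000 -> 1.000
#>   fold 3 (test S3): TPR 1.000 ACC 1.000 | Dice 0.182 -> 0.563 | cover 1.000 -> 1.000
#>   pooled: TPR 1.000 ACC 1.000 | Dice 0.183 -> 0.551
```

Refinement roughly triples the pixel Dice of the predicted masks (large
coarse footprints contain mostly non-bush pixels) while ground-truth cover
stays high — the qualitative signature of the coarse-to-fine step.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study and write tables
under `results/`:

1. `01_simulate_scenes.R` — synthetic site + three-mosaic corpus, scene
   export with manifest.
2. `02_bush_inventory.R` — bush records, inventory table, height
   histograms.
3. `03_spread_patterns.R` — 3 m / 6 m cluster tables, density, hotspots,
   persistence radii.
4. `04_patch_classifier.R` — leave-one-mosaic-out training, per-fold
   metrics, refinement table.
5. `05_report.R` — assembled run report.

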