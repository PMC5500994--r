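# orchardcanopy

Individual-tree delineation and 3-D phenotyping from orchard digital surface
models (DSMs), with multi-temporal pruning analysis.

Given a geo-referenced elevation raster of an orchard — the kind produced by
UAV photogrammetry at a few centimeters per pixel — the package automatically
finds every tree and measures, per tree, its projected canopy area (m²),
height (m) and crown volume (m³). Run on DSMs from several dates, it matches
trees across dates by their plantation (row, column) position and quantifies
the impact of pruning, the annual regrowth and the restoration of each tree
and each pruning treatment. It is aimed at precision-agriculture researchers
and agronomists working with woody crops (olives, vineyards, fruit orchards).

## The algorithm

Delineation is object-based image analysis (OBIA) in four phases, driven by
the height layer only:

1. **Chessboard segmentation** — the DSM is tiled into 1 m² square objects.
2. **Coarse classification** — a tile is *tree* iff the population standard
   deviation of its DSM values satisfies SD > 0.10 m (strictly), else
   *bare soil*: canopies are rough, soil is flat.
3. **Border refinement** — tree tiles touching soil are re-segmented at the
   pixel level; a border pixel with elevation *z* joins the trees iff
   |z − μ_tree| < |z − μ_soil|, the class means taken in a local circular
   window (adaptively widened where a class is absent). Newly exposed soil
   makes neighbouring tiles borders in a next pass. The result is labeled
   into 8-connected components; enclosed holes are joined into their tree and
   dust components (< 0.5 m²) dropped.
4. **Per-tree features** — for every tree *T* with local bare-soil ground
   reference z₀ (mean soil DSM in a 1 m buffer ring around the crown):

   - height  h(T) = max_{px ∈ T} z(px) − z₀
   - area    A(T) = |T| · a_px
   - volume  V(T) = Σ_{px ∈ T} a_px · max(0, z(px) − z₀)

   plus the centroid, its rounded (row, column) plantation-grid identity and
   the treatment of its row block.

Change statistics per matched tree and date pair use
`% = 100 · (later − earlier) / earlier`, summarized per treatment as
mean ± SD, and per pruning-severity class (`<10%`, `10–30%`, `30–50%`,
`>50%` of crown volume removed).

Because public centimeter-scale orchard DSMs with per-tree truth do not
exist, the package ships a synthetic-orchard simulator: half-ellipsoid
crowns on a 27 × 24 grid at 8 × 4 m spacing (648 trees, three 9-row
treatment sub-plots), with closed-form truth for area, height and volume —
including exact truncated integrals for mechanical topping cuts — and
simulators for traditional / adapted / mechanical pruning and
severity-dependent regrowth. See the methods vignette
(`vignettes/orchard-obia-methods.Rmd`) for the model, parameter defaults and
design rationale.

## Worked example

```r
library(orchardcanopy)

cfg <- orchard_config(n_rows = 3, n_cols = 4, origin_xy = c(8, 8),
                      treatment_blocks = list(traditional = 1, adapted = 2,
                                              mechanical = 3))
sim <- simulate_orchard_series(cfg, seed = 42)   # three dates + exact truth
scene <- sim$dates$date1$scene
scene
#> <multilayer_scene> date1  (no RGB)
#> <dsm_grid> 560 x 480 px @ 0.05 m (24 x 28 m)
#>   origin (xmin, ymax): 2.000, 30.000   crs: synthetic local grid (m)
#>   elevation range: 100.000 .. 104.276 m   nodata: 0 px

mask <- delineate(scene)                         # phases 1-3
mask
#> <tree_mask> 12 trees over 560 x 480 px @ 0.05 m

records <- extract_features(mask, scene, cfg)    # phase 4
records[1:4, c("tree_id", "row", "column", "treatment",
               "area_m2", "height_m", "volume_m3")]
#>   tree_id row column   treatment area_m2 height_m volume_m3
#> 1       1   1      1 traditional   10.95    4.021     31.67
#> 2       2   1      2 traditional   10.26    4.060     29.95
#> 3       3   1      3 traditional   10.60    3.895     29.72
#> 4       4   1      4 traditional   11.69    4.085     34.22
```

Each row is one delineated tree: ~10–12 m² crowns of ~4 m height holding
~30 m³ of canopy, located on plantation row 1. Comparing dates 1 and 2
quantifies what each pruning treatment removed:

```r
r2 <- extract_features(delineate(sim$dates$date2$scene),
                       sim$dates$date2$scene, cfg)
impact <- change_table(match_trees(records, r2)$pairs, "impact")
s <- summarize_change(impact)
s[s$feature == "volume", c("treatment", "n_trees", "mean_delta",
                           "sd_delta", "mean_pct")]
#>     treatment n_trees mean_delta sd_delta mean_pct
#> 3 traditional       4    -11.309    0.753  -36.025
#> 6     adapted       4    -16.774    1.319  -47.110
#> 9  mechanical       4     -0.199    0.234   -0.593
```

The traditional block was simulated at a 36% volume-removal fraction and is
recovered at −36.0%; the adapted block loses more than its nominal 42%
because the simulated central gap removes additional volume; mechanical
topping at 3.5–4 m barely touches these ≤4.4 m crowns.

The same machinery is scriptable end to end (`run_pipeline()` with a YAML
config, or the CLI in `inst/scripts/orchard-obia.R` with `generate`,
`delineate`, `features`, `compare` and `run` subcommands), writing feature
CSVs, GeoJSON crown polygons, change and severity tables, four-level maps
and a manifest with every parameter and seed.

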