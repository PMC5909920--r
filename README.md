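# plantspace

Locates individual row-crop plants (maize seedlings around the V2 stage) in
nadir RGB images taken from a low-flying UAV and measures the ground-metric
**interval distance** between consecutive plants within each planting row —
the stand-uniformity quantity agronomists assess right after emergence. It
is written for crop scientists and precision-agriculture engineers who have
a down-looking RGB frame plus a handful of priors (camera height, angle of
view, average plant height, row direction and width) and want a per-row
table of plant spacings with accuracy metrics, without GPS, orthomosaics or
a learned detector.

## Method

The pipeline chains five steps, each exposed as a data-frame-in /
tibble-out function:

1. **Geometry.** A nadir camera at height *H* with diagonal angle of view
   *v* covers a ground diagonal *L* = 2 tan(*v*/2) *H*; pixels map linearly
   to ground meters (`camera_model()`, `pixel_to_metric()`).
2. **Segmentation.** Excess-green index EXG = 2*g* − *r* − *b* on chromatic
   coordinates, thresholded by Otsu or a fixed cutoff; 8-connected
   components are filtered by *relative* area/shape cutoffs
   (`t_area`, `t_shape`, default 0.3/0.3 of the collection means) and
   fragments re-joined by dilation-buffer merging (`compute_exg()`,
   `threshold_vegetation()`, `extract_objects()`, `filter_objects()`,
   `merge_fragments()`).
3. **Perspective correction.** An off-nadir plant of height *AD* projects
   its canopy centroid *B* radially outside its stem *A*; similar triangles
   give the displacement *AB* = *AD*·*OB* / (2*H* − *AD*), and the stem is
   recovered by moving *B* that far toward the nadir point
   (`correct_plants()`).
4. **Rows.** With the row angle and width as priors, an iterative
   seed–buffer–recentre procedure (buffer = ⅓ row width) partitions plants
   into ridge lines; vegetation beyond the buffer of every ridge is flagged
   as weeds (`detect_ridges()`, `prune_ridges()`, `filter_weeds()`).
5. **Spacing and accuracy.** Stems project to perpendicular feet on their
   ridge, are ordered along the row from a far reference point, and
   consecutive differences become intervals; accuracy against truth is
   *d*<sub>e</sub> (mean absolute error), *r* = *d*<sub>e</sub>/*d*
   (relative to the design interval, in %) and the signed bias
   *d*<sub>t</sub>, with row-wise unpaired-mean variants for scenes where
   estimated and measured counts differ (`project_to_ridges()`,
   `measure_spacing()`, `pairwise_metrics()`, `rowwise_metrics()`).

A forward-model simulator (`scene_spec()`, `render_scene()`,
`scenario_grid()`) renders row-planted scenes — soil noise, leaf-pair
glyphs with realistic centroid asymmetry, optional inter-row weeds and
residue — with full ground truth, using the same displacement model in the
forward direction, so the whole chain is validated end-to-end in the test
suite. No external imagery is required.

## Worked example

```r
library(plantspace)

scene <- render_scene(indoor_scene_spec(interval_m = 0.18, height_m = 2,
                                        seed = 42))
cfg <- run_config(camera = scene$cam, plant_height_m = 0.10,
                  row_angle_deg = 90, row_width_m = 0.765,
                  threshold_mode = "fixed", fixed_threshold = 0)
run <- run_pipeline(scene$image, cfg)
run
#> <spacing_run> 25 objects -> 25 plants on 3 ridges; 22 intervals, mean 0.182 m (sd 0.015)

evaluate_run(run, scene$truth, "pairwise", design_d_m = 0.18)
#> # A tibble: 1 × 4
#>   d_e_cm r_pct d_t_cm     n
#>    <dbl> <dbl>  <dbl> <int>
#> 1   1.04  5.79  0.504    22

head(tidy(run), 3)
#> # A tibble: 3 × 8
#>   ridge_id plant_id_a plant_id_b interval_m cum_a_m cum_b_m duplicate_pair
#>      <int>      <int>      <int>      <dbl>   <dbl>   <dbl> <lgl>
#> 1        1          3          5      0.192   0       0.192 FALSE
#> 2        1          5          8      0.193   0.192   0.385 FALSE
#> 3        1          8         11      0.182   0.385   0.567 FALSE
```

The scene is a simulated 18 cm planting photographed from 2 m: 26 stems on
three 76.5 cm rows. The pipeline finds 25 objects (one close pair merged),
measures 22 within-row intervals averaging 0.182 m, and — against the
simulator's truth — gets each interval right to about 1 cm, a 5.8% relative
error with half a centimeter of bias. `autoplot(run, image = scene$image)`
draws the diagnostic overlay (red canopy centroids, blue corrected stems,
grey ridge lines); `glance(run)` gives the one-row run summary.

A thin command-line front end wraps the same functions for shell use
(`exec/plantspace`, installed with the package):

```sh
plantspace simulate --config scene.yaml --out sim/
plantspace run --image sim/scene.png --config run.yaml --out out/ --emit-overlay
plantspace evaluate --est est.csv --truth truth.csv --mode rowwise
```

YAML keys may use `_cm` anywhere a `_m` length is expected.

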