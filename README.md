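# porcimetry

Point-cloud morphometry and neural body-weight prediction for growing
pigs.

Manual weighing and taping of pigs is slow, stressful for the animals and
error-prone, so commercial farms increasingly estimate body measures from
depth-camera recordings instead. porcimetry implements that workflow as a
reproducible R pipeline for researchers in precision livestock farming
and for anyone who needs a fully testable reference implementation:

1. **Synthetic scenes with ground truth** — a parametric pig body (lofted
   superellipse cross-sections with head, withers and belly anatomy),
   pen floor, railings, sparse noise, a three-camera rig and a reference
   calibration cuboid. Every measured quantity is known analytically, so
   the whole pipeline is verifiable without farm hardware.
2. **Rigid multi-view registration** — per-view Euler-angle rotation
   matrices `R = RMq RMr RMs` and translations `T`, with `p' = R p + T`;
   the per-camera transforms are calibrated from least-squares fits of
   the cuboid's face planes.
3. **Scene filtering** — pass-through cropping, RANSAC floor-plane
   removal, radius outlier removal (keep a point iff it has at least `h`
   neighbours within radius `r`).
4. **Morphometry** — body length as the dorsal-ridge arc length
   `L = ∫ sqrt(dx² + dy² + dz²)`; withers height as the second prominent
   maximum of the height profile above the floor plane; abdominal width
   as the maximal lateral extent between the limb girdles; abdominal
   circumference by mapping the slice to polar coordinates
   `ρ_i = sqrt((y_i−y_0)² + (z_i−z_0)²)` about the slice centroid,
   fitting a periodic cubic B-spline ρ = f(θ), and evaluating
   `S = ∫₀^{2π} sqrt(f(θ)² + f'(θ)²) dθ`.
5. **Tabular pipeline** — record cleaning (age in days, one-hot breed and
   sex, median height imputation), per-row L2 normalization, Pearson
   correlation matrix, variance-threshold feature selection.
6. **Weight models** — multilayer perceptrons `[D, 5, 4, 4, 1]` with ReLU
   hidden layers, trained with Adam (lr 0.01, 300 epochs, batch 10) on a
   70/15/15 split and scored by MSE, RMSE = sqrt(MSE), MAE and MAPE
   (reported as a fraction). Four feature variants are provided, from all
   ten features (model 1) down to abdominal circumference + age
   (model 3).

## Worked example

Measure a synthetic pig and train the two-feature weight model:

```r
library(porcimetry)

pig <- generate_pig_cloud(pig_shape(), n = 1e5, noise_sd = 0, seed = 1)
measure_pig(pig$cloud)
#> morphometry_result
#>   body length: 1.1961 m
#>   withers height: 0.7000 m
#>   abdominal width: 0.3800 m
#>   abdominal circumference: 1.2160 m
#>   slice position: 0.5900 m

pig$truth        # generator ground truth, derived from the shape itself
#> morphometry_result
#>   body length: 1.2000 m
#>   withers height: 0.7000 m
#>   abdominal width: 0.3800 m
#>   abdominal circumference: 1.2131 m
#>   slice position: 0.5868 m

herd <- generate_herd_records(5000, seed = 1, noise_sd_kg = 2)
fit  <- fit_weight_model(clean_records(herd), model_id = 3, seed = 1)
fit$report
#> evaluation_report (n = 750)
#>   MSE  4.5419
#>   RMSE 2.1312
#>   MAE  1.6878
#>   MAPE 0.0152
```

The measured length, height, width and circumference sit within a
fraction of a percent of the ground truth, and the two-feature model's
test RMSE of 2.13 kg is essentially the 2 kg noise floor the herd was
generated with — the model has recovered the underlying weight law.

`run_measurement_pipeline()` and `run_weight_pipeline()` run the
end-to-end versions (scene → views → registration → filtering →
measurement; herd → features → four models → metrics table), and
`inst/scripts/porcimetry.R` exposes them as a command-line tool
(`simulate`, `register`, `filter`, `measure`, `features`, `train`,
`evaluate`, `run-all`).

## Package layout

- `R/` — synthetic scenes (`pig_shape`, `compose_scene`, `render_views`,
  `generate_herd_records`), registration (`rotation_from_angles`,
  `apply_transform`, `estimate_cube_registration`, `merge_views`),
  filtering (`pass_through`, `remove_floor`, `radius_outlier_removal`),
  morphometry (`measure_pig` and its parts), the tabular pipeline
  (`clean_records`, `normalize_rows`, `variance_filter`, `feature_set`)
  and the MLP (`build_model`, `train_mlp`, `evaluate_predictions`).
- `src/` — compiled neighbour counting and the Adam training loop.
- `vignettes/porcimetry-methods.Rmd` — the model and algorithm notes,
  parameter choices and known limitations.
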