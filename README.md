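# pigweigh

Estimate the live body weight of grow-finish pigs (20–120 kg) from
top-down 3D point clouds captured by a single ceiling-mounted depth camera
(≈2.7 m above the pen floor).

The package implements and compares the two standard routes from cloud to
weight:

* **Projected-volume baseline.** The cloud's heights above the floor
  (`h = L − z`, floor at `z = L`) are rasterized onto a 1 cm grid keeping
  the per-cell maximum, summed into a 2.5D volume
  `V = step² · Σᵢⱼ hᵢⱼ`, and weight is regressed on volume by OLS,
  `w = β₀ + β₁ V`, reported with `R² = 1 − SS_res/SS_tot` and
  `RMSE = √(SS_res/n)`.
* **Point-set neural regressor.** A PointNet-style network
  `f(X) = ReLU(g(max-pool(φ(X·T(X)))))` consumes the raw 1500 × 3 point
  set: an input T-Net predicts a 3×3 alignment, a shared per-point MLP
  (64-64-64-128-1024, batch-norm + ReLU) extracts features, channel-wise
  max pooling makes the output permutation-invariant, and a dense head
  (512-256) regresses a nonnegative weight. Training: Adam (lr 0.01), MSE
  loss, minibatch 32, per-epoch uniform jitter of ±0.005 m on training
  clouds, 9:1 train/validation split, early stopping (patience 10) with
  best-epoch restoration. The forward/backward/Adam core is implemented in
  C++ (RcppArmadillo); no deep-learning framework is required.

Around the two models sit the full pipeline: PLY/CSV point-cloud I/O, the
animal-extraction filter chain (depth band → polygon ROI → Otsu colour
segmentation → statistical outlier removal), random subsampling to the
canonical 1500 points, automated head cropping for the volume baseline, a
synthetic pig-cloud generator with exact ground truth (superellipsoid body,
ellipsoidal head and neck, posture and pen-position perturbations,
depth-sensor artifacts), and evaluation by weight class (<55, 55–90,
≥90 kg).

## Worked example

Generate a synthetic herd, train both models, and compare them on a
reserved test set:

```r
library(pigweigh)

ex <- run_experiment(n_animals = 80, clouds_per_animal = 5,
                     n_test = 50,
                     config = pointnet_config(width_scale = 0.25),
                     control = pointnet_control(max_epochs = 60),
                     seed = 1)
print(ex)
#> Two-method weight-prediction experiment (350 train, 50 test clouds)
#>
#>    class  n volume_r2 volume_rmse pointnet_r2 pointnet_rmse
#>      <55 13     0.727       6.714       0.937         3.231
#>    55-90 19     0.896       3.475       0.920         3.043
#>     >=90 18     0.545       4.528       0.881         2.311
#>  overall 50     0.969       4.867       0.989         2.856
```

Each row gives, per weight class and overall, the number of test clouds
and the coefficient of determination and RMSE (kg) of each method. The
pattern mirrors the motivating field result: the volume baseline degrades
where posture perturbs the projected volume (and per-class, as weight
grows), while the point-set network stays accurate across classes and
beats the baseline overall — here 2.86 kg versus 4.87 kg test RMSE on
identical clouds.

The pieces are available individually:

```r
ds  <- make_dataset(n_animals = 10, clouds_per_animal = 7, seed = 1)
cl  <- ds$clouds[[1]]                      # a 1500-point cloud
v   <- cloud_volume(cl, crop = TRUE)       # head-cropped 2.5D volume, m^3
fit <- pointnet(ds$clouds, ds$labels$weight_kg,
                config = pointnet_config(width_scale = 0.25),
                control = pointnet_control(max_epochs = 30, seed = 1))
predict(fit, ds$clouds[1:3])               # kg
plot(fit)                                  # training history
```

A thin command-line front end over the same functions lives at
`inst/cli/pigweigh.R` (subcommands `simulate`, `preprocess`, `volume`,
`train`, `predict`, `evaluate`, `experiment`).

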