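---
title: "Estimating pig body weight from top-down point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pig body weight from top-down point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigweigh)
```

## The problem

Weighing grow-finish pigs (20--120 kg) individually is labour-intensive and
stressful for the animals, yet weight drives marketing decisions and is an
early indicator of health problems. A single depth camera mounted about
2.7 m above a holding pen sees the animal's back as a 3D point cloud, and
two routes lead from that cloud to a weight estimate:

1. **A projected-volume baseline.** Rasterize the cloud's heights above the
   floor onto a 1 cm grid, sum the per-cell maxima into a "2.5D" volume, and
   regress scale weight on volume by ordinary least squares. This is the
   conventional machine-vision approach; it works well when the animal
   stands still in a canonical pose and degrades when it does not, because
   posture (especially the head) changes the projected volume while the
   animal's mass stays fixed.
2. **A point-set neural regressor.** Feed the raw point set to a
   PointNet-style network -- shared per-point layers, a symmetric max-pool
   aggregation, a dense head -- which learns features that are robust to the
   posture and position changes that corrupt the volume signal.

`pigweigh` implements both, end to end: point-cloud I/O, the filter chain
that isolates the animal from the pen scene, the rasterizer and baseline
fit, the network and its training loop, and a synthetic-data generator with
known ground truth so that every stage is testable without animal data.

## Scene filtering

A raw frame contains the floor, the pen walls, and occasionally off-colour
clutter. The extraction chain applies, in order:

* **Depth band** (`depth_band_filter`): keep points with
  `z_min <= z <= z_max`. The floor plane at `z = L` and most wall structure
  fall outside the band of depths at which a pig's back appears.
* **Polygon region of interest** (`polygon_roi_filter`): keep points whose
  `(x, y)` lies in the pen's interior polygon. Containment is ray casting
  with a half-open edge rule and an explicit boundary test, so points
  exactly on an edge are kept; edge handling is otherwise arbitrary, and
  fixing it makes the filter deterministic.
* **Colour segmentation** (`color_segment`): convert RGB to grayscale with
  the standard luma weights 0.299/0.587/0.114, threshold with Otsu's method
  on the 256-bin 8-bit histogram, and keep the side of the threshold
  holding the majority of points. After the two spatial filters the animal
  dominates the scene, so the majority class is the animal; a 50/50 tie is
  broken toward the brighter class because pigs image lighter than
  background shadow. When the between-class variance has a plateau of
  maximizing thresholds (e.g. a two-valued histogram) the middle of the
  plateau is returned, so a symmetric bimodal input yields a threshold
  strictly between the modes. Degenerate single-valued colour input leaves
  the cloud unchanged with a warning.
* **Statistical outlier removal** (`remove_statistical_outliers`): drop
  points whose mean distance to their `k = 20` nearest neighbours exceeds
  the global mean by more than `std_ratio = 2` standard deviations. The
  defaults are the common choice for depth-sensor speckle; the rule is
  deliberately not idempotent (re-running recomputes the statistics on the
  survivors).

Every filter returns an order-preserving subsequence of its input with
colours carried along -- asserted point-by-point in the tests against
brute-force per-point oracles, including an end-to-end comparison on a
generator-labelled synthetic scene.

Two further operations support the models:

* **Random subsampling** (`random_subsample`) draws exactly `n = 1500`
  points uniformly without replacement (the fixed network input size). By
  default a smaller cloud is an error; `pad = "resample"` duplicates
  uniformly chosen points instead, which the dataset generator uses because
  dropout artifacts can push a cloud below the target size.
* **Jitter** (`jitter_points`) perturbs every coordinate by an independent
  uniform draw in `[-0.005, +0.005]` m. Uniform, not clipped-Gaussian: the
  stated bounds are the definition here. Training applies it afresh each
  epoch to training clouds only.

## Automated head cropping

Head-up/head-down posture changes the projected volume substantially, so
the baseline benefits from removing the head and neck before volume
computation. Done manually in practice (find the narrowest neck width by
eye, crop everything above it), here it must be deterministic:

1. find the principal body axis in the `xy` plane (SVD of the centred
   coordinates);
2. slice the cloud into 2 cm bins along the axis and record each slice's
   transverse extent, ignoring slices with fewer than 0.5 % of the points;
3. call the end with the smaller mean slice width over its 35 % of the axis
   the anterior (head) end;
4. among slices whose centre lies between 5 % and 35 % of the body length
   from the anterior tip, consider only slices with a distinctly wider
   structure (≥ 15 % wider) anterior to them -- a neck has a head beyond
   it, whereas the monotone taper of a bare body tip does not;
5. cut at the narrowest qualifying slice, removing everything anterior.

Step 4 is the load-bearing refinement: a naive "narrowest slice in the
anterior region" rule always picks the outermost sliver of *any* convex
body (slice width goes to zero at a tip), and would therefore never remove
a head. Requiring anterior prominence makes the crop a no-op on headless
bodies (the tests require ≥ 95 % retention there) while reliably separating
a head joined through a neck narrower than both body and head.

## The 2.5D volume and the linear baseline

`rasterize_height_grid` anchors a grid of `step = 0.01` m at the cloud's
`(min x, min y)` corner with half-open cell membership -- anchoring to the
cloud makes the result translation-covariant and deterministic -- and
stores in each cell the *maximum* height `L - z` over the points falling in
it; empty cells contribute zero and are not interpolated. `grid_volume`
returns `step^2 * sum(heights)`. Points exactly at the floor (`z = L`) are
legal and contribute nothing; points below the floor (`z > L`) are
rejected rather than clamped.

Two discretization effects deserve attention because they pull in opposite
directions:

* the per-cell **max** rule overestimates curved surfaces by `O(step)`
  (each cell reports its highest sample, not its mean); on a hemisphere of
  radius 0.25 m this saturates near +5 % at a 1 cm step regardless of
  sampling density, and drops under 1 % at 2.5 mm;
* **empty cells** underestimate: a 1500-point cloud over a mid-size pig's
  ~2000 footprint cells leaves roughly half of them empty.

At moderate densities (about five points per cell) the two effects largely
cancel, which is where the generator-versus-rasterizer agreement test
operates; the tests of closed-form solids use a flat slab at the 1 cm step
(no curvature bias) and a 2.5 mm step for the hemisphere. For the baseline
itself none of this matters much: the OLS slope absorbs any systematic
scale factor, and only the *variance* of the coverage degrades the fit.

`fit_weight_volume` delegates the OLS fit to `stats::lm` and reports slope,
intercept, `R^2 = 1 - SS_res/SS_tot` and `RMSE = sqrt(SS_res/n)` (division
by `n`, matching the evaluation metric, not the `n - 2` of regression
inference). For a univariate linear fit this `R^2` equals the squared
Pearson correlation of volume and weight.

## The point-set regressor

The network maps an `n x 3` coordinate array to one nonnegative scalar:

* **Featurization.** Each cloud is centred at its `xy` centroid and `z` is
  re-expressed as height above the floor, `L - z`. Coordinates are *not*
  rescaled to a unit sphere, deliberately: the animal's absolute size is
  the weight signal, and the standard PointNet normalization would destroy
  it. Centring only removes pen position, which carries no mass
  information.
* **Input transform (T-Net).** A small point network (shared layers
  32-64-256, max pool, dense 128-64) predicts a 3x3 matrix applied to the
  points, initialized to the exact identity (zero weights, identity bias).
  It learns to align clouds to a canonical orientation; a trained T-Net
  model shifts its predictions less under in-plane rotations than an
  ablated one, which the tests assert at fixed seeds. The feature-space
  transform between shared layers is removed from this architecture for
  computational simplicity, and with it the usual orthogonality
  regularizer, whose target it was.
* **Shared MLP** with widths 64-64-64-128-1024, each layer dense (no bias)
  + batch normalization + ReLU, applied identically to every point.
* **Max pooling** per feature channel over the cloud's points -- the
  symmetric aggregation that makes the output invariant to point order
  (exactly so in exact arithmetic; the tests allow 1e-4 kg for
  floating-point noise, observed differences are orders of magnitude
  smaller).
* **Head** of dense 512-256 layers (again BN + ReLU) and a final dense unit
  with a ReLU output, so predicted weights are nonnegative by construction.

`width_scale` multiplies every width (minimum 4) so the full architecture
can run at desk scale; 0.25 is used throughout the scaled experiments.

**Training** (`pointnet`): Adam at a constant learning rate 0.01 (no
schedule), MSE loss in kg², RMSE tracked in kg, minibatches of 32 (the
batch size is otherwise unconstrained; 32 is the conventional choice),
up to 1000 epochs with early stopping at patience 10 on the validation
RMSE, restoring the best-epoch weights (including batch-norm running
statistics). The dataset is split 9:1 into training and validation at the
cloud level -- grouping all clouds of an animal on one side of the split is
deliberately *not* enforced, matching a protocol in which test clouds are
drawn from the same animals; the experiment-level test split is cloud-level
too. Jitter is applied on the fly each epoch to training clouds only;
validation and test clouds are never augmented. The rectified output unit
starts at the training-label mean so it begins in its active regime.

Two implementation choices are worth recording. Batch normalization is not
mentioned in the usual one-line architecture summaries but is part of the
reference PointNet blocks; at learning rate 0.01 it is also what keeps
training stable. And the forward/backward/Adam loop is written in C++
(RcppArmadillo) with all workspaces preallocated and reused across batches,
which is what makes the scaled experiments run in minutes on one core; no
deep-learning framework is involved.

**Determinism contract:** one integer seed drives initialization, the
split, epoch shuffling and jitter (all randomness is drawn from R's RNG,
including inside the C++ core), so identical seeds give bit-identical
histories on the same BLAS and threading configuration; the tests run
single-threaded.

## The synthetic generator

The generator produces clouds whose ground truth is known exactly, so the
pipeline can be validated without the study's animals. A pig is a
superellipsoid body (half-axes 0.45 x 0.14 x 0.13 m, exponent 2.5, resting
on the floor) joined to an ellipsoidal head (35 % of body scale) through a
narrower ellipsoidal neck (radius 25 % of the body half-width). Only the
camera-visible top surface is sampled: candidate `xy` positions are drawn
over the footprint, assigned the *upper envelope* height of all components
(which also resolves occlusion along the camera ray), and accepted
area-weighted with the weight capped at 8 so that near-vertical flanks --
which a top-down camera barely sees -- are not oversampled. Because the
body is a full solid standing on the floor, the projected (top-view)
volume of the equal-axes, exponent-2, headless limit is
`pi r^3 + (2/3) pi r^3` (the column under the equator plus the upper
hemisphere), which is the closed form the tests check; legs are omitted as
invisible from above and irrelevant to the 2.5D volume.

`reference_projected_volume` integrates the same height functions on a
2 mm grid, in closed form per component (the superellipsoid height
directly, the head/neck as quadric top-surface roots), entirely
independent of the point-cloud rasterizer it serves as an oracle for.

**Weight labels** are `density_coeff x` canonical-posture volume plus
Gaussian noise (`sd` 2 kg), truncated into the requested range. The
density coefficient defaults to 1000 kg/m³, which puts realistic body
dimensions in the 20--120 kg range. Posture fields (yaw, pen offset, head
pitch) are zeroed before the volume is computed: posture changes what the
camera sees, never the animal's mass. This is the central property of the
design -- the label is invariant to the perturbations, the projected
volume is not (a lowered head visibly reduces it), so the baseline
degrades on perturbed data while the network can learn the invariance.

**Sensor artifacts** emulate real depth-capture quality issues with
declared (not fitted -- no quantitative characterization exists to fit)
defaults: a sinusoidal z-displacement of amplitude 1 cm and frequency
2 cycles/m in a random direction, two deleted discs of radius 6 cm, and
3 mm isotropic Gaussian noise.

**Datasets** (`make_dataset`) draw per-animal target weights uniformly in
range, scale the base body isotropically (volume, hence weight, scales as
the cube), and capture several clouds per animal at independently drawn
yaw (uniform over the circle), pen offset (±0.4 m by ±0.25 m) and head
pitch (−0.5 to +0.1 rad, head-down more common), all inside a 2.9 x 1.5 m
pen. `make_test_scene` adds a floor plane at `z = L`, wall bands, and a
dark distractor blob, each point labelled by source, for exact filter-chain
validation.

What the generator does *not* emulate: perspective foreshortening and
self-occlusion changing with pen position (offsets translate the cloud
rigidly), multi-animal scenes, articulated posture beyond head pitch, ear
and tail detail, and any nonlinearity in the weight--volume relationship
(the generator is linear by construction, which is precisely what the
clean-data `r² > 0.99` check exploits). Passing the synthetic recovery
experiment therefore demonstrates that the pipeline's machinery works and
that the network can out-predict the volume baseline under posture
perturbations and sensor artifacts; it does not certify accuracy on real
animals.

## Evaluation

`evaluate_predictions` reports `n`, `R²` and RMSE overall and within three
weight classes -- below 55 kg, 55--90 kg, at and above 90 kg -- with
half-open boundaries (55.0 falls in the middle class, 90.0 in the upper)
and membership decided by the *actual* scale weight. Per-class `R²` is the
coefficient of determination about the class mean, computed within the
class; single-sample or constant classes report RMSE only. The overall MSE
equals the class-size-weighted mean of class MSEs, asserted numerically in
the tests.

`run_experiment` ties everything together: generate or accept a dataset,
reserve a cloud-level random test set, fit the baseline on head-cropped
training clouds, train the network on the same training clouds, evaluate
both on the identical test set.

## Problem sizes and numerical choices

The scaled recovery experiment used by the tests and the acceptance script
runs 80 animals x 5 clouds of 1500 points (20--120 kg, perturbations and
mild artifacts on), a 50-cloud reserved test set, a quarter-width network,
and at most 60 epochs; one run takes a few minutes on one core, and the
overfit sanity check (16 clouds, 200 epochs) about half a minute. Other
defaults: batch-norm epsilon 1e-5 and running-statistics momentum 0.9;
Adam beta of 0.9/0.999 and epsilon 1e-8; He-normal dense initialization;
early-stopping improvement is strict (`<`), ties do not reset patience.
Degenerate inputs fail loudly rather than silently: empty clouds cannot be
rasterized, constant actuals have no `R²`, all-identical intensities have
no Otsu threshold, collinear clouds have no body axis.

## Known limitations

* The preprocessing defaults (depth band, ROI polygon, outlier parameters)
  are declared choices, not values recovered from any particular rig;
  real installations must calibrate them.
* The head crop is a deterministic proxy for a manual step; on clouds with
  severe dropout through the neck region it can decline to crop (it then
  returns the cloud unchanged).
* The volume baseline inherits the coverage noise of 1500-point clouds at
  a 1 cm grid; denser clouds tighten it considerably.
* Real weight--volume relationships flatten for large pigs; the linear
  generator does not reproduce that regime, so per-class degradation
  patterns on synthetic data are milder than on real animals.
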