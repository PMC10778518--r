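# The point-set regressor: contracts, invariances, training behaviour.
# Desk-scale configs (few hundred points, width_scale <= 0.25) keep these
# fast; the scaled recovery experiment lives in test-acceptance.R.

tiny_cfg <- function(n = 256L, scale = 0.1, tnet = TRUE)
  pointnet_config(n_points = n, width_scale = scale, use_input_transform = tnet)

tiny_ds <- function(n_animals, cpa = 1L, n = 256L, seed = 1L, ...)
  make_dataset(n_animals = n_animals, clouds_per_animal = cpa, n_points = n,
               n_raw = 800L, seed = seed, ...)

test_that("model maps a batch of clouds to one nonnegative scalar each", {
  m <- pointnet_build(tiny_cfg(), seed = 1)
  ds <- tiny_ds(4, seed = 2)
  p <- predict(m, ds$clouds)
  expect_length(p, 4L)
  expect_true(all(p >= 0))  # rectified output, even untrained

  set.seed(3)  # adversarial inputs: rectified head keeps the output >= 0
  weird <- lapply(1:5, function(i) matrix(rnorm(256 * 3, sd = 5), 256, 3))
  expect_true(all(predict(m, weird) >= 0))

  expect_error(predict(m, list(matrix(0, 100, 3))), "exactly 256")
  expect_error(pointnet_config(use_feature_transform = TRUE), "removed")
})

test_that("trainable parameter count equals the layer-by-layer hand sum", {
  cfg <- pointnet_config(n_points = 64, use_input_transform = FALSE,
                         shared_mlp_widths = c(8, 16), head_widths = 8)
  m <- pointnet_build(cfg, seed = 1)
  # dense W + batch-norm scale/shift per block, plus the biased output unit
  hand <- (3 * 8 + 8 + 8) + (8 * 16 + 16 + 16) + (16 * 8 + 8 + 8) + (8 * 1 + 1)
  expect_identical(n_parameters(m), as.integer(hand))
})

test_that("inference is deterministic and permutation-invariant", {
  ds <- tiny_ds(12, seed = 4)
  m <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(),
                pointnet_control(max_epochs = 10, seed = 4))
  cl <- ds$clouds[[1]]
  expect_identical(predict(m, list(cl)), predict(m, list(cl)))

  set.seed(5)
  base <- predict(m, list(cl))
  for (i in 1:10) {
    shuf <- cl$points[sample(nrow(cl$points)), ]
    expect_lt(abs(predict(m, list(shuf)) - base), 1e-4)
  }
})

test_that("a constant-label dataset is learned to under 1 kg", {
  ds <- tiny_ds(12, seed = 6)
  m <- pointnet(ds$clouds, rep(50, 12), tiny_cfg(),
                pointnet_control(max_epochs = 30, seed = 6))
  expect_lt(m$best_val_rmse, 1)
})

test_that("training is bit-reproducible from the seed", {
  ds <- tiny_ds(12, seed = 7)
  ctl <- pointnet_control(max_epochs = 8, seed = 7)
  m1 <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(), ctl)
  m2 <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(), ctl)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  ctl2 <- pointnet_control(max_epochs = 8, seed = 8)
  m3 <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(), ctl2)
  expect_false(identical(m1$history, m3$history))
})

test_that("jitter augmentation is applied per epoch to training data only", {
  ds <- tiny_ds(12, seed = 9)
  ctl_j <- pointnet_control(max_epochs = 6, seed = 9, jitter = 0.005)
  ctl_0 <- pointnet_control(max_epochs = 6, seed = 9, jitter = 0)
  m_j <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(), ctl_j)
  m_0 <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(), ctl_0)
  expect_false(identical(m_j$history$train_rmse, m_0$history$train_rmse))
  # predictions stay deterministic regardless of the training-time jitter
  expect_identical(predict(m_j, ds$clouds[1:2]), predict(m_j, ds$clouds[1:2]))
})

test_that("early stopping halts within patience of the best epoch and
           restores the best weights", {
  ds <- tiny_ds(24, cpa = 2L, seed = 10)
  ctl <- pointnet_control(max_epochs = 60, patience = 5, seed = 10)
  m <- pointnet(ds$clouds, ds$labels$weight_kg, tiny_cfg(), ctl)
  expect_lte(m$stopped_epoch, m$best_epoch + 5)
  expect_equal(m$best_val_rmse, min(m$history$val_rmse))
  expect_equal(m$best_epoch, which.min(m$history$val_rmse))

  # the restored model reproduces the best validation RMSE exactly
  val_pred <- predict(m, ds$clouds[m$val_indices])
  val_rmse <- sqrt(mean((val_pred - ds$labels$weight_kg[m$val_indices])^2))
  expect_equal(val_rmse, m$best_val_rmse, tolerance = 1e-10)
})

test_that("input transform improves robustness to in-plane rotation", {
  ds <- make_dataset(n_animals = 15, clouds_per_animal = 4, n_points = 256,
                     n_raw = 1200, artifacts = NULL, seed = 21)
  ctl <- pointnet_control(max_epochs = 30, patience = Inf, seed = 21)
  m_t <- pointnet(ds$clouds, ds$labels$weight_kg,
                  tiny_cfg(scale = 0.25, tnet = TRUE), ctl)
  m_n <- pointnet(ds$clouds, ds$labels$weight_kg,
                  tiny_cfg(scale = 0.25, tnet = FALSE), ctl)
  rot <- function(cl, ang) {
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    ctr <- colMeans(cl$points)
    point_cloud(sweep(sweep(cl$points, 2, ctr) %*% R, 2, ctr, "+"))
  }
  test_cl <- ds$clouds[seq(1, 60, by = 4)]
  shift <- function(m) {
    base <- predict(m, test_cl)
    mean(vapply(c(-0.2, -0.1, 0.1, 0.2), function(a)
      mean(abs(predict(m, lapply(test_cl, rot, ang = a)) - base)), numeric(1)))
  }
  expect_lte(shift(m_t), shift(m_n))
})

test_that("degenerate training inputs are rejected with clear errors", {
  ds <- tiny_ds(12, seed = 12)
  expect_error(pointnet(ds$clouds[1:5], ds$labels$weight_kg[1:5], tiny_cfg()),
               "at least 10")
  expect_error(pointnet(ds$clouds, ds$labels$weight_kg[-1], tiny_cfg()),
               "one weight")
  expect_error(pointnet(ds$clouds, c(-1, ds$labels$weight_kg[-1]), tiny_cfg()),
               "positive")
})
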