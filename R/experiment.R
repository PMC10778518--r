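# The two-method recovery experiment: on one dataset, fit the projected-
# volume linear baseline and the point-set network, evaluate both on an
# identical reserved test set, and report overall plus per-weight-class
# metrics side by side.

#' Run the baseline-versus-network comparison experiment
#'
#' Generates (or takes) a labelled dataset, reserves a test set, fits the
#' linear weight~volume baseline on the head-cropped training clouds, trains
#' the point-set regressor on the same training clouds (with its internal
#' 9:1 train/validation split), and evaluates both methods on the identical
#' test clouds, overall and per weight class.
#'
#' @param dataset a `pig_dataset` from [make_dataset()], or `NULL` to
#'   generate one from the arguments below.
#' @param n_animals,clouds_per_animal,weight_range,artifacts,perturb,n_points
#'   passed to [make_dataset()] when `dataset` is `NULL`.
#' @param n_test number of clouds reserved for testing (uniform random at
#'   cloud level).
#' @param config a [pointnet_config()] for the network.
#' @param control a [pointnet_control()]; its seed is overridden by `seed`.
#' @param grid_step rasterizer step for the volume baseline, meters.
#' @param plane_distance camera-to-floor distance, meters.
#' @param crop head-crop the clouds before volume computation (default
#'   `TRUE`; the network always receives uncropped clouds).
#' @param seed integer seed governing dataset generation, the test split and
#'   network training.
#' @return an object of class `weight_experiment`: list with
#'   `baseline_report` and `pointnet_report` (both [evaluate_predictions()]
#'   reports on the test set), `fit` (the `weight_volume_fit`), `model` (the
#'   trained `pointnet`), and `predictions` (per-test-cloud data frame).
#' @export
run_experiment <- function(dataset = NULL, n_animals = 80L,
                           clouds_per_animal = 5L, weight_range = c(20, 120),
                           artifacts = sensor_artifacts(), perturb = TRUE,
                           n_points = 1500L, n_test = 50L,
                           config = pointnet_config(width_scale = 0.25,
                                                    n_points = n_points),
                           control = pointnet_control(max_epochs = 60L),
                           grid_step = 0.01, plane_distance = 2.7,
                           crop = TRUE, seed = 1L) {
  if (is.null(dataset))
    dataset <- make_dataset(n_animals, clouds_per_animal, weight_range,
                            artifacts, perturb, n_points,
                            plane_distance = plane_distance, seed = seed)
  stopifnot(inherits(dataset, "pig_dataset"))
  n <- length(dataset$clouds)
  if (n_test >= n - 10L)
    stop("n_test leaves too few clouds for training")
  test_idx <- with_seed(seed + 1L, sort.int(sample.int(n, n_test)))
  train_idx <- setdiff(seq_len(n), test_idx)
  y <- dataset$labels$weight_kg

  vol <- vapply(dataset$clouds, function(cl) {
    cl2 <- if (crop) tryCatch(crop_head(cl), error = function(e) cl) else cl
    cloud_volume(cl2, step = grid_step, plane_distance = plane_distance)
  }, numeric(1L))
  fit <- fit_weight_volume(vol[train_idx], y[train_idx])
  pred_vol <- predict(fit, vol[test_idx])

  control$seed <- as.integer(seed)
  model <- pointnet(dataset$clouds[train_idx], y[train_idx],
                    config = config, control = control)
  pred_net <- predict(model, dataset$clouds[test_idx])

  structure(list(
    baseline_report = evaluate_predictions(pred_vol, y[test_idx]),
    pointnet_report = evaluate_predictions(pred_net, y[test_idx]),
    fit = fit, model = model,
    predictions = data.frame(animal_id = dataset$labels$animal_id[test_idx],
                             weight_kg = y[test_idx],
                             volume_m3 = vol[test_idx],
                             pred_baseline = pred_vol,
                             pred_pointnet = pred_net,
                             stringsAsFactors = FALSE),
    n_train = length(train_idx), n_test = n_test, seed = seed),
    class = "weight_experiment")
}

#' @export
print.weight_experiment <- function(x, digits = 3L, ...) {
  cat(sprintf(
    "Two-method weight-prediction experiment (%d train, %d test clouds)\n\n",
    x$n_train, x$n_test))
  b <- x$baseline_report; p <- x$pointnet_report
  tab <- data.frame(
    class = c(as.character(b$per_class$class), "overall"),
    n = c(b$per_class$n, b$overall$n),
    volume_r2 = round(c(b$per_class$r_squared, b$overall$r_squared), digits),
    volume_rmse = round(c(b$per_class$rmse, b$overall$rmse), digits),
    pointnet_r2 = round(c(p$per_class$r_squared, p$overall$r_squared), digits),
    pointnet_rmse = round(c(p$per_class$rmse, p$overall$rmse), digits))
  print(tab, row.names = FALSE)
  invisible(x)
}
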