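# Point-set weight regressor: a PointNet-style network mapping a fixed-size
# cloud of body-surface points to a scalar weight. Per-point shared MLP
# layers (dense + batch norm + ReLU) extract local features, channel-wise
# max pooling aggregates them into a global feature vector (this symmetric
# reduction is what makes the prediction invariant to point order), a dense
# head regresses the weight, and a rectified output keeps it nonnegative.
# An input transform sub-network (T-Net) predicts a 3x3 alignment matrix
# applied to the points before feature extraction; the feature transform
# between shared layers is removed from this architecture for computational
# simplicity.

#' Architecture configuration for the point-set regressor
#'
#' @param n_points fixed input size: every cloud fed to the network must have
#'   exactly this many points (default 1500, the canonical subsample size).
#' @param use_input_transform include the input T-Net, a small point network
#'   that learns a 3x3 linear transform aligning the cloud to a canonical
#'   orientation before feature extraction (default `TRUE`).
#' @param use_feature_transform the feature-space transform between shared
#'   layers was removed from this architecture; only `FALSE` is supported.
#' @param shared_mlp_widths widths of the shared per-point MLP layers
#'   (default `c(64, 64, 64, 128, 1024)`).
#' @param head_widths widths of the dense layers after max pooling
#'   (default `c(512, 256)`).
#' @param tnet_conv_widths,tnet_fc_widths widths of the T-Net's per-point
#'   layers and of its dense layers after pooling.
#' @param width_scale positive multiplier applied to every width (rounded,
#'   minimum 4) for desk-scale runs; `0.25` shrinks the network ~16-fold in
#'   parameter count while preserving the architecture.
#' @param plane_distance camera-to-floor distance `L` in meters (default
#'   2.7). Internally each cloud is centred at its `xy` centroid and `z` is
#'   re-expressed as height above the floor (`L - z`); coordinates are
#'   deliberately NOT rescaled to a unit sphere because the animal's absolute
#'   size is the weight signal.
#' @return an object of class `pointnet_config`.
#' @export
pointnet_config <- function(n_points = 1500L,
                            use_input_transform = TRUE,
                            use_feature_transform = FALSE,
                            shared_mlp_widths = c(64L, 64L, 64L, 128L, 1024L),
                            head_widths = c(512L, 256L),
                            tnet_conv_widths = c(32L, 64L, 256L),
                            tnet_fc_widths = c(128L, 64L),
                            width_scale = 1,
                            plane_distance = 2.7) {
  if (isTRUE(use_feature_transform))
    stop("the feature transform was removed from this architecture; ",
         "use_feature_transform must be FALSE")
  stopifnot(n_points >= 8L, width_scale > 0, plane_distance > 0,
            length(shared_mlp_widths) >= 1L, length(head_widths) >= 1L,
            all(shared_mlp_widths > 0), all(head_widths > 0),
            all(tnet_conv_widths > 0), all(tnet_fc_widths > 0))
  sw <- function(w) pmax(4L, as.integer(round(w * width_scale)))
  structure(list(n_points = as.integer(n_points),
                 use_input_transform = isTRUE(use_input_transform),
                 use_feature_transform = FALSE,
                 conv = sw(shared_mlp_widths),
                 head = sw(head_widths),
                 tnet_conv = sw(tnet_conv_widths),
                 tnet_fc = sw(tnet_fc_widths),
                 width_scale = width_scale,
                 plane_distance = plane_distance,
                 bn_momentum = 0.9),
            class = "pointnet_config")
}

#' Training configuration for the point-set regressor
#'
#' Defaults mirror the training protocol of the weight-prediction study this
#' package implements: Adam with a constant learning rate of 0.01, mean
#' squared error loss (kg^2) with RMSE (kg) as the tracked metric, up to 1000
#' epochs with early stopping at patience 10 on the validation RMSE, a 9:1
#' train/validation split, and per-epoch jitter augmentation of +/-0.005 m
#' applied to training clouds only.
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param max_epochs epoch budget (default 1000).
#' @param patience early-stopping patience in epochs; training halts when the
#'   validation RMSE has not improved for this many consecutive epochs and
#'   the best-epoch weights are restored. Use `Inf` to disable.
#' @param val_fraction fraction of the dataset held out for validation
#'   (default 0.1, the 9:1 split).
#' @param batch_size minibatch size (default 32).
#' @param jitter amplitude in meters of the uniform per-coordinate jitter
#'   applied to training clouds each epoch (default 0.005); 0 disables
#'   augmentation.
#' @param seed integer seed governing every source of randomness in the fit:
#'   weight initialization, the split, epoch shuffling and jitter. Identical
#'   seeds give bit-identical training histories.
#' @return an object of class `pointnet_control`.
#' @export
pointnet_control <- function(learning_rate = 0.01, max_epochs = 1000L,
                             patience = 10L, val_fraction = 0.1,
                             batch_size = 32L, jitter = 0.005, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1L,
            is.infinite(patience) || patience >= 1L,
            val_fraction > 0, val_fraction < 1,
            batch_size >= 1L, jitter >= 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = if (is.infinite(patience)) 0L else as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 jitter = jitter,
                 seed = as.integer(seed),
                 beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8),
            class = "pointnet_control")
}

# He-normal initialization for one dense+bn block; draws from the current RNG
pn_init_block <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       gamma = rep(1, d_out), beta = rep(0, d_out),
       rmean = rep(0, d_out), rvar = rep(1, d_out))
}

# Flat parameter list in the fixed order the C++ core expects.
pn_init_params <- function(config) {
  params <- list()
  push_block <- function(params, prefix, bl) {
    params[[paste0(prefix, "_W")]] <- bl$W
    params[[paste0(prefix, "_gamma")]] <- bl$gamma
    params[[paste0(prefix, "_beta")]] <- bl$beta
    params[[paste0(prefix, "_rmean")]] <- bl$rmean
    params[[paste0(prefix, "_rvar")]] <- bl$rvar
    params
  }
  if (config$use_input_transform) {
    d <- 3L
    for (i in seq_along(config$tnet_conv)) {
      params <- push_block(params, paste0("tconv", i),
                           pn_init_block(d, config$tnet_conv[i]))
      d <- config$tnet_conv[i]
    }
    for (i in seq_along(config$tnet_fc)) {
      params <- push_block(params, paste0("tfc", i),
                           pn_init_block(d, config$tnet_fc[i]))
      d <- config$tnet_fc[i]
    }
    # zero weights + identity bias: the transform starts as the identity
    params[["tout_W"]] <- matrix(0, d, 9L)
    params[["tout_b"]] <- as.double(diag(3))
  }
  d <- 3L
  for (i in seq_along(config$conv)) {
    params <- push_block(params, paste0("conv", i),
                         pn_init_block(d, config$conv[i]))
    d <- config$conv[i]
  }
  for (i in seq_along(config$head)) {
    params <- push_block(params, paste0("head", i),
                         pn_init_block(d, config$head[i]))
    d <- config$head[i]
  }
  params[["out_W"]] <- matrix(stats::rnorm(d, sd = 0.01), d, 1L)
  params[["out_b"]] <- 0.0
  params
}

pn_cfg_list <- function(config) {
  list(n_points = config$n_points,
       plane_distance = config$plane_distance,
       use_input_transform = config$use_input_transform,
       bn_momentum = config$bn_momentum,
       tnet_conv = config$tnet_conv, tnet_fc = config$tnet_fc,
       conv = config$conv, head = config$head)
}

# Coerce a list of clouds/matrices to n_points x 3 matrices, with errors
# naming the offending cloud.
pn_coord_list <- function(x, n_points) {
  if (is_point_cloud(x) || (is.matrix(x) && ncol(x) == 3L)) x <- list(x)
  stopifnot(is.list(x), length(x) >= 1L)
  lapply(seq_along(x), function(i) {
    m <- coord_matrix(x[[i]])
    if (nrow(m) != n_points) {
      id <- if (is_point_cloud(x[[i]]) && nzchar(x[[i]]$source_id))
        paste0(" ('", x[[i]]$source_id, "')") else ""
      stop("cloud ", i, id, " has ", nrow(m), " points; the network requires ",
           "exactly ", n_points, " (use random_subsample() upstream)")
    }
    dimnames(m) <- NULL
    m
  })
}

#' Build an untrained point-set regressor
#'
#' Initializes the network weights (He-normal for dense layers; the input
#' T-Net starts as the exact identity transform) without training. Useful
#' for architecture checks; predictions from an untrained model are already
#' well-defined (and nonnegative, via the rectified output).
#'
#' @param config a [pointnet_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `pointnet` with `trained = FALSE`.
#' @export
pointnet_build <- function(config = pointnet_config(), seed = 1L) {
  stopifnot(inherits(config, "pointnet_config"))
  params <- with_seed(seed, pn_init_params(config))
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_,
                 stopped_epoch = NA_integer_, best_val_rmse = NA_real_,
                 val_indices = integer(0)),
            class = "pointnet")
}

#' Fit the point-set weight regressor
#'
#' Trains a PointNet-style regression network on labelled point clouds:
#' the dataset is split `val_fraction : (1 - val_fraction)` into validation
#' and training clouds, each training epoch applies fresh uniform jitter to
#' the training clouds only, the MSE loss (kg^2) is minimized with Adam, and
#' training halts when the validation RMSE fails to improve for `patience`
#' consecutive epochs (or at `max_epochs`), restoring the best-epoch weights.
#'
#' @param x list of [point_cloud]s (or `n x 3` matrices, camera frame,
#'   meters), each with exactly `config$n_points` points.
#' @param y numeric vector of scale weights in kg, one per cloud.
#' @param config a [pointnet_config()].
#' @param control a [pointnet_control()].
#' @param model optionally, an existing `pointnet` object to continue
#'   training (its config overrides `config`).
#' @return a fitted object of class `pointnet`, with a `history` data frame
#'   (per-epoch training and validation RMSE in kg), `best_epoch`,
#'   `stopped_epoch`, `best_val_rmse`, and the indices of the validation
#'   clouds in `val_indices`.
#' @examples
#' \donttest{
#' ds <- make_dataset(n_animals = 4, clouds_per_animal = 3, n_points = 64,
#'                    n_raw = 500, artifacts = NULL, seed = 1)
#' fit <- pointnet(ds$clouds, ds$labels$weight_kg,
#'                 config = pointnet_config(n_points = 64, width_scale = 0.1),
#'                 control = pointnet_control(max_epochs = 5, seed = 1))
#' predict(fit, ds$clouds[1:2])
#' }
#' @seealso [predict.pointnet()], [plot.pointnet()]
#' @export
pointnet <- function(x, y, config = pointnet_config(),
                     control = pointnet_control(), model = NULL) {
  stopifnot(inherits(config, "pointnet_config"),
            inherits(control, "pointnet_control"))
  if (!is.null(model)) {
    stopifnot(inherits(model, "pointnet"))
    config <- model$config
  }
  mats <- pn_coord_list(x, config$n_points)
  y <- as.numeric(y)
  if (length(y) != length(mats))
    stop("'y' must provide one weight per cloud")
  if (!all(is.finite(y)) || any(y <= 0))
    stop("weights must be finite and positive (kg)")
  n <- length(mats)
  if (n < 10L) stop("dataset too small: need at least 10 labelled clouds")

  res <- with_seed(control$seed, {
    params <- if (is.null(model)) pn_init_params(config) else model$params
    n_val <- max(1L, round(control$val_fraction * n))
    if (n_val >= n) stop("val_fraction leaves no training clouds")
    val_idx <- sort.int(sample.int(n, n_val))
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (is.null(model))  # start the rectified output at the label mean
      params[["out_b"]] <- mean(y[tr_idx])
    fit <- cpp_pn_train(params, pn_cfg_list(config), unclass(control),
                        mats[tr_idx], y[tr_idx], mats[val_idx], y[val_idx])
    fit$val_idx <- val_idx
    fit
  })

  structure(list(config = config, params = res$params, trained = TRUE,
                 history = data.frame(epoch = seq_along(res$train_rmse),
                                      train_rmse = res$train_rmse,
                                      val_rmse = res$val_rmse),
                 best_epoch = res$best_epoch,
                 stopped_epoch = res$stopped_epoch,
                 best_val_rmse = res$best_val_rmse,
                 val_indices = res$val_idx,
                 control = control),
            class = "pointnet")
}

#' Predict weights for point clouds
#'
#' Inference is deterministic (no jitter, batch-norm running statistics) and
#' permutation-invariant: shuffling the points of a cloud leaves the
#' prediction unchanged up to floating-point noise far below 1e-4 kg.
#'
#' @param object a `pointnet` model.
#' @param newdata a list of [point_cloud]s or `n x 3` matrices, each with
#'   exactly `config$n_points` points.
#' @param ... unused.
#' @return numeric vector of nonnegative predicted weights (kg).
#' @export
predict.pointnet <- function(object, newdata, ...) {
  mats <- pn_coord_list(newdata, object$config$n_points)
  as.numeric(cpp_pn_predict(object$params, pn_cfg_list(object$config), mats))
}

#' Number of trainable parameters
#'
#' Counts dense weights and biases plus the batch-normalization scale and
#' shift vectors (running statistics are not trainable).
#'
#' @param model a `pointnet` object.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "pointnet"))
  trainable <- !grepl("_(rmean|rvar)$", names(model$params))
  sum(vapply(model$params[trainable], length, integer(1L)))
}

#' @export
print.pointnet <- function(x, ...) {
  cfg <- x$config
  cat("Point-set weight regressor (PointNet-style)\n")
  cat(sprintf("  input: %d points x 3; T-Net: %s\n", cfg$n_points,
              if (cfg$use_input_transform) "on" else "off"))
  cat(sprintf("  shared MLP: %s | head: %s | trainable parameters: %d\n",
              paste(cfg$conv, collapse = "-"),
              paste(cfg$head, collapse = "-"), n_parameters(x)))
  if (x$trained)
    cat(sprintf("  trained %d epochs (best epoch %d, val RMSE %.3f kg)\n",
                x$stopped_epoch, x$best_epoch, x$best_val_rmse))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.pointnet <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history
#' @param x a trained `pointnet`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pointnet <- function(x, ...) {
  if (!x$trained) stop("model is untrained; nothing to plot")
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_rmse, x$history$val_rmse),
                    type = "l", lty = 1, col = c("grey40", "red"),
                    xlab = "epoch", ylab = "RMSE (kg)",
                    main = "Training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "red"), bty = "n")
  invisible(x)
}
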