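# 2.5D projected volume: rasterize the cloud's heights above the floor plane
# onto a regular xy grid (per-cell maximum), sum the cells, and regress scale
# weight on the resulting volume.

#' Rasterize a cloud into a height grid
#'
#' Projects the cloud along the camera axis onto a regular `xy` grid covering
#' its bounding box. Each cell holds the maximum height above the floor plane
#' (`plane_distance - z`) over the points falling in it -- the 2.5D rule used
#' when multiple points fall inside a cell -- and cells containing no points
#' hold 0. The grid is anchored at the cloud's `(min x, min y)` corner with
#' half-open cell membership, which makes the result translation-covariant
#' and deterministic.
#'
#' @param cloud a nonempty [point_cloud]; all `z` must lie in
#'   `[0, plane_distance]` (a point with `z > plane_distance` would be below
#'   the floor and is rejected).
#' @param step grid step in meters (default 0.01).
#' @param plane_distance distance `L` from the camera to the floor plane in
#'   meters (default 2.7).
#' @return an object of class `height_grid`: list with `origin` (x, y of the
#'   min corner), `step`, `plane_distance` and `heights` (numeric matrix,
#'   rows indexing x cells, columns y cells).
#' @export
rasterize_height_grid <- function(cloud, step = 0.01, plane_distance = 2.7) {
  stopifnot(is_point_cloud(cloud), step > 0, plane_distance > 0)
  n <- n_points(cloud)
  if (n == 0L) stop("cannot rasterize an empty cloud")
  p <- cloud$points
  if (any(p[, 3L] > plane_distance + 1e-12))
    stop("point below the floor plane: z = ", max(p[, 3L]),
         " > plane_distance = ", plane_distance)
  if (any(p[, 3L] < 0))
    stop("negative z: the camera frame has z >= 0")
  h <- plane_distance - p[, 3L]
  ox <- min(p[, 1L]); oy <- min(p[, 2L])
  ix <- pmin(floor((p[, 1L] - ox) / step), floor((max(p[, 1L]) - ox) / step)) + 1L
  iy <- pmin(floor((p[, 2L] - oy) / step), floor((max(p[, 2L]) - oy) / step)) + 1L
  nx <- max(ix); ny <- max(iy)
  key <- (iy - 1L) * nx + ix
  o <- order(key, h)
  k <- key[o]
  last <- c(k[-1L] != k[-length(k)], TRUE)
  heights <- matrix(0, nx, ny)
  heights[k[last]] <- h[o][last]
  structure(list(origin = c(x = ox, y = oy), step = step,
                 plane_distance = plane_distance, heights = heights),
            class = "height_grid")
}

#' @export
print.height_grid <- function(x, ...) {
  cat(sprintf("<height_grid> %d x %d cells, step %.4g m, volume %.5g m^3\n",
              nrow(x$heights), ncol(x$heights), x$step, grid_volume(x)))
  invisible(x)
}

#' Projected volume of a height grid
#'
#' The volume of the solid between the rasterized top surface and the floor
#' plane: `step^2 * sum(heights)`. Empty cells contribute zero.
#'
#' @param grid a `height_grid` from [rasterize_height_grid()].
#' @return volume in cubic meters (nonnegative).
#' @export
grid_volume <- function(grid) {
  stopifnot(inherits(grid, "height_grid"))
  grid$step^2 * sum(grid$heights)
}

#' Projected volume of a cloud
#'
#' Convenience wrapper: optionally crop the head, rasterize, and integrate.
#'
#' @inheritParams rasterize_height_grid
#' @param crop apply [crop_head()] first (the adjustment that stabilizes the
#'   volume--weight relationship against head posture).
#' @return volume in cubic meters.
#' @export
cloud_volume <- function(cloud, step = 0.01, plane_distance = 2.7, crop = FALSE) {
  if (crop) cloud <- crop_head(cloud)
  grid_volume(rasterize_height_grid(cloud, step, plane_distance))
}

#' Fit the linear weight~volume baseline
#'
#' Ordinary least squares of scale weight on projected volume with an
#' intercept -- the conventional machine-vision baseline against which the
#' point-set network is compared.
#'
#' @param volume numeric vector of projected volumes, cubic meters.
#' @param weight numeric vector of scale weights, kg (same length).
#' @return an object of class `weight_volume_fit` with components `slope`
#'   (kg per cubic meter), `intercept` (kg), `r_squared`, `rmse` (kg,
#'   `sqrt(SS_res / n)`), `n`, and the underlying `lm` fit.
#' @examples
#' fit <- fit_weight_volume(c(1, 2, 3), c(2, 4, 6))
#' coef(fit)
#' predict(fit, volume = 1.5)
#' @export
fit_weight_volume <- function(volume, weight) {
  volume <- as.numeric(volume); weight <- as.numeric(weight)
  if (length(volume) != length(weight))
    stop("'volume' and 'weight' must have the same length")
  if (length(volume) < 2L)
    stop("need at least two (volume, weight) pairs")
  if (stats::var(volume) == 0)
    stop("singular fit: all volumes identical")
  lmfit <- stats::lm(weight ~ volume)
  res <- stats::residuals(lmfit)
  ss_res <- sum(res^2)
  ss_tot <- sum((weight - mean(weight))^2)
  structure(list(slope = unname(stats::coef(lmfit)[2L]),
                 intercept = unname(stats::coef(lmfit)[1L]),
                 r_squared = 1 - ss_res / ss_tot,
                 rmse = sqrt(ss_res / length(weight)),
                 n = length(weight),
                 lm = lmfit,
                 data = data.frame(volume = volume, weight = weight)),
            class = "weight_volume_fit")
}

#' @export
print.weight_volume_fit <- function(x, ...) {
  cat("Linear weight~volume baseline\n")
  cat(sprintf("  weight = %.4g + %.4g * volume   (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.4f, RMSE = %.3f kg\n", x$r_squared, x$rmse))
  invisible(x)
}

#' @export
summary.weight_volume_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying OLS fit:\n")
  print(summary(object$lm)$coefficients)
  invisible(object)
}

#' @export
coef.weight_volume_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict weight from projected volume
#' @param object a `weight_volume_fit`.
#' @param volume numeric vector of volumes, cubic meters.
#' @param ... unused.
#' @return predicted weights in kg (`slope * volume + intercept`).
#' @export
predict.weight_volume_fit <- function(object, volume, ...) {
  object$slope * as.numeric(volume) + object$intercept
}

#' @export
residuals.weight_volume_fit <- function(object, ...) {
  object$data$weight - predict(object, object$data$volume)
}

#' @export
plot.weight_volume_fit <- function(x, ...) {
  graphics::plot(x$data$volume, x$data$weight,
                 xlab = expression(volume ~ (m^3)), ylab = "scale weight (kg)",
                 main = sprintf("weight ~ volume (R² = %.3f, RMSE = %.2f kg)",
                                x$r_squared, x$rmse), ...)
  graphics::abline(x$intercept, x$slope, col = "red", lwd = 2)
  invisible(x)
}
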