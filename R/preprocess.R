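# The filter chain that isolates the animal's surface from a raw top-down
# scene: depth band -> polygon ROI -> colour segmentation -> statistical
# outlier removal, plus random subsampling to the canonical network input
# size, jitter augmentation, and the automated head crop used before volume
# computation. Every filter returns a subsequence of its input: order is
# preserved, colours are carried along, and no point is ever invented.

# Run code with a temporarily-seeded RNG; the caller's RNG state is restored.
# With seed = NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Depth-band filter
#'
#' Keeps points whose camera-axis coordinate lies inside
#' `[z_min, z_max]` (both inclusive). Removing everything outside the band of
#' depths at which the animal's back appears strips the floor plane and most
#' wall structure from a top-down scene.
#'
#' @param cloud a [point_cloud].
#' @param z_min,z_max band limits in meters along the camera axis,
#'   `0 < z_min < z_max`.
#' @return the filtered [point_cloud] (a subsequence of the input; may be
#'   empty).
#' @export
depth_band_filter <- function(cloud, z_min, z_max) {
  stopifnot(is_point_cloud(cloud), is.numeric(z_min), is.numeric(z_max))
  if (!(z_min < z_max) || z_min <= 0)
    stop("invalid depth band: need 0 < z_min < z_max")
  z <- cloud$points[, 3L]
  subset_cloud(cloud, which(z >= z_min & z <= z_max))
}

#' Polygon region-of-interest filter
#'
#' Keeps points whose `(x, y)` projection lies inside or on the boundary of a
#' simple polygon (the pen's area of interest). Containment uses ray casting
#' with a half-open edge rule; boundary points are kept.
#'
#' @param cloud a [point_cloud].
#' @param polygon numeric matrix with two columns (`x`, `y` in meters) and at
#'   least three rows, listing the polygon vertices in order (open ring; do
#'   not repeat the first vertex).
#' @return the filtered [point_cloud].
#' @export
polygon_roi_filter <- function(cloud, polygon) {
  stopifnot(is_point_cloud(cloud))
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("'polygon' must be a matrix of >= 3 (x, y) vertices")
  storage.mode(polygon) <- "double"
  if (n_points(cloud) == 0L) return(cloud)
  keep <- point_in_polygon(cloud$points[, 1L], cloud$points[, 2L], polygon)
  subset_cloud(cloud, which(keep))
}

# Vectorized ray casting (crossing parity) with an explicit boundary test so
# that points exactly on an edge or vertex are kept.
point_in_polygon <- function(px, py, poly, eps = 1e-12) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- poly[j, 1L]; y1 <- poly[j, 2L]
    x2 <- poly[i, 1L]; y2 <- poly[i, 2L]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xeor(inside, crosses & (px < xint))
    }
    # on-segment test: zero cross product and inside the bounding box
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    scale <- max(abs(c(x1, y1, x2, y2, 1)))
    on <- abs(d) <= eps * scale * scale &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on
    j <- i
  }
  inside | boundary
}

xeor <- function(a, b) (a | b) & !(a & b)

#' Otsu threshold of 8-bit intensities
#'
#' Builds the 256-bin histogram of the given intensities and returns the
#' threshold `t` in `[0, 255]` that maximizes the between-class variance of
#' the split `{values <= t}` versus `{values > t}`. When several thresholds
#' attain the maximum (a plateau, e.g. for a two-valued input) the middle of
#' the plateau is returned, so a symmetric bimodal histogram yields a
#' threshold strictly between the two modes.
#'
#' @param values numeric vector of intensities in `[0, 255]`; values are
#'   rounded to integer bins. At least two distinct values are required.
#' @return integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("'values' must be non-empty and free of NA")
  if (min(values) < 0 || max(values) > 255)
    stop("'values' must lie in [0, 255]")
  bins <- as.integer(round(values))
  if (length(unique(bins)) < 2L)
    stop("degenerate input: all intensities identical, no separating threshold")
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  # cumulative class probability and cumulative mean, vectorized over all t
  w0 <- cumsum(h) / n
  mu_t <- cumsum(h * (0:255)) / n
  mu_T <- mu_t[256L]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 256L)
  sigma_b[valid] <- (mu_T * w0[valid] - mu_t[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  peak <- which(sigma_b >= max(sigma_b) - 1e-12 * max(1, max(sigma_b)))
  as.integer(peak[ceiling(length(peak) / 2)] - 1L)
}

#' Colour-based segmentation of a cloud
#'
#' Converts the per-point RGB to grayscale (luma weights 0.299/0.587/0.114),
#' finds the Otsu threshold, and keeps the side of the threshold containing
#' the majority of points -- after the spatial filters the animal dominates
#' the scene, so the majority class is the animal and off-colour structures
#' are discarded. A tie between the two sides is broken toward the brighter
#' class (the animal is lighter than background shadow in this imagery).
#'
#' @param cloud a [point_cloud] with colours.
#' @return the filtered [point_cloud]. If the colours are degenerate (all
#'   identical, so no threshold exists) the input is returned unchanged with
#'   a warning.
#' @export
color_segment <- function(cloud) {
  stopifnot(is_point_cloud(cloud))
  if (is.null(cloud$colors))
    stop("color_segment() needs a cloud with colours")
  if (n_points(cloud) == 0L) return(cloud)
  gray <- as.integer(round(0.299 * cloud$colors[, 1L] +
                           0.587 * cloud$colors[, 2L] +
                           0.114 * cloud$colors[, 3L]))
  t <- tryCatch(otsu_threshold(gray), error = function(e) NULL)
  if (is.null(t)) {
    warning("degenerate colour distribution; cloud returned unchanged")
    return(cloud)
  }
  dark <- gray <= t
  n_dark <- sum(dark)
  keep_bright <- n_dark < length(gray) - n_dark ||
    (n_dark == length(gray) - n_dark)  # tie -> brighter class
  subset_cloud(cloud, which(if (keep_bright) !dark else dark))
}

#' Statistical outlier removal
#'
#' For each point, computes the mean Euclidean distance to its `k` nearest
#' neighbours; points whose mean distance exceeds the global mean by more
#' than `std_ratio` standard deviations are removed. This is the standard
#' mean-kNN-distance rule used to strip sparse sensor speckle from a depth
#' cloud. The operation is not idempotent: re-applying it recomputes the
#' statistics on the surviving points and may remove more.
#'
#' @param cloud a [point_cloud] with more than `k` points.
#' @param k number of nearest neighbours (default 20).
#' @param std_ratio multiple of the standard deviation above the mean at
#'   which a point is declared an outlier (default 2.0).
#' @return the filtered [point_cloud].
#' @export
remove_statistical_outliers <- function(cloud, k = 20L, std_ratio = 2.0) {
  stopifnot(is_point_cloud(cloud), k >= 1L, std_ratio > 0)
  n <- n_points(cloud)
  if (n <= k)
    stop("cloud has ", n, " points; need more than k = ", k)
  d <- knn_mean_distance(cloud$points, as.integer(k))
  keep <- d <= mean(d) + std_ratio * stats::sd(d)
  subset_cloud(cloud, which(keep))
}

# Mean distance to the k nearest neighbours, exact, via blocked BLAS
# cross-distances (|a|^2 + |b|^2 - 2 a.b) to bound memory on large clouds.
knn_mean_distance <- function(pts, k, block = 512L) {
  n <- nrow(pts)
  sq <- rowSums(pts * pts)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(pts[idx, , drop = FALSE], pts)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    d2[d2 < 0] <- 0
    out[idx] <- apply(d2, 1L, function(r) mean(sqrt(sort.int(r, partial = k)[seq_len(k)])))
  }
  out
}

#' Random subsampling to a fixed size
#'
#' Draws exactly `n` points uniformly without replacement, in support of the
#' fixed-size network input (1500 points by default). The selected points
#' keep their original relative order, so the result is a subsequence of the
#' input and `n == n_points(cloud)` returns the cloud unchanged.
#'
#' @param cloud a [point_cloud].
#' @param n target size (default 1500).
#' @param seed integer seed; identical seeds give identical draws. `NULL`
#'   uses (and advances) the current RNG stream.
#' @param pad what to do when the cloud has fewer than `n` points:
#'   `"error"` (default) or `"resample"`, which duplicates uniformly chosen
#'   points to reach exactly `n`.
#' @return a [point_cloud] with exactly `n` points.
#' @export
random_subsample <- function(cloud, n = 1500L, seed = NULL,
                             pad = c("error", "resample")) {
  stopifnot(is_point_cloud(cloud), n >= 1L)
  pad <- match.arg(pad)
  m <- n_points(cloud)
  if (m < n) {
    if (pad == "error")
      stop("cloud has ", m, " points, fewer than n = ", n,
           "; use pad = 'resample' to upsample")
    idx <- with_seed(seed, c(seq_len(m), sample.int(m, n - m, replace = TRUE)))
    return(subset_cloud(cloud, idx))
  }
  idx <- with_seed(seed, sort.int(sample.int(m, n)))
  subset_cloud(cloud, idx)
}

#' Jitter augmentation
#'
#' Perturbs every coordinate by an independent uniform draw in
#' `[-amplitude, +amplitude]` meters, leaving the point count, order, colours
#' and the weight label unchanged. Used during training to create variation;
#' validation and test clouds are never jittered.
#'
#' @param cloud a [point_cloud].
#' @param amplitude nonnegative bound in meters (default 0.005, i.e. the
#'   perturbation lies between -0.005 and +0.005).
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @return the jittered [point_cloud].
#' @export
jitter_points <- function(cloud, amplitude = 0.005, seed = NULL) {
  stopifnot(is_point_cloud(cloud), amplitude >= 0)
  m <- n_points(cloud)
  if (m == 0L || amplitude == 0) return(cloud)
  delta <- with_seed(seed, matrix(stats::runif(3L * m, -amplitude, amplitude), m, 3L))
  point_cloud(cloud$points + delta, cloud$colors, cloud$source_id)
}

#' Automated head crop
#'
#' Automates the manual step of cropping the head and neck before volume
#' computation: head-down/head-up posture changes the projected volume of the
#' head substantially, so removing everything anterior to the narrowest part
#' of the neck stabilizes the volume--weight relationship.
#'
#' The procedure: (1) find the principal body axis in the `xy` plane;
#' (2) slice the cloud into 2 cm bins along that axis and record each slice's
#' transverse width; (3) call the end whose slices are on average narrower
#' the anterior (head) end; (4) within 5--35 percent of the body length from
#' the anterior tip, find the narrowest slice containing at least 0.5 percent
#' of the points; (5) remove all points anterior to that slice's centre.
#' Step (4)'s inner exclusion keeps the taper at the very tip of any convex
#' body (where slice width necessarily goes to zero) from masquerading as a
#' neck, so a headless body loses at most a small nose sliver.
#'
#' @param cloud a [point_cloud] with at least 100 points.
#' @param slice_width slice thickness along the body axis, meters.
#' @return the cropped [point_cloud].
#' @export
crop_head <- function(cloud, slice_width = 0.02) {
  stopifnot(is_point_cloud(cloud))
  m <- n_points(cloud)
  if (m < 100L) stop("crop_head() needs at least 100 points (got ", m, ")")
  xy <- cloud$points[, 1:2, drop = FALSE]
  ctr <- colMeans(xy)
  sv <- svd(sweep(xy, 2L, ctr))
  if (sv$d[1L] < 1e-9 || !is.finite(sv$d[1L]))
    stop("degenerate geometry: principal body axis undefined")
  axis1 <- sv$v[, 1L]; axis2 <- sv$v[, 2L]
  tt <- as.vector(sweep(xy, 2L, ctr) %*% axis1)
  ww <- as.vector(sweep(xy, 2L, ctr) %*% axis2)
  t_rng <- range(tt)
  len <- diff(t_rng)
  if (len < 3 * slice_width)
    stop("degenerate geometry: cloud too short along its principal axis")

  n_slices <- max(3L, ceiling(len / slice_width))
  slice <- pmin(pmax(1L, ceiling((tt - t_rng[1L]) / (len / n_slices))), n_slices)
  counts <- tabulate(slice, n_slices)
  width <- rep(NA_real_, n_slices)
  min_pts <- max(5L, ceiling(0.005 * m))
  for (s in which(counts >= min_pts))
    width[s] <- diff(range(ww[slice == s]))
  centers <- t_rng[1L] + (seq_len(n_slices) - 0.5) * (len / n_slices)

  # anterior end = the end with the smaller mean width over its 35% of slices
  n_end <- max(1L, floor(0.35 * n_slices))
  w_lo <- mean(width[seq_len(n_end)], na.rm = TRUE)
  w_hi <- mean(width[seq(n_slices - n_end + 1L, n_slices)], na.rm = TRUE)
  anterior_high <- isTRUE(w_hi <= w_lo)  # tie -> high end, fixed for determinism

  dist_tip <- if (anterior_high) t_rng[2L] - centers else centers - t_rng[1L]
  cand <- which(!is.na(width) & dist_tip >= 0.05 * len & dist_tip <= 0.35 * len)
  # a neck must have a distinctly wider structure (the head) anterior to it;
  # a monotone taper toward a bare body tip never qualifies
  is_neck <- vapply(cand, function(s) {
    ahead <- which(!is.na(width) & dist_tip < dist_tip[s])
    length(ahead) > 0L && max(width[ahead]) > 1.15 * width[s]
  }, logical(1L))
  cand <- cand[is_neck]
  if (length(cand) == 0L) return(cloud)  # nothing resembling a neck region
  cut_slice <- cand[which.min(width[cand])]
  cut_t <- centers[cut_slice]
  keep <- if (anterior_high) tt <= cut_t else tt >= cut_t
  subset_cloud(cloud, which(keep))
}

#' Full animal-extraction chain
#'
#' Convenience wrapper applying the filter chain in the standard order:
#' depth band, polygon region of interest, colour segmentation (if the cloud
#' has colours and `use_color` is `TRUE`), and statistical outlier removal.
#'
#' @param cloud a raw scene [point_cloud].
#' @param z_min,z_max depth band in meters, see [depth_band_filter()].
#' @param polygon optional ROI polygon, see [polygon_roi_filter()].
#' @param use_color apply [color_segment()] when colours are present.
#' @param k,std_ratio outlier-removal parameters, see
#'   [remove_statistical_outliers()].
#' @return the extracted animal [point_cloud].
#' @export
extract_animal <- function(cloud, z_min, z_max, polygon = NULL,
                           use_color = TRUE, k = 20L, std_ratio = 2.0) {
  out <- depth_band_filter(cloud, z_min, z_max)
  if (!is.null(polygon)) out <- polygon_roi_filter(out, polygon)
  if (use_color && !is.null(out$colors) && n_points(out) > 0L)
    out <- color_segment(out)
  if (n_points(out) > k) out <- remove_statistical_outliers(out, k, std_ratio)
  out
}
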