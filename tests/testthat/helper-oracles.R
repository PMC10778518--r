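# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain per-point / per-candidate loops.

# exhaustive Otsu: scan all 256 thresholds, between-class variance by direct
# class statistics; same plateau-midpoint tie rule as documented.
oracle_otsu <- function(values) {
  bins <- as.integer(round(values))
  best <- -1
  peaks <- integer(0)
  for (t in 0:255) {
    lo <- bins[bins <= t]
    hi <- bins[bins > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(bins)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12 * max(1, abs(best))) {
      best <- sb
      peaks <- t
    } else if (abs(sb - best) <= 1e-12 * max(1, abs(best))) {
      peaks <- c(peaks, t)
    }
  }
  peaks[ceiling(length(peaks) / 2)]
}

# point-in-polygon by per-point ray casting loop, boundary-inclusive
oracle_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- nv
    for (k in seq_len(nv)) {
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[k, 1]; y2 <- poly[k, 2]
      # boundary?
      d <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(d) < 1e-9 && x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9)
        return(TRUE)
      if ((y1 > y) != (y2 > y) &&
          x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
        inside <- !inside
      j <- k
    }
    inside
  }, logical(1L))
}

# per-point kNN mean distance by full pairwise loop-free but independent path
oracle_knn_mean_dist <- function(pts, k) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    mean(sort(d[-i])[seq_len(k)])
  }, numeric(1L))
}

oracle_outlier_keep <- function(pts, k, std_ratio) {
  d <- oracle_knn_mean_dist(pts, k)
  d <= mean(d) + std_ratio * sd(d)
}

# exhaustive per-point height-grid binning
oracle_raster <- function(pts, step, L) {
  ox <- min(pts[, 1]); oy <- min(pts[, 2])
  ix <- floor((pts[, 1] - ox) / step) + 1L
  iy <- floor((pts[, 2] - oy) / step) + 1L
  g <- matrix(0, max(ix), max(iy))
  for (i in seq_len(nrow(pts))) {
    h <- L - pts[i, 3]
    if (h > g[ix[i], iy[i]]) g[ix[i], iy[i]] <- h
  }
  g
}

# closed-form OLS for y ~ x
oracle_ols <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  res <- y - (ic + sl * x)
  list(slope = sl, intercept = ic,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean(res^2)))
}

# body-with-head test shape for crop_head: wide ellipsoid + small head
# ellipsoid joined by a thin neck cylinder, labelled by component
labelled_body_head <- function(n_body = 2000L, n_neck = 150L, n_head = 600L,
                               seed = 1L, head = TRUE, mirror = FALSE) {
  set.seed(seed)
  su <- function(n, a, b, c, ctr) {
    x <- runif(n, -a, a)
    y <- runif(n, -b, b) * sqrt(pmax(1 - (x / a)^2, 0))
    z <- ctr[3] + c * sqrt(pmax(1 - (x / a)^2 - ifelse(b > 0, (y / b)^2, 0), 0))
    cbind(ctr[1] + x, ctr[2] + y, z)
  }
  pts <- su(n_body, 0.42, 0.15, 0.12, c(0, 0, 2.45))
  lab <- rep("body", n_body)
  if (head) {
    neck <- cbind(runif(n_neck, 0.40, 0.50), runif(n_neck, -0.035, 0.035),
                  2.45 + runif(n_neck, 0, 0.05))
    hd <- su(n_head, 0.12, 0.07, 0.07, c(0.62, 0, 2.45))
    pts <- rbind(pts, neck, hd)
    lab <- c(lab, rep("neck", n_neck), rep("head", n_head))
  }
  if (mirror) pts[, 1] <- -pts[, 1]
  list(cloud = point_cloud(pts), labels = lab)
}
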