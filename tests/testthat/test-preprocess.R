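# The animal-extraction filter chain, subsampling, jitter, and head crop.

test_that("depth-band filter keeps exactly the in-band subsequence", {
  expect_equal(n_points(depth_band_filter(point_cloud(NULL), 1, 2)), 0L)

  set.seed(1)
  pts <- cbind(rnorm(10), rnorm(10), c(runif(6, 2.0, 2.4), runif(4, 2.55, 2.7)))
  pc <- point_cloud(pts, colors = matrix(sample(0:255, 30, TRUE), ncol = 3))
  out <- depth_band_filter(pc, 1.9, 2.5)
  keep <- which(pts[, 3] >= 1.9 & pts[, 3] <= 2.5)  # per-point scan
  expect_equal(unname(out$points), unname(pts[keep, , drop = FALSE]))
  expect_equal(unname(out$colors), unname(pc$colors[keep, , drop = FALSE]))

  all_in <- depth_band_filter(pc, 1, 3)
  expect_equal(all_in$points, pc$points)  # identity when all inside
  expect_error(depth_band_filter(pc, 2.5, 1.9), "z_min < z_max")
})

test_that("polygon ROI filter is boundary-inclusive and matches ray casting", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  pc <- point_cloud(rbind(c(0.5, 0.5, 2), c(1, 0.5, 2), c(1.5, 0.5, 2)))
  out <- polygon_roi_filter(pc, sq)
  expect_equal(nrow(out$points), 2L)  # centre kept, edge point kept, outside dropped

  set.seed(2)
  pent <- cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5))
  pts <- cbind(runif(1000, -1.2, 1.2), runif(1000, -1.2, 1.2), 2)
  got <- polygon_roi_filter(point_cloud(pts), pent)
  want <- oracle_in_polygon(pts[, 1], pts[, 2], pent)
  expect_equal(unname(got$points), unname(pts[want, , drop = FALSE]))

  expect_error(polygon_roi_filter(pc, rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("otsu threshold separates a symmetric bimodal histogram", {
  t <- otsu_threshold(c(rep(0, 50), rep(255, 50)))
  expect_gt(t, 0)
  expect_lt(t, 255)
  v <- c(rep(0, 50), rep(255, 50))
  expect_true(sum(v <= t) > 0 && sum(v > t) > 0)
  expect_error(otsu_threshold(rep(7, 10)), "degenerate")
  expect_error(otsu_threshold(c(-1, 5)), "\\[0, 255\\]")
})

test_that("otsu threshold equals the exhaustive 256-candidate argmax", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(20:400, 1)
    vals <- switch(1 + i %% 3,
                   sample(0:255, n, TRUE),
                   pmin(pmax(round(c(rnorm(n, 70, 15), rnorm(n, 180, 20))), 0), 255),
                   sample(0:20, n, TRUE) * sample(c(1, 12), n, TRUE))
    if (length(unique(round(vals))) < 2) next
    expect_identical(otsu_threshold(vals), as.integer(oracle_otsu(vals)),
                     label = paste("histogram", i))
  }
})

test_that("colour segmentation keeps the majority class", {
  set.seed(4)
  light <- matrix(pmin(pmax(round(rnorm(2700, 200, 10)), 0), 255), ncol = 3)
  dark <- matrix(pmin(pmax(round(rnorm(300, 60, 10)), 0), 255), ncol = 3)
  pc <- point_cloud(cbind(runif(1000), runif(1000), 2), rbind(light, dark))
  out <- color_segment(pc)
  expect_equal(nrow(out$points), 900L)
  expect_equal(unname(out$points), unname(pc$points[1:900, , drop = FALSE]))

  mono <- point_cloud(cbind(1:5, 1:5, 2), matrix(100L, 5, 3))
  expect_warning(out2 <- color_segment(mono), "degenerate")
  expect_equal(out2$points, mono$points)

  # 50/50 two-tone: exactly one tone survives, the brighter one
  two <- point_cloud(cbind(1:10, 1:10, 2),
                     rbind(matrix(40L, 5, 3), matrix(220L, 5, 3)))
  out3 <- color_segment(two)
  expect_equal(nrow(out3$points), 5L)
  expect_true(all(out3$colors == 220L))

  expect_error(color_segment(point_cloud(cbind(1, 1, 2))), "colours")
})

test_that("statistical outlier removal drops isolated points only", {
  g <- expand.grid(x = seq(0, 0.2, by = 0.01), y = seq(0, 0.2, by = 0.01))
  plane <- cbind(g$x, g$y, 2.5)
  pc <- point_cloud(rbind(plane, c(1, 1, 2.5)))  # one point 1 m away
  out <- remove_statistical_outliers(pc, k = 8, std_ratio = 2)
  expect_equal(n_points(out), nrow(plane))
  expect_equal(unname(out$points), unname(plane))

  # perfectly regular arrangement (identical neighbour distances by
  # symmetry): nothing is removed
  ring <- point_cloud(cbind(cos(2 * pi * (1:100) / 100),
                            sin(2 * pi * (1:100) / 100), 2.5))
  expect_equal(n_points(remove_statistical_outliers(ring, 8, 2)), 100L)

  expect_error(remove_statistical_outliers(point_cloud(cbind(1:5, 1, 2)), k = 20),
               "more than k")
})

test_that("outlier removal matches the brute-force kNN oracle", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(900, sd = 0.05), ncol = 3),
               matrix(rnorm(30, sd = 0.6), ncol = 3))
  pc <- point_cloud(pts)
  out <- remove_statistical_outliers(pc, k = 10, std_ratio = 1.5)
  keep <- oracle_outlier_keep(pts, 10, 1.5)
  expect_equal(unname(out$points), unname(pts[keep, , drop = FALSE]))
})

test_that("random subsampling is uniform, seeded, and size-exact", {
  set.seed(10)
  pc <- point_cloud(cbind(rnorm(5000), rnorm(5000), runif(5000, 2, 2.7)))
  s1 <- random_subsample(pc, 1500, seed = 42)
  expect_equal(n_points(s1), 1500L)
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  expect_true(all(key(s1$points) %in% key(pc$points)))
  expect_identical(random_subsample(pc, 1500, seed = 42)$points, s1$points)
  s2 <- random_subsample(pc, 1500, seed = 43)
  expect_false(identical(s1$points, s2$points))

  expect_identical(random_subsample(pc, 5000, seed = 1)$points, pc$points)
  expect_error(random_subsample(pc, 6000, seed = 1), "fewer")
  padded <- random_subsample(pc, 6000, seed = 1, pad = "resample")
  expect_equal(n_points(padded), 6000L)
  expect_true(all(key(padded$points) %in% key(pc$points)))
})

test_that("jitter respects its amplitude bound and uniform moments", {
  set.seed(11)
  pc <- point_cloud(cbind(rnorm(200), rnorm(200), runif(200, 2, 2.6)))
  expect_identical(jitter_points(pc, 0, seed = 1)$points, pc$points)

  j <- jitter_points(pc, 0.005, seed = 2)
  expect_equal(dim(j$points), dim(pc$points))
  expect_lte(max(abs(j$points - pc$points)), 0.005)
  expect_identical(jitter_points(pc, 0.005, seed = 2)$points, j$points)

  # moments of U(-a, a): mean 0, variance a^2/3
  big <- point_cloud(matrix(0, 2e5, 3))
  d <- jitter_points(big, 0.005, seed = 3)$points
  expect_lt(abs(mean(d)), 1e-5)
  expect_equal(var(as.vector(d)), 0.005^2 / 3, tolerance = 0.01)
})

test_that("crop_head removes the head lobe and spares headless bodies", {
  sc <- labelled_body_head(seed = 13)
  out <- crop_head(sc$cloud)
  key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9))
  kept <- key(sc$cloud$points) %in% key(out$points)
  expect_gt(mean(kept[sc$labels == "body"]), 0.95)   # body retained
  expect_lt(mean(kept[sc$labels == "head"]), 0.05)   # head removed

  # mirrored front-to-back: the mirrored head region is removed instead
  scm <- labelled_body_head(seed = 13, mirror = TRUE)
  outm <- crop_head(scm$cloud)
  keptm <- key(scm$cloud$points) %in% key(outm$points)
  expect_gt(mean(keptm[scm$labels == "body"]), 0.95)
  expect_lt(mean(keptm[scm$labels == "head"]), 0.05)

  # headless body: no spurious large crop
  hb <- labelled_body_head(seed = 14, head = FALSE)
  expect_gte(n_points(crop_head(hb$cloud)) / n_points(hb$cloud), 0.95)

  expect_error(crop_head(point_cloud(cbind(1:50, 1, 2))), "at least 100")
  degenerate <- point_cloud(cbind(rep(1, 200), rep(2, 200), runif(200, 2, 2.5)))
  expect_error(crop_head(degenerate), "degenerate")
})

test_that("every filter returns an order-preserving subsequence", {
  set.seed(15)
  pts <- cbind(sort(rnorm(300)), rnorm(300), runif(300, 2, 2.7))
  pc <- point_cloud(pts, matrix(sample(0:255, 900, TRUE), ncol = 3))
  for (out in list(depth_band_filter(pc, 2.1, 2.6),
                   polygon_roi_filter(pc, rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))),
                   color_segment(pc),
                   remove_statistical_outliers(pc, 10, 1.5),
                   random_subsample(pc, 100, seed = 1))) {
    # x is strictly increasing in the input, so subsequence order shows there
    expect_true(!is.unsorted(out$points[, 1]))
    m <- match(out$points[, 1], pts[, 1])
    expect_false(anyNA(m))
    expect_identical(unname(out$colors), unname(pc$colors[m, , drop = FALSE]))
  }
})
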