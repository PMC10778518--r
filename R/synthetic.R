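# Synthetic pig clouds with known geometry and weight labels. The body is a
# superellipsoid resting on the floor, joined to an ellipsoidal head through
# a narrowed ellipsoidal neck; only the camera-visible top surface is
# sampled, which is exactly what a single ceiling-mounted depth camera sees
# (legs are invisible from above and irrelevant to 2.5D volume). Weight is
# tied linearly to the canonical-posture projected volume, so posture
# changes (yaw, pen position, head pitch) alter the observed cloud but never
# the label -- the property the deep model must learn and the volume
# baseline degrades on. Sensor artifacts emulate real depth-camera quality
# issues: a wavy displacement pattern, chunks of missing points, and
# isotropic point noise.

#' Synthetic pig specification
#'
#' @param half_length,half_width,half_height body superellipsoid half-axes in
#'   meters. Defaults (0.45, 0.14, 0.13) describe a mid-range grow-finish
#'   pig of roughly 55 kg at the default density coefficient.
#' @param shape_exponent superellipsoid exponent `>= 2`; 2 is an ellipsoid,
#'   larger values square off the back cross-section.
#' @param head_scale head ellipsoid size as a fraction of the body half-axes,
#'   in `(0, 0.6)`; 0 removes the head (and neck) entirely.
#' @param neck_scale neck radius as a fraction of the body half-width, in
#'   `(0, 0.5)`; the neck is the narrowest part of the silhouette, which is
#'   what [crop_head()] detects.
#' @param yaw orientation in the pen, radians.
#' @param xy_offset position in the pen, meters (length-2).
#' @param head_pitch head-down (negative) / head-up rotation, radians.
#' @param density_coeff kg per cubic meter mapping canonical projected volume
#'   to weight (default 1000).
#' @param weight_noise_sd Gaussian noise on the weight label, kg (default 2).
#' @return an object of class `pig_spec`.
#' @export
pig_spec <- function(half_length = 0.45, half_width = 0.14, half_height = 0.13,
                     shape_exponent = 2.5, head_scale = 0.35,
                     neck_scale = 0.25, yaw = 0, xy_offset = c(0, 0),
                     head_pitch = 0, density_coeff = 1000,
                     weight_noise_sd = 2) {
  stopifnot(half_length > 0, half_width > 0, half_height > 0,
            shape_exponent >= 2, head_scale >= 0, head_scale < 0.6,
            neck_scale > 0, neck_scale < 0.5, length(xy_offset) == 2L,
            density_coeff > 0, weight_noise_sd >= 0)
  structure(list(half_length = half_length, half_width = half_width,
                 half_height = half_height, shape_exponent = shape_exponent,
                 head_scale = head_scale, neck_scale = neck_scale,
                 yaw = yaw, xy_offset = as.numeric(xy_offset),
                 head_pitch = head_pitch, density_coeff = density_coeff,
                 weight_noise_sd = weight_noise_sd),
            class = "pig_spec")
}

#' Depth-sensor artifact specification
#'
#' Emulates the quality issues seen in real top-down depth captures: an
#' unexplained wavy displacement pattern across the frame and point clouds
#' missing large chunks of points, plus fine isotropic noise.
#'
#' @param wave_amplitude sinusoidal z-displacement amplitude, meters.
#' @param wave_frequency wave frequency, cycles per meter across the floor.
#' @param dropout_chunks number of random discs of points deleted.
#' @param dropout_radius radius of each dropout disc, meters.
#' @param point_noise_sd isotropic Gaussian coordinate noise, meters.
#' @return an object of class `sensor_artifacts`.
#' @export
sensor_artifacts <- function(wave_amplitude = 0.01, wave_frequency = 2,
                             dropout_chunks = 2L, dropout_radius = 0.06,
                             point_noise_sd = 0.003) {
  stopifnot(wave_amplitude >= 0, wave_frequency >= 0, dropout_chunks >= 0,
            dropout_radius >= 0, point_noise_sd >= 0)
  structure(list(wave_amplitude = wave_amplitude,
                 wave_frequency = wave_frequency,
                 dropout_chunks = as.integer(dropout_chunks),
                 dropout_radius = dropout_radius,
                 point_noise_sd = point_noise_sd),
            class = "sensor_artifacts")
}

# --- geometry -------------------------------------------------------------
# All component surfaces are expressed as top-height functions h(x, y) in the
# body frame (x along the spine, origin at the body centre, floor at height
# 0). The body superellipsoid has a closed-form height; head and neck are
# quadrics, so their top surface solves a quadratic in z. Head pitch rotates
# the head quadric about the y axis through the neck joint.

pig_components <- function(spec) {
  a <- spec$half_length; b <- spec$half_width; cb <- spec$half_height
  e <- spec$shape_exponent
  comps <- list(body = list(
    type = "super", a = a, b = b, c = cb, e = e, zc = cb))
  if (spec$head_scale > 0) {
    ah <- spec$head_scale * a; bh <- spec$head_scale * b
    ch <- spec$head_scale * cb
    rn <- spec$neck_scale * b
    x0 <- 0.92 * a                      # neck start
    ln <- 0.55 * ah                     # neck length
    zmid <- cb                          # component centre height
    pivot <- c(x0 + ln, zmid)           # head rotates about this xz point
    comps$neck <- list(type = "quadric",
                       center = c(x0 + ln / 2, 0, zmid),
                       M = diag(1 / c(0.75 * ln + rn, rn, rn)^2))
    # head centre before pitch, then rotated about the pivot
    hc0 <- c(x0 + ln + 0.85 * ah, 0, zmid)
    phi <- spec$head_pitch
    R <- matrix(c(cos(phi), 0, sin(phi), 0, 1, 0, -sin(phi), 0, cos(phi)),
                3L, 3L)
    hc <- c(pivot[1L], 0, pivot[2L]) +
      R %*% (hc0 - c(pivot[1L], 0, pivot[2L]))
    D <- diag(1 / c(ah, bh, ch)^2)
    comps$head <- list(type = "quadric", center = as.numeric(hc),
                       M = R %*% D %*% t(R))
  }
  comps
}

# top height of one component over body-frame (x, y); NA where absent
component_height <- function(comp, x, y) {
  if (comp$type == "super") {
    r <- (abs(x) / comp$a)^comp$e + (abs(y) / comp$b)^comp$e
    h <- rep(NA_real_, length(x))
    ok <- r <= 1
    h[ok] <- comp$zc + comp$c * (1 - r[ok])^(1 / comp$e)
    return(h)
  }
  dx <- x - comp$center[1L]; dy <- y - comp$center[2L]
  M <- comp$M
  A <- M[3L, 3L]
  B <- 2 * (M[1L, 3L] * dx + M[2L, 3L] * dy)
  C <- M[1L, 1L] * dx^2 + 2 * M[1L, 2L] * dx * dy + M[2L, 2L] * dy^2 - 1
  disc <- B^2 - 4 * A * C
  h <- rep(NA_real_, length(x))
  ok <- disc >= 0
  h[ok] <- comp$center[3L] + (-B[ok] + sqrt(disc[ok])) / (2 * A)
  h[!is.na(h) & h < 0] <- NA_real_  # below the floor: not visible from above
  h
}

# combined top height + component label over body-frame coordinates
pig_height <- function(comps, x, y) {
  h <- rep(NA_real_, length(x))
  lab <- rep(NA_character_, length(x))
  for (nm in names(comps)) {
    hc <- component_height(comps[[nm]], x, y)
    take <- !is.na(hc) & (is.na(h) | hc > h)
    h[take] <- hc[take]
    lab[take] <- nm
  }
  list(height = h, label = lab)
}

pig_bbox <- function(spec) {
  a <- spec$half_length; b <- spec$half_width
  xmax <- if (spec$head_scale > 0)
    0.92 * a + 0.55 * spec$head_scale * a + 2 * spec$head_scale * a else a
  c(xmin = -a, xmax = xmax, ymin = -b, ymax = b)
}

#' Sample the camera-visible surface of a synthetic pig
#'
#' Samples `n_raw` points on the top (camera-facing) surface of the body,
#' neck and head, area-weighted so steep flanks are not over-thinned,
#' applies the posture transform (yaw, pen offset, head pitch) and expresses
#' the result in the camera frame with the floor at `z = plane_distance`.
#'
#' @param spec a [pig_spec()].
#' @param n_raw number of surface points (>= 500).
#' @param plane_distance camera-to-floor distance `L`, meters.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param colors if `TRUE`, attach light pig-skin RGB colours.
#' @param labels if `TRUE`, attach the generating component of each point as
#'   `attr(cloud, "component")`.
#' @return a [point_cloud].
#' @export
sample_pig_surface <- function(spec, n_raw = 4000L, plane_distance = 2.7,
                               seed = NULL, colors = FALSE, labels = FALSE) {
  stopifnot(inherits(spec, "pig_spec"), n_raw >= 500L)
  comps <- pig_components(spec)
  bb <- pig_bbox(spec)
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0); hs <- numeric(0); ls <- character(0)
    guard <- 0L
    while (length(xs) < n_raw && guard < 50L) {
      guard <- guard + 1L
      m <- max(4L * n_raw, 2000L)
      cx <- stats::runif(m, bb["xmin"], bb["xmax"])
      cy <- stats::runif(m, bb["ymin"], bb["ymax"])
      ph <- pig_height(comps, cx, cy)
      hit <- !is.na(ph$height)
      if (!any(hit)) next
      cx <- cx[hit]; cy <- cy[hit]; hh <- ph$height[hit]; ll <- ph$label[hit]
      # area element via finite differences, capped so near-vertical flanks
      # do not dominate (a top-down camera barely sees them anyway)
      d <- 1e-3
      hx <- pig_height(comps, cx + d, cy)$height
      hy <- pig_height(comps, cx, cy + d)$height
      gx <- ifelse(is.na(hx), 0, (hx - hh) / d)
      gy <- ifelse(is.na(hy), 0, (hy - hh) / d)
      w <- pmin(sqrt(1 + gx^2 + gy^2), 8)
      acc <- stats::runif(length(w)) < w / 8
      xs <- c(xs, cx[acc]); ys <- c(ys, cy[acc])
      hs <- c(hs, hh[acc]); ls <- c(ls, ll[acc])
    }
    if (length(xs) < n_raw)
      stop("surface sampling failed for this pig_spec")
    keep <- seq_len(n_raw)
    xs <- xs[keep]; ys <- ys[keep]; hs <- hs[keep]; ls <- ls[keep]
    # posture: yaw in the pen, then pen offset; camera frame z = L - height
    cy_ <- cos(spec$yaw); sy_ <- sin(spec$yaw)
    wx <- cy_ * xs - sy_ * ys + spec$xy_offset[1L]
    wy <- sy_ * xs + cy_ * ys + spec$xy_offset[2L]
    cols <- NULL
    if (colors) {
      base <- c(215, 170, 160)
      cols <- cbind(pmin(pmax(round(base[1L] + stats::rnorm(n_raw, 0, 8)), 0), 255),
                    pmin(pmax(round(base[2L] + stats::rnorm(n_raw, 0, 8)), 0), 255),
                    pmin(pmax(round(base[3L] + stats::rnorm(n_raw, 0, 8)), 0), 255))
    }
    cloud <- point_cloud(cbind(wx, wy, plane_distance - hs), cols,
                         source_id = "synthetic-pig")
    if (labels) attr(cloud, "component") <- ls
    cloud
  })
}

#' Ground-truth projected volume of a synthetic pig
#'
#' Numerically integrates the shape's top-surface height over a fine grid
#' (independent of the point-cloud rasterizer under test, which it serves as
#' an oracle for). Deterministic; honors the posture fields of `spec`, so a
#' lowered head reduces the value.
#'
#' @param spec a [pig_spec()].
#' @param step integration step, meters (default 0.002).
#' @return projected volume in cubic meters.
#' @export
reference_projected_volume <- function(spec, step = 0.002) {
  stopifnot(inherits(spec, "pig_spec"), step > 0, step <= 0.002 + 1e-12)
  comps <- pig_components(spec)
  bb <- pig_bbox(spec)
  gx <- seq(bb["xmin"] - step, bb["xmax"] + step, by = step)
  gy <- seq(bb["ymin"] - step, bb["ymax"] + step, by = step)
  total <- 0
  for (yv in gy) {  # row-wise to bound memory
    h <- pig_height(comps, gx, rep(yv, length(gx)))$height
    total <- total + sum(h, na.rm = TRUE)
  }
  total * step^2
}

#' Assign a weight label to a synthetic pig
#'
#' Weight is the canonical-posture projected volume times the density
#' coefficient, plus Gaussian noise, truncated at 1 kg. Posture fields
#' (yaw, offset, pitch) are zeroed first: posture changes the observed
#' geometry, never the animal's mass.
#'
#' @param spec a [pig_spec()].
#' @param seed integer seed for the noise draw; `NULL` uses the current
#'   stream.
#' @return weight in kg.
#' @export
assign_weight <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "pig_spec"))
  canon <- spec
  canon$yaw <- 0; canon$xy_offset <- c(0, 0); canon$head_pitch <- 0
  v <- reference_projected_volume(canon)
  w <- spec$density_coeff * v +
    with_seed(seed, stats::rnorm(1L, 0, spec$weight_noise_sd))
  max(1, w)
}

#' Apply depth-sensor artifacts to a cloud
#'
#' Adds a sinusoidal z-displacement field across the xy plane (random
#' direction and phase), deletes all points inside `dropout_chunks` random
#' discs of radius `dropout_radius` (centred on randomly chosen cloud
#' points), and adds isotropic Gaussian coordinate noise, in that order.
#'
#' @param cloud a [point_cloud].
#' @param art a [sensor_artifacts()] (or `NULL` for none).
#' @param seed integer seed; `NULL` uses the current stream.
#' @return the corrupted [point_cloud].
#' @export
apply_sensor_artifacts <- function(cloud, art, seed = NULL) {
  stopifnot(is_point_cloud(cloud))
  if (is.null(art)) return(cloud)
  stopifnot(inherits(art, "sensor_artifacts"))
  if (n_points(cloud) == 0L) return(cloud)
  with_seed(seed, {
    p <- cloud$points
    if (art$wave_amplitude > 0 && art$wave_frequency > 0) {
      theta <- stats::runif(1L, 0, 2 * pi)
      phase <- stats::runif(1L, 0, 2 * pi)
      u <- p[, 1L] * cos(theta) + p[, 2L] * sin(theta)
      p[, 3L] <- p[, 3L] +
        art$wave_amplitude * sin(2 * pi * art$wave_frequency * u + phase)
    }
    out <- point_cloud(p, cloud$colors, cloud$source_id)
    if (art$dropout_chunks > 0L && art$dropout_radius > 0 &&
        n_points(out) > 0L) {
      ctr <- out$points[sample.int(n_points(out),
                                   min(art$dropout_chunks, n_points(out))),
                        1:2, drop = FALSE]
      keep <- rep(TRUE, n_points(out))
      for (k in seq_len(nrow(ctr))) {
        d2 <- (out$points[, 1L] - ctr[k, 1L])^2 +
          (out$points[, 2L] - ctr[k, 2L])^2
        keep <- keep & d2 > art$dropout_radius^2
      }
      out <- subset_cloud(out, which(keep))
    }
    if (art$point_noise_sd > 0 && n_points(out) > 0L) {
      out <- point_cloud(out$points +
                           matrix(stats::rnorm(3L * n_points(out), 0,
                                               art$point_noise_sd),
                                  ncol = 3L),
                         out$colors, out$source_id)
    }
    out
  })
}

#' Generate a labelled synthetic dataset
#'
#' Emulates the study design: several clouds of each animal, captured at
#' independently drawn pen positions, orientations and head postures, with
#' one scale weight per animal. Per-animal body dimensions are scaled so the
#' canonical-posture weights span `weight_range`; every cloud of an animal
#' carries the same label. Artifacts are applied per cloud and each cloud is
#' subsampled to the canonical point count.
#'
#' @param n_animals number of animals (>= 1).
#' @param clouds_per_animal clouds captured per animal (default 5).
#' @param weight_range target weight span in kg (default `c(20, 120)`, the
#'   grow-finish range); labels are truncated into this range.
#' @param artifacts a [sensor_artifacts()] or `NULL` for clean clouds.
#' @param perturb draw random yaw, pen offset and head pitch per cloud
#'   (default `TRUE`); `FALSE` keeps every animal in the canonical posture.
#' @param n_points canonical subsample size per cloud (default 1500).
#' @param n_raw raw surface samples per cloud before artifacts/subsampling.
#' @param plane_distance camera-to-floor distance, meters.
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return an object of class `pig_dataset`: list with `clouds` (list of
#'   [point_cloud]) and `labels` (data.frame: `animal_id`, `weight_kg`).
#' @export
make_dataset <- function(n_animals, clouds_per_animal = 5L,
                         weight_range = c(20, 120),
                         artifacts = sensor_artifacts(), perturb = TRUE,
                         n_points = 1500L, n_raw = 3500L,
                         plane_distance = 2.7, seed = 1L) {
  stopifnot(n_animals >= 1L, clouds_per_animal >= 1L,
            length(weight_range) == 2L, weight_range[1L] > 0,
            weight_range[2L] < 300, weight_range[1L] < weight_range[2L])
  base <- pig_spec()
  v_base <- reference_projected_volume(base)
  w_base <- base$density_coeff * v_base
  if (weight_range[2L] / w_base > 8)
    stop("infeasible weight range for the base body shape")
  with_seed(seed, {
    w_target <- stats::runif(n_animals, weight_range[1L], weight_range[2L])
    clouds <- vector("list", n_animals * clouds_per_animal)
    ids <- character(length(clouds))
    wts <- numeric(length(clouds))
    k <- 0L
    for (i in seq_len(n_animals)) {
      s <- (w_target[i] / w_base)^(1 / 3)
      spec_i <- pig_spec(half_length = base$half_length * s,
                         half_width = base$half_width * s,
                         half_height = base$half_height * s,
                         shape_exponent = base$shape_exponent,
                         head_scale = base$head_scale,
                         neck_scale = base$neck_scale,
                         density_coeff = base$density_coeff,
                         weight_noise_sd = base$weight_noise_sd)
      w_i <- assign_weight(spec_i)
      w_i <- min(max(w_i, weight_range[1L]), weight_range[2L])
      for (j in seq_len(clouds_per_animal)) {
        spec_c <- spec_i
        if (perturb) {
          spec_c$yaw <- stats::runif(1L, -pi, pi)
          spec_c$xy_offset <- c(stats::runif(1L, -0.4, 0.4),
                                stats::runif(1L, -0.25, 0.25))
          spec_c$head_pitch <- stats::runif(1L, -0.5, 0.1)
        }
        cl <- sample_pig_surface(spec_c, n_raw, plane_distance)
        cl <- apply_sensor_artifacts(cl, artifacts)
        cl <- random_subsample(cl, n_points, pad = "resample")
        k <- k + 1L
        cl$source_id <- sprintf("pig%03d-c%d", i, j)
        clouds[[k]] <- cl
        ids[k] <- sprintf("pig%03d", i)
        wts[k] <- w_i
      }
    }
    structure(list(clouds = clouds,
                   labels = data.frame(animal_id = ids, weight_kg = wts,
                                       stringsAsFactors = FALSE)),
              class = "pig_dataset")
  })
}

#' @export
print.pig_dataset <- function(x, ...) {
  cat(sprintf("<pig_dataset> %d clouds, %d animals, weights %.1f-%.1f kg\n",
              length(x$clouds), length(unique(x$labels$animal_id)),
              min(x$labels$weight_kg), max(x$labels$weight_kg)))
  invisible(x)
}

#' Construct a labelled test scene for filter validation
#'
#' A combined cloud of pig, floor plane, wall bands and a dark off-colour
#' distractor blob, with per-point ground-truth source labels, so the
#' animal-extraction chain can be validated exactly against a brute-force
#' application of each rule.
#'
#' @param spec a [pig_spec()] (give it a nonzero `xy_offset`/`yaw` to place
#'   the animal realistically).
#' @param pen_dims pen major and minor axis, meters (default `c(2.9, 1.5)`).
#' @param n_pig,n_floor,n_wall,n_blob point counts per scene component.
#' @param point_noise_sd Gaussian noise on floor/wall surfaces, meters.
#' @param plane_distance camera-to-floor distance, meters.
#' @param seed integer seed.
#' @return list with `cloud` (a coloured [point_cloud]) and `labels`
#'   (character vector: `"pig"`, `"floor"`, `"wall"`, `"blob"`), which
#'   partition the cloud.
#' @export
make_test_scene <- function(spec = pig_spec(xy_offset = c(0.3, 0.1), yaw = 0.4),
                            pen_dims = c(2.9, 1.5), n_pig = 2500L,
                            n_floor = 2500L, n_wall = 800L, n_blob = 250L,
                            point_noise_sd = 0.002, plane_distance = 2.7,
                            seed = 1L) {
  stopifnot(inherits(spec, "pig_spec"), length(pen_dims) == 2L)
  L <- plane_distance
  hx <- pen_dims[1L] / 2; hy <- pen_dims[2L] / 2
  with_seed(seed, {
    pig <- sample_pig_surface(spec, n_pig, L, colors = TRUE)
    clamp255 <- function(m) pmin(pmax(round(m), 0L), 255L)
    floor_pts <- cbind(stats::runif(n_floor, -hx, hx),
                       stats::runif(n_floor, -hy, hy),
                       L + stats::rnorm(n_floor, 0, point_noise_sd))
    floor_col <- clamp255(matrix(120 + stats::rnorm(3L * n_floor, 0, 10),
                                 ncol = 3L))
    side <- sample.int(4L, n_wall, replace = TRUE)
    wx <- ifelse(side == 1L, -hx, ifelse(side == 2L, hx,
                 stats::runif(n_wall, -hx, hx)))
    wy <- ifelse(side <= 2L, stats::runif(n_wall, -hy, hy),
                 ifelse(side == 3L, -hy, hy))
    wall_pts <- cbind(wx + stats::rnorm(n_wall, 0, point_noise_sd),
                      wy + stats::rnorm(n_wall, 0, point_noise_sd),
                      L - stats::runif(n_wall, 0, 0.8))
    wall_col <- clamp255(matrix(105 + stats::rnorm(3L * n_wall, 0, 8),
                                ncol = 3L))
    # dark distractor inside the pen at pig-like height: survives the depth
    # band and the ROI, so only the colour rule can remove it
    bc <- c(-0.6, -0.35, L - 0.2)
    bdir <- matrix(stats::rnorm(3L * n_blob), ncol = 3L)
    bdir <- bdir / sqrt(rowSums(bdir^2))
    blob_pts <- sweep(0.06 * bdir * stats::runif(n_blob)^(1 / 3), 2L, bc, "+")
    blob_col <- clamp255(cbind(70 + stats::rnorm(n_blob, 0, 5),
                               45 + stats::rnorm(n_blob, 0, 5),
                               35 + stats::rnorm(n_blob, 0, 5)))
    pts <- rbind(pig$points, floor_pts, wall_pts, blob_pts)
    cols <- rbind(pig$colors, floor_col, wall_col, blob_col)
    labels <- c(rep("pig", n_points(pig)), rep("floor", n_floor),
                rep("wall", n_wall), rep("blob", n_blob))
    list(cloud = point_cloud(pts, cols, source_id = "synthetic-scene"),
         labels = labels)
  })
}
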