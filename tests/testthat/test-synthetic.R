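# The synthetic pig generator: geometry, reference volumes, weight labels,
# sensor artifacts, datasets, and the labelled filter-test scene.

test_that("sampled surface respects symmetry and geometric bounds", {
  sp <- pig_spec()
  cl <- sample_pig_surface(sp, 3000, seed = 31)
  expect_lt(abs(mean(cl$points[, 2])), 0.01)  # midline symmetry
  expect_true(all(cl$points[, 3] <= 2.7))
  heights <- 2.7 - cl$points[, 3]
  expect_true(all(heights <= 2 * sp$half_height + sp$head_scale * sp$half_height + 1e-9))

  # headless spec: single lobe confined to the body's bounding box
  sp0 <- pig_spec(head_scale = 0)
  cl0 <- sample_pig_surface(sp0, 1000, seed = 32)
  expect_true(all(abs(cl0$points[, 1]) <= sp0$half_length + 1e-9))

  same <- sample_pig_surface(sp, 3000, seed = 31)
  expect_identical(same$points, cl$points)  # seeded reproducibility
})

test_that("reference projected volume matches closed forms", {
  # equal half-axes, exponent 2, no head: a sphere resting on the floor;
  # projected (top-view) volume = cylinder under the equator + upper half
  # = pi r^3 + (2/3) pi r^3
  r <- 0.2
  sph <- pig_spec(half_length = r, half_width = r, half_height = r,
                  shape_exponent = 2, head_scale = 0)
  expect_equal(reference_projected_volume(sph), pi * r^3 + 2 / 3 * pi * r^3,
               tolerance = 0.005)

  # large exponent: a box; projected volume = footprint x full height
  box <- pig_spec(half_length = 0.3, half_width = 0.1, half_height = 0.1,
                  shape_exponent = 40, head_scale = 0)
  expect_equal(reference_projected_volume(box), (2 * 0.3) * (2 * 0.1) * (2 * 0.1),
               tolerance = 0.01)

  # scaling law: doubling all half-axes multiplies the volume by 8
  sp <- pig_spec()
  sp2 <- pig_spec(half_length = 2 * sp$half_length,
                  half_width = 2 * sp$half_width,
                  half_height = 2 * sp$half_height)
  expect_equal(reference_projected_volume(sp2) / reference_projected_volume(sp),
               8, tolerance = 0.005)
})

test_that("rasterized volume of a clean pig tracks the reference oracle", {
  # at ~5 points per cell the discretization errors of the 1 cm grid are
  # small; see the methods vignette for the saturation behaviour
  sp <- pig_spec()
  cl <- sample_pig_surface(sp, 10000, seed = 33)
  expect_equal(cloud_volume(cl, step = 0.01), reference_projected_volume(sp),
               tolerance = 0.03)
})

test_that("weight labels are density x canonical volume, posture-invariant", {
  sp <- pig_spec(weight_noise_sd = 0)
  v <- reference_projected_volume(sp)
  expect_equal(assign_weight(sp), 1000 * v)

  posed <- sp
  posed$yaw <- 1.2; posed$xy_offset <- c(0.3, -0.2); posed$head_pitch <- -0.4
  expect_equal(assign_weight(posed), assign_weight(sp))  # mass is posture-free

  # lowered head reduces the observable projected volume, not the label
  expect_lt(reference_projected_volume(posed),
            reference_projected_volume(sp))

  noisy <- pig_spec(weight_noise_sd = 2)
  draws <- vapply(1:300, function(i) assign_weight(noisy, seed = i), numeric(1))
  expect_equal(sd(draws), 2, tolerance = 0.2)
  expect_equal(mean(draws), 1000 * v, tolerance = 0.01)
})

test_that("sensor artifacts behave as specified", {
  sp <- pig_spec()
  cl <- sample_pig_surface(sp, 2000, seed = 34)
  none <- sensor_artifacts(0, 0, 0L, 0, 0)
  expect_identical(apply_sensor_artifacts(cl, none, seed = 1)$points, cl$points)

  # wave only: |dz| bounded by the amplitude, x/y untouched
  wave <- sensor_artifacts(0.02, 3, 0L, 0, 0)
  wcl <- apply_sensor_artifacts(cl, wave, seed = 2)
  expect_identical(wcl$points[, 1:2], cl$points[, 1:2])
  expect_lte(max(abs(wcl$points[, 3] - cl$points[, 3])), 0.02)
  expect_gt(max(abs(wcl$points[, 3] - cl$points[, 3])), 0.005)

  # a dropout disc covering the whole footprint empties the cloud
  total <- sensor_artifacts(0, 0, 1L, 5, 0)
  expect_lt(n_points(apply_sensor_artifacts(cl, total, seed = 3)), 5)

  # mild dropout removes a contiguous chunk
  chunk <- sensor_artifacts(0, 0, 2L, 0.06, 0)
  expect_lt(n_points(apply_sensor_artifacts(cl, chunk, seed = 4)), 2000)
})

test_that("make_dataset produces the study layout, reproducibly", {
  ds <- make_dataset(n_animals = 10, clouds_per_animal = 7, n_points = 300,
                     n_raw = 900, seed = 35)
  expect_length(ds$clouds, 70L)
  expect_equal(length(unique(ds$labels$weight_kg)), 10L)
  expect_equal(length(unique(ds$labels$animal_id)), 10L)
  expect_true(all(ds$labels$weight_kg >= 20 & ds$labels$weight_kg <= 120))
  expect_true(all(vapply(ds$clouds, n_points, integer(1)) == 300L))
  # same animal -> same label across its clouds
  expect_true(all(tapply(ds$labels$weight_kg, ds$labels$animal_id,
                         function(w) length(unique(w))) == 1L))

  ds2 <- make_dataset(n_animals = 10, clouds_per_animal = 7, n_points = 300,
                      n_raw = 900, seed = 35)
  expect_identical(lapply(ds$clouds, `[[`, "points"),
                   lapply(ds2$clouds, `[[`, "points"))
  expect_identical(ds$labels, ds2$labels)
})

test_that("test scene is fully labelled with the documented components", {
  sc <- make_test_scene(seed = 36)
  expect_equal(length(sc$labels), n_points(sc$cloud))  # labels partition
  expect_setequal(unique(sc$labels), c("pig", "floor", "wall", "blob"))

  fl <- sc$cloud$points[sc$labels == "floor", 3]
  expect_lt(max(abs(fl - 2.7)), 0.012)  # floor at z = L up to point noise

  pig <- sc$cloud$points[sc$labels == "pig", , drop = FALSE]
  expect_true(all(abs(pig[, 1]) <= 2.9 / 2))  # inside the pen footprint
  expect_true(all(abs(pig[, 2]) <= 1.5 / 2))
  expect_false(is.null(sc$cloud$colors))
})
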