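# Point-cloud container and bit-faithful file I/O.

test_that("point_cloud validates its invariants", {
  pc <- point_cloud(cbind(0:1, 0:1, c(2.5, 2.6)))
  expect_equal(n_points(pc), 2L)
  expect_s3_class(point_cloud(NULL), "point_cloud")  # empty cloud is legal
  expect_error(point_cloud(cbind(1, 2)), "three columns")
  expect_error(point_cloud(cbind(1, 2, NaN)), "finite")
  expect_error(point_cloud(cbind(1, 2, 3), colors = cbind(1, 2)), "three columns")
  expect_error(point_cloud(cbind(1, 2, 3), colors = rbind(c(0, 0, 256))), "\\[0, 255\\]")
  expect_error(point_cloud(diag(3), colors = cbind(1, 2, 3)), "one row per point")
})

test_that("ASCII PLY reads exactly what the file declares", {
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header",
               "0 0 2.7", "1 0 2.7", "0 1 2.2"), f)
  pc <- read_cloud(f)
  expect_equal(unname(pc$points),
               rbind(c(0, 0, 2.7), c(1, 0, 2.7), c(0, 1, 2.2)))
  expect_null(pc$colors)
})

test_that("binary PLY round trip is exact at the canonical 1500-point size", {
  set.seed(5)
  pc <- point_cloud(cbind(rnorm(1500), rnorm(1500), runif(1500, 2, 2.7)),
                    colors = matrix(sample(0:255, 4500, TRUE), ncol = 3))
  f <- tempfile(fileext = ".ply")
  write_cloud(pc, f, binary = TRUE)
  back <- read_cloud(f)
  expect_identical(unname(back$points), unname(pc$points))  # bit-for-bit
  expect_identical(unname(back$colors), unname(pc$colors))
})

test_that("ASCII PLY round trip preserves coordinates to 1e-6 m", {
  set.seed(6)
  pc <- point_cloud(cbind(rnorm(50), rnorm(50), runif(50, 2, 2.7)))
  f <- tempfile(fileext = ".ply")
  write_cloud(pc, f, binary = FALSE)
  expect_lt(max(abs(read_cloud(f)$points - pc$points)), 1e-6)
})

test_that("empty cloud writes a valid PLY declaring zero vertices", {
  f <- tempfile(fileext = ".ply")
  write_cloud(point_cloud(NULL), f)
  expect_true(any(grepl("element vertex 0", readLines(f, n = 8L, warn = FALSE))))
  expect_equal(n_points(read_cloud(f)), 0L)
})

test_that("CSV clouds agree with an independent line-by-line parse", {
  f <- tempfile(fileext = ".csv")
  set.seed(7)
  df <- data.frame(x = rnorm(10), y = rnorm(10), z = runif(10, 2, 2.7),
                   r = sample(0:255, 10), g = sample(0:255, 10),
                   b = sample(0:255, 10))
  write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE)
  pc <- read_cloud(f)
  # independent parse: split each line on commas
  lines <- readLines(f)[-1]
  manual <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
  expect_equal(unname(pc$points), manual[, 1:3])
  expect_equal(unname(pc$colors), matrix(as.integer(manual[, 4:6]), ncol = 3))
  # order preserved (all coordinates distinct by construction)
  expect_equal(pc$points[, 1], df$x)
})

test_that("write_cloud to CSV round-trips including colours", {
  pc <- point_cloud(cbind(1:3, 4:6, c(2, 2.1, 2.2)),
                    colors = rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  f <- tempfile(fileext = ".csv")
  write_cloud(pc, f, format = "csv")
  back <- read_cloud(f)
  expect_equal(unname(back$points), unname(pc$points))
  expect_identical(unname(back$colors), unname(pc$colors))
})

test_that("malformed files produce errors naming the problem", {
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 5",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 1", "1 1 1"), f)
  expect_error(read_cloud(f), "vertex")
  f2 <- tempfile(fileext = ".xyzzy")
  writeLines("junk", f2)
  expect_error(read_cloud(f2), "format")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,2,3", "1,oops,3"), f3)
  expect_error(read_cloud(f3), "row 2")
})

test_that("unknown vertex properties are ignored with a warning", {
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "property float intensity", "end_header", "1 2 2.5 99"), f)
  expect_warning(pc <- read_cloud(f), "intensity")
  expect_equal(unname(pc$points), rbind(c(1, 2, 2.5)))
})

test_that("weight tables parse, keep file order, and validate rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,weight_kg,date", "p3,45.2,2021-08-05",
               "p1,20.0,2021-08-05", "p2,119.9,2021-11-09"), f)
  tab <- read_weight_table(f)
  expect_equal(tab$animal_id, c("p3", "p1", "p2"))
  expect_equal(tab$weight_kg, c(45.2, 20, 119.9))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,weight_kg", "p1,50", "p2,0"), f2)
  expect_error(read_weight_table(f2), "row 2")

  # a full-scale herd: 249 animals spanning the 20-120 kg study range
  f3 <- tempfile(fileext = ".csv")
  set.seed(9)
  writeLines(c("animal_id,weight_kg",
               sprintf("pig%03d,%.1f", 1:249, runif(249, 20, 120))), f3)
  expect_equal(nrow(read_weight_table(f3)), 249L)
})
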