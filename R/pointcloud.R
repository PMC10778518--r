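#' Construct a point cloud
#'
#' The universal payload of the package: an ordered set of 3D surface samples
#' in the camera frame, in meters. The camera looks straight down, so `z` is
#' the distance from the camera along the optical axis and increases toward
#' the floor; with the camera mounted at height `L` (default 2.7 m) the floor
#' plane lies at `z = L` and the height of a point above the floor is `L - z`.
#'
#' @param points numeric matrix (or coercible) with three columns `x`, `y`,
#'   `z`, in meters. May have zero rows (an empty cloud is legal).
#' @param colors optional integer matrix with three columns (`r`, `g`, `b`) in
#'   `[0, 255]`, one row per point, or `NULL`.
#' @param source_id free-text provenance tag carried through all filters.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(cbind(x = 0, y = 0, z = 2.5))
#' n_points(pc)
#' @export
point_cloud <- function(points, colors = NULL, source_id = "") {
  if (is.null(points)) points <- matrix(numeric(0), 0L, 3L)
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  if (ncol(points) != 3L)
    stop("'points' must have exactly three columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("all point coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (ncol(colors) != 3L)
      stop("'colors' must have exactly three columns (r, g, b)")
    if (nrow(colors) != nrow(points))
      stop("'colors' must have one row per point (got ", nrow(colors),
           " for ", nrow(points), " points)")
    storage.mode(colors) <- "integer"
    if (nrow(colors) > 0L &&
        (anyNA(colors) || min(colors) < 0L || max(colors) > 255L))
      stop("colour channels must be integers in [0, 255]")
    colnames(colors) <- c("r", "g", "b")
  }
  structure(list(points = points, colors = colors,
                 source_id = as.character(source_id)[1L]),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(is_point_cloud(cloud))
  nrow(cloud$points)
}

#' Test for point-cloud objects
#' @param x object to test.
#' @return `TRUE` for `point_cloud` objects.
#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud>", nrow(x$points), "points",
      if (!is.null(x$colors)) "with RGB" else "(no colour)",
      if (nzchar(x$source_id)) paste0("[", x$source_id, "]") else "", "\n")
  if (nrow(x$points) > 0L) {
    rng <- apply(x$points, 2L, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$points

# Keep a subsequence of points, carrying colours and provenance along.
# Every filter in the package funnels through this, which is what makes the
# "output is a subsequence of input" invariant hold by construction.
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              cloud$source_id)
}

# Validate that x is a point_cloud or an n x 3 matrix; return the matrix.
coord_matrix <- function(x) {
  if (is_point_cloud(x)) return(x$points)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected a point_cloud or an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}
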