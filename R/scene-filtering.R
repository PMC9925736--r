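# Scene filtering: pass-through crop, RANSAC floor removal, radius outlier
# removal. Survivor sets are always subsets of the input (points are never
# invented) and pass_through / radius_outlier_removal are idempotent on
# their own output.

#' Pass-through filter
#'
#' Keeps exactly the points inside all supplied per-axis closed intervals,
#' preserving order. Axes without bounds are unconstrained.
#'
#' @param cloud a \code{point_cloud}.
#' @param bounds list with optional numeric \code{x}, \code{y}, \code{z}
#'   elements, each a closed interval \code{c(min, max)}.
#' @return filtered \code{point_cloud} (possibly empty).
#' @export
pass_through <- function(cloud, bounds) {
  cloud <- as_point_cloud(cloud)
  keep <- rep(TRUE, n_points(cloud))
  for (ax in c("x", "y", "z")) {
    b <- bounds[[ax]]
    if (is.null(b)) next
    if (length(b) != 2L || b[1] > b[2])
      stop("invalid parameter: bounds must satisfy min <= max")
    v <- cloud$xyz[, ax]
    keep <- keep & v >= b[1] & v <= b[2]
  }
  subset_points(cloud, keep)
}

#' Remove the dominant floor plane by RANSAC
#'
#' Hypothesizes planes from random 3-point samples, scores by inlier count,
#' refits the winner by least squares and removes its inliers, retrieving
#' the pig points above the concrete floor.
#'
#' @param cloud a \code{point_cloud} with at least 3 points.
#' @param distance_threshold inlier distance to the plane, metres.
#' @param n_iterations maximum RANSAC iterations (adaptively reduced once a
#'   strong consensus is found).
#' @param min_inlier_fraction minimum fraction of points the plane must
#'   explain; below it a no-plane-found error is raised.
#' @param seed integer seed; results are deterministic per seed.
#' @return list with \code{cloud} (plane inliers removed) and \code{plane}
#'   (unit \code{normal}, oriented upwards, and scalar \code{offset} with
#'   normal . p = offset).
#' @export
remove_floor <- function(cloud, distance_threshold = 0.01,
                         n_iterations = 1000L, min_inlier_fraction = 0.2,
                         seed = 1) {
  cloud <- as_point_cloud(cloud)
  n <- n_points(cloud)
  if (n < 3L) stop("degenerate geometry: need at least 3 points")
  if (distance_threshold <= 0 || n_iterations < 1L)
    stop("invalid parameter: threshold > 0 and iterations >= 1 required")
  fit <- ransac_plane(cloud$xyz, distance_threshold, n_iterations, seed)
  if (fit$n_inliers / n < min_inlier_fraction)
    stop(sprintf(
      "no plane found: best consensus %.1f%% of points is below min_inlier_fraction",
      100 * fit$n_inliers / n))
  plane <- fit$plane
  if (plane$normal[3] < 0) {
    plane$normal <- -plane$normal
    plane$offset <- -plane$offset
  }
  list(cloud = subset_points(cloud, !fit$inliers), plane = plane)
}

#' Radius outlier removal
#'
#' Keeps exactly the points having at least \code{min_neighbors} other
#' points (the query point itself is not counted) within Euclidean distance
#' \code{radius}. Neighbour counting uses a uniform grid of cell size
#' \code{radius}, so only the 27 surrounding cells are examined per point.
#'
#' @param cloud a \code{point_cloud}.
#' @param radius neighbourhood radius r, metres (> 0).
#' @param min_neighbors threshold h (>= 1).
#' @return filtered \code{point_cloud}, order preserved.
#' @export
radius_outlier_removal <- function(cloud, radius = 0.03, min_neighbors = 5L) {
  cloud <- as_point_cloud(cloud)
  if (radius <= 0 || min_neighbors < 1L)
    stop("invalid parameter: radius > 0 and min_neighbors >= 1 required")
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  counts <- radius_neighbor_counts(cloud$xyz, radius)
  subset_points(cloud, counts >= min_neighbors)
}

# grid-hashed neighbour counting (compiled); exact, every candidate pair is
# distance-checked
radius_neighbor_counts <- function(xyz, radius) {
  .radius_counts_cpp(xyz, radius)
}
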