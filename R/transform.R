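#' Euler angles for view registration
#'
#' Angles delta, epsilon, lambda are rotations about the q, r and s axes of
#' the acquisition frame, applied in that fixed order.
#'
#' @param delta,epsilon,lambda rotation angles in radians.
#' @return object of class \code{euler_angles}.
#' @export
euler_angles <- function(delta = 0, epsilon = 0, lambda = 0) {
  ang <- c(delta = delta, epsilon = epsilon, lambda = lambda)
  if (!all(is.finite(ang))) stop("invalid parameter: angles must be finite")
  structure(as.list(ang), class = "euler_angles")
}

#' Rotation matrix from Euler angles
#'
#' Builds the three axis rotations and returns their product
#' \code{RMq \%*\% RMr \%*\% RMs}, acting on column vectors.
#'
#' @param angles an \code{euler_angles} object, or the delta angle when the
#'   three angles are given as separate numbers.
#' @param epsilon,lambda remaining angles when \code{angles} is numeric.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_angles <- function(angles, epsilon = 0, lambda = 0) {
  if (is.numeric(angles)) angles <- euler_angles(angles, epsilon, lambda)
  d <- angles$delta; e <- angles$epsilon; l <- angles$lambda
  RMq <- matrix(c(1, 0, 0,
                  0, cos(d), -sin(d),
                  0, sin(d), cos(d)), 3, 3, byrow = TRUE)
  RMr <- matrix(c(cos(e), 0, sin(e),
                  0, 1, 0,
                  -sin(e), 0, cos(e)), 3, 3, byrow = TRUE)
  RMs <- matrix(c(cos(l), -sin(l), 0,
                  sin(l), cos(l), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  RMq %*% RMr %*% RMs
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix; must be orthonormal with
#'   determinant +1 within 1e-9.
#' @param translation length-3 translation vector (metres).
#' @return object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("invalid parameter: need a 3x3 rotation and length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("invalid parameter: rotation is not orthonormal with det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(signif(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Invert a rigid transform
#' @param t a \code{rigid_transform}.
#' @export
transform_inverse <- function(t) {
  rigid_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Compose rigid transforms (apply \code{b} first, then \code{a})
#' @param a,b \code{rigid_transform}s.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to a point cloud
#'
#' Each point p is mapped to R p + T.
#'
#' @param cloud a \code{point_cloud} (or n x 3 matrix).
#' @param t a \code{rigid_transform}.
#' @return transformed \code{point_cloud} (labels preserved).
#' @export
apply_transform <- function(cloud, t) {
  if (!inherits(t, "rigid_transform"))
    t <- rigid_transform(t$rotation, t$translation)
  cloud <- as_point_cloud(cloud)
  xyz <- cloud$xyz %*% t(t$rotation)
  xyz <- sweep(xyz, 2L, t$translation, `+`)
  point_cloud(xyz, cloud$labels)
}

#' Merge registered views into one cloud
#'
#' @param views list of \code{point_cloud}s (camera coordinates).
#' @param transforms list of \code{rigid_transform}s, one per view, mapping
#'   each view into the global frame.
#' @return concatenated transformed \code{point_cloud}; the point count
#'   equals the sum of view counts.
#' @export
merge_views <- function(views, transforms) {
  if (is_point_cloud(views)) views <- list(views)
  if (inherits(transforms, "rigid_transform")) transforms <- list(transforms)
  if (length(views) != length(transforms))
    stop("invalid parameter: one transform per view required")
  bind_clouds(mapply(apply_transform, views, transforms, SIMPLIFY = FALSE))
}

# angular difference between rotations, radians
rotation_angle_between <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}

#' Serialize a rigid transform to JSON (row-major rotation + translation)
#' @param t a \code{rigid_transform}.
#' @param path optional file; when NULL the JSON string is returned.
#' @export
transform_to_json <- function(t, path = NULL) {
  obj <- list(rotation = as.vector(t(t$rotation)),
              translation = t$translation)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param x JSON string or file path.
#' @export
transform_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
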