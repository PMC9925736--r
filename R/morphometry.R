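# Body-size measurement from a cleaned, registered pig cloud: body length
# (dorsal-ridge arc length), withers height above the floor plane, maximal
# abdominal width, and abdominal circumference via a periodic cubic B-spline
# fitted to the polar profile of the abdominal slice.

#' Morphometry result container
#'
#' @param length,height,width,abdominal_circumference measures in metres.
#' @param slice_position axial position of the abdominal slice, metres.
#' @export
morphometry_result <- function(length, height, width,
                               abdominal_circumference, slice_position) {
  structure(list(length = length, height = height, width = width,
                 abdominal_circumference = abdominal_circumference,
                 slice_position = slice_position),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(paste0("morphometry_result\n  body length: %.4f m\n",
                     "  withers height: %.4f m\n  abdominal width: %.4f m\n",
                     "  abdominal circumference: %.4f m\n",
                     "  slice position: %.4f m\n"),
              x$length, x$height, x$width, x$abdominal_circumference,
              x$slice_position))
  invisible(x)
}

#' Least-squares longitudinal plane fit
#'
#' Fits Z = a0 x + a1 y + a2 by minimizing the summed squared vertical
#' deviations S over all points.
#'
#' @param points \code{point_cloud} or n x 3 matrix with at least 3
#'   non-collinear points.
#' @return list with coefficients \code{a0}, \code{a1}, \code{a2} and the
#'   residual sum of squares \code{S}.
#' @export
fit_longitudinal_plane <- function(points) {
  xyz <- as_point_cloud(points)$xyz
  if (nrow(xyz) < 3L) stop("degenerate geometry: need at least 3 points")
  X <- cbind(xyz[, 1], xyz[, 2], 1)
  qd <- qr(X)
  if (qd$rank < 3L)
    stop("degenerate geometry: points are collinear (plane underdetermined)")
  coef <- qr.coef(qd, xyz[, 3])
  res <- xyz[, 3] - X %*% coef
  list(a0 = unname(coef[1]), a1 = unname(coef[2]), a2 = unname(coef[3]),
       S = sum(res^2))
}

# Rotate about z so the largest horizontal spread lies along x and the head
# (higher local height maximum) sits at the anterior (small-x) end. The pig
# is assumed upright in the registered global frame, so only an in-plane
# rotation is applied.
orient_pig <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  xy <- cloud$xyz[, 1:2, drop = FALSE]
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1])
  rot_z <- function(a) rigid_transform(rotation_from_angles(0, 0, a))
  out <- apply_transform(cloud, rot_z(-ang))
  x <- out$xyz[, 1]; z <- out$xyz[, 3]
  lo <- stats::quantile(x, 1 / 3); hi <- stats::quantile(x, 2 / 3)
  if (max(z[x <= lo]) < max(z[x >= hi])) {
    out <- apply_transform(out, rot_z(pi))
    ang <- ang + pi
  }
  list(cloud = out, transform = rot_z(-ang))
}

# re-express a plane in the frame reached by a rigid transform
transform_plane <- function(plane, t) {
  normal <- as.vector(t$rotation %*% plane$normal)
  list(normal = normal, offset = plane$offset + sum(normal * t$translation))
}

# height-above-floor profile along the body axis: per-bin maxima smoothed by
# a 3-bin moving maximum (the second-extreme-value rule needs a stable,
# spike-tolerant profile)
axis_height_profile <- function(cloud, floor_plane, bin = 0.02) {
  x <- cloud$xyz[, 1]
  h <- plane_height(cloud$xyz, floor_plane)
  br <- seq(min(x) - 1e-9, max(x) + bin, by = bin)
  idx <- findInterval(x, br)
  hmax <- tapply(h, idx, max)
  ord <- order(as.integer(names(hmax)))
  hmax <- hmax[ord]
  centers <- br[as.integer(names(hmax))] + bin / 2
  hmax <- as.vector(hmax)
  m <- length(hmax)
  sm <- pmax(hmax,
             c(hmax[-1], -Inf)[seq_len(m)],
             c(-Inf, hmax[-m])[seq_len(m)])
  list(centers = unname(centers), height = unname(sm), raw = unname(hmax))
}

#' Withers height above the floor plane
#'
#' Builds the maximal-height profile along the body axis, smooths it and
#' locates its second local maximum from the anterior end: the first is the
#' head/ears, the second the withers. The pig cloud must already be
#' oriented (anterior at small x), e.g. by \code{\link{measure_pig}}.
#'
#' @param cloud oriented pig \code{point_cloud}.
#' @param floor_plane floor plane from \code{\link{remove_floor}} (list with
#'   unit \code{normal} and \code{offset}).
#' @param bin profile bin width along the axis, metres.
#' @param min_prominence minimum height (metres) a profile maximum must
#'   rise above its separating valleys to count as an anatomical extremum;
#'   suppresses sampling jitter on flat back sections.
#' @return withers height in metres.
#' @export
withers_height <- function(cloud, floor_plane, bin = 0.02,
                           min_prominence = 0.02) {
  prof <- axis_height_profile(as_point_cloud(cloud), floor_plane, bin)
  pk <- profile_peaks(prof$height, min_prominence)
  if (length(pk) < 2L)
    stop("withers not found: height profile has fewer than 2 local maxima")
  prof$height[pk[2L]]
}

#' Locate the abdominal measuring slice
#'
#' Finds the axial position of maximal lateral extent strictly between the
#' fore- and hind-limb positions (limbs are detected as axial bins whose
#' points reach close to the lowest cloud level) and returns the points of
#' a thin slab there.
#'
#' @param cloud oriented pig \code{point_cloud}.
#' @param slab slab thickness, metres.
#' @param bin scan bin width, metres.
#' @return list with \code{slice} (a \code{point_cloud}) and
#'   \code{slice_position} (metres along the body axis). Ties in lateral
#'   extent resolve to the most anterior maximal bin.
#' @export
locate_abdominal_slice <- function(cloud, slab = 0.02, bin = 0.02) {
  cloud <- as_point_cloud(cloud)
  x <- cloud$xyz[, 1]; y <- cloud$xyz[, 2]; z <- cloud$xyz[, 3]
  br <- seq(min(x) - 1e-9, max(x) + bin, by = bin)
  idx <- findInterval(x, br)
  splits <- split(seq_along(x), idx)
  splits <- splits[order(as.integer(names(splits)))]
  centers <- br[as.integer(names(splits))] + bin / 2
  widths <- vapply(splits, function(ii)
    if (length(ii) >= 5L) max(y[ii]) - min(y[ii]) else NA_real_, 0)
  zmins <- vapply(splits, function(ii) min(z[ii]), 0)
  zlo <- min(z); zhi <- max(z)
  limb <- zmins < zlo + 0.25 * (zhi - zlo)
  lower <- -Inf; upper <- Inf
  if (any(limb)) {
    groups <- cumsum(c(TRUE, diff(which(limb)) > 1L))
    limb_x <- centers[limb]
    if (max(groups) >= 2L) {
      lower <- max(limb_x[groups == 1L]) + 0.05
      upper <- min(limb_x[groups == max(groups)]) - 0.05
    }
  }
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    lower <- stats::quantile(x, 0.15)
    upper <- stats::quantile(x, 0.85)
  }
  cand <- which(centers >= lower & centers <= upper & !is.na(widths))
  if (!length(cand)) stop("insufficient data: no usable bins between limbs")
  pos <- centers[cand[which.max(widths[cand])]]
  keep <- abs(x - pos) <= slab / 2
  if (!any(keep)) stop("insufficient data: empty abdominal slab")
  list(slice = subset_points(cloud, keep), slice_position = unname(pos))
}

#' Maximal abdominal width of a slice
#'
#' @param slice non-empty \code{point_cloud} of the abdominal slab.
#' @return lateral extent (max y - min y) in metres.
#' @export
body_width <- function(slice) {
  slice <- as_point_cloud(slice)
  if (n_points(slice) == 0L) stop("insufficient data: empty slice")
  max(slice$xyz[, 2]) - min(slice$xyz[, 2])
}

# polar angle rule of the cross-section transform: equals atan2(dz, dy)
# where (y-y0)(z-z0) >= 0 and its antipode (plus pi) where the product is
# negative, which reproduces both printed arctan branches wherever the
# tangent is defined
polar_theta <- function(dy, dz) {
  phi <- atan2(dz, dy)
  phi <- ifelse(dy * dz < 0, phi + pi, phi)
  th <- phi %% (2 * pi)
  th[dy == 0 & dz == 0] <- 0
  th
}

#' Cartesian-to-polar transform of the abdominal slice
#'
#' Projects the slice to the (y, z) cut plane, takes the slice centroid as
#' the pole and returns central radii and polar angles; points coincident
#' with the pole keep rho = 0 with theta defined as 0.
#'
#' Because the angle rule permutes quadrants, the radius profile is
#' continuous only when the pole sits at the (point-symmetric) section
#' centre; for occluded slices whose centroid is displaced, pass the pole
#' explicitly.
#'
#' @param slice \code{point_cloud} of the abdominal slab.
#' @param pole optional (y0, z0) pole position; defaults to the slice
#'   centroid.
#' @return object of class \code{polar_slice}: list with \code{pole}
#'   (y0, z0), \code{rho} and \code{theta}.
#' @export
to_polar <- function(slice, pole = NULL) {
  slice <- as_point_cloud(slice)
  if (n_points(slice) == 0L) stop("insufficient data: empty slice")
  if (is.null(pole)) {
    y0 <- mean(slice$xyz[, 2]); z0 <- mean(slice$xyz[, 3])
  } else {
    y0 <- pole[1]; z0 <- pole[2]
  }
  dy <- slice$xyz[, 2] - y0; dz <- slice$xyz[, 3] - z0
  structure(list(pole = c(y0 = y0, z0 = z0),
                 rho = sqrt(dy^2 + dz^2),
                 theta = polar_theta(dy, dz)),
            class = "polar_slice")
}

# wrapped (periodic) cubic B-spline design matrix on K uniform knots over
# [0, 2*pi); columns are the K periodic basis functions
periodic_bspline_basis <- function(theta, K, deriv = 0L) {
  h <- 2 * pi / K
  knots <- h * ((-3):(K + 3))
  B <- splines::splineDesign(knots, theta %% (2 * pi), ord = 4L,
                             derivs = rep(deriv, length(theta)))
  Bp <- matrix(0, length(theta), K)
  for (j in seq_len(ncol(B))) {
    cl <- ((j - 1L) %% K) + 1L
    Bp[, cl] <- Bp[, cl] + B[, j]
  }
  Bp
}

#' Fit a closed periodic B-spline to a polar slice
#'
#' Least-squares fit of the radius as a periodic cubic B-spline function of
#' the polar angle, with a light circular second-difference penalty so the
#' curve interpolates smoothly across angular gaps (e.g. railing
#' occlusion). Closure f(0+) = f(2*pi-) holds by construction.
#'
#' @param slice a \code{polar_slice} with at least 8 samples spanning at
#'   least 270 degrees of angle.
#' @param n_knots number of uniform knots over the circle.
#' @param lambda smoothing weight; default scales with the sample count.
#' @return object of class \code{closed_curve} with functions \code{f}
#'   (radius, metres) and \code{fprime} (analytic spline derivative).
#' @export
fit_closed_curve <- function(slice, n_knots = 24L, lambda = NULL) {
  stopifnot(inherits(slice, "polar_slice"))
  th <- slice$theta; rho <- slice$rho
  if (length(th) < 8L)
    stop("insufficient coverage: need at least 8 polar samples")
  sth <- sort(th)
  gaps <- c(diff(sth), 2 * pi - sth[length(sth)] + sth[1])
  if (max(gaps) > pi / 2)
    stop("insufficient coverage: angular coverage below 270 degrees")
  K <- as.integer(n_knots)
  if (is.null(lambda)) lambda <- 1e-3 * length(th) / K
  B <- periodic_bspline_basis(th, K)
  D <- matrix(0, K, K)
  for (i in seq_len(K)) {
    D[i, i] <- 1
    D[i, (i %% K) + 1L] <- -2
    D[i, ((i + 1L) %% K) + 1L] <- 1
  }
  M <- crossprod(B) + lambda * crossprod(D)
  coef <- as.vector(solve(M, crossprod(B, rho)))
  f <- function(theta) as.vector(periodic_bspline_basis(theta, K) %*% coef)
  fprime <- function(theta)
    as.vector(periodic_bspline_basis(theta, K, deriv = 1L) %*% coef)
  structure(list(f = f, fprime = fprime, coef = coef, n_knots = K,
                 lambda = lambda),
            class = "closed_curve")
}

#' Abdominal circumference of a closed polar curve
#'
#' Evaluates the polar arc length integral of sqrt(f(theta)^2 +
#' f'(theta)^2) over the full circle by composite Simpson quadrature; for a
#' constant curve f = r this reduces exactly to 2*pi*r.
#'
#' @param curve a \code{closed_curve}.
#' @param n_intervals even number of Simpson intervals.
#' @return circumference in metres.
#' @export
abdominal_circumference <- function(curve, n_intervals = 4096L) {
  stopifnot(inherits(curve, "closed_curve"))
  n <- as.integer(n_intervals)
  if (n %% 2L) n <- n + 1L
  th <- seq(0, 2 * pi, length.out = n + 1L)
  g <- sqrt(curve$f(th)^2 + curve$fprime(th)^2)
  hstep <- 2 * pi / n
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * g) * hstep / 3
}

#' Body length along the dorsal ridge
#'
#' Extracts the crest (per-bin maximum-z point along the body axis),
#' projects it onto the longitudinal plane, appends the axial extreme
#' points so steep end sections are kept, median-smooths the profile and
#' returns the arc length of the resulting polyline - the discrete form of
#' the curve integral of sqrt(dx^2 + dy^2 + dz^2).
#'
#' @param cloud oriented pig \code{point_cloud} with at least 500 points.
#' @param bin ridge bin width along the axis, metres.
#' @return ridge arc length in metres.
#' @export
body_length <- function(cloud, bin = 0.02) {
  cloud <- as_point_cloud(cloud)
  if (n_points(cloud) < 500L)
    stop("insufficient data: need at least 500 points to extract the ridge")
  x <- cloud$xyz[, 1]; z <- cloud$xyz[, 3]
  br <- seq(min(x) - 1e-9, max(x) + bin, by = bin)
  idx <- findInterval(x, br)
  top <- vapply(split(seq_along(x), idx), function(ii) ii[which.max(z[ii])], 0L)
  rx <- x[top]; rz <- z[top]
  i_lo <- which.min(x); i_hi <- which.max(x)
  rx <- c(x[i_lo], rx, x[i_hi]); rz <- c(z[i_lo], rz, z[i_hi])
  o <- order(rx)
  rx <- rx[o]; rz <- rz[o]
  if (length(rx) >= 7L) rz <- stats::runmed(rz, 3L, endrule = "keep")
  sum(sqrt(diff(rx)^2 + diff(rz)^2))
}

#' Measure a cleaned pig cloud
#'
#' Orients the cloud along its principal horizontal axis (anterior end =
#' side with the higher height peak) and computes the four body measures.
#'
#' @param cloud filtered pig \code{point_cloud} in the registered global
#'   frame.
#' @param floor_plane floor plane from \code{\link{remove_floor}}; defaults
#'   to the horizontal plane z = 0.
#' @param bin axial bin width for the ridge/profile scans, metres.
#' @param slab abdominal slab thickness, metres.
#' @return a \code{\link{morphometry_result}}.
#' @export
measure_pig <- function(cloud, floor_plane = NULL, bin = 0.02, slab = 0.02) {
  if (is.null(floor_plane))
    floor_plane <- list(normal = c(0, 0, 1), offset = 0)
  ori <- orient_pig(cloud)
  oc <- ori$cloud
  floor_oriented <- transform_plane(floor_plane, ori$transform)
  sl <- locate_abdominal_slice(oc, slab = slab, bin = bin)
  curve <- fit_closed_curve(to_polar(sl$slice))
  morphometry_result(
    length = body_length(oc, bin = bin),
    height = withers_height(oc, floor_oriented, bin = bin),
    width = body_width(sl$slice),
    abdominal_circumference = abdominal_circumference(curve),
    slice_position = sl$slice_position)
}
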