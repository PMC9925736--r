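# Synthetic multi-view depth scenes with known ground truth.
#
# The pig body is a loft of superellipse cross-sections along a (possibly
# arched) spine: half-width w(u) and half-height v(u) vary with the
# normalized axial position u in [0, 1] (anterior at u = 0), and four short
# cylindrical leg stubs hang below the trunk. The dorsal profile carries a
# head/ear bump followed by a withers bump, giving the bimodal height profile
# the withers detector needs. Every measured quantity (ridge arc length,
# withers height, maximal abdominal width, abdominal circumference) is
# computable from the parametrization independently of any sampled points.

cos_bump <- function(u, center, width) {
  out <- numeric(length(u))
  inside <- abs(u - center) < width / 2
  out[inside] <- cos(pi * (u[inside] - center) / width)^2
  out
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# perimeter of the superellipse |y/a|^n + |z/b|^n = 1 by dense chord summation
superellipse_perimeter <- function(a, b, n, m = 2^20) {
  t <- seq(0, 2 * pi, length.out = m + 1L)
  y <- a * sign(cos(t)) * abs(cos(t))^(2 / n)
  z <- b * sign(sin(t)) * abs(sin(t))^(2 / n)
  sum(sqrt(diff(y)^2 + diff(z)^2))
}

# Strict interior local maxima of a profile, plateau-safe; with
# min_prominence > 0, a maximum only counts if it rises at least that far
# above the valley floors separating it from higher terrain on both sides
# (suppresses sampling jitter on flat stretches).
profile_peaks <- function(h, min_prominence = 0) {
  r <- rle(h)
  v <- r$values
  k <- length(v)
  if (k < 3L) return(integer(0))
  idx_end <- cumsum(r$lengths)
  peaks <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1L
  if (min_prominence > 0 && length(peaks)) {
    prom <- vapply(peaks, function(p) {
      left <- v[seq_len(p - 1L)]
      higher_l <- which(left > v[p])
      lmin <- if (length(higher_l))
        min(left[seq.int(max(higher_l), p - 1L)]) else -Inf
      right <- v[seq.int(p + 1L, k)]
      higher_r <- which(right > v[p])
      rmin <- if (length(higher_r))
        min(right[seq_len(min(higher_r))]) else -Inf
      v[p] - max(lmin, rmin)   # saddle toward higher terrain; -Inf if none
    }, 0)
    peaks <- peaks[prom > min_prominence]
  }
  idx_end[peaks] - r$lengths[peaks] %/% 2L  # centre of the plateau run
}

make_shape <- function(z_top, z_bot, half_width, exponent, body_length,
                       legs = NULL, grid_n = 4096L) {
  u <- seq(0, 1, length.out = grid_n + 1L)
  zt <- z_top(u)
  dzt <- c(zt[2] - zt[1], (zt[-(1:2)] - zt[1:(grid_n - 1L)]) / 2,
           zt[grid_n + 1L] - zt[grid_n]) * grid_n
  ridge_len <- function(s) trapz(u, sqrt(s^2 + dzt^2))
  if (ridge_len(1e-9) >= body_length)
    stop("invalid parameter: dorsal profile longer than body_length")
  axial_scale <- stats::uniroot(function(s) ridge_len(s) - body_length,
                                c(1e-9, body_length), tol = 1e-12)$root
  w <- half_width(u)
  i_star <- which.max(w)
  v_star <- (z_top(u[i_star]) - z_bot(u[i_star])) / 2
  pk <- profile_peaks(zt)
  truth <- list(
    length = ridge_len(axial_scale),
    height = if (length(pk) >= 2L) zt[pk[2L]] else NA_real_,
    width = 2 * max(w),
    abdominal_circumference = superellipse_perimeter(max(w), v_star, exponent),
    slice_position = axial_scale * u[i_star])
  structure(list(z_top = z_top, z_bot = z_bot, half_width = half_width,
                 exponent = exponent, body_length = body_length,
                 axial_scale = axial_scale, legs = legs, truth = truth),
            class = "pig_shape")
}

#' Parametric pig body shape
#'
#' Defines the lofted-superellipse pig used by the scene generator. The
#' dorsal profile has a head/ear bump (first height maximum), a withers bump
#' whose apex height equals \code{withers_height} exactly (second maximum),
#' and an optional gentle arch of amplitude \code{dorsal_curvature} over the
#' back. The axial extent is scaled so that the dorsal-ridge arc length
#' equals \code{body_length}. Cross-sections shrink to a point at snout and
#' tail.
#'
#' @param body_length dorsal-ridge arc length, metres.
#' @param withers_height height of the withers apex above the floor, metres.
#' @param head_height height of the head/ear bump apex, metres.
#' @param belly_height trunk underside height above the floor, metres.
#' @param abdominal_max_half_width maximal half-width of the trunk, metres;
#'   reached at 55 % of the body axis, between the limb girdles.
#' @param dorsal_curvature arch amplitude over the rear back, metres
#'   (dimensionless shape scale; 0 gives a level back).
#' @param leg_stub_height length of the four cylindrical leg stubs, metres;
#'   0 omits legs.
#' @param exponent superellipse exponent of the cross-sections (2 = ellipse).
#' @return object of class \code{pig_shape}; element \code{truth} holds the
#'   analytically/numerically derived \code{morphometry_result} quantities.
#' @export
pig_shape <- function(body_length = 1.2, withers_height = 0.70,
                      head_height = 0.76, belly_height = 0.30,
                      abdominal_max_half_width = 0.19,
                      dorsal_curvature = 0.02, leg_stub_height = 0.30,
                      exponent = 2.4) {
  if (any(c(body_length, withers_height, head_height, belly_height,
            abdominal_max_half_width, exponent) <= 0) ||
      dorsal_curvature < 0 || leg_stub_height < 0)
    stop("invalid parameter: shape dimensions must be positive")
  if (withers_height <= belly_height)
    stop("invalid parameter: withers_height must exceed belly_height")
  base_h <- withers_height - 0.05
  z_top <- function(u) {
    arch <- ifelse(u > 0.35, dorsal_curvature * sin(pi * (u - 0.35) / 0.65), 0)
    base_h + arch +
      (head_height - base_h) * cos_bump(u, 0.05, 0.14) +
      (withers_height - base_h) * cos_bump(u, 0.30, 0.30)
  }
  z_bot_ <- function(u) {
    g <- exp(-(u / 0.05)^2) + exp(-((1 - u) / 0.05)^2)
    belly_height + (z_top(u) - belly_height) * pmin(1, g)
  }
  half_width <- function(u) {
    t <- ifelse(u <= 0.55, u * (0.5 / 0.55), 0.5 + (u - 0.55) * (0.5 / 0.45))
    abdominal_max_half_width * pmax(0, sin(pi * t))^0.5
  }
  legs <- if (leg_stub_height > 0)
    list(u = c(0.22, 0.22, 0.85, 0.85), side = c(-1, 1, -1, 1),
         radius = 0.035, length = leg_stub_height)
  make_shape(z_top, z_bot_, half_width, exponent, body_length, legs)
}

#' Cylindrical test shape
#'
#' A constant circular cross-section of the given radius resting on the
#' floor, with an optional head bump; used for closed-form checks (the
#' abdominal circumference of a cylinder is 2*pi*radius).
#'
#' @param radius cross-section radius, metres.
#' @param body_length dorsal-ridge arc length, metres.
#' @param head_bump optional extra apex height of a head bump, metres.
#' @export
cylinder_shape <- function(radius = 0.3, body_length = 1.2, head_bump = 0) {
  if (radius <= 0 || body_length <= 0 || head_bump < 0)
    stop("invalid parameter: shape dimensions must be positive")
  z_top <- function(u) 2 * radius + head_bump * cos_bump(u, 0.05, 0.14)
  make_shape(z_top, function(u) rep(0, length(u)),
             function(u) rep(radius, length(u)),
             exponent = 2, body_length = body_length)
}

#' Elliptical-profile test shape
#'
#' Constant elliptical cross-section with half axes \code{a} (lateral) and
#' \code{b} (vertical); its true circumference is the numerically integrated
#' ellipse perimeter.
#' @param a,b ellipse half axes, metres.
#' @param body_length dorsal-ridge arc length, metres.
#' @export
ellipse_shape <- function(a = 0.30, b = 0.22, body_length = 1.2) {
  if (a <= 0 || b <= 0 || body_length <= 0)
    stop("invalid parameter: shape dimensions must be positive")
  make_shape(function(u) rep(2 * b, length(u)),
             function(u) rep(0, length(u)),
             function(u) rep(a, length(u)),
             exponent = 2, body_length = body_length)
}

#' Sample a point cloud from a pig shape
#'
#' Points are drawn uniformly in the axial parameter and the cross-section
#' angle (legs receive 8 % of the budget when present) and perturbed with
#' isotropic Gaussian noise. The returned ground truth comes from the shape
#' parametrization, not from the sampled points.
#'
#' @param shape a \code{pig_shape}.
#' @param n number of points (>= 100).
#' @param noise_sd Gaussian noise standard deviation, metres.
#' @param seed integer seed; identical seeds give bit-identical clouds.
#' @return list with elements \code{cloud} (a \code{point_cloud}) and
#'   \code{truth} (a \code{morphometry_result}).
#' @export
generate_pig_cloud <- function(shape, n = 1e5, noise_sd = 0, seed = 1) {
  stopifnot(inherits(shape, "pig_shape"))
  if (n < 100) stop("invalid parameter: need n >= 100")
  if (noise_sd < 0) stop("invalid parameter: noise_sd must be >= 0")
  with_seed(seed, {
    n_leg <- if (!is.null(shape$legs)) round(0.08 * n) else 0L
    n_body <- n - n_leg
    u <- stats::runif(n_body)
    t <- stats::runif(n_body, 0, 2 * pi)
    w <- shape$half_width(u)
    v <- (shape$z_top(u) - shape$z_bot(u)) / 2
    zc <- (shape$z_top(u) + shape$z_bot(u)) / 2
    ex <- 2 / shape$exponent
    x <- shape$axial_scale * u
    y <- w * sign(cos(t)) * abs(cos(t))^ex
    z <- zc + v * sign(sin(t)) * abs(sin(t))^ex
    if (n_leg > 0L) {
      lg <- shape$legs
      which_leg <- sample.int(4L, n_leg, replace = TRUE)
      ul <- lg$u[which_leg]
      yc <- lg$side[which_leg] * 0.55 * shape$half_width(ul)
      zb <- shape$z_bot(ul)
      ang <- stats::runif(n_leg, 0, 2 * pi)
      hz <- stats::runif(n_leg)
      x <- c(x, shape$axial_scale * ul + lg$radius * cos(ang))
      y <- c(y, yc + lg$radius * sin(ang))
      z <- c(z, pmax(0, zb - lg$length) + hz * pmin(lg$length, zb))
    }
    xyz <- cbind(x, y, z)
    if (noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(3L * nrow(xyz), 0, noise_sd), ncol = 3L)
    list(cloud = point_cloud(xyz, rep("pig", nrow(xyz))),
         truth = morphometry_result(shape$truth$length, shape$truth$height,
                                    shape$truth$width,
                                    shape$truth$abdominal_circumference,
                                    shape$truth$slice_position))
  })
}

#' Scene specification
#'
#' Describes the pen clutter surrounding a pig: concrete floor plane, two
#' railing bars parallel to the body axis at flank height, and sparse
#' uniform noise points.
#'
#' @param floor_elevation z of the floor plane, metres.
#' @param floor_bounds list with numeric \code{x} and \code{y} ranges of the
#'   floor patch.
#' @param railing list with \code{y} (lateral offset of each bar), \code{z}
#'   (bar height) and \code{radius}, metres.
#' @param n_floor,n_railing,n_noise point counts (>= 0).
#' @param noise_sd Gaussian jitter applied to floor z and railing points.
#' @param noise_bounds list with \code{x}, \code{y}, \code{z} ranges of the
#'   sparse-noise box.
#' @param seed integer seed.
#' @export
scene_spec <- function(floor_elevation = 0,
                       floor_bounds = list(x = c(-0.5, 1.8), y = c(-0.8, 0.8)),
                       railing = list(y = 0.45, z = 0.45, radius = 0.02),
                       n_floor = 5e4, n_railing = 2000, n_noise = 200,
                       noise_sd = 0,
                       noise_bounds = list(x = c(-0.5, 1.8), y = c(-0.8, 0.8),
                                           z = c(0, 1)),
                       seed = 1) {
  if (any(c(n_floor, n_railing, n_noise) < 0) || noise_sd < 0)
    stop("invalid parameter: counts and noise_sd must be >= 0")
  structure(list(floor_elevation = floor_elevation,
                 floor_bounds = floor_bounds, railing = railing,
                 n_floor = as.integer(n_floor),
                 n_railing = as.integer(n_railing),
                 n_noise = as.integer(n_noise), noise_sd = noise_sd,
                 noise_bounds = noise_bounds, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Compose a full pen scene around a pig cloud
#'
#' Adds floor, railing and sparse noise points with per-point ground-truth
#' labels; the labels partition the scene and their counts equal the spec
#' counts exactly.
#'
#' @param pig_cloud \code{point_cloud} of the pig (labelled \code{"pig"}).
#' @param spec a \code{scene_spec}.
#' @return labelled \code{point_cloud}.
#' @export
compose_scene <- function(pig_cloud, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  pig_cloud <- as_point_cloud(pig_cloud)
  with_seed(spec$seed, {
    parts <- list(point_cloud(pig_cloud$xyz, rep("pig", n_points(pig_cloud))))
    if (spec$n_floor > 0L) {
      fb <- spec$floor_bounds
      fx <- stats::runif(spec$n_floor, fb$x[1], fb$x[2])
      fy <- stats::runif(spec$n_floor, fb$y[1], fb$y[2])
      fz <- spec$floor_elevation +
        if (spec$noise_sd > 0) stats::rnorm(spec$n_floor, 0, spec$noise_sd) else 0
      parts <- c(parts, list(point_cloud(cbind(fx, fy, fz),
                                         rep("floor", spec$n_floor))))
    }
    if (spec$n_railing > 0L) {
      fb <- spec$floor_bounds
      side <- sample(c(-1, 1), spec$n_railing, replace = TRUE)
      rx <- stats::runif(spec$n_railing, fb$x[1], fb$x[2])
      ang <- stats::runif(spec$n_railing, 0, 2 * pi)
      ry <- side * spec$railing$y + spec$railing$radius * cos(ang)
      rz <- spec$railing$z + spec$railing$radius * sin(ang)
      xyz <- cbind(rx, ry, rz)
      if (spec$noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(3L * spec$n_railing, 0, spec$noise_sd),
                            ncol = 3L)
      parts <- c(parts, list(point_cloud(xyz, rep("railing", spec$n_railing))))
    }
    if (spec$n_noise > 0L) {
      nb <- spec$noise_bounds
      xyz <- cbind(stats::runif(spec$n_noise, nb$x[1], nb$x[2]),
                   stats::runif(spec$n_noise, nb$y[1], nb$y[2]),
                   stats::runif(spec$n_noise, nb$z[1], nb$z[2]))
      parts <- c(parts, list(point_cloud(xyz, rep("noise", spec$n_noise))))
    }
    bind_clouds(parts)
  })
}

#' Reference calibration cuboid
#'
#' A rectangular cuboid with three distinct edge lengths; its parallel face
#' planes calibrate the per-view registration transforms. Two faces are
#' sampled at higher density (markers): the densest face is +z and the
#' second densest +x, which resolves the cuboid's symmetry so a view's pose
#' is recoverable uniquely.
#'
#' @param dims edge lengths along local x, y, z, metres; must be pairwise
#'   distinct (axis identity is read off the parallel-plane separations).
#' @param pose \code{rigid_transform} placing the cuboid in the global frame
#'   (local origin at the cuboid centre).
#' @param face_weights relative sampling density of faces
#'   \code{x+ x- y+ y- z+ z-}.
#' @export
reference_cube <- function(dims = c(0.32, 0.40, 0.50),
                           pose = rigid_transform(),
                           face_weights = c("x+" = 2, "x-" = 1, "y+" = 1,
                                            "y-" = 1, "z+" = 3, "z-" = 1)) {
  if (length(dims) != 3L || any(dims <= 0))
    stop("invalid parameter: three positive edge lengths required")
  if (min(diff(sort(dims)) / sort(dims)[-3]) < 0.05)
    stop("invalid parameter: edge lengths must be pairwise distinct (>= 5 %)")
  fn <- c("x+", "x-", "y+", "y-", "z+", "z-")
  if (!all(fn %in% names(face_weights)))
    stop("invalid parameter: face_weights must name all six faces")
  if (face_weights["x+"] <= face_weights["x-"] ||
      face_weights["z+"] <= face_weights["z-"])
    stop("invalid parameter: marker faces x+ and z+ must be densest in their pairs")
  structure(list(dims = as.numeric(dims), pose = pose,
                 face_weights = face_weights[fn]),
            class = "reference_cube")
}

#' Sample a point cloud from the reference cuboid
#'
#' @param cube a \code{reference_cube}.
#' @param n total number of points.
#' @param noise_sd isotropic Gaussian noise, metres.
#' @param seed integer seed.
#' @return labelled \code{point_cloud} (labels are the face names) in the
#'   global frame.
#' @export
generate_cube_cloud <- function(cube, n = 6000, noise_sd = 0, seed = 1) {
  stopifnot(inherits(cube, "reference_cube"))
  d <- cube$dims
  areas <- c(d[2] * d[3], d[2] * d[3], d[1] * d[3], d[1] * d[3],
             d[1] * d[2], d[1] * d[2])
  mass <- cube$face_weights * areas
  counts <- floor(n * mass / sum(mass))
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * mass / sum(mass) - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  axis_of <- c(1L, 1L, 2L, 2L, 3L, 3L)
  sign_of <- c(1, -1, 1, -1, 1, -1)
  with_seed(seed, {
    pts <- vector("list", 6L)
    for (f in 1:6) {
      m <- counts[f]
      if (m == 0L) next
      ax <- axis_of[f]
      others <- setdiff(1:3, ax)
      loc <- matrix(0, m, 3L)
      loc[, ax] <- sign_of[f] * d[ax] / 2
      loc[, others[1]] <- stats::runif(m, -d[others[1]] / 2, d[others[1]] / 2)
      loc[, others[2]] <- stats::runif(m, -d[others[2]] / 2, d[others[2]] / 2)
      pts[[f]] <- loc
    }
    xyz <- do.call(rbind, pts)
    if (noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(3L * nrow(xyz), 0, noise_sd), ncol = 3L)
    labels <- rep(names(cube$face_weights), counts)
    apply_transform(point_cloud(xyz, labels), cube$pose)
  })
}

#' Three-camera acquisition rig
#'
#' Holds the top/left/right view poses (each a \code{rigid_transform} mapping
#' camera coordinates into the global frame) and the reference cuboid used
#' for calibration.
#'
#' @param poses named list of three \code{rigid_transform}s.
#' @param cube a \code{reference_cube}.
#' @param cube_points points sampled on the cuboid per view.
#' @param cube_noise_sd cuboid sampling noise, metres.
#' @export
camera_rig <- function(poses = list(
                         top = rigid_transform(rotation_from_angles(0.05, -0.04, 0.03),
                                               c(0.20, -0.10, 1.50)),
                         left = rigid_transform(rotation_from_angles(1.20, 0.10, -0.05),
                                                c(0.30, 1.00, 0.80)),
                         right = rigid_transform(rotation_from_angles(-1.15, -0.08, 0.04),
                                                 c(0.10, -1.00, 0.90))),
                       cube = reference_cube(), cube_points = 6000,
                       cube_noise_sd = 0) {
  if (length(poses) != 3L) stop("invalid parameter: exactly three view poses")
  for (p in poses)
    if (!inherits(p, "rigid_transform"))
      stop("invalid parameter: poses must be rigid_transforms")
  structure(list(poses = poses, cube = cube,
                 cube_points = as.integer(cube_points),
                 cube_noise_sd = cube_noise_sd),
            class = "camera_rig")
}

#' Render a scene into the three camera views
#'
#' Each view is the scene (and the calibration cuboid) expressed in camera
#' coordinates, i.e. transformed by the inverse of the view pose. Merging
#' the views back with the true poses reproduces the scene to numerical
#' precision.
#'
#' @param scene \code{point_cloud} in the global frame.
#' @param rig a \code{camera_rig}.
#' @param seed seed for the cuboid sampling.
#' @return list with \code{views} and \code{cube_views} (three
#'   \code{point_cloud}s each, camera coordinates).
#' @export
render_views <- function(scene, rig, seed = 1) {
  stopifnot(inherits(rig, "camera_rig"))
  scene <- as_point_cloud(scene)
  cube_global <- generate_cube_cloud(rig$cube, rig$cube_points,
                                     rig$cube_noise_sd, seed)
  inv <- lapply(rig$poses, transform_inverse)
  list(views = lapply(inv, function(t) apply_transform(scene, t)),
       cube_views = lapply(inv, function(t) apply_transform(cube_global, t)))
}
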