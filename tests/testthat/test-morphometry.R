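# Plane fitting, ridge length, withers detection, abdominal slice, polar
# transform, closed-curve fitting and the circumference integral.

test_that("longitudinal plane fit equals the normal-equations closed form", {
  set.seed(3)
  xy <- matrix(runif(60, -1, 1), ncol = 2)
  exact <- point_cloud(cbind(xy, 2 * xy[, 1] + 3 * xy[, 2] + 1))
  fit <- fit_longitudinal_plane(exact)
  expect_equal(c(fit$a0, fit$a1, fit$a2), c(2, 3, 1), tolerance = 1e-9)
  expect_lt(fit$S, 1e-18)
  for (i in 1:20) {
    pts <- cbind(matrix(runif(40, -2, 2), ncol = 2), rnorm(20))
    fit <- fit_longitudinal_plane(point_cloud(pts))
    X <- cbind(pts[, 1], pts[, 2], 1)
    beta <- solve(crossprod(X), crossprod(X, pts[, 3]))   # normal equations
    expect_equal(c(fit$a0, fit$a1, fit$a2), as.vector(beta),
                 tolerance = 1e-9)
    expect_equal(fit$S, sum((pts[, 3] - X %*% beta)^2), tolerance = 1e-9)
  }
  coll <- point_cloud(cbind(1:3, 2 * (1:3), 0))
  expect_error(fit_longitudinal_plane(coll), "degenerate geometry")
})

test_that("ridge arc length handles straight, circular and lofted bodies", {
  line <- point_cloud(cbind(seq(0, 1.2, length.out = 600), 0.3, 0.5))
  expect_equal(body_length(line), 1.2, tolerance = 1e-6)
  r <- 0.5
  xs <- seq(-r, r, length.out = 4000)
  semi <- point_cloud(cbind(xs, 0, sqrt(pmax(0, r^2 - xs^2))))
  expect_equal(body_length(semi), pi * r, tolerance = 0.005 * pi * r)
  pig <- generate_pig_cloud(pig_shape(), n = 1e5, noise_sd = 0, seed = 2)
  oc <- porcimetry:::orient_pig(pig$cloud)$cloud
  expect_equal(body_length(oc), pig$truth$length,
               tolerance = 0.02 * pig$truth$length)
  expect_error(body_length(point_cloud(matrix(rnorm(30), ncol = 3))),
               "insufficient data")
})

test_that("withers is the second prominent height maximum from the front", {
  x <- seq(0, 1.4, by = 0.004)
  two_bump <- 0.6 + 0.3 * exp(-((x - 0.1) / 0.05)^2) +
    0.15 * exp(-((x - 0.45) / 0.08)^2)
  expect_equal(withers_height(point_cloud(cbind(x, 0, two_bump)),
                              floor_plane_z0),
               0.75, tolerance = 0.01)
  head_only <- generate_pig_cloud(cylinder_shape(0.3, 1.2, head_bump = 0.15),
                                  2e4, 0, 1)
  expect_error(withers_height(head_only$cloud, floor_plane_z0),
               "withers not found")
  flat <- generate_pig_cloud(cylinder_shape(0.3, 1.2), 2e4, 0, 1)
  expect_error(withers_height(flat$cloud, floor_plane_z0), "withers not found")
  pig <- generate_pig_cloud(pig_shape(), n = 1e5, noise_sd = 0, seed = 5)
  oc <- porcimetry:::orient_pig(pig$cloud)$cloud
  expect_equal(withers_height(oc, floor_plane_z0), pig$truth$height,
               tolerance = 0.02 * pig$truth$height)
})

test_that("abdominal slice sits at the maximal lateral extent between limbs", {
  # bulged cylinder: radius peaks at the axis midpoint
  set.seed(8)
  u <- runif(4e4)
  th <- runif(4e4, 0, 2 * pi)
  rad <- 0.2 + 0.05 * exp(-((u - 0.5) / 0.15)^2)
  bulge <- point_cloud(cbind(1.2 * u, rad * cos(th), 0.5 + rad * sin(th)))
  sl <- locate_abdominal_slice(bulge)
  expect_equal(sl$slice_position, 0.6, tolerance = 0.03)
  expect_equal(body_width(sl$slice), 0.5, tolerance = 0.01)
  # exhaustive scan oracle on the pig: no sampled position is wider
  pig <- generate_pig_cloud(pig_shape(), n = 1e5, noise_sd = 0, seed = 6)
  oc <- porcimetry:::orient_pig(pig$cloud)$cloud
  sl2 <- locate_abdominal_slice(oc)
  w_here <- body_width(sl2$slice)
  xs <- seq(quantile(oc$xyz[, 1], 0.3), quantile(oc$xyz[, 1], 0.7), by = 0.02)
  for (p in xs) {
    inslab <- abs(oc$xyz[, 1] - p) <= 0.01
    if (sum(inslab) < 5) next
    expect_lte(diff(range(oc$xyz[inslab, 2])), w_here + 0.005)
  }
  expect_equal(w_here, pig$truth$width, tolerance = 0.02 * pig$truth$width)
})

test_that("body_width is the lateral extent of the slice", {
  th <- seq(0, 2 * pi, length.out = 361)[-1]
  circ <- point_cloud(cbind(0, 0.3 * cos(th), 0.3 * sin(th)))
  expect_equal(body_width(circ), 0.6, tolerance = 1e-9)
  two <- point_cloud(rbind(c(0, -0.25, 0), c(0, 0.25, 0)))
  expect_equal(body_width(two), 0.5)
  expect_error(body_width(point_cloud(matrix(0, 0, 3))), "insufficient data")
})

test_that("polar transform follows the printed two-branch angle rule", {
  ps <- to_polar(point_cloud(rbind(c(0, 0, 1), c(0, 1, 1), c(0, -1, 1),
                                   c(0, 0, -1))),
                 pole = c(0, 0))
  expect_equal(ps$rho, c(1, sqrt(2), sqrt(2), 1))
  expect_equal(ps$theta, c(pi / 2, pi / 4, 7 * pi / 4, 3 * pi / 2))
  # equality with the printed branch formula wherever tan is defined
  set.seed(9)
  dy <- runif(500, -1, 1); dz <- runif(500, -1, 1)
  dz[abs(dz) < 1e-6] <- 0.5
  printed <- ifelse(dy >= 0, atan(-dy / dz) + pi / 2,
                    atan(-dy / dz) + 3 * pi / 2)
  expect_equal(porcimetry:::polar_theta(dy, dz), printed, tolerance = 1e-12)
  # uniform circle: angles cover [0, 2pi) with ~1 degree circular gaps
  ang <- (seq_len(360) - 0.5) * pi / 180
  circle <- to_polar(point_cloud(cbind(0, cos(ang), sin(ang))), pole = c(0, 0))
  sth <- sort(circle$theta)
  gaps <- diff(c(sth, sth[1] + 2 * pi))
  expect_equal(max(gaps), pi / 180, tolerance = 1e-9)
  expect_equal(min(gaps), pi / 180, tolerance = 1e-9)
  # pole-coincident point keeps rho 0, theta 0
  degen <- to_polar(point_cloud(rbind(c(0, 0.5, 0.5), c(0, 0.5, 0.5),
                                      c(0, 1, 1))), pole = c(0.5, 0.5))
  expect_equal(degen$rho[1], 0)
  expect_equal(degen$theta[1], 0)
})

test_that("closed-curve fit reproduces constants, bridges gaps, resists noise", {
  th <- runif(500, 0, 2 * pi)
  const <- structure(list(pole = c(0, 0), rho = rep(0.25, 500), theta = th),
                     class = "polar_slice")
  cv <- fit_closed_curve(const)
  tg <- seq(0, 2 * pi, length.out = 1001)
  expect_lt(max(abs(cv$f(tg) - 0.25)), 1e-6)
  expect_equal(cv$f(1e-9), cv$f(2 * pi - 1e-9), tolerance = 1e-9)  # closure
  # ellipse with a 30-degree occlusion gap
  a <- 0.30; b <- 0.22
  phi <- seq(0, 2 * pi, length.out = 2001)[-1]
  keep <- !(phi > pi / 3 & phi < pi / 2)
  gap <- to_polar(point_cloud(cbind(0, a * cos(phi[keep]),
                                    b * sin(phi[keep]))), pole = c(0, 0))
  cvg <- fit_closed_curve(gap)
  gp <- seq(pi / 3 + 0.01, pi / 2 - 0.01, length.out = 25)
  gr <- sqrt((a * cos(gp))^2 + (b * sin(gp))^2)
  gth <- porcimetry:::polar_theta(a * cos(gp), b * sin(gp))
  expect_lt(max(abs(cvg$f(gth) - gr) / gr), 0.02)
  # noisy circle, sigma 2 mm
  set.seed(15)
  thn <- runif(2000, 0, 2 * pi)
  noisy <- structure(list(pole = c(0, 0),
                          rho = 0.3 + rnorm(2000, 0, 0.002), theta = thn),
                     class = "polar_slice")
  cvn <- fit_closed_curve(noisy)
  expect_lt(max(abs(cvn$f(tg) - 0.3)), 0.01)
  # insufficient angular coverage
  half <- structure(list(pole = c(0, 0), rho = rep(1, 100),
                         theta = runif(100, 0, pi)), class = "polar_slice")
  expect_error(fit_closed_curve(half), "insufficient coverage")
  expect_error(fit_closed_curve(structure(list(pole = c(0, 0), rho = 1:4,
                                               theta = c(0, 1, 2, 3)),
                                          class = "polar_slice")),
               "at least 8")
})

test_that("the polar arc-length integral reduces to 2*pi*r and matches chords", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  const <- structure(list(pole = c(0, 0), rho = rep(0.3, 720), theta = th),
                     class = "polar_slice")
  cv <- fit_closed_curve(const)
  expect_equal(abdominal_circumference(cv), 2 * pi * 0.3,
               tolerance = 1e-6 * 2 * pi * 0.3)
  a <- 0.30; b <- 0.22
  phi <- seq(0, 2 * pi, length.out = 4001)[-1]
  ell <- to_polar(point_cloud(cbind(0, a * cos(phi), b * sin(phi))),
                  pole = c(0, 0))
  per <- abdominal_circumference(fit_closed_curve(ell))
  expect_equal(per, chord_ellipse_perimeter(a, b), tolerance = 0.001 * per)
})

test_that("measurements are invariant to in-plane pose and re-registration", {
  pig <- generate_pig_cloud(pig_shape(), n = 6e4, noise_sd = 0, seed = 10)
  base <- measure_pig(pig$cloud)
  # yaw + translation, no re-registration: the orienter must recover it
  yawed <- apply_transform(pig$cloud,
                           rigid_transform(rotation_from_angles(0, 0, 2.1),
                                           c(0.7, -1.1, 0)))
  m1 <- measure_pig(yawed)
  # full rigid transform, measured after re-registration with the true pose
  tr <- rigid_transform(rotation_from_angles(0.4, -0.8, 1.3), c(1, 2, 3))
  back <- apply_transform(apply_transform(pig$cloud, tr),
                          transform_inverse(tr))
  m2 <- measure_pig(back)
  for (f in c("length", "height", "width", "abdominal_circumference")) {
    expect_equal(m1[[f]], base[[f]], tolerance = 0.005 * base[[f]])
    expect_equal(m2[[f]], base[[f]], tolerance = 0.005 * base[[f]])
  }
})
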