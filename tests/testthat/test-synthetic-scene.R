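# Synthetic pig/scene/herd generators: ground-truth correctness and
# bit-level determinism.

test_that("shape ground truths match closed forms and chord oracles", {
  cyl <- cylinder_shape(radius = 0.3, body_length = 1.2)
  expect_equal(cyl$truth$abdominal_circumference, 2 * pi * 0.3,
               tolerance = 1e-6)
  expect_equal(cyl$truth$length, 1.2, tolerance = 1e-9)   # straight ridge
  expect_equal(cyl$truth$width, 0.6, tolerance = 1e-12)
  ell <- ellipse_shape(a = 0.30, b = 0.22)
  expect_equal(ell$truth$abdominal_circumference,
               chord_ellipse_perimeter(0.30, 0.22), tolerance = 1e-8)
  pig <- pig_shape()
  expect_equal(pig$truth$length, pig$body_length, tolerance = 1e-9)
  expect_equal(pig$truth$height, 0.70, tolerance = 1e-6)
  expect_equal(pig$truth$width, 2 * 0.19, tolerance = 1e-6)
  expect_error(pig_shape(body_length = -1), "invalid parameter")
  expect_error(cylinder_shape(radius = 0), "invalid parameter")
})

test_that("pig cloud sampling is seeded, bounded and validated", {
  sh <- pig_shape()
  a <- generate_pig_cloud(sh, n = 5000, noise_sd = 0.001, seed = 7)
  b <- generate_pig_cloud(sh, n = 5000, noise_sd = 0.001, seed = 7)
  expect_identical(a$cloud$xyz, b$cloud$xyz)
  expect_equal(n_points(a$cloud), 5000L)
  expect_error(generate_pig_cloud(sh, n = 10), "n >= 100")
  expect_error(generate_pig_cloud(sh, n = 500, noise_sd = -1), "noise_sd")
})

test_that("compose_scene partitions labels with exact counts", {
  pig <- generate_pig_cloud(pig_shape(), n = 2000, noise_sd = 0, seed = 1)
  empty <- scene_spec(n_floor = 0, n_railing = 0, n_noise = 0, seed = 2)
  expect_identical(compose_scene(pig$cloud, empty)$xyz, pig$cloud$xyz)
  spec <- scene_spec(n_floor = 1000, n_railing = 300, n_noise = 50,
                     noise_sd = 0.002, seed = 3)
  sc <- compose_scene(pig$cloud, spec)
  counts <- table(sc$labels)
  expect_equal(unname(counts[c("pig", "floor", "railing", "noise")]),
               c(2000L, 1000L, 300L, 50L), ignore_attr = TRUE)
  fz <- sc$xyz[sc$labels == "floor", "z"]
  expect_true(all(abs(fz) <= 4 * spec$noise_sd))
  expect_identical(sc$xyz, compose_scene(pig$cloud, spec)$xyz)  # seeded
})

test_that("render_views is the inverse-pose map and round-trips the scene", {
  pig <- generate_pig_cloud(pig_shape(), n = 1500, noise_sd = 0, seed = 4)
  ident <- rigid_transform()
  rig_id <- camera_rig(poses = list(top = ident, left = ident, right = ident))
  rv <- render_views(pig$cloud, rig_id, seed = 1)
  for (v in rv$views) expect_equal(v$xyz, pig$cloud$xyz, tolerance = 1e-12)
  shift <- rigid_transform(translation = c(1, 2, 3))
  rig_sh <- camera_rig(poses = list(top = shift, left = ident, right = ident))
  rv2 <- render_views(pig$cloud, rig_sh, seed = 1)
  expect_equal(rv2$views[[1]]$xyz,
               sweep(pig$cloud$xyz, 2, c(1, 2, 3)), ignore_attr = TRUE)
  # round trip through the true poses
  set.seed(5)
  poses <- list(top = rigid_transform(random_rotation(), rnorm(3)),
                left = rigid_transform(random_rotation(), rnorm(3)),
                right = rigid_transform(random_rotation(), rnorm(3)))
  rigr <- camera_rig(poses = poses)
  rv3 <- render_views(pig$cloud, rigr, seed = 2)
  merged <- merge_views(rv3$views, poses)
  expect_lt(max(abs(merged$xyz - rbind(pig$cloud$xyz, pig$cloud$xyz,
                                       pig$cloud$xyz))), 1e-9)
})

test_that("herd generator honours the weight model exactly at zero noise", {
  eff <- list(coefficients = c(abdominal = 0.5), smooth = NULL)
  h <- generate_herd_records(5, seed = 1, effect_spec = eff, noise_sd_kg = 0,
                             missing_height_frac = 0)
  expect_equal(h$weight, 0.5 * h$abdominal, tolerance = 1e-12)
  expect_identical(generate_herd_records(50, seed = 9),
                   generate_herd_records(50, seed = 9))
  expect_error(generate_herd_records(0), "n >= 1")
})

test_that("herd marginals match the generator moments at large n", {
  h <- generate_herd_records(10000, seed = 2, missing_height_frac = 0)
  h$age_days <- as.integer(as.Date(h$determination_date) -
                             as.Date(h$birth_date))
  mom <- herd_moments()
  cols <- c(chest = "chest", abdominal = "abdominal", waist = "waist",
            length = "length", height = "height", age_days = "age_days")
  for (i in seq_len(nrow(mom))) {
    f <- mom$feature[i]
    col <- if (f == "age_days") "age_days" else f
    x <- h[[col]]
    se_mean <- mom$sd[i] / sqrt(length(x))
    expect_lt(abs(mean(x) - mom$mean[i]), 3 * se_mean)
    se_sd <- mom$sd[i] / sqrt(2 * length(x))
    expect_lt(abs(sd(x) - mom$sd[i]), 3 * se_sd + 0.05)  # age rounding slack
  }
  # breed/gender shares near the herd composition
  expect_equal(mean(h$breed == "S21"), 8068 / 9980, tolerance = 0.02)
  expect_equal(mean(h$gender == "female"), 5438 / 9980, tolerance = 0.02)
})

test_that("herd CSV round trip preserves records", {
  h <- generate_herd_records(25, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_herd_csv(h, path)
  back <- read_herd_csv(path)
  expect_equal(back$weight, h$weight, tolerance = 1e-9)
  expect_equal(back$determination_date, h$determination_date)
  expect_equal(back$height, h$height, tolerance = 1e-9)
})
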