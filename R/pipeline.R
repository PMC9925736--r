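# End-to-end orchestration: scene -> registration -> filtering ->
# measurement, and herd -> feature table -> MLP training -> metrics.
# Configs are nested lists (YAML-friendly); one global seed determines
# every stochastic stage.

default_measurement_config <- function() {
  list(
    seed = 1L,
    shape = list(),                    # arguments to pig_shape()
    n_points = 1e5, noise_sd = 0,
    scene = list(enabled = TRUE),      # scene_spec() arguments
    registration = list(enabled = TRUE, distance_threshold = 0.005),
    filtering = list(
      enabled = TRUE,
      pass_through = list(y = c(-0.40, 0.40), z = c(-0.05, 1.2)),
      floor = list(distance_threshold = 0.01, n_iterations = 1000L,
                   min_inlier_fraction = 0.15),
      radius = list(radius = 0.03, min_neighbors = 5L)),
    measurement = list(bin = 0.02, slab = 0.02))
}

merge_config <- function(defaults, config) {
  if (is.null(config)) return(defaults)
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(defaults[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], config[[nm]])
    else defaults[[nm]] <- config[[nm]]
  }
  defaults
}

#' Run the full measurement pipeline on a synthetic scene
#'
#' Generates a pig cloud and pen scene, renders the three camera views,
#' recovers the registration from the cuboid captures, merges the views,
#' filters the scene (pass-through crop, RANSAC floor removal, radius
#' outlier removal) and measures the pig. Every stage is logged with its
#' parameters and point counts; the same config and seed give identical
#' results.
#'
#' @param config nested list overriding
#'   \code{porcimetry:::default_measurement_config()}; unknown entries are
#'   rejected by the stages they reach.
#' @return list with \code{result} (a \code{morphometry_result}),
#'   \code{truth} (generator ground truth), and \code{log} (per-stage
#'   audit entries).
#' @export
run_measurement_pipeline <- function(config = list()) {
  cfg <- merge_config(default_measurement_config(), config)
  seed <- as.integer(cfg$seed)
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }
  shape <- do.call(pig_shape, cfg$shape)
  pig <- generate_pig_cloud(shape, n = cfg$n_points, noise_sd = cfg$noise_sd,
                            seed = seed)
  note("generate_pig_cloud", n = n_points(pig$cloud),
       noise_sd = cfg$noise_sd, seed = seed)
  floor_plane <- list(normal = c(0, 0, 1), offset = 0)
  if (isTRUE(cfg$scene$enabled)) {
    sargs <- cfg$scene; sargs$enabled <- NULL
    sargs$seed <- seed + 1L
    spec <- do.call(scene_spec, sargs)
    cloud <- compose_scene(pig$cloud, spec)
    floor_plane <- list(normal = c(0, 0, 1), offset = spec$floor_elevation)
    note("compose_scene", n = n_points(cloud))
  } else cloud <- pig$cloud
  if (isTRUE(cfg$registration$enabled)) {
    rig <- camera_rig()
    rendered <- render_views(cloud, rig, seed = seed + 2L)
    transforms <- estimate_cube_registration(
      rendered$cube_views, rig$cube,
      distance_threshold = cfg$registration$distance_threshold,
      seed = seed + 3L)
    cloud <- merge_views(rendered$views, transforms)
    note("registration", n_views = length(rendered$views),
         n_merged = n_points(cloud))
  }
  if (isTRUE(cfg$filtering$enabled)) {
    n0 <- n_points(cloud)
    cloud <- pass_through(cloud, cfg$filtering$pass_through)
    note("pass_through", n_in = n0, n_out = n_points(cloud),
         bounds = cfg$filtering$pass_through)
    fl <- cfg$filtering$floor
    rf <- remove_floor(cloud, distance_threshold = fl$distance_threshold,
                       n_iterations = fl$n_iterations,
                       min_inlier_fraction = fl$min_inlier_fraction,
                       seed = seed + 4L)
    floor_plane <- rf$plane
    note("remove_floor", n_in = n_points(cloud), n_out = n_points(rf$cloud),
         plane = unname(c(rf$plane$normal, rf$plane$offset)))
    cloud <- rf$cloud
    rr <- cfg$filtering$radius
    n0 <- n_points(cloud)
    cloud <- radius_outlier_removal(cloud, radius = rr$radius,
                                    min_neighbors = rr$min_neighbors)
    note("radius_outlier_removal", n_in = n0, n_out = n_points(cloud),
         radius = rr$radius, min_neighbors = rr$min_neighbors)
  }
  result <- measure_pig(cloud, floor_plane, bin = cfg$measurement$bin,
                        slab = cfg$measurement$slab)
  note("measure_pig", result = unclass(result))
  list(result = result, truth = pig$truth, log = log)
}

default_weight_config <- function() {
  list(seed = 1L,
       herd = list(n = 2000L, noise_sd_kg = 2, missing_height_frac = 0.05),
       records_csv = NULL,
       normalize = TRUE,
       models = 1:4,
       training = list(epochs = 300L, learning_rate = 0.01,
                       batch_size = 10L))
}

#' Run the tabular weight-prediction pipeline
#'
#' Loads (or generates) herd records, cleans them, optionally applies the
#' row normalization, then trains and evaluates the requested MLP model
#' variants, returning a metrics table with one row per model.
#'
#' @param config nested list overriding
#'   \code{porcimetry:::default_weight_config()}; set \code{records_csv} to
#'   read records from a CSV instead of generating a synthetic herd.
#' @return list with \code{metrics} (data.frame: model, mse, rmse, mae,
#'   mape, n), \code{fits} (per-model fit objects) and \code{log}.
#' @export
run_weight_pipeline <- function(config = list()) {
  cfg <- merge_config(default_weight_config(), config)
  seed <- as.integer(cfg$seed)
  log <- list()
  records <- if (!is.null(cfg$records_csv)) {
    log[[1]] <- list(stage = "read_records", path = cfg$records_csv)
    read_herd_csv(cfg$records_csv)
  } else {
    log[[1]] <- list(stage = "generate_herd", n = cfg$herd$n, seed = seed)
    generate_herd_records(cfg$herd$n, seed = seed,
                          noise_sd_kg = cfg$herd$noise_sd_kg,
                          missing_height_frac = cfg$herd$missing_height_frac)
  }
  tab <- clean_records(records)
  if (isTRUE(cfg$normalize)) tab <- normalize_rows(tab)
  log[[length(log) + 1L]] <- list(stage = "feature_table", n = nrow(tab),
                                  normalized = isTRUE(cfg$normalize))
  fits <- lapply(cfg$models, function(id)
    fit_weight_model(tab, model_id = id, seed = seed,
                     epochs = cfg$training$epochs,
                     learning_rate = cfg$training$learning_rate,
                     batch_size = cfg$training$batch_size))
  metrics <- do.call(rbind, lapply(seq_along(cfg$models), function(i) {
    r <- fits[[i]]$report
    data.frame(model = cfg$models[i], mse = r$mse, rmse = r$rmse,
               mae = r$mae, mape = r$mape, n = r$n)
  }))
  log[[length(log) + 1L]] <- list(stage = "train_models",
                                  models = cfg$models,
                                  epochs = cfg$training$epochs)
  list(metrics = metrics, fits = fits, log = log)
}
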