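# Dataset splitting, MLP construction/training/prediction and the
# evaluation metrics.

test_that("split_dataset partitions 70/15/15 deterministically", {
  tab <- data.frame(x = 1:100, weight = rnorm(100))
  sp <- split_dataset(tab, seed = 4)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$test), 15L)
  expect_equal(nrow(sp$validation), 15L)
  all_idx <- sort(unname(unlist(sp$indices)))
  expect_identical(all_idx, 1:100)             # partition: disjoint + full
  sp2 <- split_dataset(tab, seed = 4)
  expect_identical(sp$indices, sp2$indices)
  expect_false(identical(sp$indices, split_dataset(tab, seed = 5)$indices))
  expect_error(split_dataset(tab[0, ]), "empty table")
  expect_error(split_dataset(tab[1:5, ]), "at least 10")
})

test_that("model construction matches the 5D + 54 parameter count", {
  for (D in c(2L, 4L, 5L, 10L)) {
    m <- build_model(mlp_config(D, seed = 1))
    expect_equal(n_parameters(m), 5L * D + 54L)
    expect_equal(m$dims, c(D, 5L, 4L, 4L, 1L))
  }
  m1 <- build_model(mlp_config(10, seed = 3))
  m2 <- build_model(mlp_config(10, seed = 3))
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  expect_error(mlp_config(0), "non-positive")
})

test_that("prediction agrees with a hand-rolled forward pass", {
  zero <- build_model(mlp_config(3, seed = 1))
  zero$W <- lapply(zero$W, function(w) w * 0)
  zero$b <- lapply(zero$b, function(b) b * 0)
  expect_equal(predict(zero, matrix(rnorm(9), 3, 3)), c(0, 0, 0))
  set.seed(6)
  m <- build_model(mlp_config(4, seed = 2))
  X <- matrix(rnorm(40), 10, 4)
  oracle <- apply(X, 1, function(x) {
    a <- x
    for (l in 1:4) {
      z <- drop(a %*% m$W[[l]]) + m$b[[l]]
      a <- if (l < 4) pmax(z, 0) else z
    }
    a
  })
  expect_equal(predict(m, X), oracle, tolerance = 1e-6)
  expect_error(predict(m, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("training fits noiseless linear data and is seed-stable", {
  set.seed(2)
  x <- matrix(runif(200, 0, 10), ncol = 1)
  y <- 3 * x[, 1]
  cfg <- mlp_config(1, epochs = 300, seed = 5)
  m <- train_mlp(build_model(cfg), x, y, config = cfg)
  expect_length(m$train_loss, 300L)
  expect_lt(m$train_loss[300], 0.01 * m$train_loss[1])
  m2 <- train_mlp(build_model(cfg), x, y, config = cfg)
  expect_identical(m$W, m2$W)                   # bit-stable per seed
  expect_identical(m$train_loss, m2$train_loss)
  # zero epochs leaves the initialization untouched
  cfg0 <- mlp_config(1, epochs = 0, seed = 5)
  m0 <- build_model(cfg0)
  expect_identical(train_mlp(m0, x, y, config = cfg0)$W, m0$W)
})

test_that("losses reduce and stabilize on a noisy herd", {
  herd <- generate_herd_records(3000, seed = 1, noise_sd_kg = 2)
  fit <- fit_weight_model(clean_records(herd), model_id = 1, seed = 1)
  v <- fit$model$validation_loss
  expect_length(v, 300L)
  sm <- as.numeric(stats::filter(v, rep(1 / 10, 10), sides = 1))
  # plateau: late smoothed loss no higher than mid-training, and the final
  # value close to the best of the last 100 epochs
  expect_lte(mean(sm[251:300]), mean(sm[101:150]))
  expect_lte(sm[300], 1.25 * min(sm[201:300]))
})

test_that("evaluation metrics satisfy their identities and worked example", {
  r0 <- evaluate_predictions(c(100), c(110))
  expect_equal(unclass(r0)[c("mse", "rmse", "mae", "mape")],
               list(mse = 100, rmse = 10, mae = 10, mape = 0.1))
  rp <- evaluate_predictions(c(50, 60), c(50, 60))
  expect_equal(c(rp$mse, rp$rmse, rp$mae, rp$mape), rep(0, 4))
  set.seed(19)
  for (i in 1:20) {
    a <- runif(1000, 50, 150); p <- a + rnorm(1000, 0, 5)
    r <- evaluate_predictions(a, p)
    # element-wise loop oracle
    mse <- 0; mae <- 0; mape <- 0
    for (j in seq_along(a)) {
      e <- a[j] - p[j]
      mse <- mse + e^2 / 1000; mae <- mae + abs(e) / 1000
      mape <- mape + abs(e / a[j]) / 1000
    }
    expect_equal(r$mse, mse, tolerance = 1e-12)
    expect_equal(r$mae, mae, tolerance = 1e-12)
    expect_equal(r$mape, mape, tolerance = 1e-12)
    expect_equal(r$rmse^2, r$mse, tolerance = 1e-12)
    expect_lte(r$mae, r$rmse)
    # permutation invariance
    o <- sample.int(1000)
    expect_equal(unclass(evaluate_predictions(a[o], p[o])), unclass(r))
  }
  expect_error(evaluate_predictions(c(0, 1), c(1, 1)), "MAPE undefined")
  expect_error(evaluate_predictions(1:3, 1:2), "equal length")
})

test_that("end-to-end fits are reproducible and reach the noise floor", {
  herd <- generate_herd_records(4000, seed = 2, noise_sd_kg = 2)
  tab <- clean_records(herd)
  f1 <- fit_weight_model(tab, model_id = 1, seed = 3)
  f2 <- fit_weight_model(tab, model_id = 1, seed = 3)
  expect_identical(f1$report, f2$report)
  expect_gt(f1$report$rmse, 0.9 * 2)
  expect_lt(f1$report$rmse, 1.5 * 2)
  # model 3 trains on its two features only
  f3 <- fit_weight_model(tab, model_id = 3, seed = 3)
  expect_equal(f3$model$dims[1], 2L)
  expect_true(is.finite(f3$report$rmse))
})
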