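# Feed-forward weight predictor: fully connected layers of sizes
# [D, 5, 4, 4, 1] with rectifier activations on the hidden layers and a
# linear output, trained by mini-batch gradient descent with the
# adaptive-moment (Adam) update rule on a mean-squared-error loss.

#' MLP training configuration
#'
#' Defaults follow the study protocol: hidden layers of 5, 4 and 4
#' rectifier units, learning rate 0.01, 300 epochs, batch size 10,
#' mean-squared-error loss under the Adam optimizer (beta1 = 0.9,
#' beta2 = 0.999, eps = 1e-8).
#'
#' @param input_dim number of input features.
#' @param hidden_sizes hidden layer widths.
#' @param learning_rate,epochs,batch_size training protocol.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @export
mlp_config <- function(input_dim, hidden_sizes = c(5L, 4L, 4L),
                       learning_rate = 0.01, epochs = 300L,
                       batch_size = 10L, seed = 1L) {
  if (input_dim < 1L || any(hidden_sizes < 1L))
    stop("invalid parameter: non-positive layer dimension")
  if (learning_rate <= 0 || epochs < 0L || batch_size < 1L)
    stop("invalid parameter: learning_rate, epochs, batch_size must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Build an (untrained) MLP weight model
#'
#' Weights and biases are drawn from a seeded uniform fan-in scheme
#' (U(-1/sqrt(fan_in), 1/sqrt(fan_in))); the same seed reproduces
#' identical initial parameters. When a sample of training inputs is
#' supplied via \code{x_center}, each layer's biases are additionally
#' re-centred so the mean pre-activation over that sample equals the drawn
#' bias: with raw, all-positive girth/age inputs on the 100-200 scale an
#' uncentred rectifier unit is either active or inactive for every record
#' at once, and inactive units receive no gradient and never recover. The
#' centring is deterministic given the seed and sample and changes no
#' parameter counts.
#'
#' @param config an \code{mlp_config}.
#' @param x_center optional numeric matrix of training inputs used to
#'   centre the initial pre-activations.
#' @return object of class \code{weight_model} with per-layer weights
#'   \code{W} (fan_in x fan_out) and biases \code{b}.
#' @export
build_model <- function(config, x_center = NULL) {
  stopifnot(inherits(config, "mlp_config"))
  dims <- c(config$input_dim, config$hidden_sizes, 1L)
  with_seed(config$seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      bound <- 1 / sqrt(dims[l])
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -bound, bound),
                       dims[l], dims[l + 1L])
      b[[l]] <- stats::runif(dims[l + 1L], -bound, bound)
    }
    model <- structure(list(W = W, b = b, dims = dims, config = config,
                            train_loss = numeric(0),
                            validation_loss = numeric(0)),
                       class = "weight_model")
    if (!is.null(x_center)) {
      A <- as.matrix(x_center)
      if (ncol(A) != dims[1L])
        stop("invalid parameter: x_center dimension mismatch")
      for (l in seq_along(model$W)) {
        b0 <- model$b[[l]]
        Z <- sweep(A %*% model$W[[l]], 2L, b0, `+`)
        shift <- colMeans(Z) - b0        # mean of A %*% W per unit
        model$b[[l]] <- b0 - shift
        Z <- sweep(Z, 2L, shift, `-`)
        A <- if (l < length(model$W)) pmax(Z, 0) else Z
      }
    }
    model
  })
}

#' Number of trainable parameters
#'
#' For the printed architecture this is 5 D + 54 for input dimension D.
#' @param model a \code{weight_model}.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$W, length, 0L)) + sum(vapply(model$b, length, 0L))
}

mlp_forward <- function(model, X) {
  A <- X
  L <- length(model$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% model$W[[l]]
    Z <- sweep(Z, 2L, model$b[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1L]] <- A
  }
  list(output = A, acts = acts)
}

#' Predict weights with a trained model
#'
#' @param object a \code{weight_model}.
#' @param features numeric matrix (rows = pigs, columns in the model's
#'   feature order) or data.frame.
#' @param ... unused.
#' @return numeric vector of predicted weights, kg.
#' @export
predict.weight_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != object$dims[1L])
    stop("invalid parameter: feature dimension mismatch (expected ",
         object$dims[1L], ")")
  out <- as.vector(mlp_forward(object, X)$output)
  if (any(!is.finite(out))) stop("non-finite prediction")
  out
}

#' Train an MLP weight model
#'
#' Mini-batch gradient descent with the Adam update at the configured
#' learning rate; batches are reshuffled every epoch under the configured
#' seed,
#' and per-epoch training and validation MSE (full-set forward passes) are
#' recorded. Deterministic for a fixed seed.
#'
#' @param model an untrained \code{weight_model} from
#'   \code{\link{build_model}}.
#' @param x_train,y_train training features (matrix) and weights (kg).
#' @param x_val,y_val optional validation set.
#' @param config \code{mlp_config}; defaults to the model's own.
#' @return the trained \code{weight_model} with \code{train_loss} and
#'   \code{validation_loss} histories (length = epochs).
#' @export
train_mlp <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      config = model$config) {
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  if (n == 0L || length(y_train) != n)
    stop("invalid parameter: empty training set or length mismatch")
  if (ncol(x_train) != model$dims[1L])
    stop("invalid parameter: feature dimension mismatch")
  if (!is.null(x_val)) x_val <- as.matrix(x_val)
  if (config$epochs == 0L) {
    model$train_loss <- numeric(0)
    model$validation_loss <- numeric(0)
    return(model)
  }
  perms <- with_seed(config$seed + 1L,
                     vapply(seq_len(config$epochs),
                            function(e) sample.int(n), integer(n)))
  perms <- matrix(perms, nrow = n)
  out <- .mlp_train_cpp(model$W, model$b, x_train, y_train,
                        x_val, if (is.null(x_val)) NULL else y_val,
                        perms, config$batch_size, config$learning_rate)
  model$W <- out$W
  model$b <- out$b
  model$train_loss <- out$train_loss
  model$validation_loss <- out$val_loss
  model
}

#' Split a feature table into train / test / validation sets
#'
#' Shuffled partition at the given fractions (test and validation sizes are
#' floored, remainder rows go to training); deterministic per seed.
#'
#' @param table a \code{feature_table} (or data.frame).
#' @param fractions train/test/validation fractions summing to 1.
#' @param seed integer seed.
#' @return list with \code{train}, \code{test}, \code{validation} subsets
#'   and the index partition in \code{indices}.
#' @export
split_dataset <- function(table, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  n <- nrow(table)
  if (is.null(n) || n == 0L) stop("invalid parameter: empty table")
  if (n < 10L) stop("invalid parameter: need at least 10 rows to split")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("invalid parameter: fractions must sum to 1")
  with_seed(seed, {
    perm <- sample.int(n)
    n_test <- floor(fractions[2] * n)
    n_val <- floor(fractions[3] * n)
    test_idx <- sort(perm[seq_len(n_test)])
    val_idx <- sort(perm[n_test + seq_len(n_val)])
    train_idx <- sort(perm[-seq_len(n_test + n_val)])
    list(train = table[train_idx, , drop = FALSE],
         test = table[test_idx, , drop = FALSE],
         validation = table[val_idx, , drop = FALSE],
         indices = list(train = train_idx, test = test_idx,
                        validation = val_idx))
  })
}

#' Regression evaluation metrics
#'
#' MSE, RMSE (its square root), MAE and MAPE (reported as a fraction) of
#' predicted versus actual weights.
#'
#' @param actual,predicted numeric vectors of equal length >= 1, kg.
#' @return object of class \code{evaluation_report}: list with \code{mse},
#'   \code{rmse}, \code{mae}, \code{mape}, \code{n}.
#' @export
evaluate_predictions <- function(actual, predicted) {
  if (length(actual) != length(predicted) || !length(actual))
    stop("invalid parameter: actual and predicted must have equal length >= 1")
  if (any(actual == 0)) stop("MAPE undefined: zero actual value")
  err <- actual - predicted
  mse <- mean(err^2)
  structure(list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
                 mape = mean(abs(err / actual)), n = length(actual)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (n = %d)\n  MSE  %.4f\n  RMSE %.4f\n  MAE  %.4f\n  MAPE %.4f\n",
              x$n, x$mse, x$rmse, x$mae, x$mape))
  invisible(x)
}

#' Fit and evaluate one weight-model variant on a feature table
#'
#' Convenience wrapper: selects the model's feature columns, splits the
#' table 70/15/15, trains the MLP and evaluates it on the held-out test
#' set.
#'
#' A rectifier network trained on raw-scale girth/age inputs occasionally
#' collapses early: violent first Adam steps can drive every unit of a
#' hidden layer inactive for all records, after which no gradient flows
#' and the fit degenerates to a constant predictor. When the trained
#' model's predictions on its own training set are (near-)constant, the
#' fit is restarted with a re-seeded initialization (training protocol
#' unchanged; at most \code{max_restarts} attempts, fully deterministic).
#'
#' @param table a \code{feature_table} (raw or normalized).
#' @param model_id model variant 1..4 (see \code{\link{feature_set}}).
#' @param seed integer seed (split, initialization, shuffling).
#' @param epochs,learning_rate,batch_size protocol overrides.
#' @param max_restarts re-initialization attempts after a degenerate
#'   (constant-output) fit.
#' @return list with the trained \code{model}, the \code{report}
#'   (\code{evaluation_report} on the test set), the \code{split} and the
#'   number of \code{restarts} used.
#' @export
fit_weight_model <- function(table, model_id = 1L, seed = 1L, epochs = 300L,
                             learning_rate = 0.01, batch_size = 10L,
                             max_restarts = 4L) {
  feats <- feature_set(model_id)
  sp <- split_dataset(table, seed = seed)
  x_train <- as.matrix(sp$train[feats])
  restarts <- 0L
  repeat {
    cfg <- mlp_config(length(feats), learning_rate = learning_rate,
                      epochs = epochs, batch_size = batch_size,
                      seed = seed + 7919L * restarts)
    model <- build_model(cfg, x_center = x_train)
    model <- train_mlp(model, x_train, sp$train$weight,
                       as.matrix(sp$validation[feats]),
                       sp$validation$weight, cfg)
    pred_train <- predict(model, x_train)
    degenerate <- stats::sd(pred_train) < 0.01 * stats::sd(sp$train$weight)
    if (!degenerate || restarts >= max_restarts) break
    restarts <- restarts + 1L
  }
  preds <- predict(model, as.matrix(sp$test[feats]))
  list(model = model, report = evaluate_predictions(sp$test$weight, preds),
       split = sp, restarts = restarts)
}
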