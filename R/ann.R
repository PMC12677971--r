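#' Network architecture specification
#'
#' A single-hidden-layer feed-forward regressor: four environmental
#' inputs (SST, CHL-a, SSS, current), a sigmoid hidden layer (10 neurons
#' by default, the width found adequate by trial and error for this
#' problem) and one linear output neuron for continuous CPUE prediction.
#'
#' @param n_inputs Number of input features (default 4).
#' @param n_hidden Hidden-layer width (>= 1, default 10).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_inputs = 4, n_hidden = 10) {
  if (n_hidden < 1) stop("n_hidden must be >= 1", call. = FALSE)
  if (n_inputs < 1) stop("n_inputs must be >= 1", call. = FALSE)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 hidden_activation = "sigmoid",
                 output_activation = "linear"),
            class = "network_spec")
}

#' Training configuration
#'
#' Full-batch training on the mean squared error of the min-max scaled
#' data, with early stopping on held-out MSE.  Two optimizers are
#' available:
#' \describe{
#'   \item{`"rprop"` (default)}{resilient backpropagation (iRprop-), the
#'     classic full-batch variant of backpropagation: per-parameter step
#'     sizes grown by 1.2 while the gradient sign is stable and halved on
#'     a sign flip.  Converges far faster than a single global rate on
#'     sigmoid networks.}
#'   \item{`"gd"`}{plain full-batch gradient descent with backtracking
#'     step control (a step that would raise the training loss is retried
#'     at half the rate, so accepted steps are non-increasing).}
#' }
#'
#' @param learning_rate Initial step size (> 0, default 0.01; for rprop
#'   this is the initial per-parameter step).
#' @param max_epochs Maximum accepted steps (default 5000).
#' @param patience Accepted epochs without held-out improvement before
#'   stopping (default 100).
#' @param split_fraction Training share of the 70/30 random split
#'   (default 0.7).
#' @param seed Integer seed governing the split and weight init.
#' @param optimizer `"rprop"` or `"gd"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, max_epochs = 5000,
                         patience = 100, split_fraction = 0.7, seed = 1,
                         optimizer = c("rprop", "gd")) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 split_fraction = split_fraction,
                 seed = as.integer(seed),
                 optimizer = match.arg(optimizer)),
            class = "train_config")
}

#' Random 70/30 train/test partition
#'
#' Seeded random sampling into disjoint, exhaustive train and test sets
#' with `round(split_fraction * n)` training rows.
#'
#' @param table A data.frame of feature/target rows (>= 10 rows).
#' @param config A [train_config()].
#' @return A list with data.frames `train` and `test`.
#' @export
split_train_test <- function(table, config = train_config()) {
  n <- nrow(table)
  if (is.null(n) || n < 10)
    stop("need at least 10 rows to split", call. = FALSE)
  n_train <- round(config$split_fraction * n)
  idx <- with_local_seed(derive_seed(config$seed, "split"),
                         sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Min-max scaling helpers; a constant column maps to 0 (denominator 1).
fit_scaling <- function(X, y) {
  x_min <- apply(X, 2, min); x_max <- apply(X, 2, max)
  list(x_min = x_min, x_max = x_max, y_min = min(y), y_max = max(y))
}
scale_features <- function(X, sc) {
  den <- ifelse(sc$x_max > sc$x_min, sc$x_max - sc$x_min, 1)
  sweep(sweep(X, 2, sc$x_min), 2, den, "/")
}
scale_target <- function(y, sc) {
  den <- if (sc$y_max > sc$y_min) sc$y_max - sc$y_min else 1
  (y - sc$y_min) / den
}
unscale_target <- function(ys, sc) {
  den <- if (sc$y_max > sc$y_min) sc$y_max - sc$y_min else 1
  ys * den + sc$y_min
}

# Seeded Xavier-uniform initialization.
init_network <- function(spec, seed) {
  with_local_seed(derive_seed(seed, "init"), {
    lim1 <- sqrt(6 / (spec$n_inputs + spec$n_hidden))
    lim2 <- sqrt(6 / (spec$n_hidden + 1))
    list(W1 = matrix(stats::runif(spec$n_hidden * spec$n_inputs,
                                  -lim1, lim1),
                     spec$n_hidden, spec$n_inputs),
         b1 = rep(0, spec$n_hidden),
         w2 = stats::runif(spec$n_hidden, -lim2, lim2),
         b2 = 0)
  })
}

new_ann_model <- function(par, spec, scaling, feature_names, seed) {
  dimnames(par$W1) <- NULL
  par$b1 <- unname(par$b1); par$w2 <- unname(par$w2)
  par$b2 <- unname(par$b2)
  structure(list(W1 = par$W1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
                 spec = spec, scaling = scaling,
                 feature_names = feature_names, seed = seed),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("Feed-forward network: %d inputs -> %d sigmoid -> 1 linear\n",
              x$spec$n_inputs, x$spec$n_hidden))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  target scale: [%.3f, %.3f]\n",
              x$scaling$y_min, x$scaling$y_max))
  invisible(x)
}

# Forward pass in scaled space; returns scaled predictions (and hidden
# activations when requested, for backprop).
forward_scaled <- function(par, Xs, hidden = FALSE) {
  Z <- sigmoid(sweep(Xs %*% t(par$W1), 2, par$b1, "+"))
  yhat <- as.vector(Z %*% par$w2) + par$b2
  if (hidden) list(yhat = yhat, Z = Z) else yhat
}

#' Forward pass of a fitted network
#'
#' Scales the raw features to `[0, 1]` with the scaling stored in the
#' model, applies the sigmoid hidden layer and linear output, and (by
#' default) inverse-scales the prediction back to kg/trip.
#'
#' @param model An `ann_model`.
#' @param features A numeric matrix/data.frame with the model's features
#'   in columns (a single 4-vector is also accepted).
#' @param raw_scale Return predictions in original target units
#'   (default) or in scaled `[0, 1]` space.
#' @return Numeric vector of predicted CPUE.
#' @export
ann_forward <- function(model, features, raw_scale = TRUE) {
  stopifnot(inherits(model, "ann_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  X <- as.matrix(features)
  if (ncol(X) != model$spec$n_inputs)
    stop("feature dimension ", ncol(X), " does not match the network's ",
         model$spec$n_inputs, " inputs", call. = FALSE)
  if (!is.null(colnames(X)) && all(model$feature_names %in% colnames(X)))
    X <- X[, model$feature_names, drop = FALSE]
  ys <- forward_scaled(model, scale_features(X, model$scaling))
  if (raw_scale) unscale_target(ys, model$scaling) else ys
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  ann_forward(object, newdata, raw_scale = TRUE)
}

#' Exact backpropagation gradients of the batch MSE
#'
#' Gradients of `mean((y_scaled - yhat_scaled)^2)` with respect to every
#' weight and bias, by the chain rule through the sigmoid hidden layer.
#'
#' @param par Parameter list (`W1`, `b1`, `w2`, `b2`) or an `ann_model`.
#' @param Xs Scaled feature matrix (rows = observations).
#' @param ys Scaled target vector.
#' @return A list of gradients with the shapes of `W1`, `b1`, `w2`, `b2`.
#' @export
backprop_gradients <- function(par, Xs, ys) {
  Xs <- as.matrix(Xs)
  if (nrow(Xs) == 0) stop("empty batch", call. = FALSE)
  if (nrow(Xs) != length(ys))
    stop("feature/target lengths differ", call. = FALSE)
  f <- forward_scaled(par, Xs, hidden = TRUE)
  n <- nrow(Xs)
  d_out <- 2 * (f$yhat - ys) / n            # dL/dyhat
  d_hidden <- (d_out %o% par$w2) * f$Z * (1 - f$Z)
  list(W1 = t(d_hidden) %*% Xs,
       b1 = colSums(d_hidden),
       w2 = as.vector(t(f$Z) %*% d_out),
       b2 = sum(d_out))
}

batch_mse <- function(par, Xs, ys) mean((forward_scaled(par, Xs) - ys)^2)

#' Train the CPUE regression network
#'
#' Splits the table 70/30 at random (seeded), min-max scales features and
#' target on the training rows, initializes weights (seeded
#' Xavier-uniform) and runs full-batch training with the configured
#' optimizer (see [train_config()]) and early stopping on the held-out
#' MSE.  The model with the best held-out MSE seen is returned.
#'
#' @param table Data.frame with the four feature columns and a target
#'   column.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param features,target Column names (defaults: the four environmental
#'   predictors and `"cpue"`).
#' @return A list: `model` (`ann_model`), `train` and `test`
#'   ([evaluate_predictions()] reports on the raw scale), and `history`
#'   (accepted-epoch train/test MSE trace, scaled space).
#' @examples
#' \donttest{
#' cfg <- generator_config(seed = 7, months = 24)
#' flds <- generate_env_fields(cfg)
#' tab <- build_training_table(generate_catch_records(flds, cfg), flds)
#' fit <- train_ann(tab, config = train_config(max_epochs = 200, seed = 7))
#' fit$test$rmse
#' }
#' @export
train_ann <- function(table, spec = network_spec(),
                      config = train_config(),
                      features = env_parameters(), target = "cpue") {
  stopifnot(is.data.frame(table))
  miss <- setdiff(c(features, target), names(table))
  if (length(miss))
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(features) != spec$n_inputs)
    stop("spec expects ", spec$n_inputs, " inputs but ", length(features),
         " features given", call. = FALSE)

  parts <- split_train_test(table, config)
  Xtr <- as.matrix(parts$train[, features, drop = FALSE])
  Xte <- as.matrix(parts$test[, features, drop = FALSE])
  ytr <- parts$train[[target]]
  yte <- parts$test[[target]]

  sc <- fit_scaling(Xtr, ytr)
  Xtr_s <- scale_features(Xtr, sc); ytr_s <- scale_target(ytr, sc)
  Xte_s <- scale_features(Xte, sc); yte_s <- scale_target(yte, sc)

  par <- init_network(spec, config$seed)
  lr <- config$learning_rate
  delta <- lapply(par, function(p) p * 0 + config$learning_rate)
  g_prev <- lapply(par, function(p) p * 0)
  loss <- batch_mse(par, Xtr_s, ytr_s)
  test_loss <- batch_mse(par, Xte_s, yte_s)
  best <- list(par = par, test = test_loss)
  stall <- 0L
  hist_tr <- loss; hist_te <- test_loss

  for (epoch in seq_len(config$max_epochs)) {
    g <- backprop_gradients(par, Xtr_s, ytr_s)
    if (config$optimizer == "gd") {
      repeat {
        cand <- list(W1 = par$W1 - lr * g$W1, b1 = par$b1 - lr * g$b1,
                     w2 = par$w2 - lr * g$w2, b2 = par$b2 - lr * g$b2)
        cand_loss <- batch_mse(cand, Xtr_s, ytr_s)
        if (is.na(cand_loss))
          stop("training diverged (non-finite loss); try a smaller ",
               "learning_rate", call. = FALSE)
        if (cand_loss <= loss) break
        lr <- lr / 2
        if (lr < 1e-12) break
      }
      if (lr < 1e-12) break                  # no descent step available
      par <- cand; loss <- cand_loss
      lr <- min(lr * 1.05, 1)                # regrow after backtracking
    } else {
      # iRprop-: adapt per-parameter steps on gradient sign stability
      for (nm in names(par)) {
        s <- g[[nm]] * g_prev[[nm]]
        delta[[nm]] <- pmin(pmax(
          ifelse(s > 0, delta[[nm]] * 1.2,
                 ifelse(s < 0, delta[[nm]] * 0.5, delta[[nm]])),
          1e-12), 1)
        g[[nm]][s < 0] <- 0
        par[[nm]] <- par[[nm]] - sign(g[[nm]]) * delta[[nm]]
        g_prev[[nm]] <- g[[nm]]
      }
      loss <- batch_mse(par, Xtr_s, ytr_s)
      if (is.na(loss))
        stop("training diverged (non-finite loss); try a smaller ",
             "learning_rate", call. = FALSE)
    }
    test_loss <- batch_mse(par, Xte_s, yte_s)
    hist_tr <- c(hist_tr, loss); hist_te <- c(hist_te, test_loss)
    if (test_loss < best$test - 1e-15) {
      best <- list(par = par, test = test_loss)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  model <- new_ann_model(best$par, spec, sc, features, config$seed)
  list(model = model,
       train = evaluate_predictions(ytr, ann_forward(model, Xtr),
                                    split = "train"),
       test = evaluate_predictions(yte, ann_forward(model, Xte),
                                   split = "test"),
       history = data.frame(train_mse = hist_tr, test_mse = hist_te))
}

#' Regression error report
#'
#' MSE, RMSE (= sqrt(MSE)), mean absolute percentage error over nonzero
#' actuals, and range-normalized RMSE.
#'
#' @param y_actual,y_predicted Equal-length numeric vectors.
#' @param split Optional label (`"train"`/`"test"`).
#' @return A list of class `eval_report`: `mse`, `rmse`,
#'   `error_rate_percent` (MAPE), `nrmse_percent`, `n`, `split`.
#' @examples
#' evaluate_predictions(c(0, 0), c(1, 1))$rmse  # 1
#' @export
evaluate_predictions <- function(y_actual, y_predicted, split = NA_character_) {
  if (length(y_actual) != length(y_predicted))
    stop("actual and predicted lengths differ", call. = FALSE)
  if (length(y_actual) < 1) stop("empty evaluation set", call. = FALSE)
  err <- y_actual - y_predicted
  mse <- mean(err^2)
  nz <- y_actual != 0
  mape <- if (any(nz)) mean(abs(err[nz]) / abs(y_actual[nz])) * 100 else NA_real_
  rng <- diff(range(y_actual))
  structure(list(mse = mse, rmse = sqrt(mse),
                 error_rate_percent = mape,
                 nrmse_percent = if (rng > 0) sqrt(mse) / rng * 100
                                 else NA_real_,
                 n = length(y_actual), split = split),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s evaluation (n = %d): MSE %.4f, RMSE %.4f, MAPE %.2f%%\n",
              ifelse(is.na(x$split), "model", x$split), x$n, x$mse, x$rmse,
              x$error_rate_percent))
  invisible(x)
}

#' Serialize / restore a fitted network
#'
#' Writes weights, biases, scaling, architecture and seed as JSON so a
#' fitted model can be reused by the mapping stage or another session.
#'
#' @param model An `ann_model`.
#' @param path File path (`.json`).
#' @return `write_ann_model`: the path, invisibly; `read_ann_model`: the
#'   restored `ann_model`.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
              spec = unclass(model$spec),
              scaling = model$scaling,
              feature_names = model$feature_names, seed = model$seed)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(o$spec$n_inputs, o$spec$n_hidden)
  sc <- lapply(o$scaling, as.numeric)
  names(sc$x_min) <- names(sc$x_max) <- o$feature_names
  W1 <- o$W1
  if (!is.matrix(W1)) W1 <- do.call(rbind, lapply(W1, as.numeric))
  storage.mode(W1) <- "double"
  stopifnot(nrow(W1) == spec$n_hidden, ncol(W1) == spec$n_inputs)
  new_ann_model(list(W1 = W1,
                     b1 = as.numeric(o$b1), w2 = as.numeric(o$w2),
                     b2 = as.numeric(o$b2)),
                spec, sc, o$feature_names, as.integer(o$seed))
}
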