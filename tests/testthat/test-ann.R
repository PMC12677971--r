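test_that("train/test split is a seeded exact partition", {
  tab <- data.frame(x = 1:100, cpue = rnorm(100))
  cfg <- train_config(seed = 5)
  p1 <- split_train_test(tab, cfg)
  p2 <- split_train_test(tab, cfg)
  expect_identical(p1, p2)
  expect_identical(nrow(p1$train), 70L)
  expect_identical(nrow(p1$test), 30L)
  expect_identical(sort(c(p1$train$x, p1$test$x)), 1:100)
  expect_length(intersect(p1$train$x, p1$test$x), 0)
  # different seed, different partition
  expect_false(identical(split_train_test(tab, train_config(seed = 6)),
                         p1))
  expect_error(split_train_test(tab[1:5, ], cfg), "10")
})

test_that("forward pass matches a pocket-calculator computation", {
  m <- tiny_model()
  # scaled inputs (0.4, 0.8): z = sigmoid(0.5*0.4 - 0.25*0.8 + 0.1)
  z <- 1 / (1 + exp(-(0.5 * 0.4 - 0.25 * 0.8 + 0.1)))
  expect_equal(ann_forward(m, c(0.4, 0.8)), 2 * z - 0.3, tolerance = 1e-15)
  # all-zero weights predict the inverse-scaled zero
  m0 <- tiny_model()
  m0$W1[] <- 0; m0$b1 <- 0; m0$w2 <- 0; m0$b2 <- 0
  m0$scaling$y_min <- 10; m0$scaling$y_max <- 30
  expect_equal(ann_forward(m0, c(0.3, 0.9)), 10)
  expect_error(ann_forward(m, c(1, 2, 3)), "dimension")
})

test_that("vectorized forward equals a row-by-row loop", {
  s <- noiseless_setup(seed = 6)
  fit <- train_ann(s$table, config = train_config(seed = 6,
                                                  max_epochs = 50))
  X <- as.matrix(s$table[1:40, env_parameters()])
  vec <- ann_forward(fit$model, X)
  loop <- vapply(seq_len(nrow(X)),
                 function(i) ann_forward(fit$model, X[i, ]), numeric(1))
  expect_equal(vec, loop, tolerance = 1e-12)
})

test_that("backprop gradients match central finite differences", {
  set.seed(11)
  rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
  for (rep in 1:20) {
    n_in <- sample(2:5, 1); n_h <- sample(1:6, 1); n <- sample(5:20, 1)
    par <- list(W1 = matrix(rnorm(n_h * n_in), n_h, n_in),
                b1 = rnorm(n_h), w2 = rnorm(n_h), b2 = rnorm(1))
    Xs <- matrix(runif(n * n_in), n, n_in)
    ys <- runif(n)
    g <- backprop_gradients(par, Xs, ys)
    loss <- function(p) mean((ann_scaled_forward_for_test(p, Xs) - ys)^2)
    h <- 1e-6
    for (nm in names(par)) {
      fd <- par[[nm]]
      for (k in seq_along(fd)) {
        up <- par; up[[nm]][k] <- up[[nm]][k] + h
        dn <- par; dn[[nm]][k] <- dn[[nm]][k] - h
        fd[k] <- (loss(up) - loss(dn)) / (2 * h)
      }
      expect_true(all(rel_err(g[[nm]], fd) < 1e-5))
    }
  }
})

test_that("gradients vanish at a perfect fit and average over batches", {
  par <- list(W1 = matrix(c(1, -1), 1, 2), b1 = 0.5, w2 = 1.5, b2 = 0.2)
  Xs <- matrix(runif(16), 8, 2)
  ys <- as.vector(1.5 / (1 + exp(-(Xs %*% t(par$W1) + 0.5)))) + 0.2
  g <- backprop_gradients(par, Xs, ys)
  for (nm in names(g)) expect_true(all(abs(g[[nm]]) < 1e-12))

  # duplicating the batch leaves the mean gradient unchanged
  ys2 <- runif(8)
  g1 <- backprop_gradients(par, Xs, ys2)
  g2 <- backprop_gradients(par, rbind(Xs, Xs), c(ys2, ys2))
  expect_equal(g1, g2, tolerance = 1e-14)
  expect_error(backprop_gradients(par, Xs[0, ], numeric(0)), "empty")
})

test_that("training is deterministic and recovers a linear target", {
  s <- noiseless_setup(seed = 9)
  tab <- s$table
  tab$cpue <- 2 * tab$sss
  fit1 <- train_ann(tab, config = train_config(seed = 9, max_epochs = 2000))
  fit2 <- train_ann(tab, config = train_config(seed = 9, max_epochs = 2000))
  expect_identical(fit1$model$W1, fit2$model$W1)
  expect_identical(fit1$test$mse, fit2$test$mse)
  # noiseless linear target: test RMSE under 1% of the target range
  expect_lt(fit1$test$rmse, 0.01 * diff(range(tab$cpue)))
})

test_that("plain gradient descent never raises the training loss", {
  s <- noiseless_setup(seed = 13)
  fit <- train_ann(s$table, config = train_config(seed = 13,
                                                  max_epochs = 300,
                                                  optimizer = "gd"))
  expect_true(all(diff(fit$history$train_mse) <= 1e-15))
})

test_that("held-out error is small at low observation noise", {
  # at 5% multiplicative catch noise the held-out fit should be tight:
  # range-normalized RMSE under 5% on every seed (the noise alone
  # contributes ~4% to MAPE, and low-CPUE cells concentrate relative
  # error, so MAPE is only bounded loosely; see the methods vignette)
  for (s in 1:5) {
    cfg <- generator_config(seed = s, noise_cv = 0.05)
    fields <- generate_env_fields(cfg)
    tab <- build_training_table(generate_catch_records(fields, cfg),
                                fields)
    fit <- train_ann(tab, config = train_config(seed = s,
                                                max_epochs = 6000,
                                                patience = 6000))
    expect_lt(fit$test$nrmse_percent, 5)
    expect_lt(fit$test$error_rate_percent, 15)
  }
})

test_that("evaluation reports satisfy the metric identities", {
  expect_equal(evaluate_predictions(c(1, 2), c(1, 2))$mse, 0)
  expect_equal(evaluate_predictions(c(0, 0), c(1, 1))$mse, 1)
  expect_equal(evaluate_predictions(c(0, 0), c(1, 1))$rmse, 1)
  set.seed(21)
  for (rep in 1:10) {
    y <- runif(50, 1, 10); p <- y + rnorm(50)
    r <- evaluate_predictions(y, p)
    # longhand loop oracle
    s2 <- 0; ape <- 0
    for (i in 1:50) { s2 <- s2 + (y[i] - p[i])^2
                      ape <- ape + abs(y[i] - p[i]) / y[i] }
    expect_equal(r$mse, s2 / 50, tolerance = 1e-12)
    expect_equal(r$rmse, sqrt(r$mse), tolerance = 1e-12 * r$rmse)
    expect_equal(r$error_rate_percent, ape / 50 * 100, tolerance = 1e-12)
  }
  expect_error(evaluate_predictions(1:3, 1:4), "lengths")
})

test_that("prediction is invariant to affine feature rescaling after refit", {
  s <- noiseless_setup(seed = 15)
  tab <- s$table
  cfg <- train_config(seed = 15, max_epochs = 500)
  fit <- train_ann(tab, config = cfg)
  tab2 <- tab
  tab2$sss <- 100 * tab2$sss - 50   # affine rescale, scaling refit
  fit2 <- train_ann(tab2, config = cfg)
  X1 <- as.matrix(tab[, env_parameters()])
  X2 <- as.matrix(tab2[, env_parameters()])
  expect_equal(ann_forward(fit$model, X1), ann_forward(fit2$model, X2),
               tolerance = 1e-8)
})

test_that("models survive a JSON round-trip bit-faithfully", {
  s <- noiseless_setup(seed = 17)
  fit <- train_ann(s$table, config = train_config(seed = 17,
                                                  max_epochs = 100))
  path <- withr::local_tempfile(fileext = ".json")
  write_ann_model(fit$model, path)
  back <- read_ann_model(path)
  expect_equal(back$W1, fit$model$W1, tolerance = 0)
  expect_equal(back$scaling, fit$model$scaling, tolerance = 0)
  X <- as.matrix(s$table[1:20, env_parameters()])
  expect_identical(ann_forward(back, X), ann_forward(fit$model, X))
})
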