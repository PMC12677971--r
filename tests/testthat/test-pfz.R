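fit_small_model <- function(seed = 41) {
  s <- noiseless_setup(seed = seed, months = 24)
  fit <- train_ann(s$table, config = train_config(seed = seed,
                                                  max_epochs = 1500))
  list(model = fit$model, fields = s$fields, config = s$config)
}

test_that("grid prediction equals a per-cell forward loop", {
  w <- fit_small_model()
  g <- predict_grid(w$model, w$fields, 5)
  for (i in sample(length(w$fields$lat), 3)) {
    for (j in sample(length(w$fields$lon), 3)) {
      feats <- sapply(env_parameters(),
                      function(p) w$fields$data[[p]][i, j, 5])
      expect_equal(g$pred[i, j], ann_forward(w$model, feats),
                   tolerance = 1e-12)
    }
  }
  expect_identical(dim(g$pred), c(length(w$fields$lat),
                                  length(w$fields$lon)))
})

test_that("PFZ mask keeps the top decile, degenerating on constants", {
  w <- fit_small_model()
  g <- predict_grid(w$model, w$fields, 3, quantile = 0.9)
  n <- length(g$pred)
  if (length(unique(as.vector(g$pred))) == n)
    expect_identical(sum(g$mask), as.integer(ceiling(0.1 * n)))
  expect_gte(min(g$pred[g$mask]), max(g$pred[!g$mask]))

  # constant prediction: every cell is "top" (degenerate quantile)
  const <- w$fields
  for (p in env_parameters()) const$data[[p]][] <- mean(const$data[[p]])
  gc_ <- predict_grid(w$model, const, 3)
  expect_true(all(gc_$mask))
  expect_equal(diff(range(gc_$pred)), 0)
})

test_that("grid mismatches and bad months are rejected", {
  w <- fit_small_model()
  broken <- w$fields
  broken$data$sst <- broken$data$sst[-1, , , drop = FALSE]
  expect_error(predict_grid(w$model, broken, 1), "mismatch")
  expect_error(predict_grid(w$model, w$fields, 999), "coverage")
  expect_error(predict_grid(w$model, w$fields, 1, quantile = 1.2),
               "quantile")
})

test_that("hotspot report gives the argmax cell and its conditions", {
  w <- fit_small_model()
  g <- predict_grid(w$model, w$fields, 11)
  h <- locate_maximum(g, w$fields)
  # brute-force exhaustive scan
  best <- -Inf; bi <- bj <- 0
  for (i in seq_along(g$lat)) for (j in seq_along(g$lon)) {
    if (g$pred[i, j] > best) { best <- g$pred[i, j]; bi <- i; bj <- j }
  }
  expect_equal(h$max_cpue, best)
  expect_equal(h$lon, g$lon[bj])
  expect_equal(h$lat, g$lat[bi])
  for (p in env_parameters())
    expect_identical(unname(h$conditions[p]),
                     w$fields$data[[p]][bi, bj, 11])
})

test_that("ties at the maximum resolve to the first cell with a warning", {
  w <- fit_small_model()
  g <- predict_grid(w$model, w$fields, 1)
  g$pred[] <- 5
  expect_warning(h <- locate_maximum(g, w$fields), "tie")
  expect_equal(h$lon, g$lon[1])
  expect_equal(h$lat, g$lat[1])
})

test_that("the predicted hotspot lies on near-optimal true habitat", {
  # a model trained on noiseless data peaks near the generator optima:
  # the true response at the predicted argmax cell must be within a few
  # percent of the true maximum (the true top is nearly flat, so cell
  # rank is not a stable criterion, but near-optimality is)
  w <- fit_small_model(seed = 43)
  for (m in c(5, 11)) {
    g <- predict_grid(w$model, w$fields, m)
    h <- locate_maximum(g, w$fields)
    truth <- matrix(true_response(as.vector(w$fields$data$sst[, , m]),
                                  as.vector(w$fields$data$chl[, , m]),
                                  as.vector(w$fields$data$sss[, , m]),
                                  as.vector(w$fields$data$current[, , m]),
                                  w$config),
                    length(w$fields$lat), length(w$fields$lon))
    truth_at <- truth[match(h$lat, w$fields$lat),
                      match(h$lon, w$fields$lon)]
    expect_gte(truth_at, 0.9 * max(truth))
  }
})

test_that("current speeds convert explicitly to cm/s", {
  expect_equal(current_to_cms(0.0329, "m/s"), 3.29)
  expect_equal(current_to_cms(3.29), 3.29)
  expect_error(current_to_cms(1, "knots"))
})

test_that("map export round-trips through CSV and writes valid ASCII grids", {
  w <- fit_small_model()
  g <- predict_grid(w$model, w$fields, 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_map(g, csv)
  back <- read_map_csv(csv)
  expect_identical(nrow(back), length(g$pred))
  expect_equal(sum(back$pfz_flag), sum(g$mask))
  m_back <- matrix(NA_real_, length(g$lat), length(g$lon))
  m_back[cbind(match(back$lat, g$lat), match(back$lon, g$lon))] <-
    back$predicted_cpue
  expect_equal(m_back, g$pred, tolerance = 1e-7)

  asc <- withr::local_tempfile(fileext = ".asc")
  export_map(g, asc, format = "asc")
  hdr <- readLines(asc, n = 6)
  expect_match(hdr[1], sprintf("ncols %d", length(g$lon)))
  # georeferencing: lower-left corner equals the configured box corner
  expect_equal(as.numeric(sub("xllcorner ", "", hdr[3])),
               w$config$lon_range[1])
  expect_equal(as.numeric(sub("yllcorner ", "", hdr[4])),
               w$config$lat_range[1])
  body <- utils::read.table(asc, skip = 6)
  expect_identical(dim(as.matrix(body)),
                   c(length(g$lat), length(g$lon)))
  # first body row is the northernmost latitude band
  expect_equal(as.numeric(body[1, 1]),
               g$pred[which.max(g$lat), 1], tolerance = 1e-6)
})
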