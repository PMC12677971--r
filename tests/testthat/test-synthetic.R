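test_that("field generation is deterministic under the seed", {
  cfg <- small_config(seed = 11)
  f1 <- generate_env_fields(cfg)
  f2 <- generate_env_fields(cfg)
  expect_identical(f1, f2)
  f3 <- generate_env_fields(small_config(seed = 12))
  expect_false(identical(f1$data$sst, f3$data$sst))
})

test_that("fields have full coverage, correct shape and physical bounds", {
  cfg <- small_config(seed = 3)
  f <- generate_env_fields(cfg)
  nlat <- length(f$lat); nlon <- length(f$lon)
  for (p in env_parameters()) {
    expect_identical(dim(f$data[[p]]), c(nlat, nlon, cfg$months))
    expect_false(anyNA(f$data[[p]]))
    b <- cfg$fields[[p]]$bounds
    expect_true(all(f$data[[p]] >= b[1] & f$data[[p]] <= b[2]))
  }
  # salinity stays inside the 30-34.2 psu envelope of the study area
  expect_true(all(f$data$sss >= 30 & f$data$sss <= 34.2))
})

test_that("zero field noise reproduces the closed-form gradient+sinusoid", {
  cfg <- small_config(seed = 5, field_noise = 0)
  f <- generate_env_fields(cfg)
  for (p in env_parameters()) {
    for (m in c(1, 13, 24)) {
      expect_equal(f$data[[p]][, , m],
                   field_deterministic(p, f$lon, f$lat,
                                       f$calendar$month[m], cfg),
                   tolerance = 0)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, resolution = 0), "resolution")
  expect_error(generator_config(seed = 1, months = 12), "months")
  expect_error(generator_config(seed = 1, lon_range = c(126, 120)), "box")
  expect_error(generator_config(seed = 1, weights = c(sst = 0, chl = 0,
                                                      sss = 0, current = 0)),
               "weights")
  expect_error(generator_config(seed = 1, noise_cv = -1), "noise_cv")
})

test_that("true response is maximized at the optima and bounded by cpue_max", {
  cfg <- generator_config(seed = 1)
  at_opt <- true_response(31.4, 0.8, 34.2, 3.29, cfg)
  expect_equal(at_opt, cfg$cpue_max)
  # anywhere in the chl optimum band the response stays maximal
  expect_equal(true_response(31.4, 0.18, 34.2, 3.29, cfg), cfg$cpue_max)
  expect_equal(true_response(31.4, 1.5, 34.2, 3.29, cfg), cfg$cpue_max)
  set.seed(42)
  r <- true_response(runif(500, 20, 35), runif(500, 0, 3),
                     runif(500, 28, 36), runif(500, 0, 10), cfg)
  expect_true(all(r <= cfg$cpue_max))
  expect_true(all(r >= 0))
})

test_that("a zero predictor weight makes the response invariant to it", {
  cfg <- generator_config(seed = 1, weights = c(sst = 0, chl = 0.6,
                                                sss = 2, current = 1.2))
  sweep_sst <- true_response(seq(20, 35, length.out = 50),
                             0.8, 33, 3, cfg)
  expect_equal(diff(range(sweep_sst)), 0)
})

test_that("catch records are seeded, in-box, and positive", {
  cfg <- small_config(seed = 21)
  f <- generate_env_fields(cfg)
  r1 <- generate_catch_records(f, cfg)
  r2 <- generate_catch_records(f, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$trips >= 1))
  expect_true(all(r1$catch_kg >= 0))
  expect_true(all(r1$lon >= cfg$lon_range[1] & r1$lon <= cfg$lon_range[2]))
  expect_true(all(r1$lat >= cfg$lat_range[1] & r1$lat <= cfg$lat_range[2]))
  # every configured month is represented
  expect_identical(sort(unique(r1$year * 12 + r1$month)),
                   sort(f$calendar$year * 12 + f$calendar$month))
})

test_that("zero-noise CPUE equals the true response at the fished cell", {
  s <- noiseless_setup(seed = 2)
  cpue <- s$records$catch_kg / s$records$trips
  truth <- true_response(s$table$sst, s$table$chl, s$table$sss,
                         s$table$current, s$config)
  expect_equal(cpue, truth, tolerance = 1e-12)
})

test_that("mean generated CPUE matches the closed form under noise", {
  # Monte-Carlo at a fixed environment: lognormal noise has mean 1
  cfg <- generator_config(seed = 8, noise_cv = 0.4)
  n <- 10000
  resp <- true_response(30.5, 0.9, 33.5, 3.0, cfg)
  set.seed(99)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  draws <- resp * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - resp), 3 * se)
})

test_that("generation errors name missing parameters", {
  cfg <- small_config(seed = 1)
  f <- generate_env_fields(cfg)
  f$data$sss <- NULL
  expect_error(generate_catch_records(f, cfg), "sss")
})

test_that("the published season table fixture is intact", {
  t2 <- fixture_table2()
  expect_identical(nrow(t2), 12L)
  expect_equal(t2$fsi[11], 220.897)
  expect_identical(t2$label[11], "Peak season")
  expect_equal(t2$fsi[7], 19.695)
  expect_identical(t2$label[7], "Lean season")
})

test_that("env_grid extracts a consistent single-parameter slice", {
  cfg <- small_config(seed = 4)
  f <- generate_env_fields(cfg)
  g <- env_grid(f, "sst", 3)
  expect_identical(dim(g$values), c(length(f$lat), length(f$lon)))
  expect_identical(g$values, f$data$sst[, , 3])
  expect_identical(g$units, "degC")
  expect_error(env_grid(f, "sst", 99), "month_index")
})
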