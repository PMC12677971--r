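# Shared fixtures: small, fast generator configurations.

small_config <- function(seed = 1, months = 24, ...) {
  generator_config(seed = seed, months = months, resolution = 0.5,
                   trips_rate = 60, ...)
}

# A small noiseless training table with its config, fields and records.
noiseless_setup <- function(seed = 1, months = 24) {
  cfg <- small_config(seed = seed, months = months,
                      noise_cv = 0, field_noise = 1)
  fields <- generate_env_fields(cfg)
  records <- generate_catch_records(fields, cfg)
  list(config = cfg, fields = fields, records = records,
       table = build_training_table(records, fields))
}

# Hand-rolled windowed-mean oracle for the decomposition: plain loops,
# no reuse of package internals.
oracle_decompose <- function(x) {
  n <- length(x)
  ma <- rep(NA_real_, n); cma <- rep(NA_real_, n); am <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - 6; hi <- i + 5
    if (lo >= 1 && hi <= n) {
      s <- 0
      for (j in lo:hi) s <- s + x[j]
      ma[i] <- s / 12
    }
  }
  for (i in seq_len(n - 1)) {
    if (!is.na(ma[i]) && !is.na(ma[i + 1])) cma[i] <- (ma[i] + ma[i + 1]) / 2
  }
  for (i in seq_len(n)) if (!is.na(cma[i]) && cma[i] > 0) am[i] <- x[i] / cma[i]
  list(ma = ma, cma = cma, am = am)
}

# Longhand scaled-space forward pass (plain per-row loops), used as the
# independent loss for finite-difference gradient checks.
ann_scaled_forward_for_test <- function(par, Xs) {
  out <- numeric(nrow(Xs))
  for (i in seq_len(nrow(Xs))) {
    h <- as.vector(par$W1 %*% Xs[i, ]) + par$b1
    z <- 1 / (1 + exp(-h))
    out[i] <- sum(z * par$w2) + par$b2
  }
  out
}

# Tiny hand-set one-hidden-unit model for pocket-calculator checks.
tiny_model <- function() {
  spec <- network_spec(n_inputs = 2, n_hidden = 1)
  sc <- list(x_min = c(a = 0, b = 0), x_max = c(a = 1, b = 1),
             y_min = 0, y_max = 1)
  m <- list(W1 = matrix(c(0.5, -0.25), 1, 2), b1 = 0.1, w2 = 2, b2 = -0.3)
  structure(c(m, list(spec = spec, scaling = sc,
                      feature_names = c("a", "b"), seed = 1L)),
            class = "ann_model")
}
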