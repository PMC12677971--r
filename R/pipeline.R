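#' Write / read environmental fields as long-format CSV
#'
#' One row per parameter, month, cell: `parameter, year, month,
#' month_index, lon, lat, value`.
#'
#' @param fields An `env_fields` object.
#' @param path CSV path.
#' @return `write_env_csv`: the path, invisibly; `read_env_csv`: an
#'   `env_fields` object.
#' @export
write_env_csv <- function(fields, path) {
  stopifnot(inherits(fields, "env_fields"))
  nlat <- length(fields$lat); nlon <- length(fields$lon)
  nm <- nrow(fields$calendar)
  rows <- lapply(env_parameters(), function(p) {
    data.frame(parameter = p,
               year = rep(fields$calendar$year, each = nlat * nlon),
               month = rep(fields$calendar$month, each = nlat * nlon),
               month_index = rep(fields$calendar$index, each = nlat * nlon),
               lon = rep(rep(fields$lon, each = nlat), times = nm),
               lat = rep(rep(fields$lat, times = nlon), times = nm),
               value = as.vector(fields$data[[p]]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("parameter", "year", "month", "month_index", "lon", "lat",
            "value")
  stopifnot(all(need %in% names(d)))
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  idx <- sort(unique(d$month_index))
  cal <- unique(d[, c("month_index", "year", "month")])
  cal <- cal[order(cal$month_index), ]
  data <- lapply(env_parameters(), function(p) {
    sub <- d[d$parameter == p, ]
    arr <- array(NA_real_, dim = c(length(lat), length(lon), length(idx)))
    arr[cbind(match(sub$lat, lat), match(sub$lon, lon),
              match(sub$month_index, idx))] <- sub$value
    arr
  })
  names(data) <- env_parameters()
  structure(list(lon = lon, lat = lat,
                 calendar = data.frame(index = cal$month_index,
                                       year = cal$year, month = cal$month),
                 data = data, units = env_units()),
            class = "env_fields")
}

#' Join catch records to environmental conditions
#'
#' Builds the network's training table: each catch record is matched to
#' the grid cell whose center is nearest its coordinates, for its
#' year-month, and paired with that cell's four environmental values and
#' the record's CPUE (catch/trips).  Records outside the field coverage
#' (box or month span) raise an error listing the offending rows.
#'
#' @param records A `catch_records` data.frame.
#' @param fields An `env_fields` object.
#' @return A data.frame with columns `sst`, `chl`, `sss`, `current`,
#'   `cpue`, plus `year`, `month`, `lon`, `lat`.
#' @export
build_training_table <- function(records, fields) {
  stopifnot(is.data.frame(records), inherits(fields, "env_fields"))
  key <- records$year * 12L + (records$month - 1L)
  fkey <- fields$calendar$year * 12L + (fields$calendar$month - 1L)
  m_idx <- match(key, fkey)

  res_lon <- diff(fields$lon[1:2])
  res_lat <- diff(fields$lat[1:2])
  i_lon <- findInterval(records$lon,
                        c(fields$lon - res_lon / 2, Inf), all.inside = FALSE)
  i_lat <- findInterval(records$lat,
                        c(fields$lat - res_lat / 2, Inf), all.inside = FALSE)
  bad <- is.na(m_idx) | i_lon < 1 | i_lon > length(fields$lon) |
    i_lat < 1 | i_lat > length(fields$lat) |
    records$lon > max(fields$lon) + res_lon / 2 |
    records$lat > max(fields$lat) + res_lat / 2
  if (any(bad))
    stop("catch record(s) outside field coverage at row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "", call. = FALSE)

  at <- cbind(i_lat, i_lon, m_idx)
  data.frame(sst = fields$data$sst[at],
             chl = fields$data$chl[at],
             sss = fields$data$sss[at],
             current = fields$data$current[at],
             cpue = compute_cpue(records$catch_kg, records$trips),
             year = records$year, month = records$month,
             lon = records$lon, lat = records$lat)
}

#' Read a pipeline configuration file
#'
#' YAML with a mandatory `seed` and optional sections `generator`
#' (arguments to [generator_config()]), `train` ([train_config()]),
#' `fsi_thresholds` ([season_thresholds()]), `pfz_quantile`, `paths`
#' (`output_dir`, `catch_csv`, `env_csv`) and `months_to_map`.
#'
#' @param path YAML file.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed))
    stop("pipeline config must set `seed`", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_generator_config <- function(cfg) {
  args <- cfg$generator
  args$seed <- cfg$seed
  do.call(generator_config, args)
}

log_msg <- function(...) message(sprintf(...))

#' Run the simulation stage
#'
#' Generates the synthetic fields and catch records and writes them to
#' `paths$output_dir` as `env_fields.csv` and `catch_records.csv`.
#'
#' @param cfg A `pipeline_config` list (see [read_pipeline_config()]);
#'   a bare list with `seed` and `paths$output_dir` also works.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
run_simulate <- function(cfg) {
  out_dir <- cfg$paths$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gc_ <- pipeline_generator_config(cfg)
  fields <- generate_env_fields(gc_)
  records <- generate_catch_records(fields, gc_)
  env_path <- file.path(out_dir, "env_fields.csv")
  catch_path <- file.path(out_dir, "catch_records.csv")
  write_env_csv(fields, env_path)
  write_catch_csv(records, catch_path)
  log_msg("simulate: seed %d, %d months x %d parameters, %d catch records",
          gc_$seed, gc_$months, length(env_parameters()), nrow(records))
  invisible(list(fields = fields, records = records,
                 env_csv = env_path, catch_csv = catch_path))
}

#' Run the fishing-season stage
#'
#' Reads trip-level catch records, aggregates to monthly CPUE, runs the
#' FSI chain and writes `season_report.csv`.
#'
#' @param cfg A `pipeline_config`; needs `paths$catch_csv` and
#'   `paths$output_dir`.
#' @return Invisibly, the classified `seasonal_index`.
#' @export
run_fsi <- function(cfg) {
  out_dir <- cfg$paths$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_catch_csv(cfg$paths$catch_csv)
  series <- aggregate_monthly(records)
  thr <- do.call(season_thresholds, cfg$fsi_thresholds %||% list())
  si <- fishing_season_index(series, thr)
  report <- season_report(si)
  utils::write.csv(report, file.path(out_dir, "season_report.csv"),
                   row.names = FALSE)
  log_msg("fsi: %d-month series, peak = %s (FSI %.1f)",
          length(series$values), report$month[which.max(report$fsi)],
          max(report$fsi))
  invisible(si)
}

#' Run the training, contribution and mapping stage
#'
#' Builds the training table by sampling the environmental fields at the
#' catch locations and months, trains the network, evaluates it,
#' computes both contribution reports, predicts the requested monthly
#' grids and writes the model, maps and hotspot reports to
#' `paths$output_dir`.
#'
#' @param cfg A `pipeline_config`; needs `paths$catch_csv`,
#'   `paths$env_csv`, `paths$output_dir`; optional `train`,
#'   `pfz_quantile`, `months_to_map` (default: all months).
#' @return Invisibly, a list: `fit`, `permutation`, `connection_weight`,
#'   `grids`, `hotspots`.
#' @export
run_train_map <- function(cfg) {
  out_dir <- cfg$paths$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_catch_csv(cfg$paths$catch_csv)
  fields <- read_env_csv(cfg$paths$env_csv)
  table <- build_training_table(records, fields)

  tc_args <- cfg$train %||% list()
  tc_args$seed <- tc_args$seed %||% cfg$seed
  tc <- do.call(train_config, tc_args)
  fit <- train_ann(table, config = tc)
  write_ann_model(fit$model, file.path(out_dir, "ann_model.json"))
  log_msg("train: n=%d, test RMSE %.3f kg/trip, MAPE %.2f%%",
          nrow(table), fit$test$rmse, fit$test$error_rate_percent)

  test_rows <- split_train_test(table, tc)$test
  perm <- permutation_importance(fit$model, test_rows, seed = cfg$seed)
  cw <- connection_weight_contribution(fit$model)
  utils::write.csv(perm, file.path(out_dir, "contribution_permutation.csv"),
                   row.names = FALSE)
  utils::write.csv(cw, file.path(out_dir, "contribution_weights.csv"),
                   row.names = FALSE)

  months <- cfg$months_to_map %||% fields$calendar$index
  quant <- cfg$pfz_quantile %||% 0.9
  grids <- list(); hotspots <- list()
  for (m in months) {
    g <- predict_grid(fit$model, fields, m, quantile = quant)
    export_map(g, file.path(out_dir, sprintf("pfz_month_%03d.csv", m)))
    h <- locate_maximum(g, fields)
    grids[[as.character(m)]] <- g
    hotspots[[as.character(m)]] <- h
  }
  hs <- do.call(rbind, lapply(hotspots, function(h)
    data.frame(month_index = h$month_index, max_cpue = h$max_cpue,
               lon = h$lon, lat = h$lat, sst = h$conditions["sst"],
               chl = h$conditions["chl"], sss = h$conditions["sss"],
               current = h$conditions["current"], row.names = NULL)))
  utils::write.csv(hs, file.path(out_dir, "hotspots.csv"),
                   row.names = FALSE)
  log_msg("map: %d monthly grids, max predicted CPUE %.1f kg/trip",
          length(months), max(hs$max_cpue))
  invisible(list(fit = fit, permutation = perm, connection_weight = cw,
                 grids = grids, hotspots = hotspots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
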