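#' Generate monthly gridded environmental fields
#'
#' Produces one gridded field per predictor per month over the configured
#' study box.  Each field is the sum of a fixed spatial gradient, a
#' 12-month sinusoidal seasonal cycle (phase set per parameter so CHL-a,
#' current and salinity peak in the monsoon-transition months) and seeded
#' Gaussian noise, clamped to the parameter's physical bounds.
#'
#' @param config A [generator_config()].
#' @return An object of class `env_fields`: a list with cell-center axes
#'   `lon`, `lat`, a month table `calendar` (index, year, month), and
#'   `data`, a named list of `lat x lon x month` arrays, one per
#'   parameter, in the units of [env_units()].
#' @examples
#' flds <- generate_env_fields(generator_config(seed = 1, months = 24))
#' dim(flds$data$sst)
#' @seealso [field_deterministic()] for the closed-form noise-free field.
#' @export
generate_env_fields <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  axes <- grid_axes(config)
  nlat <- length(axes$lat); nlon <- length(axes$lon)
  cal <- index_calendar(seq_len(config$months),
                        config$start_year, config$start_month)

  data <- vector("list", length(env_parameters()))
  names(data) <- env_parameters()
  with_local_seed(derive_seed(config$seed, "fields"), {
    for (p in env_parameters()) {
      fp <- config$fields[[p]]
      arr <- array(NA_real_, dim = c(nlat, nlon, config$months))
      for (m in seq_len(config$months)) {
        det <- field_deterministic(p, axes$lon, axes$lat, cal$month[m], config)
        if (config$field_noise > 0 && fp$noise_sd > 0) {
          det <- det + matrix(
            stats::rnorm(nlat * nlon, 0, fp$noise_sd * config$field_noise),
            nlat, nlon)
        }
        arr[, , m] <- pmin(pmax(det, fp$bounds[1]), fp$bounds[2])
      }
      data[[p]] <- arr
    }
  })

  structure(list(
    lon = axes$lon, lat = axes$lat,
    calendar = data.frame(index = seq_len(config$months),
                          year = cal$year, month = cal$month),
    data = data,
    units = env_units()
  ), class = "env_fields")
}

#' Closed-form deterministic part of a synthetic field
#'
#' The gradient-plus-sinusoid surface a field reduces to when its noise
#' is zero: `mean + grad_lon * (lon - lon_center) + grad_lat *
#' (lat - lat_center) + amp * cos(2 pi (month - peak_month) / 12)`.
#'
#' @param parameter One of `"sst"`, `"chl"`, `"sss"`, `"current"`.
#' @param lon,lat Cell-center coordinate vectors.
#' @param calendar_month Calendar month 1-12 driving the seasonal cycle.
#' @param config A [generator_config()].
#' @return A `length(lat) x length(lon)` matrix.
#' @export
field_deterministic <- function(parameter, lon, lat, calendar_month, config) {
  fp <- config$fields[[parameter]]
  lon_c <- mean(config$lon_range); lat_c <- mean(config$lat_range)
  seasonal <- fp$amp * cos(2 * pi * (calendar_month - fp$peak_month) / 12)
  outer(fp$grad_lat * (lat - lat_c),
        fp$grad_lon * (lon - lon_c), "+") + fp$mean + seasonal
}

#' Extract one parameter-month grid
#'
#' @param fields An `env_fields` object.
#' @param parameter Predictor name.
#' @param month_index 1-based month index.
#' @return A list (class `env_grid`) with `parameter`, `month_index`,
#'   `lon`, `lat`, `values` (lat x lon matrix) and `units`.
#' @export
env_grid <- function(fields, parameter, month_index) {
  stopifnot(inherits(fields, "env_fields"))
  parameter <- match.arg(parameter, env_parameters())
  if (month_index < 1 || month_index > nrow(fields$calendar))
    stop("month_index out of range", call. = FALSE)
  structure(list(parameter = parameter, month_index = as.integer(month_index),
                 lon = fields$lon, lat = fields$lat,
                 values = fields$data[[parameter]][, , month_index],
                 units = unname(env_units()[parameter])),
            class = "env_grid")
}

#' Ground-truth expected CPUE for given environmental conditions
#'
#' The generator's known response surface: a product of per-predictor
#' suitability terms raised to the configured weights, scaled to
#' `cpue_max`.  SST, SSS and current use Gaussian suitability
#' `exp(-((x - opt) / tol)^2 / 2)`; CHL-a is 1 inside its optimum band
#' with Gaussian falloff outside.  The response is maximized exactly at
#' the configured optima and never exceeds `cpue_max`.
#'
#' @param sst,chl,sss,current Environmental values (degC, mg/m3, psu,
#'   cm/s); vectors are recycled to a common length.
#' @param config A [generator_config()].
#' @return Expected CPUE in kg/trip.
#' @examples
#' cfg <- generator_config(seed = 1)
#' true_response(31.4, 0.8, 34.2, 3.29, cfg)  # == cfg$cpue_max
#' @export
true_response <- function(sst, chl, sss, current, config) {
  stopifnot(inherits(config, "generator_config"))
  r <- config$response
  w <- config$weights
  s_gauss <- function(x, p) exp(-0.5 * ((x - p$opt) / p$tol)^2)
  band_dist <- pmax(0, pmax(r$chl$band[1] - chl, chl - r$chl$band[2]))
  s <- cbind(sst = s_gauss(sst, r$sst),
             chl = exp(-0.5 * (band_dist / r$chl$tol)^2),
             sss = s_gauss(sss, r$sss),
             current = s_gauss(current, r$current))
  suit <- rep(1, nrow(s))
  for (p in colnames(s)) suit <- suit * s[, p]^unname(w[p])  # 0^0 == 1:
  unname(config$cpue_max * suit)               # weight-0 predictors drop out
}

#' Generate trip-level catch records
#'
#' Simulates monthly purse-seine landings over the synthetic fields.  Per
#' month, the number of records is Poisson with mean
#' `trips_rate / trips_per_record` (minimum 1); each record's trip count
#' is `1 + Poisson(trips_per_record - 1)`; fishing cells are sampled with
#' probability proportional to the true response (fishers concentrate
#' effort on good habitat); catch is `trips x true_response x` lognormal
#' noise with mean 1 and the configured coefficient of variation.
#'
#' @param fields An `env_fields` object covering all configured months.
#' @param config The [generator_config()] the fields were built from.
#' @return A data.frame of class `catch_records` with columns `year`,
#'   `month`, `lon`, `lat`, `catch_kg`, `trips`.
#' @export
generate_catch_records <- function(fields, config) {
  stopifnot(inherits(fields, "env_fields"),
            inherits(config, "generator_config"))
  missing_p <- setdiff(env_parameters(), names(fields$data))
  if (length(missing_p))
    stop("fields missing parameter(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  if (nrow(fields$calendar) < config$months)
    stop("fields cover ", nrow(fields$calendar), " months but config needs ",
         config$months, call. = FALSE)

  nlat <- length(fields$lat); nlon <- length(fields$lon)
  cell_lat <- rep(fields$lat, times = nlon)   # column-major cell list
  cell_lon <- rep(fields$lon, each = nlat)
  sdlog <- sqrt(log(1 + config$noise_cv^2))

  out <- vector("list", config$months)
  with_local_seed(derive_seed(config$seed, "catch"), {
    for (m in seq_len(config$months)) {
      resp <- true_response(as.vector(fields$data$sst[, , m]),
                            as.vector(fields$data$chl[, , m]),
                            as.vector(fields$data$sss[, , m]),
                            as.vector(fields$data$current[, , m]),
                            config)
      n_rec <- max(1L, stats::rpois(1, config$trips_rate /
                                         config$trips_per_record))
      cells <- sample.int(nlat * nlon, n_rec, replace = TRUE,
                          prob = resp / sum(resp))
      trips <- 1L + stats::rpois(n_rec, config$trips_per_record - 1)
      noise <- if (config$noise_cv > 0) {
        stats::rlnorm(n_rec, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n_rec)
      out[[m]] <- data.frame(
        year = fields$calendar$year[m], month = fields$calendar$month[m],
        lon = cell_lon[cells], lat = cell_lat[cells],
        catch_kg = trips * resp[cells] * noise,
        trips = trips)
    }
  })
  rec <- do.call(rbind, out)
  class(rec) <- c("catch_records", "data.frame")
  rec
}

#' Published five-year seasonal-index table for western Banda Sea mackerel
#'
#' The printed monthly CPUE, FSI, standard deviation and season labels
#' from the 2019-2023 western Banda Sea Indian mackerel fishery,
#' reproduced verbatim as a fixture for classifier and report tests and
#' as a worked-example input.
#'
#' @return A 12-row data.frame: `month` (1-12), `month_name`, `cpue`
#'   (kg/trip), `fsi` (%), `std_dev`, `label`.
#' @examples
#' fixture_table2()[11, ]  # November, the peak season
#' @export
fixture_table2 <- function() {
  data.frame(
    month = 1:12,
    month_name = month.name,
    cpue = c(15.868, 40.353, 25.39, 41.148, 27.536, 35.179,
             11.904, 58.849, 125.25, 65.76, 122.764, 71.883),
    fsi = c(34.334, 93.609, 63.797, 107.242, 59.427, 114.364,
            19.695, 108.364, 178.093, 82.51, 220.897, 117.667),
    std_dev = c(18.486, 61.259, 47.704, 66.15, 24.521, 51.69,
                16.786, 54.022, 110.056, 63.014, 159.942, 93.508),
    label = c("Regular season", "Regular season", "Regular season",
              "Fishing season", "Regular season", "Fishing season",
              "Lean season", "Fishing season", "Fishing season",
              "Regular season", "Peak season", "Fishing season")
  )
}
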