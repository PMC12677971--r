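#' Configuration for the synthetic Banda Sea generator
#'
#' Builds a validated configuration for [generate_env_fields()] and
#' [generate_catch_records()].  Defaults emulate the western Banda Sea
#' study system: a 0.25-degree grid over 120-126E, 5-2S, sixty monthly
#' time steps, monsoon-cycled environmental fields, and a catch process
#' whose expected CPUE is a known function of sea surface temperature
#' (SST), chlorophyll-a (CHL-a), sea surface salinity (SSS) and surface
#' current speed.
#'
#' The expected-CPUE response peaks at SST 31.4 degC, SSS 34.2 psu and
#' current 3.29 cm/s, and is flat over the CHL-a band 0.18-1.5 mg/m3;
#' predictor weights are salinity-dominant with current second, so the
#' generator's ground-truth variable ranking is SSS > current > SST >
#' CHL-a.
#'
#' @param seed Integer seed; mandatory.  All randomness in field and
#'   catch generation derives from it.
#' @param lon_range,lat_range Numeric length-2, degrees (east, signed
#'   latitude; south negative).
#' @param resolution Grid cell size in degrees; must be > 0.
#' @param months Number of monthly steps (>= 24).
#' @param start_year,start_month Calendar anchor of month index 1.
#' @param response Per-predictor optimum and tolerance of the suitability
#'   terms; see Details.  `chl` uses a flat band `c(lo, hi)` with Gaussian
#'   falloff of scale `tol` outside it; the others are Gaussian with
#'   `opt`/`tol`.
#' @param weights Named nonnegative exponents (sst, chl, sss, current)
#'   applied to the suitability terms; not all zero.
#' @param cpue_max Expected CPUE (kg/trip) when every predictor sits at
#'   its optimum.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal catch noise (>= 0; 0 disables noise).
#' @param trips_rate Mean total fishing trips per month.
#' @param trips_per_record Mean trips aggregated into one catch record
#'   (a "boat-month" landing); trips per record are 1 + Poisson.
#' @param field_noise Multiplier on every field's noise standard
#'   deviation; 0 gives the deterministic gradient + sinusoid fields.
#' @param fields Per-parameter field shape: mean level, zonal/meridional
#'   gradients (units per degree), seasonal sinusoid amplitude, calendar
#'   month of the seasonal peak, noise sd, and physical clamp bounds.
#'
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$months
#' @export
generator_config <- function(seed,
                             lon_range = c(120, 126),
                             lat_range = c(-5, -2),
                             resolution = 0.25,
                             months = 60,
                             start_year = 2019,
                             start_month = 1,
                             response = list(
                               sst     = list(opt = 31.4, tol = 2.0),
                               chl     = list(band = c(0.18, 1.5), tol = 0.3),
                               sss     = list(opt = 34.2, tol = 2.5),
                               current = list(opt = 3.29, tol = 1.5)
                             ),
                             weights = c(sst = 0.8, chl = 0.6,
                                         sss = 2.0, current = 1.2),
                             cpue_max = 343,
                             noise_cv = 0.35,
                             trips_rate = 280,
                             trips_per_record = 4,
                             field_noise = 1,
                             fields = default_field_params()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  if (!is.numeric(resolution) || resolution <= 0)
    stop("`resolution` must be > 0", call. = FALSE)
  if (months < 24)
    stop("`months` must be >= 24 (two full seasonal cycles)", call. = FALSE)
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0)
    stop("invalid study box: ranges must be increasing", call. = FALSE)
  if (diff(lon_range) < resolution || diff(lat_range) < resolution)
    stop("study box smaller than one grid cell", call. = FALSE)
  weights <- weights[env_parameters()]
  if (anyNA(weights) || any(weights < 0) || all(weights == 0))
    stop("`weights` must be nonnegative for sst, chl, sss, current, not all zero",
         call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (trips_rate <= 0) stop("`trips_rate` must be > 0", call. = FALSE)
  if (field_noise < 0) stop("`field_noise` must be >= 0", call. = FALSE)
  stopifnot(setequal(names(fields), env_parameters()),
            setequal(names(response), env_parameters()))

  structure(list(
    seed = as.integer(seed),
    lon_range = lon_range, lat_range = lat_range,
    resolution = resolution, months = as.integer(months),
    start_year = as.integer(start_year),
    start_month = as.integer(start_month),
    response = response, weights = weights, cpue_max = cpue_max,
    noise_cv = noise_cv, trips_rate = trips_rate,
    trips_per_record = trips_per_record,
    field_noise = field_noise, fields = fields
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic generator configuration\n")
  cat(sprintf("  box: %g-%gE, %g-%g lat, %g deg grid\n",
              x$lon_range[1], x$lon_range[2], x$lat_range[1], x$lat_range[2],
              x$resolution))
  cat(sprintf("  months: %d (from %d-%02d), seed %d\n",
              x$months, x$start_year, x$start_month, x$seed))
  cat(sprintf("  cpue_max: %g kg/trip, noise_cv %g, trips/month %g\n",
              x$cpue_max, x$noise_cv, x$trips_rate))
  cat("  weights:", paste(sprintf("%s=%g", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' The four environmental predictors, in canonical order
#' @return Character vector `c("sst", "chl", "sss", "current")`.
#' @export
env_parameters <- function() c("sst", "chl", "sss", "current")

#' Units of the environmental predictors
#' @return Named character vector of units.
#' @export
env_units <- function() {
  c(sst = "degC", chl = "mg/m3", sss = "psu", current = "cm/s")
}

# Default field shapes.  Means, gradients and amplitudes are sized so the
# deterministic part stays strictly inside the clamp bounds (SSS inside
# the 30-34.2 psu envelope observed in the study area) and the seasonal
# peaks of CHL-a, current and SSS fall in the monsoon-transition months
# (Oct-Nov), when upwelling raises productivity.
default_field_params <- function() {
  list(
    sst = list(mean = 30.4, grad_lon = -0.08, grad_lat = 0.15,
               amp = 1.2, peak_month = 11, noise_sd = 0.15,
               bounds = c(26, 32.5)),
    chl = list(mean = 0.80, grad_lon = -0.04, grad_lat = 0.06,
               amp = 0.45, peak_month = 10, noise_sd = 0.05,
               bounds = c(0.05, 2.5)),
    sss = list(mean = 32.0, grad_lon = 0.12, grad_lat = -0.10,
               amp = 1.4, peak_month = 11, noise_sd = 0.08,
               bounds = c(30, 34.2)),
    current = list(mean = 2.2, grad_lon = 0.05, grad_lat = -0.08,
                   amp = 1.2, peak_month = 11, noise_sd = 0.12,
                   bounds = c(0.2, 8))
  )
}

# Grid cell centers implied by a config.
grid_axes <- function(config) {
  res <- config$resolution
  list(
    lon = seq(config$lon_range[1] + res / 2, config$lon_range[2] - res / 2,
              by = res),
    lat = seq(config$lat_range[1] + res / 2, config$lat_range[2] - res / 2,
              by = res)
  )
}

# Calendar month (1-12) and year of a 1-based month index.
index_calendar <- function(index, start_year, start_month) {
  k <- start_year * 12L + (start_month - 1L) + (index - 1L)
  list(year = k %/% 12L, month = k %% 12L + 1L)
}
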