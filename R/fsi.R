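#' Ratio-to-moving-average decomposition of a CPUE series
#'
#' First stage of the Fishing Season Index: removes trend from the
#' monthly CPUE series with a 12-month moving average and expresses each
#' month as a ratio to the centered trend.
#'
#' For a series `CPUE_1..CPUE_n`:
#' \itemize{
#'   \item `MA_i` = mean of the 12 values at offsets -6..+5 around `i`
#'     (defined where the window fits, i.e. `i` in `7..n-5`);
#'   \item `CMA_i = (MA_i + MA_{i+1}) / 2`, the centered moving average
#'     aligning the even-length window on month `i` (defined for `i` in
#'     `7..n-6`);
#'   \item `AM_i = CPUE_i / CMA_i`, the monthly seasonal ratio, defined
#'     where `CMA_i` exists and exceeds a small tolerance
#'     (`1e-9 x mean(CPUE)`; near-zero trend would blow the ratio up, so
#'     such indices are left undefined with a warning).
#' }
#'
#' @param series A [monthly_cpue_series()] (length >= 24).
#' @return A data.frame of class `cpue_decomposition` with columns
#'   `index`, `year`, `month`, `cpue`, `ma`, `cma`, `am` (`NA` where
#'   undefined).
#' @examples
#' s <- monthly_cpue_series(rep(50, 36), 2019)
#' d <- decompose_cpue(s)
#' range(d$am, na.rm = TRUE)  # constant series: all ratios 1
#' @export
decompose_cpue <- function(series) {
  stopifnot(inherits(series, "monthly_cpue"))
  x <- series$values
  n <- length(x)
  if (n < 24) stop("series too short for decomposition", call. = FALSE)

  ma <- rep(NA_real_, n)
  for (i in 7:(n - 5)) ma[i] <- mean(x[(i - 6):(i + 5)])
  cma <- rep(NA_real_, n)
  for (i in 7:(n - 6)) cma[i] <- (ma[i] + ma[i + 1]) / 2

  tol <- 1e-9 * mean(x)
  am <- rep(NA_real_, n)
  ok <- !is.na(cma) & cma > tol
  degenerate <- !is.na(cma) & cma <= tol
  if (any(degenerate))
    warning("CMA at or below tolerance at ", sum(degenerate),
            " index(es); seasonal ratio left undefined there")
  am[ok] <- x[ok] / cma[ok]

  cal <- index_calendar(seq_len(n), series$start_year, series$start_month)
  structure(data.frame(index = seq_len(n), year = cal$year,
                       month = cal$month, cpue = x, ma = ma, cma = cma,
                       am = am),
            class = c("cpue_decomposition", "data.frame"))
}

#' Fishing Season Index from a seasonal decomposition
#'
#' Averages the monthly seasonal ratios by calendar month and normalizes
#' them so the twelve indices sum to 1200 (mean 100):
#' `AAM_m` = mean of month `m`'s ratios over the available years;
#' `TAM = sum(AAM)`; `CF = 1200 / TAM`; `FSI_m = AAM_m x CF`.
#' The reported dispersion is the sample (n-1) standard deviation of each
#' month's CF-scaled ratios, i.e. in FSI percent units.
#'
#' @param trace A `cpue_decomposition` from [decompose_cpue()].  Every
#'   calendar month must carry at least one defined ratio.
#' @return A data.frame of class `seasonal_index` with one row per
#'   calendar month: `month`, `month_name`, `cpue` (mean observed CPUE),
#'   `aam`, `std_dev`, `fsi`, `n_ratios`, `season` (`NA` until
#'   [classify_seasons()]); attributes `tam` and `cf`.
#' @examples
#' s <- monthly_cpue_series(rep(50, 36), 2019)
#' si <- seasonal_index(decompose_cpue(s))
#' attr(si, "cf")  # 100 for a constant series
#' @export
seasonal_index <- function(trace) {
  stopifnot(inherits(trace, "cpue_decomposition"))
  have <- !is.na(trace$am)
  counts <- tabulate(trace$month[have], nbins = 12)
  if (any(counts == 0))
    stop("no seasonal ratio for calendar month(s): ",
         paste(month.name[counts == 0], collapse = ", "), call. = FALSE)

  aam <- vapply(1:12, function(m) mean(trace$am[have & trace$month == m]),
                numeric(1))
  tam <- sum(aam)
  if (tam <= 0) stop("total of monthly ratios (TAM) is zero", call. = FALSE)
  cf <- 1200 / tam
  fsi <- aam * cf
  std_dev <- vapply(1:12, function(m)
    sample_sd(trace$am[have & trace$month == m] * cf), numeric(1))
  cpue_mean <- vapply(1:12, function(m) mean(trace$cpue[trace$month == m]),
                      numeric(1))

  structure(data.frame(month = 1:12, month_name = month.name,
                       cpue = cpue_mean, aam = aam, std_dev = std_dev,
                       fsi = fsi, n_ratios = counts,
                       season = NA_character_),
            tam = tam, cf = cf,
            class = c("seasonal_index", "data.frame"))
}

#' Season classification thresholds
#'
#' @param fishing FSI at or above which a (non-peak) month is a fishing
#'   season; default 100, the all-months mean.
#' @param lean FSI below which a month is a lean season; default 30.
#' @return A named list of class `season_thresholds`.
#' @export
season_thresholds <- function(fishing = 100, lean = 30) {
  if (!(lean < fishing))
    stop("thresholds must satisfy lean < fishing", call. = FALSE)
  structure(list(fishing = fishing, lean = lean),
            class = "season_thresholds")
}

#' Classify months into peak / fishing / regular / lean seasons
#'
#' The month with the maximum FSI is the peak season (a tied maximum
#' labels every tied month peak, with a warning); of the rest, FSI at or
#' above the fishing threshold is a fishing season, FSI below the lean
#' threshold a lean season, and anything between is a regular season.
#'
#' @param result A `seasonal_index` (or any data.frame with an `fsi`
#'   column and 12 rows).
#' @param thresholds A [season_thresholds()].
#' @return `result` with its `season` column filled.
#' @examples
#' classify_seasons(fixture_table2_index())$season
#' @export
classify_seasons <- function(result, thresholds = season_thresholds()) {
  stopifnot(is.data.frame(result), "fsi" %in% names(result))
  if (nrow(result) != 12) stop("need 12 monthly FSI values", call. = FALSE)
  fsi <- result$fsi
  is_max <- fsi == max(fsi)
  if (sum(is_max) > 1)
    warning("tied maximum FSI: ", sum(is_max), " months labelled Peak season")
  season <- ifelse(fsi >= thresholds$fishing, "Fishing season",
            ifelse(fsi < thresholds$lean, "Lean season", "Regular season"))
  season[is_max] <- "Peak season"
  result$season <- season
  result
}

#' Table 2 FSI values wrapped as a seasonal_index for replay
#'
#' Convenience wrapper putting the published fixture ([fixture_table2()])
#' into the `seasonal_index` layout so the classifier and report can be
#' run against the printed values.
#' @return A `seasonal_index` data.frame (aam back-computed from FSI).
#' @export
fixture_table2_index <- function() {
  t2 <- fixture_table2()
  cf <- 1200 / sum(t2$fsi / 100)  # unknown; only fsi-scale fields are used
  structure(data.frame(month = t2$month, month_name = t2$month_name,
                       cpue = t2$cpue, aam = t2$fsi / 100,
                       std_dev = t2$std_dev, fsi = t2$fsi,
                       n_ratios = NA_integer_, season = NA_character_),
            tam = sum(t2$fsi / 100), cf = cf,
            class = c("seasonal_index", "data.frame"))
}

#' Twelve-row fishing season report
#'
#' Formats a classified seasonal index as the standard season table:
#' month, mean CPUE (kg/trip), FSI (%), +/- std. dev., season class,
#' numeric columns rounded to 3 decimals.
#'
#' @param result A classified `seasonal_index`.
#' @return A 12-row data.frame with columns `month`, `cpue`, `fsi`,
#'   `std_dev`, `season` (month given by name).
#' @export
season_report <- function(result) {
  stopifnot(inherits(result, "data.frame"),
            all(c("month_name", "cpue", "fsi", "std_dev") %in% names(result)))
  if (anyNA(result$season))
    stop("classify_seasons() must be applied before reporting", call. = FALSE)
  data.frame(month = result$month_name,
             cpue = round(result$cpue, 3),
             fsi = round(result$fsi, 3),
             std_dev = round(result$std_dev, 3),
             season = result$season)
}

#' Full FSI chain from a monthly CPUE series
#'
#' Convenience composition: decompose, index, classify.
#' @param series A [monthly_cpue_series()].
#' @param thresholds A [season_thresholds()].
#' @return A classified `seasonal_index`.
#' @export
fishing_season_index <- function(series, thresholds = season_thresholds()) {
  classify_seasons(seasonal_index(decompose_cpue(series)), thresholds)
}
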