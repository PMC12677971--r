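#' Catch per unit effort
#'
#' CPUE standardizes catch to fishing effort: `catch / effort` in
#' kg/trip.  Vectorized.
#'
#' @param catch Catch mass in kg (>= 0).
#' @param effort Number of fishing trips (> 0).
#' @return CPUE in kg/trip.
#' @examples
#' compute_cpue(500, 4)  # 125 kg/trip
#' @export
compute_cpue <- function(catch, effort) {
  if (any(effort <= 0)) stop("effort must be > 0", call. = FALSE)
  if (any(catch < 0)) stop("catch must be >= 0", call. = FALSE)
  catch / effort
}

#' Monthly CPUE series
#'
#' Constructor for the ordered monthly CPUE series the seasonal
#' decomposition consumes.  The series must span at least 24 months
#' (two seasonal cycles) with no gaps; missing months must be resolved
#' explicitly before construction.
#'
#' @param values Numeric CPUE values (kg/trip), one per consecutive
#'   month, all >= 0 and non-missing.
#' @param start_year,start_month Calendar position of `values[1]`.
#' @return An object of class `monthly_cpue`.
#' @export
monthly_cpue_series <- function(values, start_year, start_month = 1) {
  if (length(values) < 24)
    stop("CPUE series must cover at least 24 months, got ", length(values),
         call. = FALSE)
  if (anyNA(values))
    stop("CPUE series has missing values; resolve gaps before construction",
         call. = FALSE)
  if (any(values < 0)) stop("CPUE must be >= 0", call. = FALSE)
  if (start_month < 1 || start_month > 12)
    stop("start_month must be in 1..12", call. = FALSE)
  structure(list(values = as.numeric(values),
                 start_year = as.integer(start_year),
                 start_month = as.integer(start_month)),
            class = "monthly_cpue")
}

#' @export
print.monthly_cpue <- function(x, ...) {
  cat(sprintf("Monthly CPUE series: %d months from %d-%02d\n",
              length(x$values), x$start_year, x$start_month))
  cat(sprintf("  mean %.2f, range %.2f-%.2f kg/trip\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Aggregate trip-level catch records to a monthly CPUE series
#'
#' Per month, CPUE = total catch / total trips.  The records must span a
#' contiguous month range: a month inside the span with no record is an
#' error (it must be imputed or trimmed explicitly), never silently
#' zeroed.
#'
#' @param records A data.frame with columns `year`, `month`, `catch_kg`,
#'   `trips` (e.g. from [generate_catch_records()] or
#'   [read_catch_csv()]).
#' @return A [monthly_cpue_series()].
#' @export
aggregate_monthly <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  need <- c("year", "month", "catch_kg", "trips")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  key <- records$year * 12L + (records$month - 1L)
  span <- seq(min(key), max(key))
  catch <- tapply(records$catch_kg, factor(key, levels = span), sum)
  trips <- tapply(records$trips, factor(key, levels = span), sum)

  gaps <- span[is.na(trips)]
  if (length(gaps))
    stop("no records for month(s) inside the span: ",
         paste(sprintf("%d-%02d", gaps %/% 12L, gaps %% 12L + 1L),
               collapse = ", "), call. = FALSE)
  if (any(trips == 0))
    stop("month(s) with zero total trips cannot yield CPUE", call. = FALSE)

  monthly_cpue_series(as.numeric(catch) / as.numeric(trips),
                      start_year = span[1] %/% 12L,
                      start_month = span[1] %% 12L + 1L)
}

#' Read / write monthly CPUE and trip-level catch CSV files
#'
#' `read_cpue_csv` expects columns `year, month, cpue`;
#' `read_catch_csv`/`write_catch_csv` use the trip-record layout
#' `year, month, lon, lat, catch_kg, trips`.
#'
#' @param path File path.
#' @return `read_cpue_csv`: a [monthly_cpue_series()]; `read_catch_csv`:
#'   a `catch_records` data.frame.
#' @export
read_cpue_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "month", "cpue") %in% names(d)))
  d <- d[order(d$year * 12L + d$month), ]
  key <- d$year * 12L + (d$month - 1L)
  if (any(diff(key) != 1))
    stop("CPUE CSV has gaps or duplicate months", call. = FALSE)
  monthly_cpue_series(d$cpue, d$year[1], d$month[1])
}

#' @rdname read_cpue_csv
#' @export
read_catch_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("year", "month", "lon", "lat", "catch_kg", "trips")
  stopifnot(all(need %in% names(d)))
  class(d) <- c("catch_records", "data.frame")
  d
}

#' @rdname read_cpue_csv
#' @param records A `catch_records` data.frame.
#' @export
write_catch_csv <- function(records, path) {
  utils::write.csv(
    records[, c("year", "month", "lon", "lat", "catch_kg", "trips")],
    path, row.names = FALSE)
  invisible(path)
}
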