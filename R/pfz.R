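#' Predict a CPUE grid and delineate potential fishing zones
#'
#' Applies a fitted network cellwise to one month's four environmental
#' grids and flags the potential fishing zone (PFZ) as the cells in the
#' top quantile of predicted CPUE (default top 10%).  With `k =
#' ceiling((1 - quantile) * n_cells)`, the mask keeps the `k` largest
#' predictions; ties at the threshold (e.g. constant fields) enlarge the
#' mask, degenerating to all cells for a constant prediction.
#'
#' @param model A fitted `ann_model` over the four environmental
#'   predictors.
#' @param fields An `env_fields` object (all four parameters on one
#'   grid).
#' @param month_index 1-based month to predict.
#' @param quantile PFZ quantile of predicted CPUE (default 0.9, i.e. top
#'   decile).
#' @return An object of class `pfz_grid`: `month_index`, `lon`, `lat`,
#'   `pred` (lat x lon matrix, kg/trip), `mask` (logical matrix),
#'   `quantile`.
#' @export
predict_grid <- function(model, fields, month_index, quantile = 0.9) {
  stopifnot(inherits(model, "ann_model"), inherits(fields, "env_fields"))
  miss <- setdiff(model$feature_names, names(fields$data))
  if (length(miss))
    stop("fields missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dims <- unique(lapply(fields$data, function(a) dim(a)[1:2]))
  if (length(dims) != 1)
    stop("parameter grids have mismatched shapes", call. = FALSE)
  if (month_index < 1 || month_index > nrow(fields$calendar))
    stop("month_index outside field coverage", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be in (0, 1)", call. = FALSE)

  nlat <- length(fields$lat); nlon <- length(fields$lon)
  X <- sapply(model$feature_names,
              function(p) as.vector(fields$data[[p]][, , month_index]))
  pred <- matrix(ann_forward(model, X), nlat, nlon)
  if (any(!is.finite(pred)))
    stop("non-finite predictions on the grid", call. = FALSE)

  n <- length(pred)
  k <- ceiling((1 - quantile) * n)
  thr <- sort(as.vector(pred), decreasing = TRUE)[k]
  structure(list(month_index = as.integer(month_index),
                 lon = fields$lon, lat = fields$lat,
                 pred = pred, mask = pred >= thr, quantile = quantile),
            class = "pfz_grid")
}

#' @export
print.pfz_grid <- function(x, ...) {
  cat(sprintf("PFZ grid, month %d: %d x %d cells, %d in top %.0f%% zone\n",
              x$month_index, length(x$lat), length(x$lon), sum(x$mask),
              (1 - x$quantile) * 100))
  cat(sprintf("  predicted CPUE %.1f-%.1f kg/trip\n",
              min(x$pred), max(x$pred)))
  invisible(x)
}

#' Locate the predicted-CPUE maximum and its environmental conditions
#'
#' Finds the argmax cell of a predicted grid (ties resolved
#' deterministically: first cell scanning latitude fastest within
#' longitude, with a warning) and reports the four environmental values
#' at that cell, read directly from the input grids.
#'
#' @param grid A `pfz_grid`.
#' @param fields The `env_fields` the grid was predicted from.
#' @return A list of class `hotspot_report`: `month_index`, `max_cpue`,
#'   `lon`, `lat`, and `conditions` (named: sst, chl, sss, current).
#' @export
locate_maximum <- function(grid, fields) {
  stopifnot(inherits(grid, "pfz_grid"), inherits(fields, "env_fields"))
  if (all(is.na(grid$pred))) stop("all predictions are NA", call. = FALSE)
  mx <- max(grid$pred, na.rm = TRUE)
  hits <- which(grid$pred == mx)
  if (length(hits) > 1)
    warning(length(hits), " cells tie at the maximum; reporting the first")
  cell <- hits[1]
  i_lat <- (cell - 1) %% length(grid$lat) + 1
  i_lon <- (cell - 1) %/% length(grid$lat) + 1
  cond <- vapply(env_parameters(), function(p)
    fields$data[[p]][i_lat, i_lon, grid$month_index], numeric(1))
  structure(list(month_index = grid$month_index, max_cpue = mx,
                 lon = grid$lon[i_lon], lat = grid$lat[i_lat],
                 conditions = cond),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("Hotspot, month %d: %.1f kg/trip at %.3fE, %.3f lat\n",
              x$month_index, x$max_cpue, x$lon, x$lat))
  cat(sprintf("  SST %.2f degC, CHL-a %.3f mg/m3, SSS %.2f psu, current %.2f cm/s\n",
              x$conditions["sst"], x$conditions["chl"], x$conditions["sss"],
              x$conditions["current"]))
  invisible(x)
}

#' Export a predicted-CPUE map
#'
#' `"csv"` writes one row per cell (`lon, lat, month, predicted_cpue,
#' pfz_flag`).  `"asc"` writes an ESRI ASCII grid (plain-text
#' georeferenced raster, WGS84 cell-center registration) of the
#' predictions, readable by standard GIS tools.
#'
#' @param grid A `pfz_grid`.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"asc"`.
#' @return The path, invisibly.
#' @export
export_map <- function(grid, path, format = c("csv", "asc")) {
  stopifnot(inherits(grid, "pfz_grid"))
  format <- match.arg(format)
  if (format == "csv") {
    d <- data.frame(lon = rep(grid$lon, each = length(grid$lat)),
                    lat = rep(grid$lat, times = length(grid$lon)),
                    month = grid$month_index,
                    predicted_cpue = as.vector(grid$pred),
                    pfz_flag = as.integer(as.vector(grid$mask)))
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    res <- diff(grid$lon[1:2])
    # rows north -> south, columns west -> east
    m <- grid$pred[order(grid$lat, decreasing = TRUE), ]
    hdr <- c(sprintf("ncols %d", length(grid$lon)),
             sprintf("nrows %d", length(grid$lat)),
             sprintf("xllcorner %.10g", min(grid$lon) - res / 2),
             sprintf("yllcorner %.10g", min(grid$lat) - res / 2),
             sprintf("cellsize %.10g", res),
             "NODATA_value -9999")
    body <- apply(m, 1, function(r) paste(format(r, digits = 9),
                                          collapse = " "))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read back an exported CSV map
#'
#' @param path CSV written by [export_map()].
#' @return A data.frame with the exported columns.
#' @export
read_map_csv <- function(path) utils::read.csv(path)

#' Convert current speed to the package's internal unit (cm/s)
#'
#' Satellite current products are commonly distributed in m/s while the
#' catch-rate literature for this system reports cm/s; every function in
#' this package expects cm/s.  The unit must be stated explicitly.
#'
#' @param x Current speed values.
#' @param unit `"cm/s"` (returned unchanged) or `"m/s"` (multiplied by
#'   100).
#' @return Current speed in cm/s.
#' @examples
#' current_to_cms(0.0329, "m/s")  # 3.29 cm/s
#' @export
current_to_cms <- function(x, unit = c("cm/s", "m/s")) {
  unit <- match.arg(unit)
  if (unit == "m/s") x * 100 else x
}
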