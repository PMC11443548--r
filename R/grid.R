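#' Regular latitude/longitude grid
#'
#' A `geo_grid` describes the cell-center coordinates of a regular
#' latitude/longitude grid, the common registration of mapped L3 satellite
#' products. Axes must be strictly monotone (ascending or descending) and
#' regularly spaced to within `1e-6` degrees.
#'
#' @param lats Numeric vector of cell-center latitudes (degrees north).
#' @param lons Numeric vector of cell-center longitudes (degrees east);
#'   normalized to `[-180, 180)`.
#' @return An object of class `geo_grid` with elements `lats`, `lons`,
#'   `spacing` (degrees, one value per axis).
#' @examples
#' g <- geo_grid(lats = seq(-30, -24, by = 1), lons = seq(48, 66, by = 1))
#' @export
geo_grid <- function(lats, lons) {
  check_axis(lats, "lats")
  lons <- normalize_lon(lons)
  check_axis(lons, "lons")
  structure(
    list(
      lats = as.numeric(lats),
      lons = as.numeric(lons),
      spacing = c(lat = abs(stats::median(diff(lats))),
                  lon = abs(stats::median(diff(lons))))
    ),
    class = "geo_grid"
  )
}

check_axis <- function(x, name) {
  if (length(x) < 2) stop("grid axis '", name, "' needs at least 2 values")
  d <- diff(x)
  if (all(d > 0) || all(d < 0)) {
    if (max(abs(abs(d) - abs(stats::median(d)))) > 1e-6) {
      stop("grid axis '", name, "' is not regularly spaced (tolerance 1e-6 degrees)")
    }
  } else {
    stop("grid axis '", name, "' is not strictly monotone")
  }
  invisible(x)
}

normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("<geo_grid> %d lat x %d lon, spacing %.4g x %.4g deg\n",
              length(x$lats), length(x$lons), x$spacing["lat"], x$spacing["lon"]))
  cat(sprintf("  lat: [%.3f, %.3f]  lon: [%.3f, %.3f]\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons)))
  invisible(x)
}

#' Gridded variable with a time axis
#'
#' A `geo_field` holds one variable on a [geo_grid()] with a time axis:
#' a numeric array with dimensions `(time, lat, lon)`. Missing data are
#' represented as `NA` and are excluded from all statistics computed by the
#' package (never zero-filled).
#'
#' @param values Numeric array, `dim = c(length(times), nlat, nlon)`. A matrix
#'   `(nlat, nlon)` is accepted when `length(times) == 1`.
#' @param grid A [geo_grid()].
#' @param times Vector of `Date` (or `POSIXct` for sub-daily data).
#' @param units Units string, kept as metadata.
#' @param var Variable name, kept as metadata.
#' @return An object of class `geo_field`.
#' @export
geo_field <- function(values, grid, times, units = "", var = "var") {
  stopifnot(inherits(grid, "geo_grid"))
  if (is.matrix(values) && length(times) == 1L) {
    values <- array(values, dim = c(1L, dim(values)))
  }
  if (length(dim(values)) != 3L) stop("'values' must be a (time, lat, lon) array")
  if (!identical(dim(values), c(length(times), length(grid$lats), length(grid$lons)))) {
    stop(sprintf("'values' dim %s does not match (time=%d, lat=%d, lon=%d)",
                 paste(dim(values), collapse = "x"),
                 length(times), length(grid$lats), length(grid$lons)))
  }
  structure(
    list(values = values, grid = grid, times = times,
         units = units, var = var),
    class = "geo_field"
  )
}

#' @export
print.geo_field <- function(x, ...) {
  cat(sprintf("<geo_field> '%s' [%s], %d time x %d lat x %d lon, %.1f%% missing\n",
              x$var, x$units, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Extract one time slice of a field as a (lat, lon) matrix
#'
#' @param field A [geo_field()].
#' @param t Time index.
#' @return Numeric matrix `(nlat, nlon)`.
#' @export
field_slice <- function(field, t = 1L) {
  stopifnot(inherits(field, "geo_field"))
  if (t < 1 || t > dim(field$values)[1]) stop("time index out of range")
  matrix(field$values[t, , ], nrow = length(field$grid$lats))
}

#' Geographic bounding box
#'
#' @param lat_min,lat_max,lon_min,lon_max Region bounds in degrees.
#'   Cells whose centers lie inside the (inclusive) bounds belong to the
#'   region. The study domain never crosses the antimeridian and neither may
#'   a `region`.
#' @return An object of class `region`.
#' @examples
#' # the south-east Madagascar bloom box
#' bloom_box <- region(-30, -24, 48, 66)
#' @export
region <- function(lat_min, lat_max, lon_min, lon_max) {
  if (!(lat_min < lat_max)) stop("lat_min must be < lat_max")
  if (!(lon_min < lon_max)) stop("lon_min must be < lon_max")
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> lat [%g, %g], lon [%g, %g]\n",
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

region_index <- function(grid, reg) {
  list(
    lat = which(grid$lats >= reg$lat_min & grid$lats <= reg$lat_max),
    lon = which(grid$lons >= reg$lon_min & grid$lons <= reg$lon_max)
  )
}

#' Subset a field to a region
#'
#' Retains every cell whose center lies inside the region (inclusive bounds),
#' and none outside.
#'
#' @param x A [geo_field()].
#' @param reg A [region()].
#' @param ... Unused.
#' @return A [geo_field()] on the cropped grid.
#' @export
subset.geo_field <- function(x, reg, ...) {
  stopifnot(inherits(reg, "region"))
  idx <- region_index(x$grid, reg)
  if (length(idx$lat) == 0 || length(idx$lon) == 0) {
    stop("region does not intersect the field grid")
  }
  vals <- x$values[, idx$lat, idx$lon, drop = FALSE]
  if (all(is.na(vals))) {
    warning("all cells in the requested region are masked")
  }
  geo_field(vals, geo_grid(x$grid$lats[idx$lat], x$grid$lons[idx$lon]),
            x$times, units = x$units, var = x$var)
}

#' Point time series (tidy one-column series with a time axis)
#'
#' The package's currency for 1-D series: a `data.frame` with columns `time`
#' and `value`, carrying a `units` attribute. Missing values are `NA`.
#'
#' @param time Vector of `Date` or `POSIXct`.
#' @param value Numeric vector, same length.
#' @param units Units string.
#' @return A `data.frame` of class `c("geo_series", "data.frame")`.
#' @export
geo_series <- function(time, value, units = "") {
  if (length(time) != length(value)) stop("time and value lengths differ")
  out <- data.frame(time = time, value = as.numeric(value))
  class(out) <- c("geo_series", "data.frame")
  attr(out, "units") <- units
  out
}

#' @export
print.geo_series <- function(x, ...) {
  cat(sprintf("<geo_series> %d steps [%s], %d missing\n",
              nrow(x), attr(x, "units"), sum(is.na(x$value))))
  NextMethod()
}

#' Area-mean time series over a region
#'
#' Averages unmasked cells inside `reg` at every time step. The default
#' weighting is by the cosine of latitude (cell area on a regular grid is
#' proportional to `cos(lat)`); unweighted averaging is provided because
#' mapped-product analyses frequently omit the weighting.
#'
#' @param field A [geo_field()].
#' @param reg A [region()].
#' @param weighting `"coslat"` (default) or `"none"`.
#' @return A [geo_series()]; time steps with zero unmasked cells are `NA`.
#' @export
region_mean <- function(field, reg, weighting = c("coslat", "none")) {
  weighting <- match.arg(weighting)
  sub <- subset(field, reg)
  nlat <- length(sub$grid$lats)
  nlon <- length(sub$grid$lons)
  w <- if (weighting == "coslat") cos(sub$grid$lats * pi / 180) else rep(1, nlat)
  wmat <- matrix(w, nlat, nlon)
  vals <- vapply(seq_along(sub$times), function(t) {
    z <- field_slice(sub, t)
    ok <- !is.na(z)
    if (!any(ok)) return(NA_real_)
    sum(z[ok] * wmat[ok]) / sum(wmat[ok])
  }, numeric(1))
  geo_series(sub$times, vals, units = field$units)
}

#' Fraction of valid (unmasked) cells per time step
#'
#' Coverage diagnostic for gappy satellite fields (e.g. cloud-masked ocean
#' color): the proportion of cells inside the region carrying data at each
#' time step.
#'
#' @inheritParams region_mean
#' @return A [geo_series()] with values in `[0, 1]`.
#' @export
valid_pixel_fraction <- function(field, reg) {
  sub <- suppressWarnings(subset(field, reg))
  frac <- vapply(seq_along(sub$times), function(t) {
    mean(!is.na(field_slice(sub, t)))
  }, numeric(1))
  geo_series(sub$times, frac, units = "1")
}

## ---- temporal aggregation -------------------------------------------------

target_bin <- function(times, target) {
  switch(target,
    daily   = as.Date(times),
    "8day"  = {
      d <- as.Date(times)
      yr <- as.integer(format(d, "%Y"))
      as.Date(paste0(yr, "-01-01")) + 8 * (eight_day_step(d) - 1L)
    },
    monthly = as.Date(paste0(format(as.Date(times), "%Y-%m"), "-01")),
    stop("unknown target resolution: ", target)
  )
}

target_width_days <- function(target) {
  switch(target, daily = 1, "8day" = 8, monthly = 28)
}

#' Aggregate a series or field to a coarser time resolution
#'
#' Simple (unweighted) mean of unmasked samples per target bin; bins whose
#' samples are all missing come out missing. Supported targets: `"daily"`
#' (e.g. from 3-hourly), `"8day"` and `"monthly"` (e.g. from daily).
#'
#' @param x A [geo_series()] or [geo_field()].
#' @param target One of `"daily"`, `"8day"`, `"monthly"`.
#' @return Object of the same class at the target resolution.
#' @export
resample_time <- function(x, target = c("monthly", "8day", "daily")) {
  target <- match.arg(target)
  UseMethod("resample_time")
}

check_finer <- function(times, target) {
  if (length(times) < 2) stop("need at least 2 time steps to resample")
  step_days <- stats::median(as.numeric(difftime(times[-1], times[-length(times)],
                                                 units = "days")))
  if (step_days >= target_width_days(target)) {
    stop("source resolution (", signif(step_days, 3),
         " days) is not finer than target '", target, "'")
  }
}

#' @export
resample_time.geo_series <- function(x, target = c("monthly", "8day", "daily")) {
  target <- match.arg(target)
  check_finer(x$time, target)
  bin <- target_bin(x$time, target)
  ub <- sort(unique(bin))
  agg <- vapply(ub, function(b) {
    v <- x$value[bin == b]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  geo_series(ub, agg, units = attr(x, "units"))
}

#' @export
resample_time.geo_field <- function(x, target = c("monthly", "8day", "daily")) {
  target <- match.arg(target)
  check_finer(x$times, target)
  bin <- target_bin(x$times, target)
  ub <- sort(unique(bin))
  dims <- dim(x$values)
  out <- array(NA_real_, dim = c(length(ub), dims[2], dims[3]))
  for (i in seq_along(ub)) {
    sl <- x$values[bin == ub[i], , , drop = FALSE]
    m <- apply(sl, c(2, 3), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    out[i, , ] <- m
  }
  geo_field(out, x$grid, ub, units = x$units, var = x$var)
}

## ---- 8-day calendar -------------------------------------------------------

#' 8-day compositing calendar
#'
#' Mapped ocean-color products are composited on a fixed 46-step calendar:
#' each year is cut into 46 8-day steps starting 1 January, the 46th step
#' absorbing the 5- or 6-day year-end remainder. `eight_day_step` maps dates
#' to step-of-year (1-46); `eight_day_dates` generates the step start dates
#' for a span of years.
#'
#' @param dates Vector of `Date`.
#' @return Integer step-of-year in `1:46`.
#' @export
eight_day_step <- function(dates) {
  doy <- as.integer(format(as.Date(dates), "%j"))
  pmin((doy - 1L) %/% 8L + 1L, 46L)
}

#' @rdname eight_day_step
#' @param start_year,n_years First year and number of years to cover.
#' @return For `eight_day_dates`, a `Date` vector of `46 * n_years` step
#'   start dates.
#' @export
eight_day_dates <- function(start_year, n_years) {
  as.Date(unlist(lapply(seq_len(n_years) - 1L, function(k) {
    as.Date(paste0(start_year + k, "-01-01")) + 8 * (0:45)
  })), origin = "1970-01-01")
}

#' Day-of-year with 29 February pooled into 28 February
#'
#' Used as the period key of daily climatologies so that no period is
#' undersampled: in leap years day 60 (Feb 29) maps to 59 and later days
#' shift down by one, giving 365 periods for every year.
#'
#' @param dates Vector of `Date`.
#' @return Integer day-of-year in `1:365`.
#' @export
pooled_doy <- function(dates) {
  d <- as.Date(dates)
  doy <- as.integer(format(d, "%j"))
  leap <- format(d, "%m-%d") >= "02-29" &
    as.integer(format(d, "%Y")) %% 4 == 0 &
    (as.integer(format(d, "%Y")) %% 100 != 0 | as.integer(format(d, "%Y")) %% 400 == 0)
  ifelse(leap, doy - 1L, doy)
}
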