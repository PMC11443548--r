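## Climatologies, anomalies, trends and small time-series utilities.

period_key <- function(times, period_kind) {
  switch(period_kind,
    month  = as.integer(format(as.Date(times), "%m")),
    "8day" = eight_day_step(times),
    doy    = pooled_doy(times),
    stop("unknown period_kind: ", period_kind)
  )
}

n_periods <- function(period_kind) {
  switch(period_kind, month = 12L, "8day" = 46L, doy = 365L)
}

#' Per-period-of-year climatology with an explicit reference period
#'
#' Computes the long-term mean and standard deviation for each period of the
#' year (calendar month, 8-day step, or day-of-year with 29 February pooled
#' into 28 February) using only samples inside the stated reference period.
#' Reference periods are dataset-specific configuration: multi-sensor
#' archives start in different years, and anomalies are only comparable
#' against the climatology of their own record.
#'
#' Periods sampled fewer than `min_samples` times are flagged and yield
#' missing anomalies downstream.
#'
#' @param x A [geo_series()] or [geo_field()].
#' @param period_kind `"month"`, `"8day"` or `"doy"`.
#' @param reference_period Length-2 `Date` vector (start, end), inclusive.
#'   Defaults to the full data span. Must lie within the data span and cover
#'   at least 2 years.
#' @param min_samples Minimum samples per period (default 5).
#' @return An object of class `climatology` with per-period `mean`, `sd`,
#'   `n` and a `flagged` indicator. For fields, `mean` and `sd` are
#'   `(period, lat, lon)` arrays.
#' @export
build_climatology <- function(x, period_kind = c("month", "8day", "doy"),
                              reference_period = NULL, min_samples = 5L) {
  period_kind <- match.arg(period_kind)
  UseMethod("build_climatology")
}

check_reference <- function(times, reference_period) {
  times <- as.Date(times)
  if (is.null(reference_period)) reference_period <- range(times)
  reference_period <- as.Date(reference_period)
  # one period (a month) of slack at either end: reference bounds are usually
  # quoted as whole months/years while the data axis carries period starts
  if (reference_period[1] < min(times) - 31 || reference_period[2] > max(times) + 31) {
    stop("reference period extends outside the data span")
  }
  if (as.numeric(reference_period[2] - reference_period[1]) < 365) {
    stop("reference period must span at least 2 years")
  }
  reference_period
}

#' @export
build_climatology.geo_series <- function(x, period_kind = c("month", "8day", "doy"),
                                         reference_period = NULL, min_samples = 5L) {
  period_kind <- match.arg(period_kind)
  reference_period <- check_reference(x$time, reference_period)
  inref <- as.Date(x$time) >= reference_period[1] & as.Date(x$time) <= reference_period[2]
  key <- period_key(x$time, period_kind)
  np <- n_periods(period_kind)
  m <- s <- rep(NA_real_, np)
  n <- integer(np)
  for (p in seq_len(np)) {
    v <- x$value[inref & key == p]
    v <- v[!is.na(v)]
    n[p] <- length(v)
    if (n[p] >= 1) m[p] <- mean(v)
    if (n[p] >= 2) s[p] <- stats::sd(v)
  }
  structure(list(period_kind = period_kind, mean = m, sd = s, n = n,
                 flagged = n < min_samples,
                 reference_period = reference_period, min_samples = min_samples),
            class = "climatology")
}

#' @export
build_climatology.geo_field <- function(x, period_kind = c("month", "8day", "doy"),
                                        reference_period = NULL, min_samples = 5L) {
  period_kind <- match.arg(period_kind)
  reference_period <- check_reference(x$times, reference_period)
  inref <- as.Date(x$times) >= reference_period[1] & as.Date(x$times) <= reference_period[2]
  key <- period_key(x$times, period_kind)
  np <- n_periods(period_kind)
  dims <- dim(x$values)
  m <- s <- array(NA_real_, dim = c(np, dims[2], dims[3]))
  n <- array(0L, dim = c(np, dims[2], dims[3]))
  for (p in seq_len(np)) {
    sel <- inref & key == p
    if (!any(sel)) next
    sl <- x$values[sel, , , drop = FALSE]
    n[p, , ] <- apply(sl, c(2, 3), function(v) sum(!is.na(v)))
    m[p, , ] <- apply(sl, c(2, 3), function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_)
    s[p, , ] <- apply(sl, c(2, 3), function(v) if (sum(!is.na(v)) >= 2) stats::sd(v, na.rm = TRUE) else NA_real_)
  }
  structure(list(period_kind = period_kind, mean = m, sd = s, n = n,
                 flagged = n < min_samples,
                 reference_period = reference_period, min_samples = min_samples),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> %s, reference %s..%s, %d/%d periods flagged (min_samples=%d)\n",
              x$period_kind, x$reference_period[1], x$reference_period[2],
              sum(x$flagged), length(x$flagged) / max(1, prod(dim(x$flagged)[-1] %||% 1)),
              x$min_samples))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

anomaly_parts <- function(x, clim) {
  if (inherits(x, "geo_series")) {
    key <- period_key(x$time, clim$period_kind)
    if (is.array(clim$mean) && length(dim(clim$mean)) == 3) {
      stop("climatology was built from a field; series input expected a series climatology")
    }
    list(values = x$value, mean = clim$mean[key], sd = clim$sd[key],
         flagged = clim$flagged[key])
  } else if (inherits(x, "geo_field")) {
    key <- period_key(x$times, clim$period_kind)
    dims <- dim(x$values)
    m <- clim$mean[key, , , drop = FALSE]
    s <- clim$sd[key, , , drop = FALSE]
    f <- clim$flagged[key, , , drop = FALSE]
    list(values = x$values, mean = m, sd = s, flagged = f)
  } else {
    stop("x must be a geo_series or geo_field")
  }
}

wrap_like <- function(x, values, units) {
  if (inherits(x, "geo_series")) {
    geo_series(x$time, values, units = units)
  } else {
    geo_field(array(values, dim = dim(x$values)), x$grid, x$times,
              units = units, var = x$var)
  }
}

#' Relative anomaly (% above the climatological mean)
#'
#' `100 * (x - mean) / mean` against the matching period of `clim`.
#' Non-positive or flagged climatological means give missing values rather
#' than infinities.
#'
#' @param x A [geo_series()] or [geo_field()] at the climatology's resolution.
#' @param clim A [build_climatology()] result.
#' @return Same class as `x`, in percent.
#' @export
relative_anomaly <- function(x, clim) {
  p <- anomaly_parts(x, clim)
  bad <- is.na(p$mean) | p$mean <= 0 | p$flagged
  out <- 100 * (p$values - p$mean) / p$mean
  out[bad] <- NA_real_
  wrap_like(x, out, units = "%")
}

#' Standardized anomaly (departure in climatological-SD units)
#'
#' `(x - mean) / sd` against the matching period of `clim`. Zero, missing or
#' flagged climatological SDs give missing values.
#'
#' @inheritParams relative_anomaly
#' @return Same class as `x`, dimensionless (SD units).
#' @export
standardized_anomaly <- function(x, clim) {
  p <- anomaly_parts(x, clim)
  bad <- is.na(p$sd) | p$sd == 0 | p$flagged
  out <- (p$values - p$mean) / p$sd
  out[bad] <- NA_real_
  wrap_like(x, out, units = "sd")
}

#' Fill gaps in a series by linear interpolation
#'
#' Interior gaps are linearly interpolated in time; leading/trailing gaps are
#' filled with the nearest observed value (pure interpolation cannot extend
#' beyond the data). The output has no missing values, as required by the
#' cumulative-sum phenology detector, and the operation is idempotent.
#'
#' @param series A [geo_series()] with at least 2 non-missing values.
#' @return A gap-free [geo_series()].
#' @export
fill_gaps_linear <- function(series) {
  stopifnot(inherits(series, "geo_series"))
  ok <- !is.na(series$value)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to interpolate")
  if (all(ok)) return(series)
  t_num <- as.numeric(series$time)
  filled <- stats::approx(t_num[ok], series$value[ok], xout = t_num,
                          method = "linear", rule = 2)$y
  geo_series(series$time, filled, units = attr(series, "units"))
}

#' Centered moving mean
#'
#' Mean over the available samples in a centered window of `window` periods.
#' For even windows the extra sample is taken on the trailing side
#' (offsets `-(w/2 - 1) .. w/2`). Missing samples are simply excluded;
#' windows with no samples give `NA`.
#'
#' @param series A [geo_series()].
#' @param window Window length in periods (>= 1).
#' @return A smoothed [geo_series()].
#' @export
moving_mean <- function(series, window) {
  stopifnot(inherits(series, "geo_series"))
  if (window < 1) stop("window must be >= 1")
  if (window == 1) return(series)
  n <- nrow(series)
  k1 <- floor((window - 1) / 2)
  k2 <- window - 1 - k1
  out <- vapply(seq_len(n), function(i) {
    v <- series$value[max(1, i - k1):min(n, i + k2)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  geo_series(series$time, out, units = attr(series, "units"))
}

#' Time in decades since the first sample
#'
#' The common time coordinate of trend generation and estimation: decimal
#' years (365.2425-day years) since the first time stamp, divided by 10.
#'
#' @param times Vector of `Date`.
#' @return Numeric vector (decades).
#' @export
decades_since_start <- function(times) {
  times <- as.Date(times)
  as.numeric(times - times[1]) / 3652.425
}

#' Per-pixel decadal trend with significance masking
#'
#' Ordinary least-squares slope of each pixel's series against time in
#' decades, with the classical two-sided t-test p-value for slope != 0
#' (no serial-autocorrelation correction). Pixels with `p >= 0.05` are
#' flagged `masked`; pixels with fewer than `min_months` samples are missing
#' and masked.
#'
#' @param x A monthly [geo_field()] or [geo_series()].
#' @param min_months Minimum samples per pixel (default 24).
#' @param alpha Significance level for masking (default 0.05).
#' @return For fields, a `trend_result` list of `(lat, lon)` matrices
#'   `slope` (units/decade), `p_value` and `masked`; for series, a one-row
#'   data.frame.
#' @export
decadal_trend <- function(x, min_months = 24L, alpha = 0.05) {
  UseMethod("decadal_trend")
}

ols_trend <- function(tdec, y) {
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < 3) return(c(NA_real_, NA_real_))
  t1 <- tdec[ok]
  y1 <- y[ok]
  tm <- t1 - mean(t1)
  ym <- y1 - mean(y1)
  sxx <- sum(tm^2)
  slope <- sum(tm * ym) / sxx
  resid <- ym - slope * tm
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  p <- if (se == 0) {
    if (slope == 0) 1 else 0  # noiseless series: exact fit
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  c(slope, p)
}

#' @export
decadal_trend.geo_series <- function(x, min_months = 24L, alpha = 0.05) {
  ok <- sum(!is.na(x$value))
  tdec <- decades_since_start(x$time)
  if (ok < min_months) {
    res <- c(NA_real_, NA_real_)
  } else {
    res <- ols_trend(tdec, x$value)
  }
  data.frame(slope = res[1], p_value = res[2],
             masked = is.na(res[2]) | res[2] >= alpha)
}

#' @export
decadal_trend.geo_field <- function(x, min_months = 24L, alpha = 0.05) {
  dims <- dim(x$values)
  nt <- dims[1]
  npix <- dims[2] * dims[3]
  Y <- matrix(x$values, nt, npix)
  tdec <- decades_since_start(x$times)
  obs <- !is.na(Y)
  n <- colSums(obs)
  Tm <- matrix(tdec, nt, npix)
  Tm[!obs] <- NA
  tbar <- colMeans(Tm, na.rm = TRUE)
  ybar <- colMeans(Y, na.rm = TRUE)
  Tc <- sweep(Tm, 2, tbar)
  Yc <- sweep(Y, 2, ybar)
  Tc[!obs] <- 0
  Yc[!obs] <- 0
  sxx <- colSums(Tc^2)
  slope <- colSums(Tc * Yc) / sxx
  resid <- Yc - sweep(Tc, 2, slope, `*`)
  s2 <- colSums(resid^2) / pmax(n - 2, 1)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  p[se == 0] <- ifelse(slope[se == 0] == 0, 1, 0)
  bad <- n < min_months
  slope[bad] <- NA_real_
  p[bad] <- NA_real_
  masked <- is.na(p) | p >= alpha
  shape <- function(v) matrix(v, dims[2], dims[3])
  structure(list(slope = shape(slope), p_value = shape(p), masked = shape(masked),
                 grid = x$grid, alpha = alpha),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %d x %d pixels, %.1f%% masked at p >= %.2f\n",
              nrow(x$slope), ncol(x$slope), 100 * mean(x$masked), x$alpha))
  invisible(x)
}

#' Total dust wet deposition from size-binned fluxes
#'
#' Reanalysis dust deposition comes as five size-bin fluxes; the total is
#' their elementwise sum. A time step missing in any bin is missing in the
#' total (never zero-filled).
#'
#' @param bins List of exactly five aligned [geo_series()].
#' @return A [geo_series()] of the summed flux.
#' @export
total_wet_deposition <- function(bins) {
  if (length(bins) != 5) stop("expected exactly 5 size-bin series, got ", length(bins))
  stopifnot(all(vapply(bins, inherits, logical(1), "geo_series")))
  t0 <- bins[[1]]$time
  for (b in bins[-1]) {
    if (!identical(as.Date(b$time), as.Date(t0))) stop("size-bin series are not time-aligned")
  }
  vals <- rowSums(do.call(cbind, lapply(bins, `[[`, "value")))  # NA if any bin NA
  geo_series(t0, vals, units = attr(bins[[1]], "units"))
}
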