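## Seeded synthetic-data generators with recorded ground truth.
##
## Every generator draws all randomness from a single `seed` argument and
## restores the caller's RNG state, so identical calls are bit-identical and
## generators never interfere with surrounding code.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards. All generators in the package draw their randomness
#' through this helper, which is what makes identical calls bit-identical
#' without disturbing surrounding simulations. A `NULL` seed evaluates the
#' code against the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## ---- truth constructors ---------------------------------------------------

#' Ground truth for one planted bloom
#'
#' Describes one planted bloom on the 46-step 8-day calendar, in absolute
#' step indices counted from the start of the series. The elevated window
#' spans steps `initiation` to `termination - 1`: `termination` is the first
#' step at which the series is back at baseline, matching the convention of
#' the phenology detector (termination = first step below threshold after
#' the peak), so that recovery can be scored index-for-index.
#'
#' @param initiation,peak,termination Absolute 8-day step indices with
#'   `initiation < peak < termination`.
#' @param amplitude Elevation above baseline at the plateau (mg m-3), > 0.
#' @param baseline Background concentration (mg m-3), > 0.
#' @param season_label Optional label of the season the bloom belongs to.
#' @return A `bloom_truth` list.
#' @export
bloom_truth <- function(initiation, peak, termination, amplitude, baseline,
                        season_label = NA_character_) {
  if (!(initiation < peak && peak < termination)) {
    stop("need initiation < peak < termination (termination is the first step back at baseline)")
  }
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (baseline <= 0) stop("baseline must be > 0")
  structure(list(initiation = as.integer(initiation), peak = as.integer(peak),
                 termination = as.integer(termination),
                 amplitude = amplitude, baseline = baseline,
                 season_label = season_label),
            class = "bloom_truth")
}

#' Ground truth for one planted Gaussian eddy
#'
#' @param center_lat,center_lon Center (degrees).
#' @param amplitude Signed SLA extremum (m); positive = anticyclonic
#'   (sea-level elevation, Southern Hemisphere convention), negative =
#'   cyclonic.
#' @param radius Gaussian e-folding radius (km), > 0.
#' @return An `eddy_truth` list with derived `polarity`.
#' @export
eddy_truth <- function(center_lat, center_lon, amplitude, radius) {
  if (radius <= 0) stop("radius must be > 0")
  if (amplitude == 0) stop("amplitude must be non-zero")
  structure(list(center_lat = center_lat, center_lon = center_lon,
                 amplitude = amplitude, radius = radius,
                 polarity = if (amplitude > 0) "anticyclonic" else "cyclonic"),
            class = "eddy_truth")
}

#' Ground truth for one thermocline profile
#'
#' @param mld_true Mixed-layer depth (m), > 10 (below the 10 m reference
#'   depth of the detection criterion).
#' @param surface_temp Mixed-layer temperature (degC).
#' @param thermocline_width tanh transition width (m), > 0.
#' @return A `profile_truth` list.
#' @export
profile_truth <- function(mld_true, surface_temp, thermocline_width) {
  if (mld_true <= 10) stop("mld_true must exceed the 10 m reference depth")
  if (thermocline_width <= 0) stop("thermocline_width must be > 0")
  structure(list(mld_true = mld_true, surface_temp = surface_temp,
                 thermocline_width = thermocline_width),
            class = "profile_truth")
}

#' Ground truth for a planted linear trend
#'
#' @param slope Trend in units per decade.
#' @param intercept Level at the first time step (units).
#' @param noise_sd Additive Gaussian noise SD (units), >= 0.
#' @return A `trend_truth` list.
#' @export
trend_truth <- function(slope, intercept, noise_sd = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(slope = slope, intercept = intercept, noise_sd = noise_sd),
            class = "trend_truth")
}

## ---- chlorophyll series ---------------------------------------------------

#' Synthetic 8-day chlorophyll series with planted blooms
#'
#' Emulates a multi-year 8-day ocean-color series: a positive baseline,
#' planted bloom elevations with known timings, multiplicative lognormal
#' noise (mean-one, so `noise_cv` is the coefficient of variation), and a
#' missing-data mask emulating cloud gaps. Exactly `round(gap_fraction * N)`
#' steps are masked; masking is constrained so that every planted bloom
#' window keeps at least one unmasked step.
#'
#' @param n_years Number of years (>= 2); the series has `46 * n_years` steps.
#' @param baseline Background concentration (mg m-3).
#' @param blooms List of [bloom_truth()] objects; windows must not overlap.
#' @param gap_fraction Fraction of steps masked at random in `[0, 1)`.
#' @param noise_cv Coefficient of variation of the lognormal noise (0 = none).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param start_year First calendar year (used for the date axis).
#' @param shape `"flat"` plants a plateau of height `amplitude`; `"peaked"`
#'   additionally raises the single step at `peak` by another
#'   `amplitude / 2`, so the seasonal maximum is unambiguous under noise.
#' @param gap_mode `"random"` masks independent steps; `"blocked"` masks
#'   contiguous runs (median length 3) to emulate multi-day cloud cover.
#' @return A list with `series` (a [geo_series()]), `truth` (the bloom list)
#'   and `masked_steps` (integer indices).
#' @export
make_chl_series <- function(n_years, baseline = 0.1, blooms = list(),
                            gap_fraction = 0, noise_cv = 0, seed = NULL,
                            start_year = 1998,
                            shape = c("flat", "peaked"),
                            gap_mode = c("random", "blocked")) {
  shape <- match.arg(shape)
  gap_mode <- match.arg(gap_mode)
  if (n_years < 2) stop("n_years must be >= 2")
  if (gap_fraction < 0 || gap_fraction >= 1) stop("gap_fraction must be in [0, 1)")
  n <- 46L * as.integer(n_years)
  windows <- lapply(blooms, function(b) {
    stopifnot(inherits(b, "bloom_truth"))
    if (b$initiation < 1 || b$termination > n + 1) stop("bloom window outside the series")
    seq(b$initiation, b$termination - 1L)
  })
  if (length(windows) > 1) {
    all_steps <- unlist(windows)
    if (anyDuplicated(all_steps)) stop("overlapping bloom windows: each step may belong to at most one bloom")
  }
  x <- rep(baseline, n)
  for (i in seq_along(blooms)) {
    b <- blooms[[i]]
    x[windows[[i]]] <- baseline + b$amplitude
    if (shape == "peaked") x[b$peak] <- baseline + 1.5 * b$amplitude
  }
  with_seed(seed, {
    if (noise_cv > 0) {
      sigma <- sqrt(log(1 + noise_cv^2))
      x <- x * exp(stats::rnorm(n, -sigma^2 / 2, sigma))  # mean-one lognormal
    }
    n_gap <- round(gap_fraction * n)
    masked <- integer(0)
    if (n_gap > 0) {
      masked <- if (gap_mode == "random") {
        sample.int(n, n_gap)
      } else {
        blocked_gaps(n, n_gap)
      }
      # cloud gaps must not erase a planted bloom entirely
      for (w in windows) {
        if (all(w %in% masked)) {
          keep <- sample(w, 1)
          spare <- setdiff(seq_len(n), union(masked, unlist(windows)))
          masked <- setdiff(masked, keep)
          if (length(spare) > 0) masked <- c(masked, sample(spare, 1))
        }
      }
      masked <- sort(masked)
      x[masked] <- NA_real_
    }
    list(series = geo_series(eight_day_dates(start_year, n_years), x,
                             units = "mg m-3"),
         truth = blooms,
         masked_steps = masked)
  })
}

blocked_gaps <- function(n, n_gap) {
  masked <- integer(0)
  while (length(masked) < n_gap) {
    len <- sample(2:4, 1)
    start <- sample.int(n - len + 1L, 1)
    masked <- unique(c(masked, seq(start, start + len - 1L)))
  }
  sort(masked[seq_len(n_gap)])
}

## ---- SLA fields and currents ----------------------------------------------

km_per_deg <- 111.195  # pi * 6371 / 180

eddy_distance_km <- function(grid, clat, clon) {
  dlat <- outer(grid$lats - clat, rep(1, length(grid$lons)))
  dlon <- outer(rep(1, length(grid$lats)), grid$lons - clon)
  sqrt((km_per_deg * dlat)^2 + (km_per_deg * cos(clat * pi / 180) * dlon)^2)
}

#' Synthetic sea-level-anomaly field with planted Gaussian eddies
#'
#' The field is the sum of Gaussian bumps
#' `A_k * exp(-d_k^2 / (2 * r_k^2))` (distance `d_k` to the k-th center in
#' km) plus optional additive Gaussian noise, replicated identically at every
#' requested time (a stationary eddy field). For clean recovery tests keep
#' pairwise center separations above `3 * (r_i + r_j)`.
#'
#' @param grid A [geo_grid()].
#' @param eddies List of [eddy_truth()] objects with centers inside the grid.
#' @param noise_sd Additive noise SD (m).
#' @param seed Integer seed.
#' @param times Date vector (default one slice).
#' @return A list with `field` (a [geo_field()], units m) and `truth`.
#' @export
make_sla_field <- function(grid, eddies = list(), noise_sd = 0, seed = NULL,
                           times = as.Date("2019-12-01")) {
  stopifnot(inherits(grid, "geo_grid"))
  base <- matrix(0, length(grid$lats), length(grid$lons))
  for (e in eddies) {
    stopifnot(inherits(e, "eddy_truth"))
    if (e$center_lat < min(grid$lats) || e$center_lat > max(grid$lats) ||
        e$center_lon < min(grid$lons) || e$center_lon > max(grid$lons)) {
      stop("eddy center outside the grid")
    }
    d <- eddy_distance_km(grid, e$center_lat, e$center_lon)
    base <- base + e$amplitude * exp(-d^2 / (2 * e$radius^2))
  }
  nt <- length(times)
  vals <- with_seed(seed, {
    out <- array(NA_real_, dim = c(nt, dim(base)))
    for (t in seq_len(nt)) {
      z <- base
      if (noise_sd > 0) z <- z + matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base))
      out[t, , ] <- z
    }
    out
  })
  list(field = geo_field(vals, grid, times, units = "m", var = "sla"),
       truth = eddies)
}

#' Geostrophic surface currents from a sea-level-anomaly field
#'
#' Under geostrophy the surface current is proportional to the sea-surface
#' slope: `u = -(g/f) * d(eta)/dy`, `v = (g/f) * d(eta)/dx`, with `f` the
#' Coriolis parameter. Gradients are centered differences on the sphere
#' (`dy = R dlat`, `dx = R cos(lat) dlon`); boundary cells, where a centered
#' difference is unavailable, are masked.
#'
#' @param sla A [geo_field()] of sea level anomaly (m). All grid latitudes
#'   must satisfy `|lat| > 5` degrees (the geostrophic balance degenerates at
#'   the equator where `f -> 0`).
#' @param coriolis_lat Optional f-plane latitude (degrees): if given, `f` is
#'   evaluated at this single latitude instead of per grid row.
#' @return A list of two [geo_field()]s, `u` and `v` (m/s).
#' @export
make_geostrophic_currents <- function(sla, coriolis_lat = NULL) {
  stopifnot(inherits(sla, "geo_field"))
  lats <- sla$grid$lats
  if (any(abs(lats) <= 5)) {
    stop("grid latitudes within 5 degrees of the equator: f -> 0 breaks geostrophy")
  }
  g <- 9.81
  omega <- 7.292115e-5
  f <- if (is.null(coriolis_lat)) {
    2 * omega * sin(lats * pi / 180)
  } else {
    rep(2 * omega * sin(coriolis_lat * pi / 180), length(lats))
  }
  dlat <- stats::median(diff(lats))
  dlon <- stats::median(diff(sla$grid$lons))
  dy <- km_per_deg * 1000 * dlat
  dx <- km_per_deg * 1000 * cos(lats * pi / 180) * dlon
  nt <- length(sla$times)
  nlat <- length(lats)
  nlon <- length(sla$grid$lons)
  u <- array(NA_real_, dim = c(nt, nlat, nlon))
  v <- array(NA_real_, dim = c(nt, nlat, nlon))
  for (t in seq_len(nt)) {
    z <- field_slice(sla, t)
    detay <- matrix(NA_real_, nlat, nlon)
    detax <- matrix(NA_real_, nlat, nlon)
    detay[2:(nlat - 1), ] <- (z[3:nlat, ] - z[1:(nlat - 2), ]) / (2 * dy)
    detax[, 2:(nlon - 1)] <- (z[, 3:nlon] - z[, 1:(nlon - 2)]) / (2 * matrix(dx, nlat, nlon - 2))
    u[t, , ] <- -(g / f) * detay
    v[t, , ] <- (g / f) * detax
  }
  list(u = geo_field(u, sla$grid, sla$times, units = "m s-1", var = "u"),
       v = geo_field(v, sla$grid, sla$times, units = "m s-1", var = "v"))
}

## ---- profiles -------------------------------------------------------------

new_profile <- function(df, float_id = "synthetic", time = as.Date("2019-12-01"),
                        vertical = c("depth", "pressure")) {
  vertical <- match.arg(vertical)
  stopifnot(all(c(vertical, "temperature", "qc") %in% names(df)))
  if (is.unsorted(df[[vertical]], strictly = TRUE)) {
    stop("profile ", vertical, " must be strictly increasing")
  }
  structure(df, class = c("profile", "data.frame"),
            float_id = float_id, time = time, vertical = vertical)
}

#' Synthetic thermocline temperature profile
#'
#' Temperature is near-uniform at `surface_temp` through the mixed layer and
#' declines below it along a tanh ramp of width `thermocline_width` and total
#' contrast `delta_total`. The ramp is placed so that the profile crosses
#' `surface_temp - 0.2` degC exactly at `mld_true`, i.e. the planted truth is
#' expressed in the same 0.2 degC criterion the detector applies.
#'
#' @param truth A [profile_truth()].
#' @param dz Vertical sample spacing (m), > 0.
#' @param noise_sd Additive Gaussian noise on temperature (degC).
#' @param seed Integer seed.
#' @param delta_total Total temperature drop across the thermocline (degC).
#' @param max_depth Deepest sample (m); defaults to comfortably below the
#'   thermocline (`mld_true + 4 * thermocline_width`, at least 200 m).
#' @return A `profile` data.frame (`depth`, `temperature`, `qc` all-good).
#' @export
make_profile <- function(truth, dz = 2, noise_sd = 0, seed = NULL,
                         delta_total = 8, max_depth = NULL) {
  stopifnot(inherits(truth, "profile_truth"))
  if (dz <= 0) stop("dz must be > 0")
  if (is.null(max_depth)) {
    max_depth <- max(200, truth$mld_true + 4 * truth$thermocline_width)
  }
  depth <- seq(dz, max_depth, by = dz)
  w <- truth$thermocline_width
  # place the ramp so that T(mld_true) = surface_temp - 0.2 exactly
  z0 <- truth$mld_true - w * atanh(0.4 / delta_total - 1)
  temp <- truth$surface_temp - delta_total * (1 + tanh((depth - z0) / w)) / 2
  temp <- with_seed(seed, temp + if (noise_sd > 0) stats::rnorm(length(depth), 0, noise_sd) else 0)
  new_profile(data.frame(depth = depth, temperature = temp, qc = 1L),
              vertical = "depth")
}

## ---- event series and trend fields ----------------------------------------

#' Synthetic daily series with planted step events
#'
#' Emulates event-like aerosol or precipitation records: a constant base
#' level with step elevations of stated magnitude over stated windows, plus
#' optional additive Gaussian noise.
#'
#' @param n_days Series length in days.
#' @param base_level Background level.
#' @param events List of `list(start, length, magnitude)` with windows inside
#'   the series.
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @param start_date First day.
#' @param units Units string carried on the output.
#' @return A list with `series` (a daily [geo_series()]) and `truth`
#'   (a data.frame of the planted events).
#' @export
make_event_series <- function(n_days, base_level = 0, events = list(),
                              noise_sd = 0, seed = NULL,
                              start_date = as.Date("2003-01-01"), units = "") {
  x <- rep(base_level, n_days)
  for (e in events) {
    idx <- seq(e$start, e$start + e$length - 1L)
    if (min(idx) < 1 || max(idx) > n_days) stop("event window outside the series")
    x[idx] <- x[idx] + e$magnitude
  }
  x <- with_seed(seed, x + if (noise_sd > 0) stats::rnorm(n_days, 0, noise_sd) else 0)
  truth <- if (length(events)) {
    data.frame(start = vapply(events, `[[`, numeric(1), "start"),
               length = vapply(events, `[[`, numeric(1), "length"),
               magnitude = vapply(events, `[[`, numeric(1), "magnitude"))
  } else {
    data.frame(start = numeric(0), length = numeric(0), magnitude = numeric(0))
  }
  list(series = geo_series(start_date + seq_len(n_days) - 1L, x, units = units),
       truth = truth)
}

#' Monthly field with a planted linear trend
#'
#' Every pixel follows `intercept + slope * t + noise`, with `t` in decades
#' since the first month, computed from the calendar axis by
#' [decades_since_start()] -- the same time coordinate the trend estimator
#' uses, so the planted slope is the estimand without unit juggling.
#'
#' @param grid A [geo_grid()].
#' @param truth A [trend_truth()].
#' @param n_months Number of months (>= 24).
#' @param seed Integer seed.
#' @param start_date First month.
#' @return A list with `field` (a monthly [geo_field()]) and `truth`.
#' @export
make_trend_field <- function(grid, truth, n_months, seed = NULL,
                             start_date = as.Date("1980-01-01")) {
  stopifnot(inherits(grid, "geo_grid"), inherits(truth, "trend_truth"))
  if (n_months < 24) stop("n_months must be >= 24")
  times <- seq(start_date, by = "month", length.out = n_months)
  tdec <- decades_since_start(times)
  nlat <- length(grid$lats)
  nlon <- length(grid$lons)
  vals <- with_seed(seed, {
    out <- array(rep(truth$intercept + truth$slope * tdec, times = nlat * nlon),
                 dim = c(n_months, nlat, nlon))
    if (truth$noise_sd > 0) {
      out <- out + array(stats::rnorm(length(out), 0, truth$noise_sd), dim = dim(out))
    }
    out
  })
  list(field = geo_field(vals, grid, times, var = "trend_var"), truth = truth)
}
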