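## Bloom phenology from 8-day chlorophyll series: threshold-referenced
## cumulative sums of anomalies, per-season detection over the austral
## spring/summer window, and a moving-box robustness scan.

#' Phenology configuration
#'
#' @param threshold_percent Fractional increment over the long-term median
#'   defining the bloom threshold (default 0.20, i.e. median x 1.2).
#'   Values of 0.05-0.15 are in use elsewhere and may be supplied here.
#' @param season_start_month First month of the detection window (default
#'   October: the window isolates austral spring/summer and excludes
#'   secondary winter growth).
#' @param season_end_month Last month of the window in the following year
#'   (default May).
#' @return A `pheno_config` list.
#' @export
pheno_config <- function(threshold_percent = 0.20,
                         season_start_month = 10L,
                         season_end_month = 5L) {
  if (threshold_percent <= 0 || threshold_percent >= 1) {
    stop("threshold_percent must be in (0, 1)")
  }
  if (season_start_month <= season_end_month) {
    stop("the season window must wrap the year end (start month > end month)")
  }
  structure(list(threshold_percent = threshold_percent,
                 season_start_month = as.integer(season_start_month),
                 season_end_month = as.integer(season_end_month)),
            class = "pheno_config")
}

#' Bloom threshold: long-term median plus a fixed percentage
#'
#' `median(series) * (1 + threshold_percent)`, computed once over the entire
#' multi-year series (not per season). The series should be gap-free
#' (run [fill_gaps_linear()] first).
#'
#' @param series A [geo_series()] or numeric vector.
#' @param config A [pheno_config()].
#' @return The threshold, in the series' units.
#' @export
compute_threshold <- function(series, config = pheno_config()) {
  x <- if (inherits(series, "geo_series")) series$value else as.numeric(series)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("cannot compute a threshold from an empty series")
  stats::median(x) * (1 + config$threshold_percent)
}

#' Cumulative sum of threshold-referenced anomalies
#'
#' Running sum of `(x_t - threshold)`. The cumulative sum increases exactly
#' while the series exceeds the threshold and decreases while it is below,
#' so its gradient sign changes are the threshold crossings of the series.
#'
#' @param series A [geo_series()] or numeric vector (gap-free).
#' @param threshold Bloom threshold from [compute_threshold()].
#' @return Numeric vector of cumulative sums.
#' @export
cumulative_anomaly <- function(series, threshold) {
  x <- if (inherits(series, "geo_series")) series$value else as.numeric(series)
  cumsum(x - threshold)
}

#' Detect bloom phenology within one season window
#'
#' Works on one gap-free season window (October-May) against a threshold
#' computed from the full multi-year series:
#'
#' * **peak** -- first occurrence of the seasonal maximum;
#' * **initiation** -- the gradient sign change of the cumulative sum of
#'   anomalies at its minimum before the peak, i.e. the threshold upcrossing
#'   that opens the main growth period. (When noise produces several isolated
#'   upcrossings, the cumulative-sum minimum selects the transition between
#'   the decreasing and the sustained increasing trend; on a series with a
#'   single crossing pair this is the first step above the threshold.)
#' * **termination** -- the first step after the peak at which the series
#'   falls below the threshold (the first gradient sign change after the
#'   growth peak); if the series never drops below the threshold before the
#'   window ends, termination is the window end and flagged;
#' * **duration** -- `termination - initiation`, in 8-day periods.
#'
#' If no step exceeds the threshold the season is reported as
#' "no bloom detected" (a regular result, not an error). A window entirely
#' above the threshold reports initiation at the window start, flagged.
#'
#' When `observed` marks gap-filled steps, a threshold crossing that falls
#' inside an unobserved span is moved to the midpoint of the span bracketed
#' by the surrounding observations: the crossing position of a linear fill
#' inside a gap reflects where the threshold sits between the bracketing
#' values, not anything measured, and the midpoint is the unbiased timing
#' estimate for an event known only to have happened within the gap.
#'
#' @param window A [geo_series()] holding one season of gap-free 8-day data.
#' @param threshold Threshold from [compute_threshold()].
#' @param season_label Label carried into the result.
#' @param observed Optional logical vector, `FALSE` at steps that were
#'   missing before gap filling (default: all observed).
#' @return A `pheno_metrics` list: `detected`, season-relative step indices
#'   `initiation`, `peak`, `termination`, the matching dates, `duration`
#'   and `flags`.
#' @export
detect_phenology <- function(window, threshold, season_label = NA_character_,
                             observed = NULL) {
  stopifnot(inherits(window, "geo_series"))
  x <- window$value
  if (anyNA(x)) stop("season window contains missing values; run fill_gaps_linear() first")
  n <- length(x)
  if (is.null(observed)) observed <- rep(TRUE, n)
  stopifnot(length(observed) == n)
  above <- x > threshold
  flags <- character(0)
  if (!any(above)) {
    return(structure(list(season_label = season_label, detected = FALSE,
                          initiation = NA_integer_, peak = NA_integer_,
                          termination = NA_integer_, duration = NA_integer_,
                          initiation_date = as.Date(NA), peak_date = as.Date(NA),
                          termination_date = as.Date(NA),
                          threshold = threshold, flags = "no bloom detected"),
                     class = "pheno_metrics"))
  }
  peak <- which.max(x)  # ties: earliest occurrence
  if (all(above)) flags <- c(flags, "entirely above threshold")
  # cumulative sum padded with 0 so a window opening above threshold can
  # place its minimum "before" the first step
  cpad <- c(0, cumsum(x - threshold))
  initiation <- which.min(cpad[seq_len(peak)])  # index in 0..peak-1 space, = step
  after <- which(!above & seq_len(n) > peak)
  if (length(after) > 0) {
    termination <- after[1]
  } else {
    termination <- n
    flags <- c(flags, "termination at window end")
  }
  initiation <- snap_to_gap_midpoint(initiation, observed, n)
  termination <- snap_to_gap_midpoint(termination, observed, n)
  if (initiation > peak) initiation <- peak
  if (termination <= peak) termination <- min(peak + 1L, n)
  structure(list(season_label = season_label, detected = TRUE,
                 initiation = as.integer(initiation), peak = as.integer(peak),
                 termination = as.integer(termination),
                 duration = as.integer(termination - initiation),
                 initiation_date = window$time[initiation],
                 peak_date = window$time[peak],
                 termination_date = window$time[termination],
                 threshold = threshold,
                 flags = if (length(flags)) flags else NA_character_),
            class = "pheno_metrics")
}

# a crossing detected at a gap-filled step, or at the first observation after
# a gap, is localized only to the unobserved span plus its closing
# observation: report the span midpoint
snap_to_gap_midpoint <- function(step, observed, n) {
  if (observed[step] && (step == 1 || observed[step - 1])) return(as.integer(step))
  if (observed[step]) {
    e <- step
    g1 <- step - 1L
  } else {
    g2 <- step
    while (g2 < n && !observed[g2 + 1]) g2 <- g2 + 1L
    e <- min(g2 + 1L, n)
    g1 <- step
  }
  while (g1 > 1 && !observed[g1 - 1]) g1 <- g1 - 1L
  as.integer(floor((g1 + e) / 2 + 0.5))
}

#' @export
print.pheno_metrics <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("<pheno_metrics> %s: no bloom detected\n", x$season_label))
  } else {
    cat(sprintf("<pheno_metrics> %s: initiation %d (%s), peak %d, termination %d (%s), duration %d x 8-day\n",
                x$season_label, x$initiation, x$initiation_date, x$peak,
                x$termination, x$termination_date, x$duration))
  }
  invisible(x)
}

#' Split a multi-year 8-day series into seasonal detection windows
#'
#' One window per season: the 8-day steps whose start dates fall in October
#' through December of year `y` plus January through May of year `y + 1`,
#' labelled `"y/y+1"`. Window boundaries never split an 8-day step (a step
#' belongs to the window of its start date). Seasons truncated by the series
#' span are flagged `complete = FALSE`.
#'
#' @param series A multi-year 8-day [geo_series()].
#' @param config A [pheno_config()].
#' @return A list of windows: `label`, `index` (positions in the parent
#'   series), `series` (the window sub-series), `complete`.
#' @export
season_windows <- function(series, config = pheno_config()) {
  stopifnot(inherits(series, "geo_series"))
  d <- as.Date(series$time)
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  years <- sort(unique(yr))
  out <- list()
  for (y in years) {
    idx <- which((yr == y & mo >= config$season_start_month) |
                 (yr == y + 1L & mo <= config$season_end_month))
    if (length(idx) == 0) next
    # a complete window holds every step of months start..12 of year y plus
    # months 1..end of year y+1
    n_expected <- sum(as.integer(format(eight_day_dates(y, 1), "%m")) >=
                        config$season_start_month) +
      sum(as.integer(format(eight_day_dates(y + 1, 1), "%m")) <=
            config$season_end_month)
    out[[length(out) + 1L]] <- list(
      label = paste0(y, "/", y + 1L),
      index = idx,
      series = geo_series(series$time[idx], series$value[idx],
                          units = attr(series, "units")),
      complete = length(idx) == n_expected
    )
  }
  out
}

#' Run the full phenology pipeline on a multi-year series
#'
#' Fills gaps, computes the threshold once from the entire series, splits it
#' into seasonal windows and runs [detect_phenology()] on every complete
#' season. Season-relative indices are also reported as absolute step indices
#' in the parent series, so planted blooms can be scored directly.
#'
#' @param series A multi-year 8-day [geo_series()] (gaps allowed).
#' @param config A [pheno_config()].
#' @param include_partial Also detect on truncated first/last seasons
#'   (flagged); default `FALSE`.
#' @return A data.frame with one row per season: `season`, `detected`,
#'   `initiation`/`peak`/`termination` (absolute step indices),
#'   `initiation_date`, `peak_date`, `termination_date`, `duration`, `flags`.
#' @export
pheno_pipeline <- function(series, config = pheno_config(), include_partial = FALSE) {
  observed_all <- !is.na(series$value)
  filled <- fill_gaps_linear(series)
  threshold <- compute_threshold(filled, config)
  wins <- season_windows(filled, config)
  if (!include_partial) wins <- Filter(function(w) w$complete, wins)
  rows <- lapply(wins, function(w) {
    m <- detect_phenology(w$series, threshold, season_label = w$label,
                          observed = observed_all[w$index])
    data.frame(
      season = w$label,
      detected = m$detected,
      initiation = if (m$detected) w$index[m$initiation] else NA_integer_,
      peak = if (m$detected) w$index[m$peak] else NA_integer_,
      termination = if (m$detected) w$index[m$termination] else NA_integer_,
      duration = m$duration,
      initiation_date = m$initiation_date,
      peak_date = m$peak_date,
      termination_date = m$termination_date,
      threshold = threshold,
      flags = paste(m$flags, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Moving-box robustness scan
#'
#' Slides a square box of `box_size` degrees across `domain` in steps of
#' `stride` degrees (all positions fully contained in the domain) and
#' computes the area-mean series of the field in each box, to check that a
#' result does not hinge on one particular averaging region. The number of
#' positions is the closed form
#' `((lat_span - box)/stride + 1) * ((lon_span - box)/stride + 1)`
#' for integer fits.
#'
#' @param field A [geo_field()].
#' @param domain A [region()] at least as large as the box.
#' @param box_size Box edge in degrees (default 5).
#' @param stride Step in degrees (default 1).
#' @param weighting Passed to [region_mean()].
#' @return A list: `positions` (data.frame of box corner coordinates
#'   `lat_min`, `lon_min`), `series` (matrix, time x position), `times`.
#' @export
box_scan <- function(field, domain, box_size = 5, stride = 1,
                     weighting = c("coslat", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(domain, "region"))
  lat_span <- domain$lat_max - domain$lat_min
  lon_span <- domain$lon_max - domain$lon_min
  if (box_size > lat_span || box_size > lon_span) {
    stop("box is larger than the domain")
  }
  lat0 <- seq(domain$lat_min, domain$lat_max - box_size, by = stride)
  lon0 <- seq(domain$lon_min, domain$lon_max - box_size, by = stride)
  pos <- expand.grid(lat_min = lat0, lon_min = lon0, KEEP.OUT.ATTRS = FALSE)
  series <- vapply(seq_len(nrow(pos)), function(i) {
    r <- region(pos$lat_min[i], pos$lat_min[i] + box_size,
                pos$lon_min[i], pos$lon_min[i] + box_size)
    region_mean(field, r, weighting = weighting)$value
  }, numeric(length(field$times)))
  series <- matrix(series, nrow = length(field$times))
  list(positions = pos, series = series, times = field$times)
}

#' @rdname box_scan
#' @param domain,box_size,stride As in `box_scan`.
#' @return For `box_scan_count`, the closed-form number of fully contained
#'   box positions.
#' @export
box_scan_count <- function(domain, box_size = 5, stride = 1) {
  nlat <- floor((domain$lat_max - domain$lat_min - box_size) / stride) + 1
  nlon <- floor((domain$lon_max - domain$lon_min - box_size) / stride) + 1
  as.integer(nlat * nlon)
}
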