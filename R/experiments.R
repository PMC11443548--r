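## Recovery experiments: the study conditions under which the pipeline is
## validated against planted ground truth. Each driver fixes the synthetic
## conditions (sample sizes, noise levels, planted-signal scales) once and
## reports recovery statistics; tests and the acceptance script call these
## rather than re-declaring conditions.

#' Phenology recovery under noise and cloud gaps
#'
#' Simulates `n_series` multi-year 8-day chlorophyll archives (one bloom per
#' austral-summer season, plateau amplitude 0.2 mg m-3 over a 0.1 mg m-3
#' baseline -- the scale of the strongest observed seasonal elevations --
#' initiation in November, duration 10-14 steps), degrades them with
#' mean-one lognormal noise and random cloud gaps, runs the full pipeline
#' (gap filling, threshold, per-season detection), and scores detected
#' initiation/termination against the planted truth.
#'
#' @param n_series Number of independent archives (default 100).
#' @param n_years Years per archive (default 24).
#' @param noise_cv Lognormal noise coefficient of variation (default 0.1).
#' @param gap_fraction Fraction of masked steps (default 0.2).
#' @param seed Master seed; per-archive seeds are derived from it.
#' @return A list: `per_season` data.frame (truth and detected indices),
#'   and summary rates `init_within_1`, `term_within_1`, `both_within_1`,
#'   `duration_identity`, `n_seasons`.
#' @export
pheno_recovery_experiment <- function(n_series = 100, n_years = 24,
                                      noise_cv = 0.1, gap_fraction = 0.2,
                                      seed = 1) {
  start_year <- 1997
  rows <- list()
  for (i in seq_len(n_series)) {
    sim <- with_seed(seed * 1000 + i, {
      blooms <- lapply(seq_len(n_years - 1), function(j) {
        init <- 46 * (j - 1) + sample(39:42, 1)   # November of year j
        dur <- sample(10:14, 1)
        bloom_truth(init, init + floor(dur / 2), init + dur,
                    amplitude = 0.2, baseline = 0.1,
                    season_label = paste0(start_year + j - 1, "/", start_year + j))
      })
      make_chl_series(n_years, baseline = 0.1, blooms = blooms,
                      gap_fraction = gap_fraction, noise_cv = noise_cv,
                      seed = seed * 1000 + i, start_year = start_year,
                      shape = "peaked")
    })
    det <- pheno_pipeline(sim$series)
    truth_df <- data.frame(
      season = vapply(sim$truth, `[[`, character(1), "season_label"),
      init_true = vapply(sim$truth, `[[`, integer(1), "initiation"),
      term_true = vapply(sim$truth, `[[`, integer(1), "termination")
    )
    m <- merge(det, truth_df, by = "season")
    m$series_id <- i
    rows[[i]] <- m
  }
  per_season <- do.call(rbind, rows)
  ok <- per_season$detected
  init_err <- abs(per_season$initiation - per_season$init_true)
  term_err <- abs(per_season$termination - per_season$term_true)
  dur_ok <- per_season$duration ==
    (per_season$termination - per_season$initiation)
  list(
    per_season = per_season,
    init_within_1 = mean(ok & init_err <= 1),
    term_within_1 = mean(ok & term_err <= 1),
    both_within_1 = mean(ok & init_err <= 1 & term_err <= 1),
    duration_identity = mean(dur_ok[ok]),
    n_seasons = nrow(per_season)
  )
}

#' Eddy detection recovery on planted Gaussian eddies
#'
#' Simulates `n_fields` SLA fields on a 0.25-degree grid with 1-6
#' well-separated planted Gaussian eddies (amplitude 0.05-0.25 m of either
#' sign, radius 85-150 km, centers separated by more than three times the
#' radius sum) plus 0.5 cm additive noise, and scores the closed-contour
#' census: exact count and polarity recovery, and center error below one
#' grid cell.
#'
#' @param n_fields Number of fields (default 50).
#' @param noise_sd Additive noise SD in m (default 0.005).
#' @param seed Master seed.
#' @return A list: `per_field` data.frame, rates `exact_census` and
#'   `centers_within_1`, and `field_success` (both at once).
#' @export
eddy_recovery_experiment <- function(n_fields = 50, noise_sd = 0.005, seed = 1) {
  grid <- geo_grid(seq(-32, -12, by = 0.25), seq(45, 65, by = 0.25))
  cell_deg <- 0.25
  res <- lapply(seq_len(n_fields), function(i) {
    truth <- with_seed(seed * 2000 + i, {
      n_eddies <- sample(1:6, 1)
      placed <- list()
      tries <- 0
      while (length(placed) < n_eddies && tries < 500) {
        tries <- tries + 1
        cand <- eddy_truth(stats::runif(1, -29, -15), stats::runif(1, 48, 62),
                           amplitude = sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.25),
                           radius = stats::runif(1, 85, 150))
        sep_ok <- all(vapply(placed, function(e) {
          d <- sqrt(((cand$center_lat - e$center_lat) * 111.195)^2 +
                      ((cand$center_lon - e$center_lon) * 111.195 *
                         cos(cand$center_lat * pi / 180))^2)
          d > 3 * (cand$radius + e$radius)
        }, logical(1)))
        if (sep_ok) placed[[length(placed) + 1L]] <- cand
      }
      placed
    })
    sim <- make_sla_field(grid, truth, noise_sd = noise_sd, seed = seed * 2000 + i)
    cen <- detect_eddies(sim$field)
    truth_pol <- vapply(truth, `[[`, character(1), "polarity")
    det_pol <- vapply(cen$records, `[[`, character(1), "polarity")
    count_ok <- length(cen$records) == length(truth) &&
      sum(det_pol == "cyclonic") == sum(truth_pol == "cyclonic")
    center_err <- vapply(truth, function(e) {
      errs <- vapply(cen$records, function(r) {
        if (r$polarity != e$polarity) return(Inf)
        max(abs(r$center_lat - e$center_lat), abs(r$center_lon - e$center_lon))
      }, numeric(1))
      if (length(errs) == 0) Inf else min(errs)
    }, numeric(1))
    data.frame(field = i, n_true = length(truth),
               n_detected = length(cen$records),
               count_ok = count_ok,
               max_center_err_cells = max(center_err) / cell_deg)
  })
  per_field <- do.call(rbind, res)
  list(per_field = per_field,
       exact_census = mean(per_field$count_ok),
       centers_within_1 = mean(per_field$max_center_err_cells < 1),
       field_success = mean(per_field$count_ok &
                              per_field$max_center_err_cells < 1))
}

#' Mixed-layer-depth recovery on tanh thermocline profiles
#'
#' Random thermocline profiles (mixed-layer depth 30-80 m, width 5-12 m,
#' surface temperature 24-28 degC, 0.01 degC sensor noise) at vertical
#' spacings of 1-5 m; scores the 0.2 degC criterion against the planted
#' depth.
#'
#' @param n_profiles Number of profiles (default 100).
#' @param seed Master seed.
#' @return A list: `per_profile` data.frame and `within_spacing` rate.
#' @export
mld_recovery_experiment <- function(n_profiles = 100, seed = 1) {
  res <- lapply(seq_len(n_profiles), function(i) {
    par <- with_seed(seed * 3000 + i, {
      list(truth = profile_truth(stats::runif(1, 30, 80),
                                 stats::runif(1, 24, 28),
                                 stats::runif(1, 5, 12)),
           dz = sample(1:5, 1))
    })
    prof <- make_profile(par$truth, dz = par$dz, noise_sd = 0.01,
                         seed = seed * 3000 + i)
    mld <- mld_from_profile(prof)
    data.frame(profile = i, dz = par$dz, mld_true = par$truth$mld_true,
               mld = as.numeric(mld), err = abs(as.numeric(mld) - par$truth$mld_true))
  })
  per_profile <- do.call(rbind, res)
  list(per_profile = per_profile,
       within_spacing = mean(per_profile$err <= per_profile$dz))
}

#' Trend significance masking on flat-noise pixels
#'
#' A monthly field of pure iid Gaussian noise (no trend): under the
#' classical t-test the per-pixel p-values are uniform, so pixels should be
#' masked at `1 - alpha` of the nominal rate. One pixel is one independent
#' replicate.
#'
#' @param n_pixels Number of independent noise pixels (default 2000).
#' @param n_months Series length (default 492, i.e. 41 years).
#' @param seed Master seed.
#' @return A list with the observed `masked_rate` and the `trend_result`.
#' @export
trend_masking_experiment <- function(n_pixels = 2000, n_months = 492, seed = 1) {
  nlat <- 40
  nlon <- ceiling(n_pixels / nlat)
  grid <- geo_grid(seq(-35, by = 0.5, length.out = nlat),
                   seq(12, by = 0.5, length.out = nlon))
  sim <- make_trend_field(grid, trend_truth(0, 10, noise_sd = 1),
                          n_months = n_months, seed = seed * 4000 + 1)
  tr <- decadal_trend(sim$field)
  list(masked_rate = mean(tr$masked), trend = tr, n_pixels = nlat * nlon)
}

#' Recovery of a planted iron-stress excursion
#'
#' Builds a 21-year 8-day fluorescence quantum-yield series (seasonal
#' harmonic plus noise), computes the climatology over the first 20 years,
#' and plants a negative excursion of exactly `magnitude_sd` climatological
#' SDs in the final year. The standardized-anomaly pipeline should read the
#' excursion back at its planted depth.
#'
#' @param magnitude_sd Planted excursion depth in SD units (default 2.7,
#'   the scale of a strong stress-relief event).
#' @param seed Master seed.
#' @return A list: `recovered` (mean anomaly over the excursion steps),
#'   `planted` (`-magnitude_sd`), and the anomaly series.
#' @export
phif_excursion_experiment <- function(magnitude_sd = 2.7, seed = 1) {
  n_years <- 21
  dates <- eight_day_dates(2000, n_years)
  step <- eight_day_step(dates)
  base <- 0.01 * (1 + 0.3 * sin(2 * pi * step / 46))
  phi <- with_seed(seed * 5000 + 1,
                   base * exp(stats::rnorm(length(base), 0, 0.1)))
  s <- geo_series(dates, phi, units = "1")
  ref <- as.Date(c("2000-01-01", "2019-12-31"))
  clim <- build_climatology(s, "8day", reference_period = ref)
  # plant the excursion in the out-of-reference year, in mid-November
  target <- which(as.integer(format(dates, "%Y")) == 2020 & step %in% 40:42)
  s$value[target] <- clim$mean[step[target]] - magnitude_sd * clim$sd[step[target]]
  anom <- delta_phi_f(s, clim)
  list(recovered = mean(anom$value[target]), planted = -magnitude_sd,
       anomaly = anom, excursion_steps = target)
}
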