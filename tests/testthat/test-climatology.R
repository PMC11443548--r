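ref_years <- function(y0, y1) as.Date(c(paste0(y0, "-01-01"), paste0(y1, "-12-31")))

test_that("climatology reproduces constants and noiseless harmonics", {
  dates <- eight_day_dates(2000, 4)
  cl <- build_climatology(geo_series(dates, rep(0.2, length(dates))), "8day")
  expect_equal(cl$mean, rep(0.2, 46))
  expect_equal(cl$sd, rep(0, 46))
  harm <- 0.2 + 0.1 * sin(2 * pi * eight_day_step(dates) / 46)
  clh <- build_climatology(geo_series(dates, harm), "8day")
  expect_equal(clh$mean, 0.2 + 0.1 * sin(2 * pi * (1:46) / 46), tolerance = 1e-12)
  expect_equal(clh$sd, rep(0, 46), tolerance = 1e-12)
})

test_that("the reference period restricts which years define 'normal'", {
  # level shift at year 11; reference over the first 10 years only
  dates <- eight_day_dates(2000, 20)
  x <- ifelse(as.integer(format(dates, "%Y")) >= 2010, 2, 1)
  s <- geo_series(dates, x)
  cl <- build_climatology(s, "8day", reference_period = ref_years(2000, 2009))
  expect_equal(cl$mean, rep(1, 46))  # oracle: direct mean over the subset
  cl_all <- build_climatology(s, "8day")
  expect_equal(cl_all$mean, rep(1.5, 46))
  expect_error(build_climatology(s, "8day", reference_period = ref_years(1990, 2009)),
               "outside")
  expect_error(build_climatology(geo_series(dates[1:46], x[1:46]), "8day"),
               "at least 2 years")
})

test_that("relative anomalies are percentages with guarded degenerate means", {
  dates <- eight_day_dates(2000, 6)
  clim <- build_climatology(geo_series(dates, rep(0.1, length(dates))), "8day")
  probe <- geo_series(dates[1:3], c(0.1, 0.30, 0.05))
  ra <- relative_anomaly(probe, clim)
  expect_equal(ra$value, c(0, 200, -50))
  # zero climatological mean: missing, not infinite
  clim0 <- build_climatology(geo_series(dates, rep(0, length(dates))), "8day")
  expect_true(all(is.na(relative_anomaly(probe, clim0)$value)))
})

test_that("standardized anomalies are exact on their own reference period", {
  dates <- eight_day_dates(2000, 20)
  base <- 0.2 + 0.1 * sin(2 * pi * eight_day_step(dates) / 46)
  set.seed(42)
  s <- geo_series(dates, base + rnorm(length(dates), 0, 0.03))
  cl <- build_climatology(s, "8day")
  a <- standardized_anomaly(s, cl)
  # per-period mean is zero by construction (algebraic identity)
  for (p in c(1, 17, 46)) {
    expect_lt(abs(mean(a$value[eight_day_step(dates) == p])), 1e-10)
  }
  # pooled sample SD close to one on a 20-year noisy record
  expect_lt(abs(stats::sd(a$value) - 1), 0.05)
  # x = mean + 2 sd reads back as exactly 2
  probe <- geo_series(dates[5], cl$mean[5] + 2 * cl$sd[5])
  expect_equal(standardized_anomaly(probe, cl)$value, 2)
  # zero-sd periods give missing values
  cl0 <- build_climatology(geo_series(dates, rep(1, length(dates))), "8day")
  expect_true(is.na(standardized_anomaly(probe, cl0)$value))
})

test_that("anomalies invert the generator's planted perturbations exactly", {
  # noiseless series: +50% relative elevation over a known window
  dates <- eight_day_dates(2000, 6)
  x <- rep(0.2, length(dates))
  x[100:110] <- 0.3
  s <- geo_series(dates, x)
  clim <- build_climatology(geo_series(dates, rep(0.2, length(dates))), "8day")
  ra <- relative_anomaly(s, clim)
  expect_equal(ra$value[100:110], rep(50, 11))
  expect_equal(ra$value[-(100:110)], rep(0, length(dates) - 11))
})

test_that("gap filling is linear inside, nearest at edges, and idempotent", {
  d <- as.Date("2019-01-01") + 0:2
  expect_equal(fill_gaps_linear(geo_series(d, c(1, NA, 3)))$value, c(1, 2, 3))
  full <- geo_series(d, c(1, 5, 3))
  expect_identical(fill_gaps_linear(full)$value, full$value)
  d4 <- as.Date("2019-01-01") + 0:3
  edge <- fill_gaps_linear(geo_series(d4, c(NA, 2, 4, NA)))
  expect_equal(edge$value, c(2, 2, 4, 4))
  expect_identical(fill_gaps_linear(edge)$value, edge$value)
  expect_error(fill_gaps_linear(geo_series(d, c(NA, NA, NA))), "non-missing")
  expect_error(fill_gaps_linear(geo_series(d, c(NA, 2, NA))), "non-missing")
})

test_that("moving means smooth as expected", {
  d <- as.Date("2019-01-01") + 0:23
  cs <- geo_series(d, rep(3, 24))
  expect_equal(moving_mean(cs, 12)$value, rep(3, 24))
  lin <- geo_series(d, as.numeric(1:24))
  expect_identical(moving_mean(lin, 1)$value, lin$value)
  sm <- moving_mean(lin, 5)
  expect_equal(sm$value[3:22], as.numeric(3:22))  # symmetric window, interior
})

test_that("decadal trends recover planted slopes and mask flat pixels", {
  g <- small_grid(1)
  sim <- make_trend_field(g, trend_truth(0.2, 5), n_months = 120)
  tr <- decadal_trend(sim$field)
  expect_equal(as.vector(tr$slope), rep(0.2, length(tr$slope)), tolerance = 1e-9)
  expect_true(all(tr$p_value < 1e-12))
  expect_false(any(tr$masked))
  # constant pixels: zero slope, masked
  cst <- make_trend_field(g, trend_truth(0, 5), n_months = 120)
  trc <- decadal_trend(cst$field)
  expect_true(all(trc$slope == 0))
  expect_true(all(trc$masked))
  # series method agrees with the field method
  s <- geo_series(sim$field$times, sim$field$values[, 1, 1])
  expect_equal(decadal_trend(s)$slope, 0.2, tolerance = 1e-9)
})

test_that("trend estimates are unbiased within 2 standard errors (100 replicates)", {
  g <- geo_grid(seq(-35, -30.5, 0.5), seq(12, 16.5, 0.5))  # 100 pixels
  sim <- make_trend_field(g, trend_truth(0.3, 5, noise_sd = 1),
                          n_months = 240, seed = 9)
  tr <- decadal_trend(sim$field)
  slopes <- as.vector(tr$slope)
  bias <- mean(slopes) - 0.3
  se_of_mean <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(bias), 2 * se_of_mean + 1e-12)
})

test_that("wet deposition totals require five aligned bins", {
  d <- as.Date("2019-01-01") + 0:2
  zero <- lapply(1:5, function(i) geo_series(d, rep(0, 3)))
  expect_equal(total_wet_deposition(zero)$value, rep(0, 3))
  bins <- lapply(1:5, function(i) geo_series(d, c(i, i, NA)))
  expect_equal(total_wet_deposition(bins)$value, c(15, 15, NA))
  expect_error(total_wet_deposition(bins[1:4]), "exactly 5")
  misaligned <- bins
  misaligned[[2]]$time <- d + 1
  expect_error(total_wet_deposition(misaligned), "aligned")
})
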