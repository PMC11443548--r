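test_that("the bloom threshold is the series median times 1 + percent", {
  expect_equal(compute_threshold(rep(0.1, 100)), 0.12)
  # an explicitly constructed odd-length series with median 0.1
  s <- c(0.05, 0.07, 0.1, 0.4, 0.6)
  expect_equal(stats::median(s), 0.1)  # oracle: sorted midpoint
  expect_equal(compute_threshold(s), 0.12)
  expect_equal(compute_threshold(s, pheno_config(threshold_percent = 0.05)),
               0.105)
  expect_error(compute_threshold(numeric(0)), "empty")
  expect_error(pheno_config(threshold_percent = 0), "in \\(0, 1\\)")
})

test_that("cumulative anomalies track threshold exceedance", {
  expect_equal(cumulative_anomaly(rep(0.12, 5), 0.12), rep(0, 5))
  below <- cumulative_anomaly(rep(0.1, 5), 0.12)
  expect_true(all(diff(below) < 0))
  # hand-computed example
  expect_equal(cumulative_anomaly(c(0.1, 0.1, 0.3, 0.3, 0.1), 0.12),
               c(-0.02, -0.04, 0.14, 0.32, 0.30), tolerance = 1e-12)
})

test_that("detection reproduces the hand-traced season", {
  w <- season_window()
  m <- detect_phenology(w, 0.12)
  expect_true(m$detected)
  expect_equal(m$initiation, 12L)
  expect_equal(m$peak, 12L)
  expect_equal(m$termination, 19L)
  expect_equal(m$duration, 7L)
  expect_equal(m$duration, m$termination - m$initiation)
})

test_that("degenerate seasons are reported, not errored", {
  w_low <- season_window(bloom_value = 0.11)
  m <- detect_phenology(w_low, 0.12)
  expect_false(m$detected)
  expect_match(m$flags, "no bloom")
  w_high <- geo_series(eight_day_dates(2019, 1)[1:30], rep(0.5, 30))
  m2 <- detect_phenology(w_high, 0.12)
  expect_equal(m2$initiation, 1L)
  expect_match(paste(m2$flags, collapse = ";"), "above threshold")
  expect_match(paste(m2$flags, collapse = ";"), "window end")
  expect_error(detect_phenology(geo_series(w_low$time, c(NA, w_low$value[-1])), 0.12),
               "missing")
})

test_that("cumulative-sum detection and direct threshold crossings agree", {
  # the detected initiation is an upcrossing and the termination a
  # downcrossing of the same series, across noisy seeded windows
  for (seed in 1:20) {
    sim <- make_chl_series(2, blooms = list(bloom_truth(55, 58, 66, 0.2, 0.1)),
                           noise_cv = 0.1, seed = seed)
    w <- geo_series(sim$series$time[47:77], sim$series$value[47:77])
    thr <- compute_threshold(sim$series)
    m <- detect_phenology(w, thr)
    expect_true(m$detected)
    expect_gt(w$value[m$initiation], thr)
    if (m$initiation > 1) expect_lte(w$value[m$initiation - 1], thr)
    if (!grepl("window end", paste(m$flags, collapse = ";"))) {
      expect_lt(w$value[m$termination], thr)
      expect_gte(w$value[m$termination - 1], thr)
    }
  }
})

test_that("raising the threshold never advances initiation nor delays termination", {
  sim <- make_chl_series(2, blooms = list(bloom_truth(55, 58, 66, 0.25, 0.1)),
                         noise_cv = 0.1, seed = 7)
  w <- geo_series(sim$series$time[47:77], sim$series$value[47:77])
  prev_init <- -Inf
  prev_term <- Inf
  for (pct in c(0.05, 0.10, 0.20, 0.35)) {
    thr <- compute_threshold(sim$series, pheno_config(threshold_percent = pct))
    m <- detect_phenology(w, thr)
    if (!m$detected) break
    expect_gte(m$initiation, prev_init)
    expect_lte(m$termination, prev_term)
    prev_init <- m$initiation
    prev_term <- m$termination
  }
})

test_that("season windows isolate October through May without splitting steps", {
  dates <- eight_day_dates(1998, 3)
  s <- geo_series(dates, rep(0.1, length(dates)))
  wins <- season_windows(s)
  complete <- Filter(function(w) w$complete, wins)
  expect_length(complete, 2)
  labels <- vapply(complete, `[[`, character(1), "label")
  expect_equal(labels, c("1998/1999", "1999/2000"))
  for (w in complete) {
    mo <- as.integer(format(w$series$time, "%m"))
    expect_true(all(mo >= 10 | mo <= 5))
    expect_equal(length(w$index), sum(mo >= 10) + sum(mo <= 5))
  }
  # a truncated trailing season is flagged incomplete
  expect_false(wins[[length(wins)]]$complete)
})

test_that("the pipeline recovers planted noiseless blooms exactly", {
  blooms <- list(bloom_truth(85, 89, 96, 0.2, 0.1, "1998/1999"),
                 bloom_truth(131, 135, 142, 0.2, 0.1, "1999/2000"))
  sim <- make_chl_series(4, blooms = blooms, start_year = 1997)
  out <- pheno_pipeline(sim$series)
  det <- out[out$detected, ]
  expect_equal(det$season, c("1998/1999", "1999/2000"))
  expect_equal(det$initiation, c(85L, 131L))
  expect_equal(det$termination, c(96L, 142L))
  expect_equal(det$duration, det$termination - det$initiation)
})

test_that("phenology recovery stays accurate under noise and gaps", {
  r <- pheno_recovery_experiment(n_series = 10, seed = 3)
  expect_gt(r$both_within_1, 0.9)
  expect_equal(r$duration_identity, 1)
})

test_that("the box scan enumerates fully contained positions", {
  dom <- region(-40, -15, 30, 80)
  expect_equal(box_scan_count(dom, 5, 1), 966L)  # (25-5+1) x (50-5+1)
  expect_equal(box_scan_count(region(-30, -25, 50, 55), 5, 1), 1L)
  g <- geo_grid(seq(-39.5, -15.5, 1), seq(30.5, 79.5, 1))
  f <- geo_field(array(2.5, c(2, length(g$lats), length(g$lons))), g,
                 as.Date("2019-11-01") + c(0, 30))
  bs <- box_scan(f, dom)
  expect_equal(nrow(bs$positions), 966L)
  expect_true(all(abs(bs$series - 2.5) < 1e-12))  # uniform field: identical series
  expect_error(box_scan(f, region(-18, -15, 30, 80), box_size = 5), "larger")
})
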