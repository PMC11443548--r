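test_that("noiseless chlorophyll series is an exact plateau construction", {
  sim <- make_chl_series(2, baseline = 0.1,
                         blooms = list(bloom_truth(12, 15, 19, 0.2, 0.1)))
  expect_length(sim$series$value, 92)  # 46 steps per year
  expect_equal(sim$series$value[12:18], rep(0.3, 7))
  expect_equal(sim$series$value[-(12:18)], rep(0.1, 85))
  expect_equal(sim$masked_steps, integer(0))
})

test_that("gap masking counts exactly and is reproducible", {
  a <- make_chl_series(3, gap_fraction = 0.2, noise_cv = 0.1, seed = 11)
  b <- make_chl_series(3, gap_fraction = 0.2, noise_cv = 0.1, seed = 11)
  expect_identical(a$series$value, b$series$value)
  expect_identical(a$masked_steps, b$masked_steps)
  expect_length(a$masked_steps, round(0.2 * 138))
  c <- make_chl_series(3, gap_fraction = 0.2, noise_cv = 0.1, seed = 12)
  expect_false(identical(a$series$value, c$series$value))
})

test_that("masking never erases a planted bloom entirely", {
  for (seed in 1:25) {
    sim <- make_chl_series(2, blooms = list(bloom_truth(50, 52, 55, 0.2, 0.1)),
                           gap_fraction = 0.6, noise_cv = 0.1, seed = seed)
    expect_true(any(!is.na(sim$series$value[50:54])),
                info = paste("seed", seed))
  }
})

test_that("overlapping bloom windows are rejected", {
  expect_error(
    make_chl_series(2, blooms = list(bloom_truth(10, 12, 20, 0.2, 0.1),
                                     bloom_truth(18, 20, 25, 0.2, 0.1))),
    "overlapping"
  )
  expect_error(bloom_truth(10, 10, 20, 0.2, 0.1), "initiation < peak")
  expect_error(bloom_truth(10, 12, 20, -1, 0.1), "amplitude")
})

test_that("SLA field equals the closed-form Gaussian sum", {
  g <- small_grid(0.25)
  # no eddies, no noise: identically zero
  expect_true(all(make_sla_field(g)$field$values == 0))
  # single eddy: global maximum at the center cell
  sim1 <- make_sla_field(g, list(eddy_truth(-25, 55, 0.2, 80)))
  z <- field_slice(sim1$field)
  peak <- which(z == max(z), arr.ind = TRUE)
  expect_equal(g$lats[peak[1]], -25)
  expect_equal(g$lons[peak[2]], 55)
  # two well-separated eddies: extrema match signed amplitudes; oracle is a
  # direct evaluation of the two-Gaussian sum on the grid
  e1 <- eddy_truth(-28, 52, 0.2, 60)
  e2 <- eddy_truth(-22, 58, -0.15, 60)
  sim2 <- make_sla_field(g, list(e1, e2))
  z2 <- field_slice(sim2$field)
  kmlat <- 111.195
  oracle <- matrix(0, length(g$lats), length(g$lons))
  for (e in list(e1, e2)) {
    d2 <- outer((g$lats - e$center_lat) * kmlat,
                rep(1, length(g$lons)))^2 +
      outer(rep(1, length(g$lats)),
            (g$lons - e$center_lon) * kmlat * cos(e$center_lat * pi / 180))^2
    oracle <- oracle + e$amplitude * exp(-d2 / (2 * e$radius^2))
  }
  expect_equal(z2, oracle, tolerance = 1e-12)
  expect_lt(abs(max(z2) - 0.2), 1e-6)
  expect_lt(abs(min(z2) - (-0.15)), 1e-6)
  # centers must be inside the grid
  expect_error(make_sla_field(g, list(eddy_truth(-50, 55, 0.2, 80))), "outside")
})

test_that("geostrophic currents match plane and Gaussian oracles", {
  g <- small_grid(0.1, -30, -20, 50, 60)
  # constant SLA: no flow
  flat <- geo_field(array(0.05, c(1, length(g$lats), length(g$lons))), g,
                    as.Date("2019-12-01"), var = "sla")
  cur <- make_geostrophic_currents(flat)
  expect_true(all(cur$u$values == 0 | is.na(cur$u$values)))
  expect_true(all(cur$v$values == 0 | is.na(cur$v$values)))
  # SLA linear in latitude only: v = 0, u constant along rows (f-plane)
  lin <- geo_field(array(rep(0.001 * g$lats, length(g$lons)),
                         c(1, length(g$lats), length(g$lons))), g,
                   as.Date("2019-12-01"), var = "sla")
  curl <- make_geostrophic_currents(lin, coriolis_lat = -25)
  vv <- curl$v$values[1, 2:(length(g$lats) - 1), 2:(length(g$lons) - 1)]
  uu <- curl$u$values[1, 2:(length(g$lats) - 1), 2:(length(g$lons) - 1)]
  expect_true(all(abs(vv) < 1e-12))
  expect_lt(diff(range(uu)), 1e-9 * max(abs(uu)))
  # Gaussian eddy: speed matches the analytic gradient within 2% off-boundary
  A <- 0.2; r_km <- 80
  sim <- make_sla_field(g, list(eddy_truth(-25, 55, A, r_km)))
  cur2 <- make_geostrophic_currents(sim$field)
  speed <- sqrt(cur2$u$values[1, , ]^2 + cur2$v$values[1, , ]^2)
  gg <- 9.81; om <- 7.292115e-5
  kmlat <- 111.195
  d_km <- sqrt(outer((g$lats + 25) * kmlat, rep(1, length(g$lons)))^2 +
                 outer(rep(1, length(g$lats)),
                       (g$lons - 55) * kmlat * cos(-25 * pi / 180))^2)
  grad <- A * (d_km * 1000) / (r_km * 1000)^2 * exp(-d_km^2 / (2 * r_km^2))
  f <- matrix(2 * om * sin(g$lats * pi / 180), length(g$lats), length(g$lons))
  speed_an <- gg / abs(f) * grad
  sel <- speed_an > 0.2 * max(speed_an) & !is.na(speed)
  expect_lt(max(abs(speed[sel] - speed_an[sel]) / speed_an[sel]), 0.02)
  # equatorial grids are refused
  geq <- geo_grid(seq(-4, 4, 1), seq(50, 60, 1))
  feq <- geo_field(array(0, c(1, 9, 11)), geq, as.Date("2019-12-01"))
  expect_error(make_geostrophic_currents(feq), "equator")
})

test_that("synthetic profiles encode the planted mixed layer", {
  tr <- profile_truth(42, 26, 10)
  p <- make_profile(tr, dz = 1)
  expect_equal(p$temperature[p$depth == 10], 26, tolerance = 1e-3)
  first_below <- p$depth[which(p$temperature <= 26 - 0.2)[1]]
  expect_lte(abs(first_below - 42), 1)
  # coarser sampling, same truth
  p5 <- make_profile(tr, dz = 5)
  first_below5 <- p5$depth[which(p5$temperature <= 26 - 0.2)[1]]
  expect_lte(abs(first_below5 - 42), 5)
  # reproducible under a seed
  a <- make_profile(tr, dz = 2, noise_sd = 0.05, seed = 3)
  b <- make_profile(tr, dz = 2, noise_sd = 0.05, seed = 3)
  expect_identical(a$temperature, b$temperature)
  expect_error(profile_truth(8, 26, 10), "10 m")
})

test_that("event series plants disjoint step elevations", {
  ev0 <- make_event_series(100, base_level = 2)
  expect_equal(ev0$series$value, rep(2, 100))
  ev2 <- make_event_series(100, base_level = 0,
                           events = list(list(start = 10, length = 5, magnitude = 3),
                                         list(start = 50, length = 3, magnitude = 1)))
  expect_equal(which(ev2$series$value > 0), c(10:14, 50:52))
  expect_equal(ev2$series$value[10:14], rep(3, 5))
  expect_error(make_event_series(20, 0, events = list(list(start = 18, length = 5, magnitude = 1))),
               "outside")
})

test_that("a planted 3-SD event reads back at 3 SD through the anomaly pipeline", {
  # climatology from the 20 non-event years; event planted in the final year
  n_days <- 365 * 21
  ev <- make_event_series(n_days, base_level = 1, noise_sd = 0.5, seed = 8,
                          start_date = as.Date("2000-01-01"))
  s <- ev$series
  ref <- as.Date(c("2000-01-01", "2019-12-31"))
  clim <- build_climatology(s, "doy", reference_period = ref)
  target <- which(s$time >= as.Date("2020-06-01") & s$time <= as.Date("2020-06-05"))
  key <- pooled_doy(s$time[target])
  s$value[target] <- clim$mean[key] + 3 * clim$sd[key]
  anom <- standardized_anomaly(s, clim)
  expect_equal(anom$value[target], rep(3, 5), tolerance = 1e-10)
})

test_that("trend fields are exactly linear without noise and reproducible", {
  g <- small_grid(1)
  sim <- make_trend_field(g, trend_truth(0.2, 5), n_months = 492)
  px <- sim$field$values[, 3, 4]
  tdec <- decades_since_start(sim$field$times)
  expect_equal(px, 5 + 0.2 * tdec, tolerance = 1e-12)
  flat <- make_trend_field(g, trend_truth(0, 5), n_months = 48)
  expect_true(all(flat$field$values == 5))
  a <- make_trend_field(g, trend_truth(0.2, 5, 1), n_months = 48, seed = 2)
  b <- make_trend_field(g, trend_truth(0.2, 5, 1), n_months = 48, seed = 2)
  expect_identical(a$field$values, b$field$values)
  expect_error(make_trend_field(g, trend_truth(0.2, 5), n_months = 12), ">= 24")
})
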