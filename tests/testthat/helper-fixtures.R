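# Small shared fixtures, built in code.

small_grid <- function(dlat = 0.5, lat0 = -30, lat1 = -20, lon0 = 50, lon1 = 60) {
  geo_grid(seq(lat0, lat1, by = dlat), seq(lon0, lon1, by = dlat))
}

constant_field <- function(value, grid = small_grid(),
                           times = as.Date("2019-12-01") + 0:2) {
  geo_field(array(value, c(length(times), length(grid$lats), length(grid$lons))),
            grid, times, units = "u", var = "x")
}

# one-season chlorophyll window: baseline with a plateau bloom
season_window <- function(n = 30, baseline = 0.1, bloom_steps = 12:18,
                          bloom_value = 0.3) {
  x <- rep(baseline, n)
  x[bloom_steps] <- bloom_value
  geo_series(eight_day_dates(2019, 1)[seq_len(n)], x, units = "mg m-3")
}
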