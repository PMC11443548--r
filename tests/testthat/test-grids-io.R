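test_that("grid constructor enforces monotone regular axes", {
  expect_error(geo_grid(c(1, 2, 4), c(1, 2)), "regularly spaced")
  expect_error(geo_grid(c(1, 3, 2), c(1, 2)), "monotone")
  expect_error(geo_grid(5, c(1, 2)), "at least 2")
  g <- geo_grid(seq(-30, -24, 1), seq(48, 66, 1))
  expect_equal(unname(g$spacing), c(1, 1))
})

test_that("subset keeps exactly the cells whose centers fall in the region", {
  gg <- geo_grid(seq(-89.5, 89.5, 1), seq(-179.5, 179.5, 1))
  ff <- geo_field(array(1, c(1, 180, 360)), gg, as.Date("2019-12-01"))
  sub <- subset(ff, region(-30, -24, 48, 66))  # the bloom box on a 1-deg grid
  expect_equal(dim(sub$values)[2:3], c(6L, 18L))
  # full domain is the identity
  f <- constant_field(3)
  idf <- subset(f, region(-90, 90, -180, 180))
  expect_identical(idf$values, f$values)
  # empty intersection errors; all-masked region warns
  expect_error(subset(f, region(10, 20, 50, 60)), "intersect")
  fm <- f
  fm$values[, 1:3, 1:3] <- NA
  expect_warning(subset(fm, region(-30, -29, 50, 51)), "masked")
})

test_that("region means honour masks and latitude weighting", {
  f <- constant_field(2.5)
  r <- region(-30, -20, 50, 60)
  expect_equal(region_mean(f, r, "coslat")$value, rep(2.5, 3))
  expect_equal(region_mean(f, r, "none")$value, rep(2.5, 3))
  # half the cells masked: mean of the remainder
  fm <- constant_field(1)
  fm$values[, , 1:11] <- 4
  fm$values[, , 12:21] <- NA
  expect_equal(region_mean(fm, r, "none")$value, rep(4, 3))
  # all cells masked at one time step -> missing
  fm2 <- constant_field(1)
  fm2$values[2, , ] <- NA
  expect_equal(is.na(region_mean(fm2, r)$value), c(FALSE, TRUE, FALSE))
  # field linear in latitude: unweighted mean = mid-latitude value,
  # cos-lat mean matches the closed-form weighted average
  g <- small_grid(0.5)
  vals <- array(rep(g$lats, length(g$lons)), c(1, length(g$lats), length(g$lons)))
  fl <- geo_field(vals, g, as.Date("2019-12-01"))
  expect_equal(region_mean(fl, r, "none")$value, mean(g$lats))
  w <- cos(g$lats * pi / 180)
  expect_equal(region_mean(fl, r, "coslat")$value, sum(w * g$lats) / sum(w))
})

test_that("valid pixel fraction counts unmasked cells", {
  g <- geo_grid(seq(-30, -20.5, 0.5), seq(50, 59.5, 0.5))  # 400 cells
  f <- constant_field(1, g)
  r <- region(-30, -20, 50, 60)
  expect_equal(valid_pixel_fraction(f, r)$value, rep(1, 3))
  n_cells <- prod(dim(f$values)[2:3])
  f$values[1, , ][seq_len(0.2 * n_cells)] <- NA
  f$values[2, , ] <- NA
  vf <- valid_pixel_fraction(f, r)
  expect_equal(vf$value[1], 0.8, tolerance = 1e-9)
  expect_equal(vf$value[2], 0)
})

test_that("temporal resampling averages available samples per bin", {
  s <- geo_series(as.Date("2019-01-01") + 0:89,
                  c(rep(1, 31), rep(2, 28), rep(NA, 31)))
  m <- resample_time(s, "monthly")
  expect_equal(m$value, c(1, 2, NA))
  # constant series stays constant at every resolution
  cs <- geo_series(as.Date("2019-01-01") + 0:365, rep(7, 366))
  expect_true(all(resample_time(cs, "monthly")$value == 7))
  expect_true(all(resample_time(cs, "8day")$value == 7))
  # a coarser-than-target source is refused
  ms <- geo_series(seq(as.Date("2019-01-01"), by = "month", length.out = 24), 1:24)
  expect_error(resample_time(ms, "daily"), "not finer")
  # aggregation commutes with spatial averaging for complete unweighted data
  f <- constant_field(1, times = as.Date("2019-01-01") + 0:59)
  f$values[] <- rep(sin(1:60), prod(dim(f$values)[2:3]))
  r <- region(-30, -20, 50, 60)
  a <- resample_time(region_mean(f, r, "none"), "monthly")$value
  b <- region_mean(resample_time(f, "monthly"), r, "none")$value
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("field text serialization round-trips exactly", {
  sim <- make_sla_field(small_grid(0.5), list(eddy_truth(-25, 55, 0.1, 60)),
                        noise_sd = 0.01, seed = 3,
                        times = as.Date("2019-12-01") + 0:2)
  fld <- sim$field
  fld$values[1, 2, 3] <- NA
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_field(fld, tmp)
  back <- read_field(tmp, "sla")
  expect_identical(back$values, fld$values)
  expect_equal(back$units, "m")
  expect_equal(back$grid$lats, fld$grid$lats)
  expect_error(read_field(tmp, "chl"), "available: sla")
  # row order on disk is irrelevant: axes are normalized on read
  rows <- utils::read.csv(tmp)
  shuffled <- rows[rev(seq_len(nrow(rows))), ]
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shuffled, tmp2, row.names = FALSE, na = "")
  file.copy(paste0(tmp, ".json"), paste0(tmp2, ".json"))
  back2 <- read_field(tmp2, "sla")
  expect_equal(back2$values, fld$values, tolerance = 1e-12)
})

test_that("series and profile CSV round-trips preserve values and metadata", {
  s <- geo_series(as.Date("2019-01-01") + 0:9, c(1:9, NA), units = "mg m-3")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_series(s, tmp)
  b <- read_series(tmp)
  expect_identical(b$value, s$value)
  expect_equal(attr(b, "units"), "mg m-3")
  p <- make_profile(profile_truth(42, 26, 10), dz = 2)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_profile(p, tmp2)
  bp <- read_profile(tmp2)
  expect_equal(bp$temperature, p$temperature)
  expect_equal(mld_from_profile(bp), mld_from_profile(p))
})

test_that("truth sidecars survive the JSON round trip", {
  tr <- list(blooms = data.frame(initiation = c(12L, 60L), termination = c(19L, 70L)))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, tmp)
  back <- read_truth(tmp)
  expect_equal(back$blooms$initiation, c(12, 60))
})

test_that("region means are invariant under pre-subsetting", {
  sim <- make_sla_field(small_grid(0.5), list(eddy_truth(-25, 55, 0.1, 60)),
                        noise_sd = 0.02, seed = 5)
  r <- region(-28, -22, 52, 58)
  a <- region_mean(sim$field, r)$value
  b <- region_mean(subset(sim$field, r), r)$value
  expect_equal(a, b, tolerance = 1e-12)
})
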