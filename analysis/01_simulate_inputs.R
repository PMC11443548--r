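#!/usr/bin/env Rscript
# Build the synthetic study archive: every input the downstream analyses
# consume, with ground truth saved alongside as JSON sidecars.
#
# The archive emulates the observational setting of the 2019/2020
# south-east Madagascar bloom analyses: a 24-year 8-day chlorophyll record
# over the bloom box with one planted austral-summer bloom per season (the
# final season's bloom made stronger and earlier), an SLA field with planted
# mesoscale eddies, Argo-style thermocline profiles, daily event-like dust
# and precipitation series, and a multi-decade monthly trend field.

suppressPackageStartupMessages(library(seabloom))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2019

## 24-year chlorophyll archive, one bloom per season ------------------------
blooms <- with_seed(seed, lapply(1:23, function(j) {
  if (j == 23) {
    # the exceptional final season: initiation in mid-November instead of
    # the usual January (~2.5 months early), three times the usual
    # amplitude, and ~3 weeks longer
    init <- 46 * (j - 1) + 41
    dur <- 15
    amp <- 0.3
  } else {
    # ordinary austral-summer blooms: initiation in early-mid January
    init <- 46 * j + sample(2:5, 1)
    dur <- sample(10:14, 1)
    amp <- 0.1
  }
  bloom_truth(init, init + floor(dur / 2), init + dur, amplitude = amp,
              baseline = 0.1,
              season_label = paste0(1996 + j, "/", 1997 + j))
}))
chl <- make_chl_series(24, baseline = 0.1, blooms = blooms,
                       gap_fraction = 0.15, noise_cv = 0.1, seed = seed,
                       start_year = 1997, shape = "peaked")
write_series(chl$series, file.path(out, "chl_8day.csv"))
write_truth(lapply(chl$truth, unclass), file.path(out, "chl_truth.json"))
cat("chlorophyll archive:", length(chl$series$value), "8-day steps,",
    length(chl$truth), "planted blooms,",
    length(chl$masked_steps), "cloud-masked steps\n")

## SLA field with planted eddies over the bloom region ----------------------
grid <- geo_grid(seq(-32, -12, by = 0.25), seq(45, 65, by = 0.25))
eddies <- list(eddy_truth(-26.5, 51.5, 0.22, 110),   # the two bloom-carrying
               eddy_truth(-25.5, 56.0, 0.18, 95),    # anticyclones
               eddy_truth(-18.5, 60.5, -0.12, 120))
sla <- make_sla_field(grid, eddies, noise_sd = 0.005, seed = seed,
                      times = as.Date("2019-12-01") + 0:4)
write_field(sla$field, file.path(out, "sla.csv"))
write_truth(lapply(sla$truth, unclass), file.path(out, "sla_truth.json"))
cat("SLA field:", paste(dim(sla$field$values), collapse = " x "),
    "with", length(eddies), "planted eddies\n")

## Argo-style profiles -------------------------------------------------------
profiles <- with_seed(seed, lapply(1:8, function(i) {
  tr <- profile_truth(runif(1, 25, 60), runif(1, 23.5, 26.5), runif(1, 6, 12))
  list(truth = tr,
       profile = make_profile(tr, dz = 2, noise_sd = 0.01, seed = seed + i))
}))
for (i in seq_along(profiles)) {
  write_profile(profiles[[i]]$profile, file.path(out, sprintf("profile_%02d.csv", i)))
}
write_truth(lapply(profiles, function(p) unclass(p$truth)),
            file.path(out, "profile_truth.json"))
cat("profiles:", length(profiles), "written\n")

## Daily dust-AOD and precipitation event series -----------------------------
# two deposition episodes in Nov/Dec of the final year of an 18-year record
n_days <- as.integer(as.Date("2020-12-31") - as.Date("2003-01-01")) + 1L
ev_start <- as.integer(as.Date("2019-11-15") - as.Date("2003-01-01")) + 1L
ev2_start <- as.integer(as.Date("2019-12-05") - as.Date("2003-01-01")) + 1L
aod <- make_event_series(n_days, base_level = 0.08,
                         events = list(list(start = ev_start, length = 6, magnitude = 0.12),
                                       list(start = ev2_start, length = 5, magnitude = 0.10)),
                         noise_sd = 0.03, seed = seed, units = "1")
rain <- make_event_series(n_days, base_level = 2,
                          events = list(list(start = ev_start + 4, length = 4, magnitude = 4),
                                        list(start = ev2_start + 3, length = 5, magnitude = 3.2)),
                          noise_sd = 0.8, seed = seed + 1, units = "mm day-1")
write_series(aod$series, file.path(out, "dust_aod_daily.csv"))
write_series(rain$series, file.path(out, "precip_daily.csv"))
write_truth(list(aod = aod$truth, precipitation = rain$truth),
            file.path(out, "event_truth.json"))
cat("event series:", n_days, "days, episodes at",
    format(aod$series$time[ev_start]), "and", format(aod$series$time[ev2_start]), "\n")

## Five MERRA-2-style wet-deposition size bins -------------------------------
dep_bins <- with_seed(seed + 2, lapply(1:5, function(b) {
  ev <- make_event_series(n_days, base_level = 0.2 / b,
                          events = list(list(start = ev_start + 4, length = 4,
                                             magnitude = 0.8 / b)),
                          noise_sd = 0.3 / b, seed = seed + 10 + b,
                          units = "mg m-2 day-1")
  ev$series
}))
for (b in 1:5) write_series(dep_bins[[b]], file.path(out, sprintf("wetdep_bin%d.csv", b)))

## 41-year monthly temperature-like trend field ------------------------------
tgrid <- geo_grid(seq(-35, -18, by = 1), seq(12, 32, by = 1))
trend <- make_trend_field(tgrid, trend_truth(0.25, 22, noise_sd = 0.6),
                          n_months = 492, seed = seed,
                          start_date = as.Date("1980-01-01"))
write_field(trend$field, file.path(out, "airtemp_monthly.csv"))
write_truth(unclass(trend$truth), file.path(out, "trend_truth.json"))
cat("trend field:", paste(dim(trend$field$values), collapse = " x "),
    "months x lat x lon, planted slope 0.25 units/decade\n")
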