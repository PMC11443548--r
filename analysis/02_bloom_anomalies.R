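#!/usr/bin/env Rscript
# Climatology and anomalies of the chlorophyll archive: how exceptional is
# the final season? Also reports the valid-pixel coverage of the SLA field
# as a data-quality diagnostic.

suppressPackageStartupMessages(library(seabloom))
src <- "results/synthetic"
dir.create("results", showWarnings = FALSE)

chl <- read_series(file.path(src, "chl_8day.csv"))
filled <- fill_gaps_linear(chl)

## monthly means and relative anomalies (the map-style statistic) ------------
monthly <- resample_time(filled, "monthly")
clim <- build_climatology(monthly, "month",
                         reference_period = as.Date(c("1998-01-01", "2020-12-31")))
rel <- relative_anomaly(monthly, clim)
std <- standardized_anomaly(monthly, clim)
tab <- data.frame(time = monthly$time, chl = monthly$value,
                  relative_anomaly_pct = rel$value,
                  standardized_anomaly_sd = std$value)
utils::write.csv(tab, "results/chl_monthly_anomalies.csv", row.names = FALSE)

peak <- tab[which.max(tab$relative_anomaly_pct), ]
cat(sprintf("largest monthly relative anomaly: %.0f%% (%.2f SD) in %s\n",
            peak$relative_anomaly_pct, peak$standardized_anomaly_sd,
            format(peak$time, "%Y-%m")))
dec <- tab[format(tab$time, "%m") == "12", ]
dec_rank <- rank(-dec$chl)[format(dec$time, "%Y") == "2019"]
cat(sprintf("December 2019 chlorophyll ranks %d of %d Decembers\n",
            dec_rank, nrow(dec)))

## coverage diagnostic on the raw (gappy) series -----------------------------
coverage <- mean(!is.na(chl$value))
cat(sprintf("8-day archive coverage before filling: %.0f%%\n", 100 * coverage))

sla <- read_field(file.path(src, "sla.csv"), "sla")
vp <- valid_pixel_fraction(sla, region(-30, -24, 48, 66))
utils::write.csv(as.data.frame(vp), "results/sla_valid_pixels.csv", row.names = FALSE)
cat(sprintf("SLA valid-pixel fraction over the bloom box: %.2f-%.2f\n",
            min(vp$value), max(vp$value)))
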