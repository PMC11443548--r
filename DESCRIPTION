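Package: seabloom
Title: Phenology and Physical Drivers of Open-Ocean Phytoplankton Blooms from Gridded Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing satellite-style gridded ocean fields and point
    time series around anomalous open-ocean phytoplankton blooms: seeded
    synthetic-data generators with recorded ground truth (chlorophyll series
    with planted blooms, sea-level-anomaly fields with planted Gaussian eddies,
    thermocline profiles, event-like aerosol/precipitation series, linear-trend
    fields); gridded-field containers with region subsetting, area means and
    coverage diagnostics; climatologies, relative and standardized anomalies,
    significance-masked decadal trends and gap interpolation; bloom phenology
    (initiation, peak, termination, duration) by threshold-referenced
    cumulative sums of anomalies with a moving-box robustness scan; mesoscale
    eddy detection from closed sea-level-anomaly contours with polarity
    counting and eddy kinetic energy; mixed-layer depth and temperature from
    vertical profiles; diffuse-attenuation and mixed-layer-averaged irradiance;
    and the chlorophyll fluorescence quantum yield iron-stress proxy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
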