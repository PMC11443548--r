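# seabloom

Desk-scale analysis of anomalous open-ocean phytoplankton blooms from
satellite-style gridded fields and point time series — built around the kind
of event exemplified by the 2019/2020 austral-summer bloom south-east of
Madagascar, where an unseasonal chlorophyll surge coincided with dust
deposition, mesoscale eddy stirring, and relief of iron stress.

The package is aimed at ocean-color / biological-oceanography analysts who
want the full chain of methods behind such an event study as tested,
reusable code: every stage runs on synthetic inputs with planted ground
truth, so the whole pipeline is verifiable without multi-gigabyte satellite
downloads.

## What it computes

**Bloom phenology** from a gap-filled 8-day chlorophyll series. The bloom
threshold is the long-term median of the whole record plus 20%
(`thr = 1.2 · median(Chl)`). Anomalies `Chl_t − thr` are accumulated and
the gradient sign changes of the cumulative sum locate the transitions:
initiation is the threshold upcrossing that opens the main growth period
(the cumulative-sum minimum before the seasonal peak), termination the first
downcrossing after the peak, and duration the number of 8-day periods
between them. Detection runs per austral season (October–May) on a fixed
46-step-per-year calendar; a 5°×5° moving-box scan checks that conclusions
do not hinge on one averaging region.

**Climatologies and anomalies** with dataset-specific reference periods:
relative anomalies `100·(x − μ_clim)/μ_clim` (percent above the monthly
climatological mean), standardized anomalies `(x − μ_clim)/σ_clim` (SD
units), linear gap filling, centered moving means, and per-pixel decadal
trends (OLS slope in units/decade with the two-sided t-test, pixels with
p ≥ 0.05 masked).

**Eddy dynamics**: eddy kinetic energy `EKE = ½(u² + v²)` from (geostrophic)
surface currents, and a closed-contour SLA eddy detector — center from the
innermost closed contour's anomaly-weighted mass center, edge as the
outermost closed contour enclosing a single core, anticyclones at SLA maxima
and cyclones at minima (Southern Hemisphere), censused by polarity.

**Mixed layer and light**: mixed-layer depth by the 0.2 °C
temperature-difference criterion against a 10 m reference, mixed-layer mean
temperature (with the 24 °C diazotroph lower limit as a flag), Kd(490) and
Kd(PAR) from chlorophyll, and mixed-layer-averaged PAR
`PAR_ml = PAR_0 (1 − e^{−K_d·H})/(K_d·H)`.

**Iron stress**: the chlorophyll fluorescence quantum yield
`φ_f ∝ nFLH / (a_ph(Chl) · iPAR)` and its standardized anomaly Δφ_f, the
satellite proxy of iron limitation.

**Synthetic data with truth**: seeded generators for all of the above
(planted blooms, Gaussian eddies with geostrophically consistent currents,
tanh thermoclines, step events, linear trends), each returning the ground
truth needed to score recovery.

## Worked example

The numbered scripts under `analysis/` run the pipeline end to end on a
synthetic 24-year archive (one planted austral-summer bloom per season, the
final one stronger, earlier and longer) and write tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_bloom_anomalies.R
Rscript analysis/03_phenology.R
# ... 04 eddies/EKE, 05 mixed layer/light, 06 iron stress & trends
```

which prints, among other things:

```
largest monthly relative anomaly: 267% (4.58 SD) in 2019-12
December 2019 chlorophyll ranks 1 of 24 Decembers
threshold: 0.1240 mg m-3 (1.2 x long-term median)
seasons detected: 23/23; timing within +/-1 step: 23/23
2019/2020: initiation step-of-year 41 vs usual 49.5 (8.5 steps ~ 2.2 months early), duration 15 vs usual 12.0 steps
census per slice: 1 cyclonic, 2 anticyclonic (planted: 1, 2)
fluorescence quantum yield: planted -2.7 SD excursion read back as -2.70 SD
```

Read: the planted exceptional season is recovered as such — its December
chlorophyll is the highest of the 24-year record and more than 200% above
the monthly climatology, its initiation is detected ~2.5 months before the
usual January onset and its duration ~3 eight-day periods longer, the eddy
census matches the planted field exactly, and the planted iron-stress relief
excursion is read back at its planted depth.

In code, the core call pattern is:

```r
library(seabloom)
sim <- make_chl_series(24, blooms = my_blooms, gap_fraction = 0.2,
                       noise_cv = 0.1, seed = 1)
pheno_pipeline(sim$series)   # one row per season: initiation/peak/termination
```

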