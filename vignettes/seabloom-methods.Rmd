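---
title: "Methods behind seabloom: bloom phenology, eddies, mixed layers and iron stress on gridded fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind seabloom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seabloom)
```

seabloom packages the analysis chain behind event studies of anomalous
open-ocean phytoplankton blooms: phenology from ocean-color time series,
anomaly and trend statistics on gridded environmental fields, mesoscale eddy
detection from sea level anomaly (SLA), mixed-layer physics and light, and
the fluorescence-based iron-stress proxy. This vignette explains each model,
the tunable parameters and their defaults, the numerical choices, what the
synthetic-data generators do and do not emulate, and the known limitations.

## The data model

All gridded data live in a `geo_field`: a `(time, lat, lon)` array on a
regular cell-centered latitude/longitude grid with `NA` as the missing-data
mask. Statistics always run over available cells — missing data are never
zero-filled. Point records are `geo_series` data frames (`time`, `value`).
Ocean-color style composites use a fixed 46-step 8-day calendar (step 46
absorbs the year-end remainder), which keeps step indices aligned across
years. Region means default to cos-latitude weighting (cell area on a
regular grid scales with cos φ); an unweighted mode exists because mapped
L3 analyses often skip the weighting, and the two differ only when the
field co-varies with latitude inside the region.

Gridded I/O uses a long-format CSV plus a JSON metadata sidecar (units per
variable, ISO-8601 dates). The format is deliberately plain text: it
round-trips doubles exactly (values are printed with `%.17g`), keeps
fixtures human-readable, and carries the same information the package needs
from a CF-attributed file (axes, units, fill). Axes are normalized to
ascending order on read regardless of row order on disk.

## Bloom phenology

The detector implements the threshold-referenced cumulative-sums method.
The threshold is

> thr = median(entire multi-year series) × (1 + p),  p = 0.20 by default,

computed **once** from the full record, not per season; `threshold_percent`
is exposed because 5–15% variants are in use for climatological analyses.
The cumulative sum of anomalies `C_t = Σ (x_s − thr)` rises exactly while
the series exceeds the threshold, so its gradient sign changes are the
threshold crossings. Within one season window:

* the **peak** is the first occurrence of the seasonal maximum (ties break
  to the earliest step);
* **initiation** is the gradient sign change at the cumulative-sum minimum
  before the peak. On a clean series with a single crossing pair this *is*
  the first step above the threshold; when noise produces isolated one-step
  exceedances, the cumulative-sum minimum picks the transition from the
  decreasing to the sustained increasing trend — the beginning of the main
  growth period — rather than the first noise spike. Either way the
  selected step is a genuine upcrossing, so the cumulative-sum and
  direct-crossing formulations agree on the reported event;
* **termination** is the first step after the peak below the threshold; if
  the season ends first, the window end is reported and flagged;
* **duration** = termination − initiation, in 8-day periods.

The method needs a gap-free series, so `fill_gaps_linear()` interpolates
interior gaps linearly in time and extends edge gaps with the nearest
observation (pure interpolation cannot extrapolate; phenology windows need
values at both ends). Gap filling interacts with timing: inside a filled
gap, the crossing position of a linear ramp reflects only where the
threshold sits between the two bracketing observations, not anything
measured. Detection therefore snaps a crossing that falls inside an
unobserved span (or on its closing observation) to the midpoint of that
span — the unbiased estimate for an event known only to have happened
within the gap. On fully observed series the snap is a no-op.

Seasons are October-of-year-y through May-of-year-y+1 (configurable),
which isolates austral spring/summer and excludes secondary winter growth;
a step belongs to the window of its start date, so windows never split a
step. Bloom years are not taken from a fixed list: detection runs on every
complete season and reports a detected/not-detected flag, which is a
reproducible replacement for choosing seasons by prior literature or eye.

The `box_scan()` robustness analysis slides a 5°×5° box at 1° stride over a
domain and recomputes the region-mean series at every fully contained
position; the position count is the closed form
`((Δlat − box)/stride + 1)·((Δlon − box)/stride + 1)` — 966 for a 25°×50°
domain. Counting corner positions including partially contained boxes would
give 1,250; no stated convention reproduces a count of several thousand for
such a domain, so the package reports its own closed-form count.

## Climatologies, anomalies, trends

A `climatology` holds per-period-of-year means and SDs (calendar month,
8-day step, or day-of-year with Feb 29 pooled into Feb 28 — pooling avoids a
4-fold undersampled period) over an explicit reference period. Reference
periods are per-dataset configuration because multi-sensor archives start in
different years; anomalies are only comparable against their own record's
climatology. Periods with fewer than `min_samples = 5` samples are flagged
and propagate to missing anomalies rather than unstable ones.

Relative anomalies are `100·(x − μ)/μ` with non-positive or flagged means
giving missing values (never infinities); standardized anomalies are
`(x − μ)/σ` with zero/flagged SDs giving missing values. A useful identity
for calibration: over its own reference period each period's standardized
anomalies have sample mean exactly 0 and sample SD exactly 1, so the pooled
SD equals `sqrt(Σ(n_p − 1)/(N − 1))` — about 0.975 for 20 years of 8-day
data — independent of the data.

Decadal trends are per-pixel OLS slopes against time in decades
(365.2425-day years from the first sample), with the classical two-sided
t-test and masking at p ≥ 0.05. No serial-autocorrelation correction is
applied — the simplest reading of per-pixel trend maps — and that choice is
deliberate and visible: with autocorrelated monthly data the nominal test is
anticonservative, which matters for significance maps but not for the
slope estimates themselves. Noiseless linear input recovers the slope to
machine precision with p set to 0 by convention (exact fit).

Dust wet deposition arrives as five size-bin fluxes; the total is their
elementwise sum, missing wherever any bin is missing.

## Eddy detection and EKE

`detect_eddies()` traces SLA contours on a ladder of levels spaced
`contour_interval` apart (1 cm default) with `grDevices::contourLines`;
contours that close (equal endpoints) are candidate eddy boundaries, and
contours that intersect the domain edge are discarded. For each local
extremum, enclosing closed contours are accepted outward — SLA strictly
nearer the background at each successive level — until a contour would
enclose a second eddy core. A second enclosed maximum counts as a core only
if it rises at least `min_amplitude` above the contour level **and** is
separated from the first by a saddle at least `min_amplitude` deep (checked
along the straight grid path between them); without the saddle condition,
sub-noise bumps on a flat eddy crown would truncate growth. The outermost
accepted contour is the edge; amplitude is extremum minus edge level;
detections are filtered by amplitude (≥ 2 cm) and edge-enclosed area
(8–1000 cells) and discarded if they touch a supplied shallow-water mask
(the contour method is conventionally trusted only beyond the 200 m
isobath). The center is the anomaly-weighted mass center of the cells
inside the innermost accepted contour that encloses at least
`min_area_cells` centers — the very smallest contours circle residual noise
bumps and carry no positional information. The reported equivalent radius
derives from the edge-enclosed area, so it is larger than a Gaussian
e-folding radius (roughly the 2-sigma contour for the synthetic eddies).

These numeric criteria are declared defaults in `eddy_criteria()`, in the
range conventional for 25 km altimetry products; none is claimed from a
published table. Cyclones are found by running the identical detector on
the negated field, which makes the polarity swap under `SLA → −SLA` exact
by construction. Eddies are not tracked across time steps.

EKE is `½(u² + v²)`. The package computes it from whatever current fields
it is given; the synthetic route derives geostrophic currents from SLA
(`u = −(g/f)·∂η/∂y`, `v = (g/f)·∂η/∂x`, centered differences on the
sphere, boundary cells masked, equatorward of 5° refused because f → 0).
Whether "EKE" should use absolute or anomaly currents is a genuine
ambiguity in the literature; the functions are agnostic — pass anomaly
currents to get anomaly EKE.

## Mixed layer, temperature, light

`mld_from_profile()` implements the temperature-difference criterion: the
shallowest depth where T ≤ T(10 m) − 0.2 °C, with the reference sample
taken as the good-QC sample nearest 10 m within ±5 m (floats rarely sample
10 m exactly) and the crossing located by linear interpolation between
bracketing samples. Profiles that never meet the criterion return a flagged
missing value ("deeper than profile"), never a number. Pressure coordinates
are converted by the hydrostatic approximation `z = 10⁴·p/(ρg)` with
ρ = 1025 kg m⁻³ (about 0.6% shallower than the dbar value), recorded in the
function documentation. Mixed-layer temperature is the mean of good samples
above the MLD, and the 24 °C diazotroph lower limit is exposed as a labelled
flag (`diazotroph_temperature_ok()`), since nitrogen-fixer growth collapses
below roughly that temperature.

Light: Kd(490) is the case-1 pure-water intercept plus a concave power law
in chlorophyll (defaults 0.0166 + 0.0773·Chl^0.6715 m⁻¹), Kd(PAR) the
rational map 0.0665 + 0.874·Kd(490) − 0.00121/Kd(490) m⁻¹, and mixed-layer
PAR the depth average of exponentially attenuated surface irradiance,
`PAR_0·(1 − e^{−K_d H})/(K_d H)`, evaluated with `expm1` for stability and
tending to the surface value as H → 0. All optical coefficients ship in
`optics_config()` so they can be revised without touching code.

## Fluorescence quantum yield

The iron-stress proxy divides fluorescence emission by absorbed radiation:
`φ_f = scale · nFLH / (a_ph(Chl) · iPAR)` with a Bricaud-style power law
`a_ph = a·Chl^b` (defaults 0.0147·Chl^0.582). The structure — exact
linearity in nFLH, strict monotone decrease in iPAR — is what the analyses
rely on; absolute coefficient values live in `fluor_config()` and any
constant scale cancels in the standardized anomaly Δφ_f, which delegates to
the generic anomaly pipeline with no special-casing. Validity floors
(Chl ≥ 0.01 mg m⁻³, iPAR ≥ 10 µE m⁻² s⁻¹ by default) turn degenerate
inputs into counted missing values rather than exceptions. No
non-photochemical-quenching correction beyond this formulation is applied.

## Synthetic data: what it emulates, and what passing tests show

The generators emulate the *statistical shape* of the real inputs:
multi-year 8-day/daily/monthly series with seasonal cycles, mean-one
lognormal noise for chlorophyll (multiplicative, positivity-preserving;
`noise_cv` is the coefficient of variation), additive Gaussian noise for
SLA and temperature, missing-at-random cloud gaps (with a blocked-gap
option for contiguous cloud runs), Gaussian SLA eddies with geostrophically
consistent currents, tanh thermoclines placed so the planted MLD is exactly
where the 0.2 °C criterion crosses, step events, and linear trends. Every
generator returns the truth needed to score recovery, and all randomness
flows from one seed per call (`with_seed()` restores the caller's RNG
state, so runs are bit-reproducible and composable).

Two conventions are worth stating. First, a planted bloom's
`termination` index denotes the first step *back at baseline* (elevation
spans `[initiation, termination)`), matching the detector's definition of
termination as the first below-threshold step, so recovery is scored
index-for-index. Second, the recovery experiments fix the study conditions
once: 100 archives × 24 years, noise CV 0.1, 20% gaps, plateau amplitude
0.2 mg m⁻³ on a 0.1 mg m⁻³ baseline for phenology; 50 fields with 1–6
well-separated eddies (|A| ≥ 5 cm, radius ≥ ~3 grid cells, 0.5 cm noise);
100 tanh profiles at 1–5 m spacing; 2000 flat-noise pixels for masking
calibration. These sizes keep the full suite under a minute or two of CPU
while leaving the statistical margins wide.

What the generators do **not** emulate: radiative transfer, eddy dynamics
(advection, merging, tracking), dust transport, spatially correlated cloud
masks, sensor drift and inter-mission biases, or non-Gaussian SLA noise.
Passing recovery tests therefore demonstrates that the *algorithms* are
implemented correctly and are robust at realistic noise and gap levels —
not that real retrievals are unbiased. On real archives the dominant error
sources (product merging, coastal contamination, coverage shifts) enter
upstream of this package.

## Numerical choices and degenerate inputs

* Medians and OLS use the standard R implementations; no reimplementation
  of base statistics.
* Ties: the seasonal peak takes the earliest occurrence; series exactly at
  the threshold do not cross it (strict inequalities on both sides).
* A season entirely below threshold is a regular "no bloom detected"
  result; entirely above is initiation-at-window-start, flagged.
* Climatology SDs from a single sample are undefined and flagged; `sd = 0`
  periods yield missing standardized anomalies.
* Contour levels snap to multiples of the contour interval; the
  floor/ceiling construction is symmetric under negation, which the
  polarity-swap property requires.
* `p = 0` is reported for exact (zero-residual) trend fits, `p = 1` for
  exactly constant pixels.
* Reading gridded text files normalizes axes to ascending order and
  reconstructs the mask from empty cells.

## Limitations

Known limitations, beyond the emulation gaps above: per-pixel trend
p-values ignore serial autocorrelation (an option a future version could
add via effective sample sizes); the eddy detector reports no tracks and
no multi-core structures; the phenology detector reports one bloom per
season window (secondary winter growth is excluded by the window, not
modelled); longitudes are normalized to [−180, 180) and domains may not
cross the antimeridian; and regridding between resolutions is out of scope
— fields must arrive co-registered.
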