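## Mixed-layer depth and temperature from vertical profiles; diffuse
## attenuation and mixed-layer-averaged irradiance from surface fields.

profile_depth <- function(profile) {
  if (attr(profile, "vertical") == "depth") {
    profile$depth
  } else {
    # hydrostatic approximation z = 1e4 p / (rho g), rho = 1025 kg m-3,
    # g = 9.81 m s-2 (~0.6% shallower than the dbar value); recorded here
    # because float profiles report pressure, not depth
    profile$pressure * 1e4 / (1025 * 9.81)
  }
}

good_samples <- function(profile) {
  ok <- profile$qc == 1L & !is.na(profile$temperature)
  data.frame(depth = profile_depth(profile)[ok],
             temperature = profile$temperature[ok])
}

#' Mixed-layer depth by the 0.2 degC temperature-difference criterion
#'
#' The shallowest depth at which temperature has fallen `delta_t` below the
#' reference temperature near `ref_depth` (default 10 m), located by linear
#' interpolation between the bracketing samples. The reference temperature is
#' taken from the good-quality sample nearest `ref_depth` within +/- 5 m
#' (float profiles rarely sample 10 m exactly). Only samples with QC flag 1
#' are used.
#'
#' @param profile A profile (see [make_profile()], [read_profile()]).
#' @param delta_t Temperature-difference threshold (degC, default 0.2).
#' @param ref_depth Reference depth (m, default 10).
#' @return The mixed-layer depth in m, or `NA` with attribute
#'   `flag = "deeper than profile"` when the criterion is never met within
#'   the profile (e.g. an isothermal profile).
#' @export
mld_from_profile <- function(profile, delta_t = 0.2, ref_depth = 10) {
  stopifnot(inherits(profile, "profile"))
  s <- good_samples(profile)
  if (nrow(s) < 2) stop("profile has fewer than 2 good samples")
  near <- which(abs(s$depth - ref_depth) <= 5)
  if (length(near) == 0) {
    stop("no good sample within 5 m of the ", ref_depth, " m reference depth")
  }
  iref <- near[which.min(abs(s$depth[near] - ref_depth))]
  tref <- s$temperature[iref]
  target <- tref - delta_t
  below <- which(s$depth > s$depth[iref] & s$temperature <= target)
  if (length(below) == 0) {
    out <- NA_real_
    attr(out, "flag") <- "deeper than profile"
    return(out)
  }
  j <- below[1]
  if (j == 1) return(s$depth[1])
  z1 <- s$depth[j - 1]; t1 <- s$temperature[j - 1]
  z2 <- s$depth[j];     t2 <- s$temperature[j]
  if (t1 == t2) return(z2)
  z1 + (target - t1) * (z2 - z1) / (t2 - t1)
}

#' Mean temperature within the mixed layer
#'
#' Average of the good-quality temperature samples at depths at or above the
#' mixed-layer depth.
#'
#' @param profile A profile.
#' @param mld Mixed-layer depth (m), within the profile's depth range.
#' @return Mean mixed-layer temperature (degC).
#' @export
ml_temperature <- function(profile, mld) {
  stopifnot(inherits(profile, "profile"))
  if (is.na(mld)) stop("mld is missing")
  s <- good_samples(profile)
  sel <- s$depth <= mld
  if (!any(sel)) stop("no good samples above the mixed-layer depth")
  mean(s$temperature[sel])
}

#' Is the mixed layer warm enough for diazotrophs?
#'
#' Nitrogen-fixing phytoplankton such as *Trichodesmium* grow poorly below
#' about 24 degC; this labels a mixed-layer temperature against that lower
#' limit.
#'
#' @param tml Mixed-layer temperature (degC), vectorized.
#' @param lower_limit Threshold (degC, default 24).
#' @return Logical: `TRUE` where `tml >= lower_limit`.
#' @export
diazotroph_temperature_ok <- function(tml, lower_limit = 24) {
  tml >= lower_limit
}

#' Optical coefficients for attenuation and mixed-layer irradiance
#'
#' Coefficient set for the chlorophyll-based diffuse-attenuation
#' parameterizations (case-1 water bio-optical models of the Morel family):
#' `Kd(490) = kd490_pure + kd490_coef * Chl^kd490_exp` and
#' `Kd(PAR) = kdpar_c0 + kdpar_c1 * Kd(490) + kdpar_c2 / Kd(490)`.
#' Shipping the coefficients as configuration keeps the formulas updatable
#' without touching code.
#'
#' @param kd490_pure Pure-water intercept at 490 nm (1/m).
#' @param kd490_coef,kd490_exp Power-law coefficients on chlorophyll.
#' @param kdpar_c0,kdpar_c1,kdpar_c2 Rational-form coefficients mapping
#'   Kd(490) to Kd(PAR) over the first optical depth.
#' @return An `optics_config` list.
#' @export
optics_config <- function(kd490_pure = 0.0166, kd490_coef = 0.0773,
                          kd490_exp = 0.6715, kdpar_c0 = 0.0665,
                          kdpar_c1 = 0.874, kdpar_c2 = -0.00121) {
  structure(list(kd490_pure = kd490_pure, kd490_coef = kd490_coef,
                 kd490_exp = kd490_exp, kdpar_c0 = kdpar_c0,
                 kdpar_c1 = kdpar_c1, kdpar_c2 = kdpar_c2),
            class = "optics_config")
}

#' Diffuse attenuation at 490 nm from chlorophyll
#'
#' Pure-water intercept plus a concave power law in chlorophyll (exponent
#' < 1): strictly increasing, and tending to the pure-water value as
#' chlorophyll goes to zero.
#'
#' @param chl Chlorophyll-a concentration (mg m-3), >= 0, vectorized.
#' @param config An [optics_config()].
#' @return Kd(490) in 1/m.
#' @export
kd490_from_chl <- function(chl, config = optics_config()) {
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be >= 0")
  config$kd490_pure + config$kd490_coef * chl^config$kd490_exp
}

#' Diffuse attenuation for PAR from Kd(490)
#'
#' Rational closed form mapping the 490 nm attenuation to the broadband PAR
#' attenuation over the upper layer; monotone increasing over the oceanic
#' range and positive for all physically admissible inputs.
#'
#' @param kd490 Kd(490) in 1/m, at or above the pure-water intercept.
#' @param config An [optics_config()].
#' @return Kd(PAR) in 1/m.
#' @export
kdpar_from_kd490 <- function(kd490, config = optics_config()) {
  if (any(kd490 < config$kd490_pure, na.rm = TRUE)) {
    stop("kd490 below the pure-water value is non-physical")
  }
  config$kdpar_c0 + config$kdpar_c1 * kd490 + config$kdpar_c2 / kd490
}

#' Mean PAR within the mixed layer
#'
#' Depth average of exponentially attenuated irradiance over `[0, mld]`:
#' `PAR_ml = PAR_0 * (1 - exp(-Kd_PAR * mld)) / (Kd_PAR * mld)`.
#' As `mld -> 0` this tends to the surface value; it decreases strictly with
#' deepening of the mixed layer at fixed attenuation.
#'
#' @param par_surface Surface PAR (E m-2 day-1), vectorized.
#' @param kd_par Kd(PAR) in 1/m, > 0.
#' @param mld Mixed-layer depth (m), >= 0.
#' @return Mixed-layer-averaged PAR (E m-2 day-1).
#' @export
par_in_mixed_layer <- function(par_surface, kd_par, mld) {
  if (any(kd_par <= 0, na.rm = TRUE)) stop("kd_par must be > 0")
  if (any(mld < 0, na.rm = TRUE)) stop("mld must be >= 0")
  x <- kd_par * mld
  frac <- ifelse(x == 0, 1, -expm1(-x) / x)  # numerically stable (1 - e^-x)/x
  par_surface * frac
}
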