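## Chlorophyll fluorescence quantum yield: the iron-stress proxy.
##
## Iron stress raises the fraction of absorbed light that phytoplankton
## re-emit as fluorescence; a drop in the quantum yield therefore signals
## relief of iron limitation (for instance after a dust-deposition event).

#' Coefficients for the fluorescence quantum yield
#'
#' The yield is fluorescence emission over absorbed radiation:
#' emission is proportional to the normalized fluorescence line height
#' (nFLH), absorption to `aph * iPAR` with a chlorophyll-dependent
#' phytoplankton absorption power law `aph = aph_coef * Chl^aph_exp`
#' (Bricaud-style case-1 parameterization). All coefficients live here, as
#' configuration: the structural properties of the yield (linearity in nFLH,
#' monotone decrease in iPAR) do not depend on their exact values.
#'
#' @param scale Overall radiometric conversion factor (default 1; any
#'   constant cancels in standardized anomalies).
#' @param aph_coef,aph_exp Absorption power-law coefficients (default
#'   0.0147, 0.582; exponent < 1 so specific absorption falls as pigment
#'   packaging increases).
#' @param min_chl,min_ipar Validity floors below which the yield is reported
#'   missing (defaults 0.01 mg m-3 and 10 uE m-2 s-1, in the spirit of the
#'   product documentation; both configurable).
#' @return A `fluor_config` list.
#' @export
fluor_config <- function(scale = 1, aph_coef = 0.0147, aph_exp = 0.582,
                         min_chl = 0.01, min_ipar = 10) {
  structure(list(scale = scale, aph_coef = aph_coef, aph_exp = aph_exp,
                 min_chl = min_chl, min_ipar = min_ipar),
            class = "fluor_config")
}

#' Chlorophyll fluorescence quantum yield
#'
#' `phi_f = scale * nflh / (aph(chl) * ipar)`, elementwise over co-registered
#' inputs. The yield is exactly linear in `nflh` and strictly decreasing in
#' `ipar`. Cells where chlorophyll or instantaneous irradiance are missing,
#' non-positive, or below the validity floors are reported missing (never an
#' exception); the number of such cells is attached as attribute
#' `"n_invalid"`.
#'
#' @param nflh Normalized fluorescence line height (W m-2 um-1 sr-1):
#'   numeric vector/array or [geo_field()].
#' @param ipar Instantaneous irradiance (uE m-2 s-1), same shape.
#' @param chl Chlorophyll-a (mg m-3), same shape.
#' @param par Daily-integrated irradiance (E m-2 day-1); carried for
#'   completeness of the co-registered input set and validity screening of
#'   daylight cells (cells with missing `par` are reported missing).
#' @param config A [fluor_config()].
#' @return Same shape/class as `nflh`: the dimensionless yield.
#' @export
phi_f <- function(nflh, ipar, chl, par = NULL, config = fluor_config()) {
  as_field <- inherits(nflh, "geo_field")
  take <- function(x) if (inherits(x, "geo_field")) x$values else x
  v_nflh <- take(nflh); v_ipar <- take(ipar); v_chl <- take(chl)
  v_par <- if (is.null(par)) NULL else take(par)
  bad <- is.na(v_nflh) | is.na(v_ipar) | is.na(v_chl) |
    v_chl < config$min_chl | v_ipar < config$min_ipar
  if (!is.null(v_par)) bad <- bad | is.na(v_par)
  aph <- config$aph_coef * v_chl^config$aph_exp
  out <- config$scale * v_nflh / (aph * v_ipar)
  out[bad] <- NA_real_
  attr(out, "n_invalid") <- sum(bad)
  if (as_field) {
    f <- geo_field(array(out, dim = dim(v_nflh)), nflh$grid, nflh$times,
                   units = "1", var = "phi_f")
    attr(f, "n_invalid") <- sum(bad)
    f
  } else {
    out
  }
}

#' Standardized anomaly of the fluorescence quantum yield
#'
#' The iron-stress index: the yield expressed in climatological-SD units.
#' Delegates to the generic [standardized_anomaly()] pipeline -- no
#' special-casing.
#'
#' @param phi A [geo_series()] or [geo_field()] of the yield.
#' @param clim A [build_climatology()] result computed on the yield.
#' @return Same class as `phi`, in SD units.
#' @export
delta_phi_f <- function(phi, clim) {
  standardized_anomaly(phi, clim)
}
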