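# CT density calibration and density-modulus mapping.
#
# Unit convention throughout the package: lengths mm, forces N, moduli MPa.
# Radiological density (rhoCT) from the calibration curve is in mgHA/cm^3;
# the ash-density conversion and the modulus power law work in g/cm^3, so
# callers divide by 1000 when crossing between the two (see rhoCtToRhoAsh).

#' Default hydroxyapatite phantom calibration curve
#'
#' The scanner calibration used by the pipeline:
#' `rhoCT = (HU - 93.0710) / 1.0123` with rhoCT in mgHA/cm^3, derived from
#' a four-plug electron density phantom (200, 800, 1250, 1750 mgHA/cm^3).
#'
#' @return A [CalibrationCurve-class].
#' @export
#' @examples
#' huToRhoCt(1500, defaultCalibrationCurve())  # ~1390 mgHA/cm^3
defaultCalibrationCurve <- function() {
  dens <- c(200, 800, 1250, 1750)
  new("CalibrationCurve", slope = 1.0123, intercept = 93.0710,
      plugDensities = dens, plugHU = 1.0123 * dens + 93.0710)
}

#' Default density-modulus law
#'
#' `rho_ash = 0.8772 * rho_ct + 0.07895` (g/cm^3) and
#' `E = 3378 * rho_ash^1.52` (MPa), with an ash-density floor of
#' 0.01 g/cm^3.
#'
#' @return A [DensityModulusLaw-class].
#' @export
defaultDensityModulusLaw <- function() {
  new("DensityModulusLaw", coefficient = 3378, exponent = 1.52,
      ashSlope = 0.8772, ashIntercept = 0.07895, densityFloor = 0.01)
}

#' Default adaptive-factor law
#'
#' `aScl = 994.23 * vScl - 184.55`, clamped to `[-1, 0.5]`.
#'
#' @return An [AsclLaw-class].
#' @export
defaultAsclLaw <- function() {
  new("AsclLaw", slope = 994.23, intercept = -184.55,
      clampLo = -1, clampHi = 0.5)
}

#' Construct region factors
#'
#' @param aScl Adaptive factor for sclerotic bone, in `[-1, 0.5]`.
#' @param dLys Damage factor for lytic bone, in `[0, 0.95]`.
#' @return A [RegionFactors-class]. `regionFactors(0, 0)` is the non-tuned
#'   material model.
#' @export
regionFactors <- function(aScl = 0, dLys = 0) {
  new("RegionFactors", aScl = aScl, dLys = dLys)
}

#' Fit the phantom calibration curve
#'
#' Ordinary least-squares fit of measured CT number on known plug density,
#' `HU = slope * density + intercept`. The returned curve converts CT
#' number to radiological density via `rhoCT = (HU - intercept) / slope`.
#'
#' @param plugDensities Known HA plug densities (mgHA/cm^3), strictly
#'   increasing, at least two.
#' @param plugHU Mean measured CT numbers of the plugs.
#' @return A [CalibrationCurve-class].
#' @export
#' @examples
#' d <- c(200, 800, 1250, 1750)
#' fitPhantomCurve(d, 1.0123 * d + 93.0710)
fitPhantomCurve <- function(plugDensities, plugHU) {
  if (length(plugDensities) < 2)
    .stopInvalid("invalid-input: need at least 2 calibration plugs")
  if (length(plugDensities) != length(plugHU))
    .stopInvalid("invalid-input: plugDensities and plugHU lengths differ")
  if (any(!is.finite(plugHU)) || any(!is.finite(plugDensities)))
    .stopInvalid("invalid-input: non-finite plug data")
  if (any(diff(plugDensities) <= 0))
    .stopInvalid("invalid-input: plug densities must be strictly increasing")
  if (sd(plugDensities) == 0)
    .stopInvalid("degenerate-fit: zero variance in plug densities")
  fit <- lm(plugHU ~ plugDensities)
  cf <- coef(fit)
  new("CalibrationCurve", slope = unname(cf[2]), intercept = unname(cf[1]),
      plugDensities = as.numeric(plugDensities), plugHU = as.numeric(plugHU))
}

#' CT number to radiological density
#'
#' Applies `rhoCT = (HU - intercept) / slope`. No clamping is applied at
#' this stage; values below zero can legitimately occur for air/marrow.
#'
#' @param hu CT numbers (HU); vectorized.
#' @param curve A [CalibrationCurve-class]; default the scanner curve of
#'   [defaultCalibrationCurve()].
#' @return Radiological density in mgHA/cm^3.
#' @export
#' @examples
#' huToRhoCt(1500)   # ~1390
huToRhoCt <- function(hu, curve = defaultCalibrationCurve()) {
  stopifnot(is(curve, "CalibrationCurve"))
  validObject(curve)
  (hu - curve@intercept) / curve@slope
}

#' Inverse calibration: radiological density to CT number
#'
#' @param rhoCt Radiological density in mgHA/cm^3; vectorized.
#' @param curve A [CalibrationCurve-class].
#' @return CT numbers. Exact round trip with [huToRhoCt()].
#' @export
rhoCtToHu <- function(rhoCt, curve = defaultCalibrationCurve()) {
  stopifnot(is(curve, "CalibrationCurve"))
  rhoCt * curve@slope + curve@intercept
}

#' Radiological to ash density
#'
#' `rho_ash = ashSlope * rho_ct + ashIntercept`, both in g/cm^3. The input
#' must already be converted from mgHA/cm^3 to g/cm^3 (divide by 1000);
#' that conversion is deliberately left to the caller so the unit change
#' is always explicit. Non-positive outputs are clamped to the law's
#' density floor.
#'
#' @param rhoCt Radiological density in g/cm^3; vectorized.
#' @param law A [DensityModulusLaw-class].
#' @return Ash density in g/cm^3, at least `law@densityFloor`.
#' @export
#' @examples
#' rhoCtToRhoAsh(1.38996)  # density at the HU=1500 threshold
rhoCtToRhoAsh <- function(rhoCt, law = defaultDensityModulusLaw()) {
  stopifnot(is(law, "DensityModulusLaw"))
  pmax(law@ashSlope * rhoCt + law@ashIntercept, law@densityFloor)
}

#' Ash density to Young's modulus, with region factors
#'
#' Power law `E = coefficient * rho_ash^exponent` (MPa), multiplied by
#' `(1 - aScl)` in sclerotic elements and `(1 - dLys)` in lytic elements.
#'
#' @param rhoAsh Ash density in g/cm^3; vectorized.
#' @param law A [DensityModulusLaw-class].
#' @param region Character vector (recycled against `rhoAsh`): `"plain"`,
#'   `"sclerotic"` or `"lytic"`.
#' @param factors A [RegionFactors-class]; validated against its invariant
#'   ranges.
#' @return Young's modulus in MPa, strictly positive.
#' @export
#' @examples
#' rhoAshToModulus(1)                               # 3378 MPa
#' rhoAshToModulus(1, region = "sclerotic",
#'                 factors = regionFactors(aScl = 0.5))  # 1689 MPa
rhoAshToModulus <- function(rhoAsh, law = defaultDensityModulusLaw(),
                            region = "plain", factors = regionFactors()) {
  stopifnot(is(law, "DensityModulusLaw"), is(factors, "RegionFactors"))
  validObject(factors)
  if (!all(region %in% c("plain", "sclerotic", "lytic")))
    .stopInvalid("invalid-input: unknown region label")
  if (any(rhoAsh < law@densityFloor - 1e-12))
    .stopInvalid("invalid-input: rhoAsh below the density floor; ",
                 "apply rhoCtToRhoAsh first")
  e <- law@coefficient * rhoAsh^law@exponent
  region <- rep_len(region, length(e))
  scale <- rep_len(1, length(e))
  scale[region == "sclerotic"] <- 1 - factors@aScl
  scale[region == "lytic"] <- 1 - factors@dLys
  e * scale
}

#' Adaptive factor from sclerotic volume fraction
#'
#' Linear law `aScl = slope * vScl + intercept`, clamped to the law's
#' clamp range. With the default coefficients the raw value traverses the
#' whole clamp range over a very narrow band of `vScl`, so clamping is
#' the common case at both ends.
#'
#' @param vScl Sclerotic volume fraction in `[0, 1]`; vectorized.
#' @param law An [AsclLaw-class].
#' @return Adaptive factor in `[clampLo, clampHi]`.
#' @export
#' @examples
#' asclFromVscl(0)       # clamps at -1
#' asclFromVscl(0.1856)  # ~0
asclFromVscl <- function(vScl, law = defaultAsclLaw()) {
  stopifnot(is(law, "AsclLaw"))
  if (any(vScl < 0 | vScl > 1))
    .stopInvalid("invalid-input: vScl must lie in [0, 1]")
  pmin(pmax(law@slope * vScl + law@intercept, law@clampLo), law@clampHi)
}

#' Full chain: CT numbers to per-element modulus
#'
#' Convenience wrapper applying calibration, the mgHA/cm^3 to g/cm^3 unit
#' conversion, the ash-density law and the modulus law in one step.
#'
#' @param hu CT numbers; vectorized.
#' @param curve A [CalibrationCurve-class].
#' @param law A [DensityModulusLaw-class].
#' @param region,factors Passed to [rhoAshToModulus()].
#' @return List with `rhoAsh` (g/cm^3) and `modulus` (MPa).
#' @export
huToModulus <- function(hu, curve = defaultCalibrationCurve(),
                        law = defaultDensityModulusLaw(),
                        region = "plain", factors = regionFactors()) {
  rhoCt <- huToRhoCt(hu, curve) / 1000  # mgHA/cm^3 -> g/cm^3
  rhoAsh <- rhoCtToRhoAsh(rhoCt, law)
  list(rhoAsh = rhoAsh,
       modulus = rhoAshToModulus(rhoAsh, law, region, factors))
}

#' Serialize calibration constants to a YAML config
#'
#' @param curve A [CalibrationCurve-class].
#' @param law A [DensityModulusLaw-class].
#' @param asclLaw An [AsclLaw-class].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [readCalibrationConfig()]
#' @export
writeCalibrationConfig <- function(path, curve = defaultCalibrationCurve(),
                                   law = defaultDensityModulusLaw(),
                                   asclLaw = defaultAsclLaw()) {
  cfg <- list(
    calibration = list(slope = curve@slope, intercept = curve@intercept,
                       plug_densities = curve@plugDensities,
                       plug_hu = curve@plugHU),
    density_modulus = list(coefficient = law@coefficient,
                           exponent = law@exponent,
                           ash_slope = law@ashSlope,
                           ash_intercept = law@ashIntercept,
                           density_floor = law@densityFloor),
    ascl_law = list(slope = asclLaw@slope, intercept = asclLaw@intercept,
                    clamp_lo = asclLaw@clampLo, clamp_hi = asclLaw@clampHi))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read calibration constants from a YAML config
#'
#' @param path File written by [writeCalibrationConfig()].
#' @return List with elements `curve`, `law`, `asclLaw`.
#' @export
readCalibrationConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    curve = new("CalibrationCurve",
                slope = cfg$calibration$slope,
                intercept = cfg$calibration$intercept,
                plugDensities = as.numeric(cfg$calibration$plug_densities),
                plugHU = as.numeric(cfg$calibration$plug_hu)),
    law = new("DensityModulusLaw",
              coefficient = cfg$density_modulus$coefficient,
              exponent = cfg$density_modulus$exponent,
              ashSlope = cfg$density_modulus$ash_slope,
              ashIntercept = cfg$density_modulus$ash_intercept,
              densityFloor = cfg$density_modulus$density_floor),
    asclLaw = new("AsclLaw",
                  slope = cfg$ascl_law$slope,
                  intercept = cfg$ascl_law$intercept,
                  clampLo = cfg$ascl_law$clamp_lo,
                  clampHi = cfg$ascl_law$clamp_hi))
}
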