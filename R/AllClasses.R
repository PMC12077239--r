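#' @import methods
#' @importFrom stats lm coef sd setNames
NULL

# ---- region label dictionary -------------------------------------------------

#' Voxel label dictionary
#'
#' Integer codes used in [LabelVolume-class] label grids: `OUTSIDE = 0`,
#' `CORTEX = 1`, `TRABECULAR = 2`, `SCL = 3` (sclerotic), `LYS = 4` (lytic).
#'
#' @return Named integer vector of label codes.
#' @export
#' @examples
#' labelCodes()
labelCodes <- function() {
  c(OUTSIDE = 0L, CORTEX = 1L, TRABECULAR = 2L, SCL = 3L, LYS = 4L)
}

.stopInvalid <- function(...) stop(..., call. = FALSE)

.isNumeric3 <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x))

# ---- calibration -------------------------------------------------------------

#' CalibrationCurve: affine CT-number / radiological-density map
#'
#' Affine relation `HU = slope * rhoCT + intercept` fitted from a
#' hydroxyapatite calibration phantom, inverted as
#' `rhoCT = (HU - intercept) / slope` with `rhoCT` in mgHA/cm^3.
#'
#' @slot slope CT number per (mgHA/cm^3); must be positive.
#' @slot intercept CT number at zero radiological density.
#' @slot plugDensities Known HA plug densities (mgHA/cm^3).
#' @slot plugHU Mean measured CT numbers for the plugs.
#'
#' @seealso [fitPhantomCurve()], [huToRhoCt()], [defaultCalibrationCurve()]
#' @export
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric",
                 plugDensities = "numeric", plugHU = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@slope) != 1 || !is.finite(object@slope) ||
        object@slope <= 0)
      msg <- c(msg, "slope must be a single positive finite number")
    if (length(object@intercept) != 1 || !is.finite(object@intercept))
      msg <- c(msg, "intercept must be a single finite number")
    if (length(object@plugDensities) != length(object@plugHU))
      msg <- c(msg, "plugDensities and plugHU must have equal length")
    if (length(msg)) msg else TRUE
  })

#' DensityModulusLaw: ash-density conversion and power-law modulus
#'
#' Holds the affine radiological-to-ash density conversion
#' `rho_ash = ashSlope * rho_ct + ashIntercept` (both in g/cm^3) and the
#' power law `E = coefficient * rho_ash^exponent` (E in MPa).
#' `densityFloor` is the minimum ash density (g/cm^3) substituted for
#' non-positive calibrated densities so that every element keeps a small
#' positive modulus.
#'
#' @slot coefficient MPa; default 3378.
#' @slot exponent dimensionless; default 1.52.
#' @slot ashSlope dimensionless; default 0.8772.
#' @slot ashIntercept g/cm^3; default 0.07895.
#' @slot densityFloor g/cm^3; default 0.01.
#'
#' @seealso [rhoCtToRhoAsh()], [rhoAshToModulus()], [defaultDensityModulusLaw()]
#' @export
setClass("DensityModulusLaw",
  representation(coefficient = "numeric", exponent = "numeric",
                 ashSlope = "numeric", ashIntercept = "numeric",
                 densityFloor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@coefficient <= 0) msg <- c(msg, "coefficient must be > 0")
    if (object@exponent <= 0) msg <- c(msg, "exponent must be > 0")
    if (object@densityFloor <= 0) msg <- c(msg, "densityFloor must be > 0")
    if (length(msg)) msg else TRUE
  })

#' RegionFactors: adaptive and damage modulus modifiers
#'
#' The adaptive factor `aScl` rescales the sclerotic-region modulus as
#' `(1 - aScl) * E`; the damage factor `dLys` rescales the lytic-region
#' modulus as `(1 - dLys) * E`. `RegionFactors(0, 0)` is the non-tuned
#' model.
#'
#' @slot aScl dimensionless, in [-1, 0.5].
#' @slot dLys dimensionless, in [0, 0.95] (0 = non-tuned; tuning grids use
#'   0.50-0.95).
#' @export
setClass("RegionFactors",
  representation(aScl = "numeric", dLys = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@aScl) || object@aScl < -1 || object@aScl > 0.5)
      msg <- c(msg, "aScl must lie in [-1, 0.5]")
    if (!is.finite(object@dLys) || object@dLys < 0 || object@dLys > 0.95)
      msg <- c(msg, "dLys must lie in [0, 0.95]")
    if (length(msg)) msg else TRUE
  })

#' AsclLaw: adaptive factor as a linear function of sclerotic volume fraction
#'
#' `aScl = slope * vScl + intercept`, clamped to `[clampLo, clampHi]`.
#' The printed coefficients make the output traverse the full clamp range
#' over a very narrow band of `vScl`, so the clamp is mandatory and both
#' coefficients are configurable.
#'
#' @slot slope dimensionless; default 994.23.
#' @slot intercept dimensionless; default -184.55.
#' @slot clampLo lower clamp; -1.
#' @slot clampHi upper clamp; 0.5.
#' @seealso [asclFromVscl()], [fitAsclLaw()], [defaultAsclLaw()]
#' @export
setClass("AsclLaw",
  representation(slope = "numeric", intercept = "numeric",
                 clampLo = "numeric", clampHi = "numeric"),
  validity = function(object) {
    if (object@clampLo >= object@clampHi) "clampLo must be < clampHi" else TRUE
  })

# ---- image domain ------------------------------------------------------------

#' VoxelImage: 3-D grid of CT numbers
#'
#' @slot values 3-D numeric array of CT numbers (HU).
#' @slot spacing Voxel spacing in mm, length 3, strictly positive.
#' @slot origin World coordinate (mm) of the centre of voxel (1,1,1).
#'   World position of voxel `(i,j,k)` (1-based) is
#'   `origin + (i-1, j-1, k-1) * spacing`.
#' @export
setClass("VoxelImage",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3 || any(dim(object@values) < 1))
      msg <- c(msg, "values must be a non-empty 3-D array")
    if (!.isNumeric3(object@spacing) || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (!.isNumeric3(object@origin))
      msg <- c(msg, "origin must be 3 finite numbers")
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: voxel region labels
#'
#' Integer label grid over the codes of [labelCodes()], congruent with its
#' source [VoxelImage-class].
#'
#' @slot labels 3-D integer array with values in `labelCodes()`.
#' @slot spacing,origin As in [VoxelImage-class].
#' @export
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3)
      msg <- c(msg, "labels must be a 3-D array")
    if (!all(object@labels %in% labelCodes()))
      msg <- c(msg, "labels contain codes outside labelCodes()")
    if (!.isNumeric3(object@spacing) || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (length(msg)) msg else TRUE
  })

#' AnatomicalFrame: orthonormal bone-fixed coordinate frame
#'
#' Right-handed orthonormal triad. `transverseNormal` equals `longAxis`
#' and points proximally; `frontalNormal` points dorsally;
#' `sagittalNormal` is the medio-lateral direction.
#'
#' @slot longAxis Unit vector along the bone's long axis (proximal sense).
#' @slot frontalNormal Unit normal of the frontal plane (dorsal sense).
#' @slot sagittalNormal Unit normal of the sagittal plane (medio-lateral).
#' @slot transverseNormal Unit normal of the transverse plane (= longAxis).
#' @slot origin Frame origin in mm.
#' @export
setClass("AnatomicalFrame",
  representation(longAxis = "numeric", frontalNormal = "numeric",
                 sagittalNormal = "numeric", transverseNormal = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    tol <- 1e-9
    v <- list(object@longAxis, object@frontalNormal, object@sagittalNormal,
              object@transverseNormal)
    if (!all(vapply(v, .isNumeric3, logical(1))))
      return("all axes must be length-3 finite numeric vectors")
    if (any(abs(vapply(v, function(x) sum(x^2), numeric(1)) - 1) > 1e-6))
      return("all axes must be unit vectors")
    dots <- c(sum(object@frontalNormal * object@sagittalNormal),
              sum(object@frontalNormal * object@transverseNormal),
              sum(object@sagittalNormal * object@transverseNormal))
    if (any(abs(dots) > tol)) return("plane normals must be mutually orthogonal")
    if (max(abs(object@transverseNormal - object@longAxis)) > 1e-6)
      return("transverseNormal must equal longAxis")
    TRUE
  })

# ---- meshing -----------------------------------------------------------------

#' TetrahedralMesh: linear tetrahedral mesh with named sets
#'
#' @slot nodes Numeric n x 3 matrix of node coordinates (mm).
#' @slot tets Integer m x 4 matrix of node indices; positive signed volume.
#' @slot elementRegion Character vector, per tet: one of
#'   `"plain"`, `"sclerotic"`, `"lytic"`.
#' @slot elementRhoAsh Numeric vector, per tet, ash density (g/cm^3).
#' @slot boundary List describing boundary facets: `facets` (f x 3 node
#'   indices), `owner` (owning tet index), `normal` (f x 3 outward unit
#'   normals), `area` (mm^2), `centroid` (f x 3, mm).
#' @slot nodeSets Named list of integer node-index vectors
#'   (`PROXIMAL_FIXED`).
#' @slot facetSets Named list of integer boundary-facet index vectors
#'   (`LOAD_SURFACE`, `PSG_STRIP`).
#' @slot fineEdge,coarseEdge Cell edge lengths used to build the mesh (mm).
#' @export
setClass("TetrahedralMesh",
  representation(nodes = "matrix", tets = "matrix",
                 elementRegion = "character", elementRhoAsh = "numeric",
                 boundary = "list", nodeSets = "list", facetSets = "list",
                 fineEdge = "numeric", coarseEdge = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@nodes) != 3) msg <- c(msg, "nodes must be n x 3")
    if (ncol(object@tets) != 4) msg <- c(msg, "tets must be m x 4")
    m <- nrow(object@tets)
    if (length(object@elementRegion) != m)
      msg <- c(msg, "elementRegion length must equal number of tets")
    if (length(object@elementRhoAsh) != m)
      msg <- c(msg, "elementRhoAsh length must equal number of tets")
    if (m > 0 && (min(object@tets) < 1 || max(object@tets) > nrow(object@nodes)))
      msg <- c(msg, "tets index outside node range")
    if (length(msg)) msg else TRUE
  })

# ---- fe solver ---------------------------------------------------------------

#' LoadCase: condylar loading specification
#'
#' Total force applied to the palmar load surface at the stated angles to
#' the frontal and transverse planes, distributed over the load-surface
#' nodes either equally (`"uniform-nodal"`) or by tributary facet area
#' (`"area-weighted"`).
#'
#' @slot totalForce N; default 7500.
#' @slot angleFrontal degrees from the frontal plane; default 60.
#' @slot angleTransverse degrees from the transverse plane; default 30.
#' @slot distribution `"uniform-nodal"` or `"area-weighted"`.
#' @seealso [directionFromAngles()], [assembleAndSolve()]
#' @export
setClass("LoadCase",
  representation(totalForce = "numeric", angleFrontal = "numeric",
                 angleTransverse = "numeric", distribution = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@totalForce))
      msg <- c(msg, "totalForce must be finite")
    sf <- sin(object@angleFrontal * pi / 180)
    st <- sin(object@angleTransverse * pi / 180)
    if (sf^2 + st^2 > 1 + 1e-12)
      msg <- c(msg, "infeasible angles: sin^2(frontal) + sin^2(transverse) > 1")
    if (!object@distribution %in% c("uniform-nodal", "area-weighted"))
      msg <- c(msg, "distribution must be 'uniform-nodal' or 'area-weighted'")
    if (length(msg)) msg else TRUE
  })

#' StrainField: solution of the linear elastic problem
#'
#' @slot displacements n x 3 nodal displacements (mm).
#' @slot elementStrain m x 6 small-strain tensors in Voigt order
#'   (xx, yy, zz, xy, yz, xz; tensor shear components, not engineering).
#' @slot elementPrincipal m x 3 principal strains, sorted descending.
#' @slot surfaceMaxPrincipal Per boundary facet, the maximum principal
#'   strain of the owning tet.
#' @slot reactions n x 3 nodal reaction forces (N); non-zero only at
#'   constrained nodes.
#' @export
setClass("StrainField",
  representation(displacements = "matrix", elementStrain = "matrix",
                 elementPrincipal = "matrix", surfaceMaxPrincipal = "numeric",
                 reactions = "matrix"))

#' PSGStrainSummary: strip-averaged maximum principal strain
#'
#' Area-weighted mean of the surface maximum principal strain over the
#' parasagittal-groove strip facets. Strain is stored dimensionless;
#' multiply by 100 for percent strain.
#'
#' @slot meanMaxPrincipal dimensionless strain.
#' @slot facetCount number of strip facets.
#' @slot areaMm2 total strip area (mm^2).
#' @export
setClass("PSGStrainSummary",
  representation(meanMaxPrincipal = "numeric", facetCount = "numeric",
                 areaMm2 = "numeric"))

# ---- tuning ------------------------------------------------------------------

#' TuningGrid: exhaustive grid search over one material factor
#'
#' @slot factorName `"aScl"` or `"dLys"`.
#' @slot candidates Ordered candidate factor values.
#' @slot predicted Predicted PSG mean strain per candidate.
#' @slot objective `|predicted - target|` per candidate.
#' @slot optimum Selected candidate (minimum objective).
#' @slot tieRule Character record of any tie-break applied.
#' @slot target The target strain tuned against.
#' @export
setClass("TuningGrid",
  representation(factorName = "character", candidates = "numeric",
                 predicted = "numeric", objective = "numeric",
                 optimum = "numeric", tieRule = "character",
                 target = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@candidates) == 0) msg <- c(msg, "empty candidate grid")
    if (length(object@objective) != length(object@candidates))
      msg <- c(msg, "objective length must match candidates")
    if (length(object@optimum) == 1 &&
        !any(abs(object@candidates - object@optimum) < 1e-12))
      msg <- c(msg, "optimum must be one of the candidates")
    if (length(msg)) msg else TRUE
  })

#' ValidationReport: per-specimen prediction accuracy summary
#'
#' @slot table data.frame with columns `id`, `group`, `predicted`,
#'   `measured`, `absDifference`.
#' @slot slope,intercept OLS regression of predicted on measured
#'   (NA when fewer than 3 specimens).
#' @slot rSquared Squared Pearson correlation (NA when regression skipped).
#' @slot meanRelativeError mean(|pred - meas| / meas), as a fraction.
#' @export
setClass("ValidationReport",
  representation(table = "data.frame", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric",
                 meanRelativeError = "numeric"))
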