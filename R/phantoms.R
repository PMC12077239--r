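# Synthetic phantoms: the four-plug calibration phantom and idealized
# condyle phantoms (cylindrical shaft + spherical condyle, cortical shell,
# subchondral sclerotic cap, optional focal lytic sphere in the groove).
#
# Geometry is deliberately idealized: the pipeline's correctness claims
# concern the equations and procedures, not condylar anatomy. All
# generators are pure functions of (spec, seed).

# Evaluate expr with a temporary RNG state seeded by `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a four-plug calibration phantom image
#'
#' Cylindrical hydroxyapatite plugs in a water-equivalent background;
#' plug CT numbers are the forward calibration map of the plug densities
#' plus optional Gaussian noise.
#'
#' @param plugDensities Plug densities (mgHA/cm^3), positive increasing;
#'   default `c(200, 800, 1250, 1750)`.
#' @param curve Generating [CalibrationCurve-class] (forward map
#'   `HU = slope * density + intercept`).
#' @param noiseSdHu Gaussian HU noise standard deviation (default 0).
#' @param seed RNG seed for the noise.
#' @param spacingMm Isotropic voxel spacing (default 0.5).
#' @param plugRadiusMm,plugSpacingMm Plug radius and centre-to-centre
#'   spacing (mm).
#' @return List with `image` ([VoxelImage-class]), `plugMasks` (list of
#'   logical arrays), `plugDensities`, and `expectedHu` (noiseless plug
#'   means).
#' @export
makeCalibrationPhantom <- function(plugDensities = c(200, 800, 1250, 1750),
                                   curve = defaultCalibrationCurve(),
                                   noiseSdHu = 0, seed = 1,
                                   spacingMm = 0.5, plugRadiusMm = 2.5,
                                   plugSpacingMm = 8) {
  if (any(plugDensities <= 0) || any(diff(plugDensities) <= 0))
    .stopInvalid("invalid-spec: plug densities must be positive increasing")
  if (plugSpacingMm <= 2 * plugRadiusMm)
    .stopInvalid("invalid-spec: overlapping plug geometry")
  np <- length(plugDensities)
  margin <- plugRadiusMm + 2
  lenX <- (np - 1) * plugSpacingMm + 2 * margin
  sp <- rep(spacingMm, 3)
  d <- c(ceiling(lenX / spacingMm), ceiling(2 * margin / spacingMm),
         ceiling(6 / spacingMm))
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  hu <- array(0, d)
  centresX <- margin + (seq_len(np) - 1) * plugSpacingMm
  cy <- margin
  expectedHu <- rhoCtToHu(plugDensities, curve)
  plugMasks <- vector("list", np)
  for (p in seq_len(np)) {
    inPlane <- outer((x - centresX[p])^2, (y - cy)^2, "+") <= plugRadiusMm^2
    mask <- array(inPlane, d)  # plugs run the full z extent
    plugMasks[[p]] <- mask
    hu[mask] <- expectedHu[p]
  }
  if (noiseSdHu > 0)
    hu <- hu + .withSeed(seed, array(stats::rnorm(prod(d), 0, noiseSdHu), d))
  list(image = new("VoxelImage", values = hu, spacing = sp,
                   origin = c(0, 0, 0)),
       plugMasks = plugMasks, plugDensities = plugDensities,
       expectedHu = expectedHu)
}

#' Measure plug mean CT numbers and fit the calibration curve
#'
#' Convenience wrapper: mean HU per plug ROI, then [fitPhantomCurve()].
#'
#' @param phantom Output of [makeCalibrationPhantom()].
#' @return A [CalibrationCurve-class].
#' @export
calibrateFromPhantom <- function(phantom) {
  hu <- vapply(phantom$plugMasks,
               function(m) mean(phantom$image@values[m]), numeric(1))
  fitPhantomCurve(phantom$plugDensities, hu)
}

#' Specification for a synthetic condyle phantom
#'
#' Defaults give a small capsule-shaped bone (cylindrical shaft plus
#' spherical condyle) whose full tune-and-validate forward solves stay at
#' desk scale. CT numbers: cortex 2000 HU, trabecular background 900 HU,
#' sclerotic cap 1800 HU (> 1500), lysis 600 HU (< 1500).
#'
#' @param shaftRadiusMm,shaftLengthMm,condyleRadiusMm Geometry (mm).
#' @param corticalThicknessMm Cortical shell thickness (mm).
#' @param grooveOffsetMm Medial offset of the parasagittal groove plane
#'   from the mid-sagittal plane (mm).
#' @param backgroundTrabecularHu,corticalHu,scleroticHu CT numbers; the
#'   sclerotic value must exceed 1500.
#' @param scleroticTargetFraction Target sclerotic volume fraction
#'   V_SCL = V_sclerosis / V_condyle.
#' @param lysis NULL (CTRL-class phantom) or a list with `radiusMm` and
#'   `hu` (< 1500) for a focal lytic sphere inside the sclerotic cap at
#'   the groove (PSG-SBI-class phantom).
#' @param noiseSdHu Additive Gaussian HU noise (default 0).
#' @param seed RNG seed.
#' @param spacingMm Isotropic voxel spacing (default 0.5).
#' @return Named list of generator parameters.
#' @export
condylePhantomSpec <- function(shaftRadiusMm = 4, shaftLengthMm = 14,
                               condyleRadiusMm = 5,
                               corticalThicknessMm = 1,
                               grooveOffsetMm = 1.5,
                               backgroundTrabecularHu = 900,
                               corticalHu = 2000, scleroticHu = 1800,
                               scleroticTargetFraction = 0.185,
                               lysis = NULL, noiseSdHu = 0, seed = 1,
                               spacingMm = 0.5) {
  spec <- list(shaftRadiusMm = shaftRadiusMm, shaftLengthMm = shaftLengthMm,
               condyleRadiusMm = condyleRadiusMm,
               corticalThicknessMm = corticalThicknessMm,
               grooveOffsetMm = grooveOffsetMm,
               backgroundTrabecularHu = backgroundTrabecularHu,
               corticalHu = corticalHu, scleroticHu = scleroticHu,
               scleroticTargetFraction = scleroticTargetFraction,
               lysis = lysis, noiseSdHu = noiseSdHu, seed = seed,
               spacingMm = spacingMm)
  if (scleroticHu <= 1500)
    .stopInvalid("invalid-spec: scleroticHu must exceed 1500")
  if (backgroundTrabecularHu >= 1500)
    .stopInvalid("invalid-spec: backgroundTrabecularHu must be below 1500")
  if (!is.null(lysis)) {
    if (is.null(lysis$radiusMm) || lysis$radiusMm < 0)
      .stopInvalid("invalid-spec: lysis needs a non-negative radiusMm")
    if (is.null(lysis$hu)) spec$lysis$hu <- 600
    else if (lysis$hu >= 1500)
      .stopInvalid("invalid-spec: lysis hu must be below 1500")
    if (lysis$radiusMm == 0) spec$lysis <- NULL
  }
  if (scleroticTargetFraction < 0 || scleroticTargetFraction > 1)
    .stopInvalid("invalid-spec: scleroticTargetFraction must be in [0, 1]")
  spec
}

#' Rasterize a synthetic condyle phantom
#'
#' Builds the CT image and all ground truth: label volume, anatomical
#' frame and landmarks, condyle / trabecular / PSG-search masks, groove
#' plane and load-patch declaration. The sclerotic cap thickness is
#' chosen so the sclerotic volume fraction matches the spec's target to
#' within voxel quantization.
#'
#' Axes: +z is proximal (the shaft, cut at its proximal end), -z distal
#' (the condyle), +y dorsal, -y palmar, +x medial.
#'
#' @param spec Output of [condylePhantomSpec()].
#' @return List with `image`, `labels`, `frame`, `landmarks`, masks
#'   (`boneMask`, `trabecularMask`, `condyleMask`, `psgRegionMask`),
#'   `psgPlane`, `loadPatchSpec`, `vScl` (achieved fraction), and
#'   `hasLysis`.
#' @export
makeCondylePhantom <- function(spec = condylePhantomSpec()) {
  sp <- rep(spec$spacingMm, 3)
  R <- spec$condyleRadiusMm
  rs <- spec$shaftRadiusMm
  t <- spec$corticalThicknessMm
  margin <- 1.5
  cx <- margin + R; cy <- margin + R; zc <- margin + R
  zTop <- zc + spec$shaftLengthMm
  d <- c(ceiling((2 * (margin + R)) / sp[1]),
         ceiling((2 * (margin + R)) / sp[2]),
         ceiling((zTop + 0.5) / sp[3]))
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(x, d)
  Y <- array(rep(y, each = d[1]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)

  rxy2 <- (X - cx)^2 + (Y - cy)^2
  distC <- sqrt(rxy2 + (Z - zc)^2)
  inSphere <- distC <= R
  inCyl <- rxy2 <= rs^2 & Z >= zc & Z <= zTop
  bone <- inSphere | inCyl
  depthSphere <- ifelse(inSphere, R - distC, -Inf)
  depthCyl <- ifelse(inCyl, pmin(rs - sqrt(rxy2), zTop - Z), -Inf)
  depth <- pmax(depthSphere, depthCyl)
  cortex <- bone & depth < t
  trab <- bone & depth >= t

  condyleMask <- bone & Z <= zc
  nCond <- sum(condyleMask)

  # sclerotic cap: outermost trabecular shell of the distal hemisphere,
  # thickness solved so the volume fraction hits the target
  eligible <- trab & Z <= zc
  target <- spec$scleroticTargetFraction
  scl <- array(FALSE, d)
  thr <- NA_real_
  if (target > 0) {
    k <- round(target * nCond)
    dEl <- distC[eligible]
    if (k > length(dEl))
      .stopInvalid("invalid-spec: sclerotic fraction infeasible for this ",
                   "geometry (needs ", k, " voxels, only ", length(dEl),
                   " eligible)")
    if (k > 0) {
      elIdx <- which(eligible)
      # exactly k outermost voxels; ties resolved by linear index order
      ord <- order(dEl, seq_along(dEl), decreasing = TRUE)
      pick <- elIdx[ord[seq_len(k)]]
      thr <- dEl[ord[k]]
      scl[pick] <- TRUE
    }
  }

  grooveX <- cx + spec$grooveOffsetMm
  lys <- array(FALSE, d)
  if (!is.null(spec$lysis)) {
    rl <- spec$lysis$radiusMm
    sAch <- R - t - thr  # achieved cap thickness
    # one-voxel sclerotic margin inside the cap so the pocket's whole
    # 6-neighbourhood stays in above-threshold bone (isolation)
    loR <- R - t - sAch + rl + max(sp)
    hiR <- R - t - rl
    if (!is.finite(sAch) || loR > hiR)
      .stopInvalid("invalid-spec: lysis sphere of radius ", rl,
                   " mm does not fit inside the sclerotic cap (thickness ",
                   format(sAch), " mm)")
    rho <- (loR + hiR) / 2
    if (rho <= spec$grooveOffsetMm)
      .stopInvalid("invalid-spec: lysis radius position inside groove offset")
    rYZ <- sqrt(rho^2 - spec$grooveOffsetMm^2)
    u <- c(-0.53, -0.85) / sqrt(0.53^2 + 0.85^2)  # palmar-distal
    lysC <- c(grooveX, cy + rYZ * u[1], zc + rYZ * u[2])
    if (abs(rYZ * u[2]) < rl)
      .stopInvalid("invalid-spec: lysis sphere crosses the condyle equator")
    dLys <- sqrt((X - lysC[1])^2 + (Y - lysC[2])^2 + (Z - lysC[3])^2)
    lys <- dLys <= rl
    if (!any(lys))
      .stopInvalid("invalid-spec: lysis sphere rasterizes to zero voxels")
    if (!all(scl[lys]))
      .stopInvalid("invalid-spec: lysis sphere not contained in the ",
                   "sclerotic cap")
    scl <- scl & !lys
  }

  code <- labelCodes()
  lab <- array(code[["OUTSIDE"]], d)
  lab[cortex] <- code[["CORTEX"]]
  lab[trab] <- code[["TRABECULAR"]]
  lab[scl] <- code[["SCL"]]
  lab[lys] <- code[["LYS"]]

  hu <- array(-1000, d)
  hu[cortex] <- spec$corticalHu
  hu[trab] <- spec$backgroundTrabecularHu
  hu[scl] <- spec$scleroticHu
  if (any(lys)) hu[lys] <- spec$lysis$hu
  if (spec$noiseSdHu > 0)
    hu <- hu + .withSeed(spec$seed,
                         array(stats::rnorm(prod(d), 0, spec$noiseSdHu), d))

  psgRegion <- bone & abs(X - grooveX) <= 2.5 & Z <= zc

  frame <- new("AnatomicalFrame", longAxis = c(0, 0, 1),
               frontalNormal = c(0, 1, 0), sagittalNormal = c(1, 0, 0),
               transverseNormal = c(0, 0, 1), origin = c(cx, cy, zc))
  labels <- new("LabelVolume", labels = lab, spacing = sp,
                origin = c(0, 0, 0))
  vScl <- if (nCond > 0) sum(lab[condyleMask] == code[["SCL"]]) / nCond else 0

  list(image = new("VoxelImage", values = hu, spacing = sp,
                   origin = c(0, 0, 0)),
       labels = labels, frame = frame,
       landmarks = list(dorsal = c(cx, cy + R, zc),
                        distal = c(cx, cy, zc - R)),
       boneMask = bone, trabecularMask = trab | scl | lys,
       condyleMask = condyleMask, psgRegionMask = psgRegion,
       psgPlane = list(point = c(grooveX, cy, zc), normal = c(1, 0, 0),
                       axisMax = zc),
       loadPatchSpec = list(box = rbind(c(grooveX - 1, Inf), c(-Inf, cy),
                                        c(-Inf, zc)),
                            normalDir = c(0, -1, 0), minCos = 0.2),
       spec = spec, vScl = vScl, hasLysis = any(lys))
}

#' Mesh a condyle phantom and tag its boundary sets
#'
#' @param phantom Output of [makeCondylePhantom()].
#' @param curve,law Calibration chain for element densities.
#' @param fineEdgeMm,coarseEdgeMm Mesh edges (mm).
#' @param stripWidthMm PSG strip width (mm).
#' @return A tagged [TetrahedralMesh-class].
#' @export
meshPhantom <- function(phantom, curve = defaultCalibrationCurve(),
                        law = defaultDensityModulusLaw(),
                        fineEdgeMm = 0.5, coarseEdgeMm = 1,
                        stripWidthMm = 3) {
  mesh <- voxelsToTets(phantom$labels, phantom$image, curve, law,
                       fineEdgeMm = fineEdgeMm, coarseEdgeMm = coarseEdgeMm)
  tagBoundarySets(mesh, phantom$frame, phantom$psgPlane, stripWidthMm,
                  phantom$loadPatchSpec)
}

#' Build a parameter-recovery specimen with a forward-generated target
#'
#' Runs the forward pipeline on a condyle phantom with known true
#' adaptive/damage factors and records the resulting PSG mean strain as
#' the synthetic "measured" target, enabling tuning recovery tests
#' without ex vivo data.
#'
#' @param spec Output of [condylePhantomSpec()].
#' @param trueAScl,trueDLys Generating factors (within the factor
#'   invariant ranges).
#' @param load A [LoadCase-class].
#' @param curve,law Calibration chain.
#' @param fineEdgeMm,coarseEdgeMm Mesh edges (mm).
#' @param id Specimen identifier.
#' @return Specimen manifest: list with `id`, `group` (`"CTRL"` or
#'   `"PSG-SBI"`), `phantom`, `mesh`, `frame`, `load`, `vScl`,
#'   `hasLysis`, `trueFactors`, and `target` (the forward PSG mean).
#' @export
makeRecoveryCase <- function(spec = condylePhantomSpec(), trueAScl = 0,
                             trueDLys = 0, load = loadCase(),
                             curve = defaultCalibrationCurve(),
                             law = defaultDensityModulusLaw(),
                             fineEdgeMm = 0.5, coarseEdgeMm = 1,
                             id = "phantom-1") {
  factors <- regionFactors(trueAScl, trueDLys)  # validates ranges
  phantom <- makeCondylePhantom(spec)
  mesh <- meshPhantom(phantom, curve, law, fineEdgeMm, coarseEdgeMm)
  fld <- assembleAndSolve(mesh, law = law, factors = factors,
                          load = load, frame = phantom$frame)
  target <- psgMean(psgSummary(fld, mesh))
  list(id = id, group = if (phantom$hasLysis) "PSG-SBI" else "CTRL",
       phantom = phantom, mesh = mesh, frame = phantom$frame, load = load,
       vScl = phantom$vScl, hasLysis = phantom$hasLysis,
       trueFactors = factors, target = target)
}
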