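# Voxel-level operations: erosion, anatomical frame, distal isolation,
# region labelling, sclerotic volume fraction.

test_that("erosion of a solid cube peels one face-connected layer", {
  cube <- array(TRUE, c(5, 5, 5))
  er <- erodeSurface(cube)
  expect_equal(sum(er), 27)
  expect_true(all(which(er) %in% which(cube)))
  expect_error(erodeSurface(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3))),
               "degenerate-geometry")
})

test_that("erosion output is contained in the input and composes", {
  set.seed(21)
  blob <- array(FALSE, c(12, 12, 12))
  ctr <- matrix(runif(9, 4, 9), 3)
  idx <- arrayInd(seq_len(12^3), c(12, 12, 12))
  for (k in 1:3)
    blob <- blob | array(sqrt(rowSums(sweep(idx, 2, ctr[k, ])^2)) < 4,
                         c(12, 12, 12))
  er1 <- erodeSurface(blob, 1)
  expect_true(all(blob[er1]))
  expect_lt(sum(er1), sum(blob))
  # erode twice by one equals erode once by two
  expect_identical(erodeSurface(er1, 1), erodeSurface(blob, 2))
})

test_that("anatomical frame recovers the long axis of a cylinder", {
  sp <- 0.5
  mask <- cylinderMask(c(20, 20, 60), sp, c(5, 5, 15), c(0, 0, 1), 3, 12)
  fr <- fitAnatomicalFrame(mask, rep(sp, 3), c(0, 0, 0),
                           dorsalLandmark = c(5, 10, 15),
                           distalLandmark = c(5, 5, 0))
  expect_equal(abs(fr@longAxis), c(0, 0, 1), tolerance = 1e-6)
  expect_gt(sum(fr@longAxis * c(0, 0, 1)), 0)  # proximal away from distal
  # orthonormal right-handed triad
  expect_equal(sum(fr@frontalNormal * fr@sagittalNormal), 0,
               tolerance = 1e-9)
  expect_equal(crossprod(fr@frontalNormal), matrix(1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("anatomical frame recovers a rotated cylinder within 0.5 degrees", {
  th <- 30 * pi / 180
  axis <- c(0, -sin(th), cos(th))  # rotate z-axis about x by 30 degrees
  mask <- cylinderMask(c(40, 40, 40), 0.5, c(10, 10, 10), axis, 2.5, 8)
  fr <- fitAnatomicalFrame(mask, rep(0.5, 3), c(0, 0, 0),
                           dorsalLandmark = c(10, 18, 14),
                           distalLandmark = c(10, 10, 10) - 8 * axis)
  ang <- acos(min(abs(sum(fr@longAxis * axis)), 1)) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("near-isotropic masks are rejected as ambiguous", {
  idx <- arrayInd(seq_len(20^3), rep(20, 3))
  sph <- array(sqrt(rowSums(sweep(idx, 2, c(10, 10, 10))^2)) < 8,
               rep(20, 3))
  expect_error(
    fitAnatomicalFrame(sph, rep(1, 3), c(0, 0, 0), c(10, 20, 10),
                       c(10, 10, 2)),
    "ambiguous-axis")
})

test_that("distal isolation keeps the stated extent along the axis", {
  sp <- 1
  mask <- cylinderMask(c(16, 16, 104), sp, c(7, 7, 51), c(0, 0, 1), 5, 50)
  fr <- fitAnatomicalFrame(mask, rep(sp, 3), c(0, 0, 0),
                           dorsalLandmark = c(7, 14, 51),
                           distalLandmark = c(7, 7, 0))
  iso <- isolateDistal(mask, fr, rep(sp, 3), length = 63.5)
  z <- range(arrayInd(which(iso), dim(iso))[, 3])
  extent <- (z[2] - z[1]) * sp
  expect_lt(abs(extent - 63.5), 1 * sp + 1e-9)
  # distal end preserved
  expect_equal(min(arrayInd(which(iso), dim(iso))[, 3]),
               min(arrayInd(which(mask), dim(mask))[, 3]))
  # the full extent is the identity
  pts <- arrayInd(which(mask), dim(mask))
  proj <- as.numeric(sweep(pts - 1, 2, rep(sp, 3), "*") %*% fr@longAxis)
  extent <- max(proj) - min(proj)
  expect_identical(isolateDistal(mask, fr, rep(sp, 3), length = extent),
                   mask)
  # mask shorter than the requested extent
  short <- cylinderMask(c(16, 16, 52), sp, c(7, 7, 25), c(0, 0, 1), 5, 24)
  frS <- fitAnatomicalFrame(short, rep(sp, 3), c(0, 0, 0),
                            dorsalLandmark = c(7, 14, 25),
                            distalLandmark = c(7, 7, 0))
  expect_error(isolateDistal(short, frS, rep(sp, 3), length = 63.5),
               "invalid-input")
})

test_that("labelling a uniform sub-threshold trabecular volume yields no SCL/LYS", {
  d <- c(10, 10, 10)
  img <- new("VoxelImage", values = array(1200, d), spacing = rep(1, 3),
             origin = c(0, 0, 0))
  bone <- array(TRUE, d)
  trab <- array(FALSE, d); trab[3:8, 3:8, 3:8] <- TRUE
  lab <- labelRegions(img, bone, trab, psgRegionMask = bone)
  code <- labelCodes()
  expect_equal(sum(labelArray(lab) == code[["SCL"]]), 0)
  expect_equal(sum(labelArray(lab) == code[["LYS"]]), 0)
  expect_equal(sum(labelArray(lab) == code[["TRABECULAR"]]), sum(trab))
  expect_equal(sum(labelArray(lab) == code[["CORTEX"]]), sum(bone & !trab))
})

test_that("an isolated low-HU pocket inside the PSG region becomes LYS", {
  d <- c(16, 16, 16)
  idx <- arrayInd(seq_len(prod(d)), d)
  hu <- array(1800, d)  # dense bone everywhere
  pocket <- array(sqrt(rowSums(sweep(idx, 2, c(8, 8, 8))^2)) <= 3, d)
  hu[pocket] <- 600
  img <- new("VoxelImage", values = hu, spacing = rep(1, 3),
             origin = c(0, 0, 0))
  bone <- array(TRUE, d)
  trab <- array(FALSE, d); trab[2:15, 2:15, 2:15] <- TRUE
  psg <- array(FALSE, d); psg[4:12, 4:12, 4:12] <- TRUE
  lab <- labelRegions(img, bone, trab, psg)
  code <- labelCodes()
  # the pocket (its rasterized voxel count exactly) is the one LYS blob
  expect_equal(which(labelArray(lab) == code[["LYS"]]), which(pocket))
  # the same pocket outside the PSG region is not lysis
  psgFar <- array(FALSE, d); psgFar[1:3, 1:3, 1:3] <- TRUE
  lab2 <- labelRegions(img, bone, trab, psgFar)
  expect_equal(sum(labelArray(lab2) == code[["LYS"]]), 0)
  # and below the minimum size it is suppressed
  lab3 <- labelRegions(img, bone, trab, psg, minLysisVoxels = 1000)
  expect_equal(sum(labelArray(lab3) == code[["LYS"]]), 0)
})

test_that("region labelling is deterministic and idempotent", {
  ph <- lyticPhantom()
  lab1 <- labelRegions(ph$image, ph$boneMask, ph$trabecularMask,
                       ph$psgRegionMask)
  lab2 <- labelRegions(ph$image, ph$boneMask, ph$trabecularMask,
                       ph$psgRegionMask)
  expect_identical(labelArray(lab1), labelArray(lab2))
})

test_that("sclerotic volume fraction is a proper fraction", {
  d <- c(6, 6, 6)
  code <- labelCodes()
  lab <- array(code[["SCL"]], d)
  lv <- new("LabelVolume", labels = lab, spacing = rep(1, 3),
            origin = c(0, 0, 0))
  expect_equal(scleroticVolumeFraction(lv, array(TRUE, d)), 1)
  lv2 <- new("LabelVolume", labels = array(code[["TRABECULAR"]], d),
             spacing = rep(1, 3), origin = c(0, 0, 0))
  expect_equal(scleroticVolumeFraction(lv2, array(TRUE, d)), 0)
  expect_error(scleroticVolumeFraction(lv, array(FALSE, d)),
               "invalid-input")
})

test_that("fraction grows with the generator's sclerotic inclusion", {
  fr <- vapply(c(0.1, 0.2, 0.3), function(tgt) {
    ph <- makeCondylePhantom(condylePhantomSpec(scleroticTargetFraction = tgt))
    scleroticVolumeFraction(ph$labels, ph$condyleMask)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_true(all(abs(fr - c(0.1, 0.2, 0.3)) <= 0.005))
})
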