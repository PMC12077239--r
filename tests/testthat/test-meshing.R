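# Voxel-to-tet meshing: Kuhn decomposition, mixed-resolution scheme,
# conformity, boundary sets.

.tinyVolume <- function(dims, hu = 1000, lab = NULL, spacing = 0.5) {
  code <- labelCodes()
  if (is.null(lab)) lab <- array(code[["TRABECULAR"]], dims)
  list(labels = new("LabelVolume", labels = lab, spacing = rep(spacing, 3),
                    origin = c(0, 0, 0)),
       image = new("VoxelImage", values = array(hu, dims),
                   spacing = rep(spacing, 3), origin = c(0, 0, 0)))
}

test_that("a single cubic cell splits into 6 Kuhn tets conserving volume", {
  v <- .tinyVolume(c(2, 2, 2))
  m <- voxelsToTets(v$labels, v$image, fineEdgeMm = 1, coarseEdgeMm = 1)
  expect_equal(nrow(meshTets(m)), 6)
  expect_equal(sum(tetVolumes(meshNodes(m), meshTets(m))), 1,
               tolerance = 1e-9)
})

test_that("uniform meshing at voxel pitch conserves the voxelized volume", {
  ph <- ctrlPhantom()
  sp <- imageSpacing(ph$image)
  m <- voxelsToTets(ph$labels, ph$image, fineEdgeMm = sp[1],
                    coarseEdgeMm = sp[1])
  voxVol <- sum(ph$boneMask) * prod(sp)
  expect_equal(sum(tetVolumes(meshNodes(m), meshTets(m))), voxVol,
               tolerance = 1e-6 * voxVol)
})

test_that("element region uses majority with LYS over SCL tie-break", {
  code <- labelCodes()
  lab <- array(code[["SCL"]], c(2, 2, 2))
  lab[1:2, 1:2, 1] <- code[["LYS"]]  # exactly half LYS, half SCL
  v <- .tinyVolume(c(2, 2, 2), hu = 1700, lab = lab)
  m <- voxelsToTets(v$labels, v$image, fineEdgeMm = 1, coarseEdgeMm = 1)
  expect_true(all(elementRegion(m) == "lytic"))
  # SCL wins over plain labels at equal counts
  lab2 <- array(code[["TRABECULAR"]], c(2, 2, 2))
  lab2[1:2, 1:2, 1] <- code[["SCL"]]
  v2 <- .tinyVolume(c(2, 2, 2), hu = 1700, lab = lab2)
  m2 <- voxelsToTets(v2$labels, v2$image, fineEdgeMm = 1, coarseEdgeMm = 1)
  expect_true(all(elementRegion(m2) == "sclerotic"))
})

test_that("element density is the mean calibrated ash density of the cell", {
  v <- .tinyVolume(c(2, 2, 2), hu = 1500)
  m <- voxelsToTets(v$labels, v$image, fineEdgeMm = 1, coarseEdgeMm = 1)
  expect_equal(unique(elementRhoAsh(m)),
               rhoCtToRhoAsh(huToRhoCt(1500) / 1000), tolerance = 1e-12)
})

test_that("meshes are conforming: interior facets shared by exactly 2 tets", {
  for (m in list(ctrlMesh(), lyticMesh())) {
    tets <- meshTets(m)
    faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                   tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
    srt <- t(apply(faces, 1, sort.int))
    key <- paste(srt[, 1], srt[, 2], srt[, 3])
    counts <- table(table(key))
    expect_true(all(names(counts) %in% c("1", "2")))
    expect_equal(unname(counts[["1"]]), nrow(meshBoundary(m)$facets))
    # all volumes positive
    expect_true(all(tetVolumes(meshNodes(m), tets) > 0))
  }
})

test_that("boundary is watertight: area-weighted normals sum to zero", {
  bd <- meshBoundary(ctrlMesh())
  flux <- colSums(bd$normal * bd$area)
  expect_lt(max(abs(flux)), 1e-9 * sum(bd$area))
})

test_that("refining the fine edge adds elements in the fine zone", {
  ph <- lyticPhantom()
  m1 <- voxelsToTets(ph$labels, ph$image, fineEdgeMm = 1, coarseEdgeMm = 1)
  m2 <- voxelsToTets(ph$labels, ph$image, fineEdgeMm = 0.5, coarseEdgeMm = 1)
  expect_gt(nrow(meshTets(m2)), nrow(meshTets(m1)))
  # fine zone captures the lesion: lytic elements exist at both levels
  expect_true(any(elementRegion(m1) == "lytic"))
  expect_true(any(elementRegion(m2) == "lytic"))
})

test_that("incommensurate or inverted edge specs are rejected", {
  v <- .tinyVolume(c(4, 4, 4))
  expect_error(voxelsToTets(v$labels, v$image, fineEdgeMm = 0.3,
                            coarseEdgeMm = 0.9), "invalid-input")
  expect_error(voxelsToTets(v$labels, v$image, fineEdgeMm = 1,
                            coarseEdgeMm = 0.5), "invalid-input")
  expect_error(voxelsToTets(v$labels, v$image, fineEdgeMm = 0.5,
                            coarseEdgeMm = 2), "invalid-input")
})

test_that("boundary sets land where declared", {
  ph <- ctrlPhantom()
  mesh <- ctrlMesh()
  bd <- meshBoundary(mesh)
  # every strip facet centroid within half the strip width of the plane
  strip <- facetSet(mesh, "PSG_STRIP")
  dplane <- abs((bd$centroid[strip, , drop = FALSE] -
                 matrix(ph$psgPlane$point, length(strip), 3, byrow = TRUE))
                %*% ph$psgPlane$normal)
  expect_true(all(dplane <= 1.5 + 1e-9))
  # fixed nodes hug the proximal cut plane
  fixed <- nodeSet(mesh, "PROXIMAL_FIXED")
  zf <- meshNodes(mesh)[fixed, 3]
  expect_true(all(zf >= max(meshNodes(mesh)[, 3]) - mesh@coarseEdge - 1e-9))
  # load facets face palmar
  lf <- facetSet(mesh, "LOAD_SURFACE")
  expect_true(all(bd$normal[lf, 2] <= -0.2 + 1e-9))
  # zero strip width is degenerate
  expect_error(tagBoundarySets(mesh, ph$frame, ph$psgPlane, 0,
                               ph$loadPatchSpec), "degenerate-geometry")
})

test_that("a permissive load patch takes every non-proximal boundary facet", {
  ph <- ctrlPhantom()
  mesh <- tagBoundarySets(ctrlMesh(), ph$frame, ph$psgPlane, 3,
                          loadPatchSpec = list(box = NULL))
  lf <- facetSet(mesh, "LOAD_SURFACE")
  bd <- meshBoundary(mesh)
  fixed <- nodeSet(mesh, "PROXIMAL_FIXED")
  allFixed <- rowSums(matrix(bd$facets %in% fixed, nrow(bd$facets), 3)) == 3
  expect_equal(sort(lf), which(!allFixed))
})
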