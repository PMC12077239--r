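# Voxel-based tetrahedral meshing.
#
# Bone voxels are grouped into axis-aligned cells (fine in the sclerotic/
# lytic zone, coarse elsewhere). Uniform meshes (fine == coarse) use the
# 6-tet Kuhn/Freudenthal decomposition of each cell, which tiles space
# conformingly when every cell uses the same diagonal. Mixed meshes use a
# one-level (2:1) cell-centre scheme: each cell receives a centre node,
# each quad face is split by a canonical diagonal (subdivided 2x2 first
# when the across-neighbour is finer), and tets are pyramids from the face
# triangles to the cell centre; shared faces are triangulated identically
# from both sides, so interior facets are conforming.
#
# Node positions are encoded as integer triples in half-voxel units, so
# coincident nodes merge exactly.

.encodeKey <- function(enc) {
  # enc: integer matrix n x 3, non-negative, each < 2^16
  (enc[, 3] * 65536 + enc[, 2]) * 65536 + enc[, 1]
}

# Per-voxel block decomposition for block size m (integer length-3).
.cellGrid <- function(d, m) {
  nb <- as.integer(ceiling(d / m))
  i1 <- (seq_len(d[1]) - 1L) %/% m[1]
  i2 <- (seq_len(d[2]) - 1L) %/% m[2]
  i3 <- (seq_len(d[3]) - 1L) %/% m[3]
  bid <- array(i1, d) +
    nb[1] * (array(rep(i2, each = d[1]), d) +
             nb[2] * array(rep(i3, each = d[1] * d[2]), d))
  list(nb = nb, bid = bid, nBlocks = prod(nb))
}

.blockCoords <- function(b, nb) {
  # b: 0-based linear block ids -> 0-based (bx, by, bz)
  cbind(b %% nb[1], (b %/% nb[1]) %% nb[2], b %/% (nb[1] * nb[2]))
}

# Majority region label per block with LYS > SCL > CORTEX > TRABECULAR
# tie-break, plus mean ash density over bone voxels.
.cellStats <- function(bid, nBlocks, lab, rhoVox, boneMask) {
  code <- labelCodes()
  cnt <- vapply(c("LYS", "SCL", "CORTEX", "TRABECULAR"), function(nm)
    tabulate(bid[boneMask & lab == code[[nm]]] + 1L, nBlocks),
    numeric(nBlocks))
  cnt <- matrix(cnt, nrow = nBlocks)
  boneCnt <- tabulate(bid[boneMask] + 1L, nBlocks)
  rhoSum <- numeric(nBlocks)
  rs <- rowsum(rhoVox[boneMask], bid[boneMask] + 1L)
  rhoSum[as.integer(rownames(rs))] <- rs[, 1]
  # which.max on the reordered count matrix applies the priority tie-break
  best <- max.col(cnt, ties.method = "first")
  region <- c("lytic", "sclerotic", "plain", "plain")[best]
  list(region = region, rhoMean = ifelse(boneCnt > 0, rhoSum / boneCnt, NA_real_),
       boneCnt = boneCnt)
}

# Kuhn/Freudenthal 6-tet decomposition of boxes.
# low, size: n x 3 (voxel units). Returns tet corner encodings.
.kuhnTets <- function(low, size) {
  n <- nrow(low)
  e <- diag(3)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  enc <- vector("list", 6L)
  for (p in seq_along(perms)) {
    pr <- perms[[p]]
    d0 <- c(0, 0, 0)
    d1 <- e[pr[1], ]
    d2 <- e[pr[1], ] + e[pr[2], ]
    d3 <- c(1, 1, 1)
    corner <- function(dd)
      2L * (low + size * matrix(dd, n, 3, byrow = TRUE))
    enc[[p]] <- cbind(corner(d0), corner(d1), corner(d2), corner(d3))
  }
  list(enc = do.call(rbind, enc), cell = rep(seq_len(n), times = 6L))
}

# Cell-centre scheme: quads -> 2 tets each (canonical low-corner diagonal).
# quadLow n x 3, a1/a2 span axes (scalars per call), s1/s2 spans (n),
# center n x 3 (voxel units, may be half-integral; encoded x2 stays exact).
.quadTets <- function(quadLow, a1, a2, s1, s2, center, cellIdx) {
  n <- nrow(quadLow)
  q00 <- quadLow
  q10 <- quadLow; q10[, a1] <- q10[, a1] + s1
  q01 <- quadLow; q01[, a2] <- q01[, a2] + s2
  q11 <- q10;     q11[, a2] <- q11[, a2] + s2
  enc <- function(x) 2 * x
  t1 <- cbind(enc(q00), enc(q10), enc(q11), enc(center))
  t2 <- cbind(enc(q00), enc(q11), enc(q01), enc(center))
  list(enc = rbind(t1, t2), cell = rep(cellIdx, 2L))
}

#' Signed and absolute tetrahedron volumes
#'
#' @param nodes n x 3 node coordinate matrix (mm).
#' @param tets m x 4 integer matrix of node indices.
#' @return Numeric vector of signed volumes (mm^3); positive for
#'   correctly oriented tets.
#' @export
tetVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  (cx * c3[, 1] + cy * c3[, 2] + cz * c3[, 3]) / 6
}

# Extract boundary facets (faces owned by exactly one tet), with outward
# unit normals, areas and centroids.
.boundaryFacets <- function(nodes, tets) {
  m <- nrow(tets)
  faceDef <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- rbind(tets[, faceDef[1, ]], tets[, faceDef[2, ]],
                 tets[, faceDef[3, ]], tets[, faceDef[4, ]])
  owner <- rep(seq_len(m), times = 4L)
  opp <- c(tets[, 4], tets[, 3], tets[, 2], tets[, 1])
  srt <- t(apply(faces, 1, sort.int))
  key <- (srt[, 3] * 2^18 + srt[, 2]) * 2^18 + srt[, 1]
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  keep <- which(!dup)
  faces <- faces[keep, , drop = FALSE]
  owner <- owner[keep]
  opp <- opp[keep]
  p1 <- nodes[faces[, 1], , drop = FALSE]
  u <- nodes[faces[, 2], , drop = FALSE] - p1
  v <- nodes[faces[, 3], , drop = FALSE] - p1
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nrm <- cbind(nx, ny, nz)
  area <- sqrt(rowSums(nrm^2)) / 2
  nrm <- nrm / (2 * area)
  centroid <- (nodes[faces[, 1], , drop = FALSE] +
               nodes[faces[, 2], , drop = FALSE] +
               nodes[faces[, 3], , drop = FALSE]) / 3
  flip <- rowSums(nrm * (centroid - nodes[opp, , drop = FALSE])) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  list(facets = faces, owner = owner, normal = nrm, area = area,
       centroid = centroid)
}

#' Build a tetrahedral mesh from a label volume
#'
#' Groups bone voxels into cells of edge `coarseEdgeMm`, refined to
#' `fineEdgeMm` inside the bounding box of the `fineRegions` labels plus
#' `fineMarginMm`. A cell is kept when at least half of its voxels are
#' bone. Uniform meshes use the 6-tet Kuhn decomposition; mixed meshes a
#' conforming one-level 2:1 cell-centre scheme (the edge ratio must be 1
#' or 2). Element ash density is the mean calibrated ash density of the
#' cell's bone voxels; the element region is the majority label with ties
#' resolved LYS over SCL over the rest.
#'
#' @param labels A [LabelVolume-class].
#' @param image The congruent [VoxelImage-class] of CT numbers.
#' @param curve [CalibrationCurve-class] used for the density chain.
#' @param law [DensityModulusLaw-class] (ash conversion and floor).
#' @param fineRegions Labels meshed at the fine edge
#'   (default `c("SCL", "LYS")`).
#' @param fineEdgeMm,coarseEdgeMm Cell edge lengths (mm); must be integer
#'   multiples of the voxel spacing, with `fineEdgeMm <= coarseEdgeMm`.
#' @param fineMarginMm Margin added around the fine-region bounding box
#'   (default one coarse edge).
#' @return A [TetrahedralMesh-class] (named sets still empty; see
#'   [tagBoundarySets()]).
#' @export
voxelsToTets <- function(labels, image, curve = defaultCalibrationCurve(),
                         law = defaultDensityModulusLaw(),
                         fineRegions = c("SCL", "LYS"),
                         fineEdgeMm = 0.5, coarseEdgeMm = 1,
                         fineMarginMm = coarseEdgeMm) {
  stopifnot(is(labels, "LabelVolume"), is(image, "VoxelImage"))
  lab <- labels@labels
  d <- dim(lab)
  if (!identical(dim(image@values), d))
    .stopInvalid("invalid-input: image and labels are not congruent")
  if (fineEdgeMm > coarseEdgeMm)
    .stopInvalid("invalid-input: fineEdgeMm must be <= coarseEdgeMm")
  sp <- labels@spacing
  m <- coarseEdgeMm / sp
  f <- fineEdgeMm / sp
  if (any(abs(m - round(m)) > 1e-9) || any(abs(f - round(f)) > 1e-9))
    .stopInvalid("invalid-input: edge lengths must be integer multiples ",
                 "of the voxel spacing")
  m <- as.integer(round(m)); f <- as.integer(round(f))
  ratio <- unique(m %/% f)
  if (length(ratio) != 1 || any(m != ratio * f) || !ratio %in% c(1L, 2L))
    .stopInvalid("invalid-input: coarse/fine edge ratio must be 1 or 2")
  boneMask <- lab != labelCodes()[["OUTSIDE"]]
  if (!any(boneMask)) .stopInvalid("invalid-input: empty bone volume")

  rhoVox <- rhoCtToRhoAsh(huToRhoCt(image@values, curve) / 1000, law)

  cg <- .cellGrid(d, m)
  totC <- tabulate(cg$bid + 1L, cg$nBlocks)
  boneC <- tabulate(cg$bid[boneMask] + 1L, cg$nBlocks)
  coarseIncl <- boneC > 0 & boneC >= 0.5 * totC

  fineCode <- labelCodes()[fineRegions]
  fineVox <- which(array(lab %in% fineCode, d))
  mixed <- ratio == 2L && length(fineVox) > 0
  cellLow <- NULL; cellSize <- NULL; cellStatsIdx <- NULL
  fg <- NULL; fineIncl <- NULL

  if (!mixed) {
    ids <- which(coarseIncl) - 1L
    bc <- .blockCoords(ids, cg$nb)
    cellLow <- sweep(bc, 2, m, "*")
    cellSize <- matrix(m, length(ids), 3, byrow = TRUE)
    stats <- .cellStats(cg$bid, cg$nBlocks, lab, rhoVox, boneMask)
    cellRegion <- stats$region[ids + 1L]
    cellRho <- stats$rhoMean[ids + 1L]
  } else {
    fg <- .cellGrid(d, f)
    totF <- tabulate(fg$bid + 1L, fg$nBlocks)
    boneF <- tabulate(fg$bid[boneMask] + 1L, fg$nBlocks)
    # fine zone: coarse blocks overlapping bbox(fine regions) + margin
    ijk <- arrayInd(fineVox, d)
    marginVox <- ceiling(fineMarginMm / sp)
    lo <- pmax(apply(ijk, 2, min) - marginVox, 1)
    hi <- pmin(apply(ijk, 2, max) + marginVox, d)
    bLo <- (lo - 1L) %/% m
    bHi <- (hi - 1L) %/% m
    allB <- .blockCoords(seq_len(cg$nBlocks) - 1L, cg$nb)
    inZone <- allB[, 1] >= bLo[1] & allB[, 1] <= bHi[1] &
              allB[, 2] >= bLo[2] & allB[, 2] <= bHi[2] &
              allB[, 3] >= bLo[3] & allB[, 3] <= bHi[3]
    # fine cells: decided at fine level inside the zone
    allF <- .blockCoords(seq_len(fg$nBlocks) - 1L, fg$nb)
    fInZone <- (allF[, 1] %/% 2L) >= bLo[1] & (allF[, 1] %/% 2L) <= bHi[1] &
               (allF[, 2] %/% 2L) >= bLo[2] & (allF[, 2] %/% 2L) <= bHi[2] &
               (allF[, 3] %/% 2L) >= bLo[3] & (allF[, 3] %/% 2L) <= bHi[3]
    fineIncl <- fInZone & boneF > 0 & boneF >= 0.5 * totF
    coarseKeep <- coarseIncl & !inZone
    idsC <- which(coarseKeep) - 1L
    idsF <- which(fineIncl) - 1L
    bcC <- .blockCoords(idsC, cg$nb)
    bcF <- .blockCoords(idsF, fg$nb)
    cellLow <- rbind(sweep(bcC, 2, m, "*"), sweep(bcF, 2, f, "*"))
    cellSize <- rbind(matrix(m, length(idsC), 3, byrow = TRUE),
                      matrix(f, length(idsF), 3, byrow = TRUE))
    statsC <- .cellStats(cg$bid, cg$nBlocks, lab, rhoVox, boneMask)
    statsF <- .cellStats(fg$bid, fg$nBlocks, lab, rhoVox, boneMask)
    cellRegion <- c(statsC$region[idsC + 1L], statsF$region[idsF + 1L])
    cellRho <- c(statsC$rhoMean[idsC + 1L], statsF$rhoMean[idsF + 1L])
    nCoarse <- length(idsC)
  }
  nCells <- nrow(cellLow)
  if (nCells == 0) .stopInvalid("invalid-input: no cells met the bone rule")

  if (!mixed) {
    kt <- .kuhnTets(cellLow, cellSize)
    tetEnc <- kt$enc
    tetCell <- kt$cell
  } else {
    # cell-centre scheme for every cell; coarse faces subdivide 2x2 when
    # the across-neighbour block holds face-adjacent fine cells
    fineExists <- fineIncl
    nf <- fg$nb
    center <- cellLow + cellSize / 2
    pieces <- list()
    isCoarse <- seq_len(nCells) <= nCoarse
    for (axis in 1:3) {
      others <- setdiff(1:3, axis)
      a1 <- others[1]; a2 <- others[2]
      for (dir in c(-1L, 1L)) {
        # ---- coarse cells: check the 4 face-adjacent fine slots
        ci <- which(isCoarse)
        if (length(ci)) {
          bc <- cellLow[ci, , drop = FALSE] %/% rep(m, each = length(ci))
          fAxis <- if (dir > 0) 2L * bc[, axis] + 2L else 2L * bc[, axis] - 1L
          anyFine <- rep(FALSE, length(ci))
          for (o1 in 0:1) for (o2 in 0:1) {
            fc <- matrix(0L, length(ci), 3)
            fc[, axis] <- fAxis
            fc[, a1] <- 2L * bc[, a1] + o1
            fc[, a2] <- 2L * bc[, a2] + o2
            ok <- fc[, 1] >= 0 & fc[, 1] < nf[1] & fc[, 2] >= 0 &
                  fc[, 2] < nf[2] & fc[, 3] >= 0 & fc[, 3] < nf[3]
            id <- fc[, 1] + nf[1] * (fc[, 2] + nf[2] * fc[, 3])
            hit <- ok
            hit[ok] <- fineExists[id[ok] + 1L]
            anyFine <- anyFine | hit
          }
          faceLowAll <- cellLow[ci, , drop = FALSE]
          if (dir > 0) faceLowAll[, axis] <- faceLowAll[, axis] + m[axis]
          # unsubdivided coarse faces
          un <- which(!anyFine)
          if (length(un)) {
            pieces[[length(pieces) + 1L]] <- .quadTets(
              faceLowAll[un, , drop = FALSE], a1, a2,
              rep(m[a1], length(un)), rep(m[a2], length(un)),
              center[ci[un], , drop = FALSE], ci[un])
          }
          # subdivided coarse faces: 4 sub-quads of fine size
          sb <- which(anyFine)
          if (length(sb)) for (o1 in 0:1) for (o2 in 0:1) {
            ql <- faceLowAll[sb, , drop = FALSE]
            ql[, a1] <- ql[, a1] + o1 * f[a1]
            ql[, a2] <- ql[, a2] + o2 * f[a2]
            pieces[[length(pieces) + 1L]] <- .quadTets(
              ql, a1, a2, rep(f[a1], length(sb)), rep(f[a2], length(sb)),
              center[ci[sb], , drop = FALSE], ci[sb])
          }
        }
        # ---- fine cells: single quad per face
        fi <- which(!isCoarse)
        if (length(fi)) {
          ql <- cellLow[fi, , drop = FALSE]
          if (dir > 0) ql[, axis] <- ql[, axis] + f[axis]
          pieces[[length(pieces) + 1L]] <- .quadTets(
            ql, a1, a2, rep(f[a1], length(fi)), rep(f[a2], length(fi)),
            center[fi, , drop = FALSE], fi)
        }
      }
    }
    tetEnc <- do.call(rbind, lapply(pieces, `[[`, "enc"))
    tetCell <- unlist(lapply(pieces, `[[`, "cell"))
  }

  # dedupe nodes by encoded half-voxel coordinates
  allEnc <- rbind(tetEnc[, 1:3], tetEnc[, 4:6], tetEnc[, 7:9],
                  tetEnc[, 10:12])
  storage.mode(allEnc) <- "integer"
  key <- .encodeKey(allEnc + 8L)
  uk <- unique(key)
  nid <- match(key, uk)
  nt <- nrow(tetEnc)
  tets <- cbind(nid[seq_len(nt)], nid[nt + seq_len(nt)],
                nid[2L * nt + seq_len(nt)], nid[3L * nt + seq_len(nt)])
  firstOcc <- match(uk, key)
  nodeEnc <- allEnc[firstOcc, , drop = FALSE]
  nodes <- sweep(sweep(nodeEnc / 2 - 0.5, 2, sp, "*"), 2, labels@origin, "+")

  vol <- tetVolumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
  }
  if (any(tetVolumes(nodes, tets) <= 0))
    .stopInvalid("degenerate-geometry: non-positive tet volume")

  storage.mode(tets) <- "integer"
  new("TetrahedralMesh", nodes = nodes, tets = tets,
      elementRegion = cellRegion[tetCell],
      elementRhoAsh = cellRho[tetCell],
      boundary = .boundaryFacets(nodes, tets),
      nodeSets = list(), facetSets = list(),
      fineEdge = fineEdgeMm, coarseEdge = coarseEdgeMm)
}

#' Tag named boundary sets on a mesh
#'
#' Defines the three named sets used by the load case: `PROXIMAL_FIXED`
#' (boundary nodes within one coarse edge of the proximal cut plane),
#' `PSG_STRIP` (boundary facets whose centroid lies within half the strip
#' width of the groove plane, optionally restricted to the distal
#' condyle), and `LOAD_SURFACE` (boundary facets inside the declared
#' palmar patch of the medial condyle, excluding fully fixed facets).
#'
#' @param mesh A [TetrahedralMesh-class].
#' @param frame An [AnatomicalFrame-class]; its long axis defines
#'   proximal/distal.
#' @param psgPlane List with `point` (mm) and unit `normal` for the groove
#'   plane, and optionally `axisMax`: facets are kept only while their
#'   centroid's long-axis coordinate stays below it (restricting the strip
#'   to the condyle).
#' @param stripWidthMm Strip width (default 3 mm; the strip spans half of
#'   it on each side of the groove plane).
#' @param loadPatchSpec List with `box` (3 x 2 matrix of world bounds, may
#'   be infinite), optional `normalDir` with `minCos` (default 0.2):
#'   facets qualify when their outward normal has cosine at least
#'   `minCos` with `normalDir`.
#' @param proximalTolMm Thickness of the fixed proximal slab (default one
#'   coarse edge).
#' @return The mesh with `nodeSets` and `facetSets` filled.
#' @export
tagBoundarySets <- function(mesh, frame, psgPlane, stripWidthMm = 3,
                            loadPatchSpec = list(box = NULL),
                            proximalTolMm = mesh@coarseEdge) {
  stopifnot(is(mesh, "TetrahedralMesh"), is(frame, "AnatomicalFrame"))
  if (stripWidthMm <= 0)
    .stopInvalid("degenerate-geometry: strip width must be positive")
  bd <- mesh@boundary
  if (nrow(bd$facets) == 0)
    .stopInvalid("degenerate-geometry: mesh has no boundary")
  axis <- frame@longAxis
  bNodes <- sort(unique(as.vector(bd$facets)))
  projN <- as.numeric(mesh@nodes[bNodes, , drop = FALSE] %*% axis)
  fixed <- bNodes[projN >= max(projN) - proximalTolMm]
  if (!length(fixed))
    .stopInvalid("degenerate-geometry: empty PROXIMAL_FIXED set")

  dplane <- as.numeric((bd$centroid -
            matrix(psgPlane$point, nrow(bd$centroid), 3, byrow = TRUE)) %*%
            psgPlane$normal)
  strip <- abs(dplane) <= stripWidthMm / 2
  projC <- as.numeric(bd$centroid %*% axis)
  if (!is.null(psgPlane$axisMax)) strip <- strip & projC <= psgPlane$axisMax
  stripIdx <- which(strip)
  if (!length(stripIdx))
    .stopInvalid("degenerate-geometry: empty PSG_STRIP set")

  inFixed <- matrix(bd$facets %in% fixed, nrow(bd$facets), 3)
  allFixed <- rowSums(inFixed) == 3
  loadSel <- !allFixed
  if (!is.null(loadPatchSpec$box)) {
    box <- loadPatchSpec$box
    loadSel <- loadSel &
      bd$centroid[, 1] >= box[1, 1] & bd$centroid[, 1] <= box[1, 2] &
      bd$centroid[, 2] >= box[2, 1] & bd$centroid[, 2] <= box[2, 2] &
      bd$centroid[, 3] >= box[3, 1] & bd$centroid[, 3] <= box[3, 2]
  }
  if (!is.null(loadPatchSpec$normalDir)) {
    minCos <- if (is.null(loadPatchSpec$minCos)) 0.2 else loadPatchSpec$minCos
    nd <- loadPatchSpec$normalDir / sqrt(sum(loadPatchSpec$normalDir^2))
    loadSel <- loadSel & as.numeric(bd$normal %*% nd) >= minCos
  }
  loadIdx <- which(loadSel)
  if (!length(loadIdx))
    .stopInvalid("degenerate-geometry: empty LOAD_SURFACE set")

  mesh@nodeSets <- list(PROXIMAL_FIXED = as.integer(fixed))
  mesh@facetSets <- list(LOAD_SURFACE = as.integer(loadIdx),
                         PSG_STRIP = as.integer(stripIdx))
  mesh
}
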