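# Voxel-level operations: mask conditioning, anatomical frame, distal
# isolation, region labeling by the HU=1500 rule, sclerotic volume fraction.
#
# Masks are plain logical 3-D arrays congruent with their source image.
# Voxel (i,j,k) (1-based) sits at world position origin + (i-1,j-1,k-1)*spacing.

#' World coordinates of voxels
#'
#' @param dims Grid dimensions (length 3).
#' @param spacing,origin mm.
#' @param which Linear indices of the voxels wanted (default all).
#' @return Matrix (length(which) x 3) of world coordinates in mm.
#' @keywords internal
.voxelCoords <- function(dims, spacing, origin, which = NULL) {
  if (is.null(which)) which <- seq_len(prod(dims))
  ijk <- arrayInd(which, dims)
  sweep(sweep(ijk - 1, 2, spacing, "*"), 2, origin, "+")
}

# Shift a 3-D array by one voxel along `axis` in direction `dir` (+1/-1),
# padding with `fill`.
.shift3 <- function(a, axis, dir, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else         { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Erode a binary mask from its external surface
#'
#' Morphological erosion with the 6-connected (face-adjacency)
#' structuring element, applied `iterations` times. Used to pull a
#' segmented bone surface one pixel tight onto the cortex.
#'
#' @param mask Logical 3-D array.
#' @param iterations Number of single-voxel erosions (default 1).
#' @return Logical array, a subset of `mask`.
#' @export
#' @examples
#' cube <- array(TRUE, c(5, 5, 5))
#' sum(erodeSurface(cube))  # 27: the inner 3 x 3 x 3 core
erodeSurface <- function(mask, iterations = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (!any(mask)) .stopInvalid("invalid-input: empty mask")
  out <- mask
  for (it in seq_len(iterations)) {
    res <- out
    for (axis in 1:3) for (dir in c(-1L, 1L))
      res <- res & .shift3(out, axis, dir, fill = FALSE)
    if (!any(res))
      .stopInvalid("degenerate-geometry: erosion produced an empty mask")
    out <- res
  }
  out
}

#' Fit the anatomical coordinate frame of an elongated bone mask
#'
#' The long axis is the principal direction of the voxel point cloud (a
#' surrogate for a cylinder fit, with which it agrees to well under a
#' degree on elongated near-cylindrical shapes). The dorsal direction is
#' supplied as a landmark - known exactly for synthetic phantoms,
#' user-provided for real data - and orthogonalized against the long
#' axis; the medio-lateral (sagittal-normal) axis completes a
#' right-handed orthonormal triad.
#'
#' @param mask Logical 3-D array with at least 100 voxels.
#' @param spacing,origin Voxel spacing and origin (mm).
#' @param dorsalLandmark World point (mm) on the dorsal side of the bone.
#' @param distalLandmark World point (mm) near the distal end; fixes the
#'   sign of the long axis (proximal sense is away from this point).
#' @return An [AnatomicalFrame-class] with origin at the mask centroid.
#' @export
fitAnatomicalFrame <- function(mask, spacing, origin = c(0, 0, 0),
                               dorsalLandmark, distalLandmark) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  idx <- which(mask)
  if (length(idx) < 100)
    .stopInvalid("invalid-input: mask must contain at least 100 voxels")
  pts <- .voxelCoords(dim(mask), spacing, origin, idx)
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  if (sqrt(ev$values[1] / ev$values[2]) < 1.5)
    .stopInvalid("ambiguous-axis: point cloud is not elongated ",
                 "(principal extent ratio < 1.5)")
  axis <- ev$vectors[, 1]
  if (sum(axis * (ctr - distalLandmark)) < 0) axis <- -axis
  d <- dorsalLandmark - ctr
  d <- d - sum(d * axis) * axis
  if (sqrt(sum(d^2)) < 1e-9)
    .stopInvalid("invalid-input: dorsal landmark is collinear with the ",
                 "long axis")
  frontal <- d / sqrt(sum(d^2))
  sagittal <- c(frontal[2] * axis[3] - frontal[3] * axis[2],
                frontal[3] * axis[1] - frontal[1] * axis[3],
                frontal[1] * axis[2] - frontal[2] * axis[1])
  sagittal <- sagittal / sqrt(sum(sagittal^2))
  new("AnatomicalFrame", longAxis = axis, frontalNormal = frontal,
      sagittalNormal = sagittal, transverseNormal = axis, origin = ctr)
}

#' Isolate the distal segment of a bone mask
#'
#' Keeps voxels whose coordinate along the long axis lies within `length`
#' of the distal-most bone voxel. The default 63.5 mm is the standard
#' distal 2.5 inch segment of the MC3.
#'
#' @param mask Logical 3-D array.
#' @param frame [AnatomicalFrame-class] (long axis points proximally).
#' @param spacing,origin mm.
#' @param length Retained extent along the long axis (mm; default 63.5).
#' @return Logical array.
#' @export
isolateDistal <- function(mask, frame, spacing, origin = c(0, 0, 0),
                          length = 63.5) {
  stopifnot(is.logical(mask), is(frame, "AnatomicalFrame"), length > 0)
  idx <- which(mask)
  if (!length(idx)) .stopInvalid("invalid-input: empty mask")
  pts <- .voxelCoords(dim(mask), spacing, origin, idx)
  proj <- as.numeric(pts %*% frame@longAxis)
  if (max(proj) - min(proj) < length - 1e-9)
    .stopInvalid("invalid-input: mask extent along the long axis (",
                 format(max(proj) - min(proj)), " mm) is shorter than ",
                 length, " mm")
  out <- array(FALSE, dim(mask))
  out[idx[proj <= min(proj) + length]] <- TRUE
  out
}

# 26-connected components of a logical array, via igraph.
# Returns a list of integer vectors of linear voxel indices.
.connectedComponents26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
           (offs[, 1] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 3] > 0)))), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbid <- vid[nb[ok, , drop = FALSE]]
    src <- which(ok)[nbid > 0]
    if (length(src)) edges[[o]] <- cbind(src, nbid[nbid > 0])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  split(idx, comp$membership)
}

#' Label bone regions by the HU threshold rule
#'
#' Sclerotic bone (SCL) is every trabecular voxel with CT number above
#' `thresholdHu`. Lytic bone (LYS) is any isolated focal pocket below the
#' threshold inside the declared parasagittal-groove search region:
#' 26-connected components of sub-threshold bone voxels in
#' `psgRegionMask`, of at least `minLysisVoxels` voxels, whose entire
#' 6-neighbourhood outside the component is bone at or above the
#' threshold. Remaining bone is labelled CORTEX (outside the trabecular
#' mask) or TRABECULAR.
#'
#' @param image A [VoxelImage-class].
#' @param boneMask,trabecularMask,psgRegionMask Logical arrays congruent
#'   with `image`; `trabecularMask` must be a subset of `boneMask`.
#' @param thresholdHu Threshold CT number (default 1500, the density
#'   histogram secondary-peak threshold, equivalent to 1390 mgHA/cm^3
#'   under the default calibration).
#' @param minLysisVoxels Minimum lysis component size (default 8).
#' @return A [LabelVolume-class].
#' @export
labelRegions <- function(image, boneMask, trabecularMask, psgRegionMask,
                         thresholdHu = 1500, minLysisVoxels = 8) {
  stopifnot(is(image, "VoxelImage"))
  hu <- image@values
  d <- dim(hu)
  for (m in list(boneMask, trabecularMask, psgRegionMask))
    if (!identical(dim(m), d))
      .stopInvalid("invalid-input: masks must be congruent with the image")
  if (!any(boneMask)) .stopInvalid("invalid-input: empty bone mask")
  if (any(trabecularMask & !boneMask))
    .stopInvalid("invalid-input: trabecularMask must be a subset of boneMask")
  code <- labelCodes()
  lab <- array(code[["OUTSIDE"]], d)
  lab[boneMask] <- code[["CORTEX"]]
  lab[trabecularMask] <- code[["TRABECULAR"]]
  lab[trabecularMask & hu > thresholdHu] <- code[["SCL"]]

  cand <- boneMask & psgRegionMask & hu < thresholdHu
  comps <- .connectedComponents26(cand)
  inComp <- array(FALSE, d)
  for (cp in comps) {
    if (length(cp) < minLysisVoxels) next
    inComp[] <- FALSE
    inComp[cp] <- TRUE
    ijk <- arrayInd(cp, d)
    isolated <- TRUE
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      nb <- ijk
      nb[, axis] <- nb[, axis] + dir
      if (any(nb[, axis] < 1 | nb[, axis] > d[axis])) { isolated <- FALSE; break }
      out <- !inComp[nb]
      if (any(out & (!boneMask[nb] | hu[nb] < thresholdHu))) {
        isolated <- FALSE; break
      }
    }
    if (isolated) lab[cp] <- code[["LYS"]]
  }
  new("LabelVolume", labels = lab, spacing = image@spacing,
      origin = image@origin)
}

#' Sclerotic volume fraction of a condyle
#'
#' `V_SCL = V_sclerosis / V_condyle`: the volume of SCL-labelled voxels
#' inside the condyle mask divided by the condyle volume.
#'
#' @param labels A [LabelVolume-class].
#' @param condyleMask Logical array congruent with `labels`.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
scleroticVolumeFraction <- function(labels, condyleMask) {
  stopifnot(is(labels, "LabelVolume"))
  if (!identical(dim(condyleMask), dim(labels@labels)))
    .stopInvalid("invalid-input: condyle mask not congruent with labels")
  n <- sum(condyleMask)
  if (n == 0) .stopInvalid("invalid-input: empty condyle mask")
  sum(labels@labels[condyleMask] == labelCodes()[["SCL"]]) / n
}
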