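# Linear isotropic elasticity on linear (constant-strain) tetrahedra.
#
# Element stiffness in closed form from the shape-function gradients g_a:
#   K[ai, bj] = V * ( lambda g_a,i g_b,j + mu g_a,j g_b,i
#                     + mu delta_ij (g_a . g_b) )
# Assembly is fully vectorized over elements (144 triplet batches).
# The solve is a sparse Cholesky factorization of the free-DOF block,
# deterministic for a given mesh.

#' @importFrom Matrix sparseMatrix forceSymmetric Cholesky solve t crossprod
NULL

#' Construct a load case
#'
#' @param totalForce Total applied force (N); default 7500 (the standard
#'   7.5 kN condylar load).
#' @param angleFrontal,angleTransverse Load angles (degrees) with respect
#'   to the frontal and transverse planes; defaults 60 and 30.
#' @param distribution `"uniform-nodal"` (equal nodal forces, the
#'   default) or `"area-weighted"` (tributary facet area).
#' @return A [LoadCase-class].
#' @export
loadCase <- function(totalForce = 7500, angleFrontal = 60,
                     angleTransverse = 30,
                     distribution = "uniform-nodal") {
  new("LoadCase", totalForce = totalForce, angleFrontal = angleFrontal,
      angleTransverse = angleTransverse, distribution = distribution)
}

#' Load direction from plane angles
#'
#' Builds the unit load direction from its angles to the frontal and
#' transverse planes: the out-of-frontal-plane component is
#' `sin(angleFrontal)` (dorsal sense), the out-of-transverse-plane
#' component `sin(angleTransverse)` (proximal sense), and the
#' medio-lateral component the non-negative remainder
#' `sqrt(1 - sin^2 - sin^2)`. At the standard 60/30 degrees the direction
#' lies exactly in the sagittal plane.
#'
#' @param angleFrontal,angleTransverse Degrees.
#' @param frame An [AnatomicalFrame-class].
#' @return Unit length-3 vector in world coordinates.
#' @export
#' @examples
#' # components in the frame basis at 60/30: (0, 0.866, 0.5)
directionFromAngles <- function(angleFrontal, angleTransverse, frame) {
  stopifnot(is(frame, "AnatomicalFrame"))
  sf <- sin(angleFrontal * pi / 180)
  st <- sin(angleTransverse * pi / 180)
  rest <- 1 - sf^2 - st^2
  if (rest < -1e-12)
    .stopInvalid("infeasible-angles: sin^2(frontal) + sin^2(transverse) > 1")
  # angles that exactly exhaust the unit norm (e.g. 60/30) lie in the
  # sagittal plane; suppress the floating-point residue
  ml <- if (rest < 1e-12) 0 else sqrt(rest)
  dir <- sf * frame@frontalNormal + st * frame@longAxis +
    ml * frame@sagittalNormal
  dir / sqrt(sum(dir^2))
}

# Shape-function gradients and volumes for all tets.
# Returns list(g: list of 4 (m x 3) gradient matrices, vol: m).
.tetGradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c3 <- nodes[tets[, 4], , drop = FALSE] - p1
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, c3)
  cxa <- cross(c3, a)
  axb <- cross(a, b)
  det <- rowSums(a * bxc)  # 6V
  g2 <- bxc / det
  g3 <- cxa / det
  g4 <- axb / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

# Sparse global stiffness (3n x 3n) for per-element E, common nu.
.assembleStiffness <- function(nodes, tets, E, nu) {
  gr <- .tetGradients(nodes, tets)
  if (any(gr$vol <= 0))
    .stopInvalid("input-validation: non-positive element volume")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  V <- gr$vol
  m <- nrow(tets)
  nTrip <- 144L * m
  ii <- integer(nTrip); jj <- integer(nTrip); xx <- numeric(nTrip)
  pos <- 0L
  for (a in 1:4) {
    ga <- gr$g[[a]]
    for (b in 1:4) {
      gb <- gr$g[[b]]
      gagb <- rowSums(ga * gb)
      for (i in 1:3) for (j in 1:3) {
        val <- V * (lam * ga[, i] * gb[, j] + mu * ga[, j] * gb[, i])
        if (i == j) val <- val + V * mu * gagb
        idx <- pos + seq_len(m)
        ii[idx] <- 3L * (tets[, a] - 1L) + i
        jj[idx] <- 3L * (tets[, b] - 1L) + j
        xx[idx] <- val
        pos <- pos + m
      }
    }
  }
  n3 <- 3L * nrow(nodes)
  forceSymmetric(sparseMatrix(i = ii, j = jj, x = xx, dims = c(n3, n3)))
}

#' Solve a linear elastic boundary-value problem
#'
#' Low-level entry point: assembles the global stiffness for the given
#' per-element Young's moduli and common Poisson's ratio, applies
#' (possibly inhomogeneous) Dirichlet constraints and nodal forces, and
#' solves by sparse Cholesky factorization.
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param tets m x 4 node indices (positive volume).
#' @param E Young's modulus per element (MPa), all positive.
#' @param nu Poisson's ratio (default 0.3).
#' @param fixedDofs Integer vector of constrained DOF indices (1-based;
#'   DOF of node k, direction d, is `3*(k-1)+d`).
#' @param fixedValues Prescribed displacement per fixed DOF (recycled;
#'   default 0).
#' @param forces n x 3 matrix (or length-3n vector) of nodal forces (N).
#' @return List with `u` (n x 3 displacements, mm), `reactions` (n x 3, N)
#'   and `K` (the assembled stiffness, for diagnostics).
#' @export
solveElasticity <- function(nodes, tets, E, nu = 0.3, fixedDofs,
                            fixedValues = 0, forces) {
  if (any(E <= 0)) .stopInvalid("input-validation: all moduli must be > 0")
  if (!length(fixedDofs))
    .stopInvalid("constraint-deficiency: no constrained DOFs; ",
                 "rigid-body modes present")
  n3 <- 3L * nrow(nodes)
  f <- if (is.matrix(forces)) as.numeric(t(forces)) else as.numeric(forces)
  stopifnot(length(f) == n3)
  K <- .assembleStiffness(nodes, tets, E, nu)
  fixedDofs <- as.integer(fixedDofs)
  uFix <- rep_len(as.numeric(fixedValues), length(fixedDofs))
  free <- setdiff(seq_len(n3), fixedDofs)
  Kff <- forceSymmetric(K[free, free, drop = FALSE])
  rhs <- f[free] - as.numeric(K[free, fixedDofs, drop = FALSE] %*% uFix)
  ch <- tryCatch(Cholesky(Kff, LDL = FALSE, super = TRUE),
                 error = function(e)
                   .stopInvalid("constraint-deficiency: stiffness not ",
                                "positive definite on free DOFs (",
                                conditionMessage(e), ")"))
  u <- numeric(n3)
  u[fixedDofs] <- uFix
  u[free] <- as.numeric(solve(ch, rhs, system = "A"))
  r <- as.numeric(K %*% u) - f
  list(u = matrix(u, ncol = 3, byrow = TRUE),
       reactions = matrix(r, ncol = 3, byrow = TRUE), K = K)
}

# Element small-strain tensors (Voigt xx,yy,zz,xy,yz,xz; tensor shears)
# and principal strains (descending) from nodal displacements.
.elementStrains <- function(nodes, tets, u) {
  gr <- .tetGradients(nodes, tets)
  m <- nrow(tets)
  H <- array(0, c(m, 3, 3))  # displacement gradient du_i/dx_j
  for (a in 1:4) {
    ua <- u[tets[, a], , drop = FALSE]
    ga <- gr$g[[a]]
    for (i in 1:3) for (j in 1:3)
      H[, i, j] <- H[, i, j] + ua[, i] * ga[, j]
  }
  eps <- cbind(H[, 1, 1], H[, 2, 2], H[, 3, 3],
               (H[, 1, 2] + H[, 2, 1]) / 2,
               (H[, 2, 3] + H[, 3, 2]) / 2,
               (H[, 1, 3] + H[, 3, 1]) / 2)
  colnames(eps) <- c("xx", "yy", "zz", "xy", "yz", "xz")
  list(strain = eps, principal = .principalValues(eps))
}

# Eigenvalues of symmetric 3x3 tensors in Voigt rows, sorted descending.
# Closed-form (deviatoric trigonometric) solution, vectorized.
.principalValues <- function(eps) {
  exx <- eps[, 1]; eyy <- eps[, 2]; ezz <- eps[, 3]
  exy <- eps[, 4]; eyz <- eps[, 5]; exz <- eps[, 6]
  q <- (exx + eyy + ezz) / 3
  dxx <- exx - q; dyy <- eyy - q; dzz <- ezz - q
  p2 <- (dxx^2 + dyy^2 + dzz^2) / 2 + exy^2 + eyz^2 + exz^2
  p <- sqrt(p2 / 3)
  detB <- dxx * (dyy * dzz - eyz^2) - exy * (exy * dzz - eyz * exz) +
    exz * (exy * eyz - dyy * exz)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  dimnames(out) <- NULL
  iso <- !is.finite(p) | p < .Machine$double.eps * pmax(abs(q), 1)
  if (any(iso)) out[iso, ] <- q[iso]
  out
}

#' Per-element Young's moduli for a mesh
#'
#' Applies the density-modulus law with region factors to the mesh's
#' per-element ash densities and region labels.
#'
#' @param mesh A [TetrahedralMesh-class].
#' @param law A [DensityModulusLaw-class].
#' @param factors A [RegionFactors-class].
#' @return Numeric vector of moduli (MPa), one per tet.
#' @export
elementModuli <- function(mesh, law = defaultDensityModulusLaw(),
                          factors = regionFactors()) {
  rhoAshToModulus(pmax(mesh@elementRhoAsh, law@densityFloor), law,
                  mesh@elementRegion, factors)
}

# Nodal force matrix for a load case on the tagged mesh.
.loadForces <- function(mesh, load, frame) {
  bd <- mesh@boundary
  loadIdx <- facetSet(mesh, "LOAD_SURFACE")
  fixed <- nodeSet(mesh, "PROXIMAL_FIXED")
  dir <- directionFromAngles(load@angleFrontal, load@angleTransverse, frame)
  facNodes <- bd$facets[loadIdx, , drop = FALSE]
  nodesL <- setdiff(sort(unique(as.vector(facNodes))), fixed)
  if (!length(nodesL))
    .stopInvalid("degenerate-geometry: load surface has no free nodes")
  f <- matrix(0, nrow(mesh@nodes), 3)
  if (load@distribution == "uniform-nodal") {
    w <- rep(1 / length(nodesL), length(nodesL))
  } else {
    wAll <- numeric(nrow(mesh@nodes))
    aThird <- bd$area[loadIdx] / 3
    for (k in 1:3) {
      acc <- rowsum(aThird, facNodes[, k])
      wAll[as.integer(rownames(acc))] <- wAll[as.integer(rownames(acc))] +
        acc[, 1]
    }
    w <- wAll[nodesL]
    w <- w / sum(w)
  }
  f[nodesL, ] <- (load@totalForce * w) %o% dir
  f
}

#' Assemble and solve the condylar load case on a tagged mesh
#'
#' Applies the total load along the direction given by the load-case
#' angles, distributed over the free `LOAD_SURFACE` nodes (equally, or by
#' tributary area), fully constrains `PROXIMAL_FIXED`, solves the linear
#' elastic system, and computes element strain tensors, principal
#' strains, and the per-boundary-facet maximum principal strain of the
#' owning tet (no nodal averaging).
#'
#' @param mesh A [TetrahedralMesh-class] with tagged sets.
#' @param youngsModulus Per-element E (MPa); defaults to
#'   [elementModuli()] under `law` and `factors`.
#' @param law,factors Used when `youngsModulus` is NULL.
#' @param nu Poisson's ratio (default 0.3).
#' @param load A [LoadCase-class].
#' @param frame An [AnatomicalFrame-class].
#' @return A [StrainField-class].
#' @export
assembleAndSolve <- function(mesh, youngsModulus = NULL,
                             law = defaultDensityModulusLaw(),
                             factors = regionFactors(), nu = 0.3,
                             load = loadCase(), frame) {
  stopifnot(is(mesh, "TetrahedralMesh"), is(load, "LoadCase"))
  validObject(load)
  if (is.null(youngsModulus)) youngsModulus <- elementModuli(mesh, law, factors)
  fixed <- nodeSet(mesh, "PROXIMAL_FIXED")
  if (!length(fixed))
    .stopInvalid("constraint-deficiency: empty PROXIMAL_FIXED set")
  fixedDofs <- as.vector(t(outer(3L * (fixed - 1L), 1:3, "+")))
  f <- .loadForces(mesh, load, frame)
  sol <- solveElasticity(mesh@nodes, mesh@tets, youngsModulus, nu,
                         fixedDofs, 0, f)
  es <- .elementStrains(mesh@nodes, mesh@tets, sol$u)
  new("StrainField", displacements = sol$u, elementStrain = es$strain,
      elementPrincipal = es$principal,
      surfaceMaxPrincipal = es$principal[mesh@boundary$owner, 1],
      reactions = sol$reactions)
}

#' Mean maximum principal strain over the PSG strip
#'
#' Area-weighted mean of the per-facet surface maximum principal strain
#' over the `PSG_STRIP` facets; the mean (rather than the absolute
#' maximum) is used to avoid single-element outliers.
#'
#' @param field A [StrainField-class].
#' @param mesh The [TetrahedralMesh-class] the field was solved on.
#' @return A [PSGStrainSummary-class].
#' @export
psgSummary <- function(field, mesh) {
  stopifnot(is(field, "StrainField"), is(mesh, "TetrahedralMesh"))
  idx <- facetSet(mesh, "PSG_STRIP")
  if (!length(idx))
    .stopInvalid("degenerate-geometry: empty PSG strip")
  a <- mesh@boundary$area[idx]
  s <- field@surfaceMaxPrincipal[idx]
  new("PSGStrainSummary", meanMaxPrincipal = sum(a * s) / sum(a),
      facetCount = length(idx), areaMm2 = sum(a))
}

#' Mesh convergence study of the PSG strain summary
#'
#' Rebuilds the mesh for each (fine, coarse) edge pair in the schedule,
#' solves the same load case, and reports the PSG summary and its
#' relative change versus the finest level.
#'
#' @param labels,image,curve,law Passed to [voxelsToTets()].
#' @param frame,psgPlane,loadPatchSpec Passed to [tagBoundarySets()].
#' @param load A [LoadCase-class].
#' @param factors [RegionFactors-class] for the material model.
#' @param edgeSchedule List of length-2 numeric vectors `(fine, coarse)`
#'   in mm, at least two entries, with edges non-increasing down the
#'   schedule (repeats allowed).
#' @param stripWidthMm Strip width passed to [tagBoundarySets()].
#' @return data.frame with columns `fine`, `coarse`, `nElements`,
#'   `psgMean`, `relChangeVsFinest`.
#' @export
convergenceStudy <- function(labels, image, curve = defaultCalibrationCurve(),
                             law = defaultDensityModulusLaw(),
                             frame, psgPlane, loadPatchSpec,
                             load = loadCase(), factors = regionFactors(),
                             edgeSchedule, stripWidthMm = 3) {
  if (length(edgeSchedule) < 2)
    .stopInvalid("invalid-input: schedule needs at least 2 entries")
  em <- do.call(rbind, edgeSchedule)
  if (any(diff(em[, 1]) > 1e-12) || any(diff(em[, 2]) > 1e-12))
    .stopInvalid("invalid-input: non-monotone schedule (edges must not ",
                 "increase)")
  res <- lapply(edgeSchedule, function(e) {
    mesh <- voxelsToTets(labels, image, curve, law,
                         fineEdgeMm = e[1], coarseEdgeMm = e[2])
    mesh <- tagBoundarySets(mesh, frame, psgPlane, stripWidthMm,
                            loadPatchSpec)
    fld <- assembleAndSolve(mesh, law = law, factors = factors,
                            load = load, frame = frame)
    c(nElements = nrow(mesh@tets),
      psgMean = psgMean(psgSummary(fld, mesh)))
  })
  tab <- do.call(rbind, res)
  finest <- tab[nrow(tab), "psgMean"]
  data.frame(fine = em[, 1], coarse = em[, 2],
             nElements = tab[, "nElements"], psgMean = tab[, "psgMean"],
             relChangeVsFinest = abs(tab[, "psgMean"] - finest) /
               abs(finest))
}
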