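# Shared fixtures, built once per test run and cached. Phantom specs are
# the package's reference study conditions; tests never alter them.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtureEnv[[name]]))
    assign(name, expr, envir = .fixtureEnv)
  .fixtureEnv[[name]]
}

# reference CTRL condyle phantom (no lysis, V_SCL target 0.185)
ctrlPhantom <- function() fixture("ctrlPhantom",
  makeCondylePhantom(condylePhantomSpec()))

# reference PSG-SBI condyle phantom: thick sclerotic cap holding a 1 mm
# focal lytic sphere
lyticSpec <- function() condylePhantomSpec(
  scleroticTargetFraction = 0.5, lysis = list(radiusMm = 1, hu = 600))

lyticPhantom <- function() fixture("lyticPhantom",
  makeCondylePhantom(lyticSpec()))

ctrlMesh <- function() fixture("ctrlMesh", meshPhantom(ctrlPhantom()))

lyticMesh <- function() fixture("lyticMesh", meshPhantom(lyticPhantom()))

# recovery cases: forward-generated "measured" targets with known factors
ctrlCaseOnGrid <- function() fixture("ctrlCaseOnGrid",
  makeRecoveryCase(condylePhantomSpec(), trueAScl = 0.25, trueDLys = 0,
                   id = "ctrl-ongrid"))

ctrlCaseOffGrid <- function() fixture("ctrlCaseOffGrid",
  makeRecoveryCase(condylePhantomSpec(), trueAScl = 0.275, trueDLys = 0,
                   id = "ctrl-offgrid"))

lyticCaseOnGrid <- function() fixture("lyticCaseOnGrid",
  makeRecoveryCase(lyticSpec(), trueAScl = 0.1, trueDLys = 0.8,
                   id = "sbi-ongrid"))

# three specimens whose "measured" targets equal the tuned-model forward
# predictions (adaptive factor from the default law, pooled damage 0.65)
validationSpecimens <- function() fixture("validationSpecimens", {
  base <- list(ctrlCaseOnGrid(), ctrlCaseOffGrid(), lyticCaseOnGrid())
  lapply(base, function(s) {
    fwd <- forwardEvaluator(s$mesh, s$frame, s$load)
    a <- asclFromVscl(s$vScl, defaultAsclLaw())
    d <- if (s$hasLysis) 0.65 else 0
    s$target <- fwd(aScl = a, dLys = d)
    s
  })
})

# uniform-HU rectangular bar meshed with Kuhn cells; for solver
# verification. dims in voxels, spacing in mm.
barMesh <- function(dims = c(4, 4, 20), spacing = 0.5, hu = 1000,
                    edge = 1) {
  code <- labelCodes()
  lab <- new("LabelVolume", labels = array(code[["TRABECULAR"]], dims),
             spacing = rep(spacing, 3), origin = c(0, 0, 0))
  img <- new("VoxelImage", values = array(hu, dims),
             spacing = rep(spacing, 3), origin = c(0, 0, 0))
  voxelsToTets(lab, img, fineEdgeMm = edge, coarseEdgeMm = edge)
}

# uniform uniaxial stress state via symmetry BCs + consistent traction;
# returns the solved strain tensors
solveUniaxial <- function(mesh, E = 1000, nu = 0, sigma = 10) {
  nodes <- meshNodes(mesh)
  tets <- meshTets(mesh)
  bd <- meshBoundary(mesh)
  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  fx <- which(abs(nodes[, 1] - min(nodes[, 1])) < 1e-9)
  fy <- which(abs(nodes[, 2] - min(nodes[, 2])) < 1e-9)
  fz <- which(abs(nodes[, 3] - zmin) < 1e-9)
  fixed <- c(3 * (fx - 1) + 1, 3 * (fy - 1) + 2, 3 * (fz - 1) + 3)
  top <- which(abs(bd$centroid[, 3] - zmax) < 1e-9)
  f <- matrix(0, nrow(nodes), 3)
  for (i in top) for (k in 1:3) {
    nd <- bd$facets[i, k]
    f[nd, 3] <- f[nd, 3] + sigma * bd$area[i] / 3
  }
  sol <- solveElasticity(nodes, tets, rep(E, nrow(tets)), nu, fixed,
                         0, f)
  c(sol, condyleFE:::.elementStrains(nodes, tets, sol$u))
}

# cylinder mask along a given unit axis, for frame-fitting tests
cylinderMask <- function(dims, spacing, centre, axis, radius, halfLen) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  pts <- sweep(sweep(idx - 1, 2, rep(spacing, 3), "*"), 2, centre, "-")
  t <- as.numeric(pts %*% axis)
  r2 <- rowSums(pts^2) - t^2
  array(abs(t) <= halfLen & r2 <= radius^2, dims)
}
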