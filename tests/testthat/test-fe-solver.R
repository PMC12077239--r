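# Finite-element verification: load direction, closed-form states,
# patch test, dense-solver oracle, equilibrium, strain summaries.

ctrlField <- function() fixture("ctrlField",
  assembleAndSolve(ctrlMesh(), load = loadCase(), frame = ctrlPhantom()$frame))

test_that("load direction follows the frontal/transverse angle convention", {
  fr <- ctrlPhantom()$frame  # identity-aligned frame
  d <- directionFromAngles(60, 30, fr)
  expect_equal(d, c(0, sin(60 * pi / 180), 0.5), tolerance = 1e-12)
  # 0 / 90 degrees is a pure long-axis push
  expect_equal(directionFromAngles(0, 90, fr), c(0, 0, 1),
               tolerance = 1e-12)
  expect_error(directionFromAngles(90, 30, fr), "infeasible-angles")
  # unit norm for arbitrary feasible angle pairs
  set.seed(5)
  for (i in 1:20) {
    af <- runif(1, 0, 60); at <- runif(1, 0, 30)
    expect_equal(sum(directionFromAngles(af, at, fr)^2), 1,
                 tolerance = 1e-12)
  }
})

test_that("homogeneous bar under uniaxial stress reproduces sigma over E", {
  m <- barMesh()
  out <- solveUniaxial(m, E = 1000, nu = 0, sigma = 10)
  expect_equal(range(out$strain[, 3]), c(0.01, 0.01), tolerance = 1e-8)
  expect_equal(max(abs(out$strain[, c(1, 2, 4, 5, 6)])), 0,
               tolerance = 1e-10)
  expect_equal(range(out$principal[, 1]), c(0.01, 0.01), tolerance = 1e-8)
})

test_that("Poisson contraction of a homogeneous cube is exact", {
  m <- barMesh(dims = c(6, 6, 6), spacing = 0.5, edge = 0.5)
  out <- solveUniaxial(m, E = 1000, nu = 0.3, sigma = 10)
  ratio <- out$strain[, 1] / out$strain[, 3]
  expect_equal(range(ratio), c(-0.3, -0.3), tolerance = 1e-6)
  expect_equal(range(out$strain[, 3]), rep(10 / 1000, 2), tolerance = 1e-8)
})

test_that("constant-strain patch test is exact on an irregular mesh", {
  m <- barMesh(dims = c(4, 4, 4), spacing = 1, edge = 2)
  nodes <- meshNodes(m)
  tets <- meshTets(m)
  # perturb interior nodes so elements are genuinely irregular
  bNodes <- sort(unique(as.vector(meshBoundary(m)$facets)))
  interior <- setdiff(seq_len(nrow(nodes)), bNodes)
  set.seed(9)
  nodes[interior, ] <- nodes[interior, ] +
    matrix(runif(3 * length(interior), -0.3, 0.3), ncol = 3)
  expect_true(all(tetVolumes(nodes, tets) > 0))
  # impose a linear displacement field on the whole boundary
  A <- matrix(c(1e-3, 4e-4, -2e-4,
                3e-4, -5e-4, 6e-4,
                -1e-4, 2e-4, 8e-4), 3, byrow = TRUE)
  uB <- nodes[bNodes, , drop = FALSE] %*% t(A)
  fixedDofs <- as.vector(t(outer(3 * (bNodes - 1), 1:3, "+")))
  sol <- solveElasticity(nodes, tets, rep(500, nrow(tets)), 0.3,
                         fixedDofs, as.vector(t(uB)),
                         matrix(0, nrow(nodes), 3))
  es <- condyleFE:::.elementStrains(nodes, tets, sol$u)
  sym <- (A + t(A)) / 2
  expected <- c(sym[1, 1], sym[2, 2], sym[3, 3], sym[1, 2], sym[2, 3],
                sym[1, 3])
  for (k in 1:6)
    expect_equal(range(es$strain[, k]), rep(expected[k], 2),
                 tolerance = 1e-10)
})

test_that("sparse solution matches an independent dense oracle", {
  m <- barMesh(dims = c(2, 2, 10), spacing = 0.5, edge = 0.5)
  nodes <- meshNodes(m); tets <- meshTets(m)
  expect_lte(3 * nrow(nodes), 500)
  E <- 800; nu <- 0.3
  # independent dense assembly: shape coefficients from a 4x4 solve,
  # B-matrix formulation with engineering shears
  n3 <- 3 * nrow(nodes)
  Kd <- matrix(0, n3, n3)
  G <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  D <- diag(c(rep(0, 3), rep(G, 3)))
  D[1:3, 1:3] <- matrix(lam, 3, 3) + 2 * G * diag(3)
  for (e in seq_len(nrow(tets))) {
    p <- nodes[tets[e, ], ]
    M <- cbind(1, p)
    C <- solve(M)          # rows: coefficients (const, x, y, z) per shape
    g <- t(C[2:4, ])       # node x gradient component
    V <- abs(det(M)) / 6
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      cidx <- 3 * (a - 1)
      B[1, cidx + 1] <- g[a, 1]
      B[2, cidx + 2] <- g[a, 2]
      B[3, cidx + 3] <- g[a, 3]
      B[4, cidx + 1] <- g[a, 2]; B[4, cidx + 2] <- g[a, 1]
      B[5, cidx + 2] <- g[a, 3]; B[5, cidx + 3] <- g[a, 2]
      B[6, cidx + 1] <- g[a, 3]; B[6, cidx + 3] <- g[a, 1]
    }
    ke <- V * t(B) %*% D %*% B
    dofs <- as.vector(t(outer(3 * (tets[e, ] - 1), 1:3, "+")))
    Kd[dofs, dofs] <- Kd[dofs, dofs] + ke
  }
  zmin <- min(nodes[, 3])
  fixedN <- which(abs(nodes[, 3] - zmin) < 1e-9)
  fixedDofs <- as.vector(t(outer(3 * (fixedN - 1), 1:3, "+")))
  set.seed(13)
  f <- matrix(0, nrow(nodes), 3)
  topN <- which(abs(nodes[, 3] - max(nodes[, 3])) < 1e-9)
  f[topN, ] <- matrix(runif(3 * length(topN), -5, 5), ncol = 3)
  fv <- as.vector(t(f))
  free <- setdiff(seq_len(n3), fixedDofs)
  uD <- numeric(n3)
  uD[free] <- solve(Kd[free, free], fv[free])
  sol <- solveElasticity(nodes, tets, rep(E, nrow(tets)), nu, fixedDofs,
                         0, f)
  expect_lt(max(abs(as.vector(t(sol$u)) - uD)),
            1e-8 * max(1, max(abs(uD))))
})

test_that("stiffness is symmetric and reactions balance the applied load", {
  m <- barMesh(dims = c(2, 2, 6), spacing = 0.5, edge = 0.5)
  nodes <- meshNodes(m); tets <- meshTets(m)
  K <- condyleFE:::.assembleStiffness(nodes, tets, rep(1000, nrow(tets)),
                                      0.3)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-9 * max(abs(K@x)))
  # equilibrium on the full condyle solve
  ph <- ctrlPhantom()
  fld <- ctrlField()
  dir <- directionFromAngles(60, 30, ph$frame)
  applied <- 7500 * dir
  resid <- colSums(fld@reactions) + applied
  expect_lt(max(abs(resid)), 1e-6 * 7500)
})

test_that("solution scales linearly with load and inversely with stiffness", {
  ph <- ctrlPhantom()
  mesh <- ctrlMesh()
  f1 <- ctrlField()
  f2 <- assembleAndSolve(mesh, load = loadCase(totalForce = 15000),
                         frame = ph$frame)
  expect_equal(psgMean(psgSummary(f2, mesh)),
               2 * psgMean(psgSummary(f1, mesh)), tolerance = 1e-9)
  eScaled <- 2 * elementModuli(mesh)
  f3 <- assembleAndSolve(mesh, youngsModulus = eScaled, load = loadCase(),
                         frame = ph$frame)
  expect_equal(psgMean(psgSummary(f3, mesh)),
               psgMean(psgSummary(f1, mesh)) / 2, tolerance = 1e-9)
})

test_that("principal strains match the eigendecomposition oracle", {
  set.seed(17)
  eps <- matrix(rnorm(6 * 200, sd = 0.01), ncol = 6)
  vals <- condyleFE:::.principalValues(eps)
  for (k in sample(200, 25)) {
    S <- matrix(c(eps[k, 1], eps[k, 4], eps[k, 6],
                  eps[k, 4], eps[k, 2], eps[k, 5],
                  eps[k, 6], eps[k, 5], eps[k, 3]), 3)
    expect_equal(vals[k, ], eigen(S, symmetric = TRUE)$values,
                 tolerance = 1e-9)
    expect_true(all(diff(vals[k, ]) <= 0))
  }
  # isotropic tensors collapse to the mean strain
  iso <- condyleFE:::.principalValues(cbind(0.02, 0.02, 0.02, 0, 0, 0))
  expect_equal(as.numeric(iso), rep(0.02, 3), tolerance = 1e-12)
})

test_that("PSG summary is the area-weighted strip mean", {
  mesh <- ctrlMesh()
  nf <- nrow(meshBoundary(mesh)$facets)
  m <- nrow(meshTets(mesh))
  uniform <- new("StrainField",
                 displacements = matrix(0, nrow(meshNodes(mesh)), 3),
                 elementStrain = matrix(0, m, 6),
                 elementPrincipal = matrix(0, m, 3),
                 surfaceMaxPrincipal = rep(0.01, nf),
                 reactions = matrix(0, nrow(meshNodes(mesh)), 3))
  s <- psgSummary(uniform, mesh)
  expect_equal(psgMean(s), 0.01, tolerance = 1e-15)
  expect_equal(s@facetCount, length(facetSet(mesh, "PSG_STRIP")))
})

test_that("a focal lytic inclusion raises the strip strain", {
  # same geometry and cap, with and without the low-density pocket
  noLys <- fixture("noLysPhantom",
    makeCondylePhantom(condylePhantomSpec(scleroticTargetFraction = 0.5)))
  mNo <- fixture("noLysMesh", meshPhantom(noLys))
  sNo <- forwardEvaluator(mNo, noLys$frame)(0, 0)
  sLys <- forwardEvaluator(lyticMesh(), lyticPhantom()$frame)(0, 0)
  expect_gt(sLys, sNo)
})

test_that("convergence schedule validation and the repeat fixed point", {
  ph <- ctrlPhantom()
  expect_error(
    convergenceStudy(ph$labels, ph$image, frame = ph$frame,
                     psgPlane = ph$psgPlane,
                     loadPatchSpec = ph$loadPatchSpec,
                     edgeSchedule = list(c(1, 1))), "invalid-input")
  expect_error(
    convergenceStudy(ph$labels, ph$image, frame = ph$frame,
                     psgPlane = ph$psgPlane,
                     loadPatchSpec = ph$loadPatchSpec,
                     edgeSchedule = list(c(0.5, 0.5), c(1, 1))),
    "invalid-input")
  tab <- convergenceStudy(ph$labels, ph$image, frame = ph$frame,
                          psgPlane = ph$psgPlane,
                          loadPatchSpec = ph$loadPatchSpec,
                          edgeSchedule = list(c(1, 1), c(1, 1)))
  expect_equal(tab$relChangeVsFinest, c(0, 0), tolerance = 1e-12)
})
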