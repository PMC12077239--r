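---
title: "Virtual mechanical testing of the equine distal MC3: models and methods"
author: "condyleFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual mechanical testing of the equine distal MC3: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condyleFE)
```

## The problem

Condylar stress fracture of the third metacarpal bone (MC3) is the
leading fatigue injury of the Thoroughbred racehorse fetlock. The
fracture initiates in the parasagittal grooves (PSG) of the distal
condyle, where cyclic loading produces dense subchondral sclerosis and,
in some limbs, focal osteolysis (PSG subchondral bone injury, PSG-SBI)
visible on standing CT. `condyleFE` implements a subject-specific
finite-element pipeline that converts a calibrated CT volume of the
distal MC3 into a prediction of the load-induced surface strain in the
PSG, the quantity that ex vivo studies measure with digital image
correlation and that correlates with fracture risk.

The pipeline has five stages: density calibration, region labelling,
voxel-based tetrahedral meshing, a linear elastic solve of the standard
condylar load case, and extraction of the mean maximum principal strain
over a 3 mm strip centred on the groove. Around this forward model sit
an inverse layer (grid-search tuning of two material factors against
measured strains) and a validation layer (tuned versus non-tuned
prediction statistics).

## Density and modulus model

CT numbers are converted to radiological (hydroxyapatite-equivalent)
density through an affine calibration fitted by ordinary least squares
to a four-plug HA phantom (200, 800, 1250, 1750 mgHA/cm^3):

$$\rho_{CT} = (\mathrm{HU} - 93.0710) / 1.0123 \quad [\mathrm{mgHA\,cm^{-3}}]$$

Radiological density converts to ash density (both in g/cm^3) by
$\rho_{ash} = 0.8772\,\rho_{CT} + 0.07895$, and ash density to Young's
modulus by the power law $E = 3378\,\rho_{ash}^{1.52}$ MPa. Units are a
consistent N–mm–MPa system; densities are carried internally in g/cm^3
with an explicit divide-by-1000 when leaving the calibration stage
(`huToModulus()` performs the whole chain).

Two numerical guards are deliberate package choices:

* **Density floor.** Calibrated densities at or below zero (air or
  marrow voxels swept into the mesh) are clamped to 0.01 g/cm^3 before
  the power law, giving those elements a small positive modulus
  (≈3 MPa) instead of a non-physical zero or negative stiffness.
* **Clamped adaptive-factor law.** The calibrated law
  $A_{SCL} = 994.23\,V_{SCL} - 184.55$ is extraordinarily steep: the
  output traverses its whole admissible range over a change of only
  ≈0.0015 in $V_{SCL}$. The implementation therefore clamps the output
  to $[-1.00, 0.50]$ unconditionally and exposes both coefficients as
  configuration, because plausible volumes fractions outside a narrow
  band always saturate the clamp.

### Region factors

Trabecular voxels above 1500 HU (equivalent to 1390 mgHA/cm^3 under
the default calibration) are labelled sclerotic (SCL); isolated focal
pockets below 1500 HU inside the declared PSG search region are
labelled lytic (LYS). The modulus in these regions is rescaled:

$$E_{SCL} = (1 - A_{SCL})\,E, \qquad E_{LYS} = (1 - D_{LYS})\,E$$

with the adaptive factor $A_{SCL} \in [-1.00, 0.50]$ (negative values
stiffen, modelling adapted dense bone; positive values soften,
modelling microdamage not resolved by clinical CT) and the damage
factor $D_{LYS} \in [0.50, 0.95]$ on the tuning grid ($D_{LYS} = 0$
denotes the non-tuned model). The non-tuned baseline is exactly
`regionFactors(0, 0)`.

The labelling rule needs three operational decisions the clinical
description leaves open; the package fixes them as follows and exposes
each as a parameter: lysis components are 26-connected; components
smaller than 8 voxels are treated as noise speckle; and "isolated"
means every face-neighbour outside the component is bone at or above
the threshold. Cortex/trabecular separation is taken from a supplied
mask (emitted by the phantom generator; user-provided for real data),
since gradient-based cortical segmentation is out of scope.

## Meshing

Bone voxels are grouped into axis-aligned cells — fine (default
0.5 mm) inside the bounding box of the SCL/LYS labels plus a one-cell
margin, coarse (default 1 mm) elsewhere — and each cell is
tetrahedralized:

* **Uniform meshes** (equal edges) use the 6-tet Kuhn/Freudenthal
  decomposition, which tiles space conformingly when all cells share
  the same diagonal orientation.
* **Mixed meshes** use a one-level 2:1 cell-centre scheme: every cell
  receives a centre node, every quad face is triangulated by a
  canonical corner diagonal (subdivided 2×2 first when the neighbour
  across the face is finer), and each face triangle forms a
  tetrahedron with the cell centre. Because a shared face is
  triangulated identically from both sides, every interior facet is
  shared by exactly two tets. At jagged fine/coarse interface corners
  an edge-hanging node can remain; this mild non-conformity does not
  affect the facet conformity invariant and sits away from the distal
  strip where strains are read. This scheme was chosen over a graded
  octree because it is deterministic, template-free, and exact in
  volume.

A cell is kept when at least half of its voxels are bone, so meshing at
the voxel pitch reproduces the voxelized bone volume exactly. Element
ash density is the mean calibrated density of the cell's bone voxels
(element-wise material assignment, not nodal interpolation); the
element region is the majority label with ties resolved LYS over SCL
over the rest, so a lesion is never diluted away by a tie.

The default phantom meshes (0.5/1 mm) resolve the 1 mm lytic sphere
with fine cells. A convergence study over the uniform schedule
2 mm → 1 mm → 0.5 mm is part of the acceptance suite; the strip-mean
strain changes by well under 5% between the two finest levels on the
reference phantom, which is the package's criterion for adequate mesh
density. The same study is available for any input through
`convergenceStudy()`.

## Load case and solver

The ex vivo protocol is replicated as a 7.5 kN load applied to the
palmar surface of the medial condyle at 60° to the frontal plane and
30° to the transverse plane, i.e. direction

$$\mathbf{d} = \sin 60^{\circ}\,\hat{\mathbf{n}}_{frontal}
            + \sin 30^{\circ}\,\hat{\mathbf{n}}_{transverse}
            + \sqrt{1 - \sin^2 60^\circ - \sin^2 30^\circ}\;\hat{\mathbf{n}}_{sagittal},$$

which at the default angles lies exactly in the sagittal plane and
pushes the palmar patch dorsally and proximally. The load is divided
equally over the load-surface nodes ("uniformly distributed as nodal
forces" taken literally); an area-weighted (tributary area) mode is
available and is what the verification tests use when they need an
exactly uniform traction. The proximal end is fully constrained over a
one-coarse-edge slab.

Elements are linear (constant-strain) tetrahedra with isotropic
elasticity, Poisson's ratio 0.3, and per-element modulus from the
density chain. The global stiffness is assembled in closed form from
the shape-function gradients and solved by sparse supernodal Cholesky
factorization; the solve is deterministic. Tensile strain is positive,
and "maximum principal strain" is the algebraically largest eigenvalue
of the element strain tensor, matching surface-tension reporting in
DIC experiments. Surface values are the owner-element values with no
nodal averaging, because the quantity of interest is a strip mean, not
a point value.

The PSG summary is the area-weighted mean of the per-facet maximum
principal strain over the strip facets (centroid within half the strip
width, 3 mm by default, of the groove plane, restricted to the
condyle). The mean is used instead of the absolute maximum to avoid
single-element outliers.

## Tuning and validation

`tuneAscl()` and `tuneDlys()` are exhaustive, deterministic grid
searches: 31 candidates from −1.00 to 0.50 (step 0.05) for the
adaptive factor, 10 candidates from 0.50 to 0.95 for the damage
factor, both endpoints inclusive. The objective is the raw distance
`|predicted − target|` on strip-mean strains, with ties broken toward
the smallest-magnitude factor (the least departure from the
unmodified law) and recorded in the result. Per-candidate forward
solves reuse the mesh and exploit the linearity of the stiffness in
the per-element modulus,

$$K(A_{SCL}, D_{LYS}) = K_{plain} + (1 - A_{SCL})\,K_{SCL}
                        + (1 - D_{LYS})\,K_{LYS},$$

so one specimen costs three assemblies plus one factorization per
candidate (`forwardEvaluator()`), a pure material update with no
remeshing.

`fitAsclLaw()` regresses optimal adaptive factors on sclerotic volume
fraction ($V_{SCL}$ = sclerotic volume / condyle volume) by OLS;
`poolDlys()` averages damage optima when too few lytic specimens exist
for a regression. `validateSpecimens()` reports per-specimen absolute
differences, the OLS slope/intercept of predicted on measured strain,
R² as the squared Pearson correlation, and the mean relative error
(reported as a percentage); below three specimens the regression is
skipped with a warning rather than fabricated.

## The synthetic phantoms: what they do and do not show

All tests run on synthetic data built by the package itself:

* `makeCalibrationPhantom()` rasterizes the four HA plugs with
  forward-mapped CT numbers plus optional Gaussian noise, so the
  calibration fit has an exact known truth.
* `makeCondylePhantom()` rasterizes an idealized bone: a cylindrical
  shaft (cut proximally) merged with a spherical condyle, a 1 mm
  cortical shell at 2000 HU, trabecular interior at 900 HU, a distal
  subchondral cap at 1800 HU sized by bisection to hit a requested
  sclerotic volume fraction to within voxel quantization, and
  optionally a spherical 600 HU lytic pocket centred on the groove
  plane inside the cap (kept one voxel clear of sub-threshold bone so
  the pocket is genuinely isolated). The generator emits every ground
  truth the pipeline needs — labels, masks, anatomical frame and
  landmarks, groove plane, load patch — so segmentation, frame
  fitting and set tagging can each be checked against truth.
* `makeRecoveryCase()` closes the loop: it runs the forward model with
  known true factors and stores the resulting strip strain as the
  synthetic "measured" target, enabling exact parameter-recovery
  tests (on-grid truths must be recovered exactly; off-grid truths to
  within one 0.05 grid step).

The reference study conditions are fixed: the control phantom uses a
sclerotic target fraction of 0.185 at 0.5 mm spacing, and the lytic
phantom a 0.5 fraction (a thicker cap, needed to contain the 1 mm
pocket with its isolation margin). Phantom volumes are a few tens of
voxels per side so that a full tune-and-validate run, including the
31 + 10 candidate solves, completes in minutes on a single core; the
mesh convergence study justifies the default edges at this scale.

These phantoms validate the *equations and procedures* — calibration
algebra, labelling rules, meshing conservation and conformity, solver
correctness against closed-form and dense oracles, recovery of
generating factors. They deliberately do not emulate condylar anatomy,
partial-volume blur, beam hardening, scanner noise statistics, or the
heterogeneity of real subchondral bone, so passing tests demonstrate
implementation correctness, not clinical accuracy. Reproducing the
published per-specimen validation statistics would require the
original standing-CT and ex vivo strain data, which the package does
not ship.

## Degenerate inputs and edge behaviour

Calibration requires at least two plugs with strictly increasing
densities and errors on zero density variance. Erosion to an empty
mask, empty named boundary sets, a zero strip width, and
non-commensurate mesh edges are all hard errors rather than silent
degradation. Frame fitting refuses near-isotropic point clouds
(principal extent ratio below 1.5). The convergence schedule must be
non-increasing; repeated identical entries are allowed and report a
relative change of zero. Grid searches propagate forward-solve
failures with the candidate attached.

## Known limitations

* Linear elasticity only: no yield, post-yield, fatigue-life or
  fracture-propagation modelling, and no contact with the proximal
  phalanx or sesamoids.
* The mixed-mesh transition is one-level (2:1); meshing a 0.25/1 mm
  pair requires an intermediate schedule step.
* The sagittal orientation comes from user/phantom landmarks; the
  package does not detect the sagittal ridge.
* Homogeneous factors per region: microdamage gradients towards the
  joint surface are not representable at clinical CT resolution.
* The steep adaptive-factor law saturates its clamp outside a narrow
  band of sclerotic volume fractions; users fitting their own law
  should inspect `fitAsclLaw()` coefficients before relying on the
  default.

## A minimal session

```{r example, eval = FALSE}
library(condyleFE)

# a PSG-SBI-class phantom and its forward "measured" strain at known
# factors
case <- makeRecoveryCase(
  condylePhantomSpec(scleroticTargetFraction = 0.5,
                     lysis = list(radiusMm = 1, hu = 600)),
  trueAScl = 0.1, trueDLys = 0.8, id = "sbi-1")

# recover the damage factor by grid search
grid <- tuneDlys(case, aScl = 0.1)
optimum(grid)        # 0.8

# tuned-vs-untuned comparison under the pooled damage factor
fwd <- forwardEvaluator(case$mesh, case$frame)
fwd(aScl = 0, dLys = 0)                               # non-tuned
fwd(aScl = asclFromVscl(case$vScl), dLys = 0.65)      # tuned
```
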