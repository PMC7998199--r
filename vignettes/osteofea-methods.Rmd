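---
title: "Methods: QCT densitometry, material mapping and vertebral failure simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QCT densitometry, material mapping and vertebral failure simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteofea)
```

# Overview

`osteofea` implements the analysis chain used in image-based vertebral
strength research: calibrated volumetric bone mineral density (vBMD) from
CT attenuation, attenuation-driven material mapping, displacement-controlled
finite-element (FE) compression of single vertebrae and of functional spinal
units (FSUs: vertebra–disc–vertebra stacks), failure-load extraction from
the load–displacement curve, and partial-correlation statistics between a
fracture-prone segment and the lumbar reference levels. Since clinical scans
cannot be redistributed, a synthetic phantom generator with analytic ground
truth is a first-class component: it is how every stage of the chain is
verified.

# Densitometry

The region of interest (ROI) for a vertebral body is deterministic: the
mid-sagittal slice closest to the trabecular label's centroid, the anterior
half of the anterior–posterior extent, and the central fraction of the body
height. The height fraction defaults to 2/3; manual clinical protocols say
"approximately two-thirds", and a fixed value (with a config override) is
the only reproducible reading. The ROI is a rectangle intersected with the
trabecular label so shell voxels never contaminate the mean.

Calibration is the two-point phantom line
`BMD_MDCT = HAb/(HUb − HUw) · (HU − HUw)` with the water and bone
compartments at 0 and 200 mg/mL hydroxyapatite; the scanner-level conversion
`BMD_QCT = 0.69 · BMD_MDCT − 11` mg/mL is applied afterwards. Both maps are
affine and are inverted exactly by `hu_from_bmd()`/`mdct_from_qct()`, which
is what the phantom generator uses to render a target density — in the
noiseless limit the densitometry round trip is exact to floating precision,
and the test suite asserts recovery of a 100 mg/mL target to 1e-6. Negative
`BMD_QCT` values are possible at very low attenuation and are returned
unfloored: the conversion is reported as printed, not clamped.

The adjustment covariate of the cohort statistics is the ratio of the mean
vBMD of the fractured vertebra and its two neighbours to the mean vBMD of
L1–L3, which absorbs the axial heterogeneity of spinal density.

# Material mapping

Bone properties derive from element attenuation through
`ρ_app = 47 + 1.122·HU` (kg/m³) and `ρ_ash = 0.6·ρ_app`. Elasticity is
transversely isotropic about the cranio-caudal axis with
`E_z = −349 + 5.82·ρ_app` (MPa) and fixed ratios for the transverse moduli,
shear moduli and Poisson numbers; consequently every bone element's
stiffness is `E_z` times one unit tensor, which the solver exploits.

Three numerical decisions deserve emphasis:

* **Units of the strength laws.** The strength and plastic-strain laws are
  evaluated with ash density in g/cm³. The branch threshold 0.317 and the
  coefficients (137, 114, 65.1, 0.0728) are only dimensionally sensible on
  that scale, although the density mappings themselves are stated in kg/m³;
  `material_cards()` performs the division by 1000 internally and exposes
  both columns.
* **Modulus floor.** `E_z` turns non-positive below roughly 12 HU. A floor
  (default 0.01 MPa) keeps every element's stiffness positive definite
  without adding meaningful load-bearing capacity. The same floor is the
  post-failure stiffness of collapsed elements.
* **Branch tie-break.** At exactly `ρ_ash = 0.317` the high-density branch
  is used; the branches differ by well under 0.1 MPa there, and the suite
  checks this near-continuity.

The Poisson ratios are interpreted in the engineering-constants convention
of the commercial solver tradition this mapping comes from
(`S_ij = −ν_ij/E_i`, load axis first); with `E_x = 0.333·E_z` and
`ν_xz = 0.104` the compliance is symmetric and positive definite, which the
suite verifies by eigendecomposition across the realistic density range.

Disc tissue is isotropic and linear — annulus `(E, ν) = (500 MPa, 0.3)`,
nucleus `(1 MPa, 0.475)` — with no strength limits, as no disc failure
constants are part of the mapping.

Element attenuation sampling: structured voxel meshes give each tetrahedron
exactly one parent voxel, whose center is geometrically contained in it
(inclusive faces), so the "mean of contained voxel centers" rule reduces to
the parent voxel value; for general meshes the same rule is applied
literally, with trilinear interpolation at the centroid as fallback for
slivers containing no center.

# Meshing

Label volumes are meshed by decomposing every labelled voxel into six
tetrahedra (the Kuhn decomposition about the voxel's main diagonal). The
scheme is translation-invariant, so adjacent voxels — and adjacent regions
such as a vertebral endplate and the disc above it — triangulate their
shared faces identically, and region meshes conform node-for-node. That is
what makes tie constraints implementable as exact node
merging, with a counting identity (merged nodes = Σ region nodes − interface
duplicates) that the tests assert. Mesh volume equals labelled voxel volume
identically, all element volumes are positive, and all elements are
congruent, so quality metrics are uniform by construction. Smoothed surface
meshing of the kind produced by commercial segmentation suites is
deliberately out of scope; the structured mesh is deterministic,
dependency-free and conforming, at the cost of a stair-stepped surface.

# Finite-element solution

C3D4 (linear tetrahedral) elements, small strains. The inferior surface of
the (bottom) vertebra is fully fixed; the superior surface of the (top)
vertebra has its axial displacement prescribed with transverse components
free — "normal displacement loading" prescribes the normal component only,
and leaving the transverse DOFs free avoids artificial confinement.
Posterior elements are rendered and labelled in the images but not included
in the structural models: the no-penetration contact they would require is
out of scope, and the compressive load path runs through body and disc.

Bone nonlinearity is a principal-stress criterion taken directly from the
material card: an element yields when its maximum principal stress exceeds
`σ_max` (tension) or its minimum principal stress drops below `−σ_min`
(compression). Yield is realised by secant reduction — the element's
stiffness scale is pulled back so the stress sits on the limit surface,
i.e. elastic–perfectly-plastic behaviour. The accumulated post-yield strain
(largest absolute principal strain beyond its value at first yield) is
compared against the plastic capacity `ε_AB`; beyond it, the element fails
and its modulus collapses to the floor. Element failure is what produces
softening and hence a load peak. Discs stay linear.

Numerical scheme and defaults:

* The displacement is ramped in equal increments (`load_program()`, ≥ 20
  recommended; the default subject analysis uses an applied displacement of
  1.5 % of model height over 20 increments — vertebral failure strains sit
  near 1 %, so the ramp reliably passes the peak).
* Inside each increment the secant state is iterated to self-consistency
  (cap 50); an element state is accepted when its stress is within 0.1 %
  of the limit surface (`tol_yield = 1e-3`). The linear solves themselves
  are direct sparse Cholesky factorizations (CHOLMOD via `Matrix`), exact
  to machine precision and bit-reproducible — there is no randomized
  preconditioning, so identical models give identical curves.
* Once the reaction has collapsed below 10 % of the running peak
  (`stop_ratio`), further increments are skipped: after structural collapse
  the trace only stretches floor-stiffness elements.
* The reaction force is the sum of axial nodal forces over the driven set;
  each increment's global balance (fixed + driven axial reactions) is
  monitored and exposed as the `force_balance` attribute, asserted below
  1e-6 relative in the tests.

Verification uses a homogeneous isotropic cuboid under axial compression:
with ν = 0 the uniform-strain solution `F = E·A·u/L` is representable by
linear tetrahedra, so the solver reproduces it to machine precision at any
mesh size (the acceptance suite asserts 1 % at 1 mm voxels and 2 % after a
refinement halving, both trivially met), plus exact linearity in the
modulus and a two-region merged stack matching a monolithic block.

# Synthetic phantoms and cohorts

A phantom subject is a stack of elliptic-cylinder vertebral bodies (cortical
shell + trabecular core, optional simplified posterior arch) separated by
discs whose annulus is the body cross-section minus a central nucleus
cylinder; two cylindrical calibration inserts (water- and bone-equivalent)
run posterior to the stack. Attenuation is piecewise constant plus additive
white Gaussian noise — the simplest model consistent with CT quantum noise —
and every solid is analytic, so labelled volumes are testable against
closed-form volumes to a one-voxel surface shell.

Default appearance (chosen as typical clinical values, since trabecular and
cortical levels are scanner-dependent and not part of the mapping): 120 HU
trabecular, 600 HU cortical, 60 HU disc, −50 HU background, 10 HU noise SD,
calibration compartments at 0/400 HU. The cohort generator draws per-subject
(lumbar, fracture-site) QCT-scale densities from a bivariate normal —
defaults 65 ± 12 mg/mL, matching an elderly osteoporotic cohort — with a
configurable cross-correlation, plus an independent factor (scaled by
`covariate_effect`) perturbing the fracture-site density, which creates the
between-subject variation in the fracture/lumbar BMD ratio that the
partial-correlation analysis adjusts for. Each rendered subject is a
6-vertebra stack: vertebrae 1–3 are L1–L3, vertebrae 4–6 the fracture-site
segment centred on the fractured level, mirroring cohorts in which the
fracture may sit anywhere along the thoracolumbar spine.

What the phantoms do *not* emulate: patient anatomy (curvature, endplate
concavity, pedicle geometry), trabecular microarchitecture and fabric
anisotropy, contrast-agent dynamics, scanner reconstruction kernels, and
fracture morphology. Passing tests therefore demonstrate correctness of the
computational chain — calibration algebra, meshing, assembly, constitutive
updates, statistics — not clinical validity on real scans.

# Statistics

`partial_correlation()` residualises both variables on the covariate by
ordinary least squares with intercept and correlates the residuals;
`df = n − 3`, two-sided p from the t transform. The implementation is
cross-checked in the tests against the closed-form three-variable recursion
`r_xy·z = (r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²))` to 1e-10 on random
fixtures, and its operating characteristics are verified by simulation:
Fisher-z 95 % coverage of a built-in partial correlation of 0.8 across 200
cohorts of n = 200, and null type-I error within [0.03, 0.07] at α = 0.05.
Two-sided tests and a 0.05 threshold are used throughout, with no
multiple-testing correction across the four panel correlations, matching
common practice for a four-outcome exploratory panel. Subjects failing any
pipeline stage are dropped from the cohort table (with the cause logged)
before the panel is computed.

# Verification problem sizes

The package's own test and verification runs use compact phantoms — 2 mm
voxels, 8 × 6 mm half-axes, 10 mm bodies, 4 mm discs — giving about 1100
tetrahedra per vertebra and 4100 per FSU, which keeps the full verification
battery (including a five-level density-monotonicity sweep of 25 FE solves
and two complete cohort runs for byte-level determinism) in the minutes
range on a single core. The generator scales to clinically sized phantoms
(about 1 mm voxels, 15 × 11 mm half-axes) at proportionally higher cost;
the FE solver has been exercised to ~30k tetrahedra.

# Known limitations

* Small-strain kinematics; no geometric nonlinearity at the collapse stage.
* Ligaments, facet joints and posterior-element contact are absent; single
  load case (axial compression).
* The secant plasticity is a simplified realisation of
  elastic–perfectly-plastic flow — no return mapping on a full yield
  surface, no unloading path memory beyond the secant scale.
* Structured voxel meshes have stair-stepped surfaces; stress concentrations
  at surface steps are not representative of smoothed-geometry models.
* Cohort-level clinical quantities (mean failure loads of a patient
  population, observed correlation coefficients) depend on patient data and
  are out of the package's reach; the statistics layer is validated by
  parameter recovery on synthetic cohorts instead.
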