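---
title: "Methods: synthetic cohort, shape-appearance model and elastic-foundation contact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohort, shape-appearance model and elastic-foundation contact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(varusknee)
```

This vignette is the package's account of its science: what each stage
models, which parameters matter, the numerical choices, and what the
synthetic study can and cannot say about real specimens.

## The study reproduced by `run_study()`

The pipeline mirrors a specimen-based varus-loading study of the rat
tibiofemoral joint in a meniscus-deficient configuration: ten hind limbs
from five animals (bilateral, left limbs mirrored to right-side
representation), a PCA-based statistical shape and appearance model (SSAM)
validated leave-one-out at the limb level, and contact analyses at 80°
flexion under a 2.94 N axial load with varus applied either as a prescribed
load redistribution (0/50/100 %) or as a prescribed femoral angulation
(0/3/6°, the experimental equivalences of those levels).  Knee-level
records of peak contact pressure and contact area per compartment feed
Shapiro–Wilk, one-way ANOVA and Tukey HSD comparisons and the summary
tables.

Two stages of the original workflow cannot be reproduced from data — the
micro-CT specimens and the commercial finite-element solve — and are
replaced by surrogates that are fully specified here: a parametric
synthetic cohort and an elastic-foundation contact model.  Everything that
*is* specified by the study design (material constants, loads, poses,
cohort layout, mesh resolution targets, the ±3 SD / 20-resample scheme,
the statistics) is consumed verbatim.

## Synthetic cohort geometry

All limbs are deformations of one template grid, so vertex-wise
correspondence holds by construction; this replaces deformable mesh
registration, which would be meaningless for meshes that never disagree in
topology.  The articular design has three deliberate features:

* **Conforming-but-nonconforming articulation.**  The femoral condylar
  region is a spherical sheet (radius `joint_radius` = 6 mm) about the
  epicondylar axis, carrying two quadric condylar caps whose surfaces
  recede from the sphere as `s²/(2·conformity_radius)` (`s` = arc distance
  from the cap centre, centres ±`condyle_offset` = 2.2 mm).  The tibial
  plateau is a nearly concentric spherical dish.  The local gap between the
  outer cartilage surfaces is therefore a shallow paraboloid of curvature
  radius `conformity_radius`, which makes closed-form contact predictions
  possible and matches the high congruence of articular surfaces.
* **Rotation–sliding decoupling.**  Because both articular surfaces are
  nearly concentric spheres about the epicondylar origin, rotating the
  femur (flexion about X, varus about Y) slides it *along* the dish instead
  of digging an edge into it, preserving bicompartmental contact across the
  tested varus range — a property the real joint owes to its congruence and
  soft tissues.  The condylar caps are generated at sagittal position
  −`flexion_design` (80°) so that posing the extended femur at standing
  flexion brings them over the plateau.
* **Varus engagement through a frontal-centre drop.**  The tibial dish
  centre sits `plateau_drop` ≈ 13 µm below the rotation origin.  Under a
  varus rotation θ this eccentricity translates the femur medially by
  `plateau_drop·θ`, deepening medial engagement and relieving the lateral
  compartment — the mechanism that converts angulation into load
  redistribution.  Its small magnitude is set by the micrometre scale of
  cartilage compression in the foundation model.

Shafts are cylinders carrying a cortical density plateau (1.2 g/cm³)
blending to trabecular values (0.6 g/cm³) at the epiphysis, with
animal-level multiplicative variation; the patella (0.2 mm mesh target) is
carried through the shape model but never loaded.  Landmarks
(epicondyles, plateau centre and normal reference) are defined as affine
combinations of template vertices, so reconstructed specimens transport
them consistently; ligament attachments are template vertex indices.

**Nominal dimensions as a design calibration.**  No geometric dimensions of
the original specimens are available, so the nominal articular dimensions
were calibrated once, as part of the package design, so the nominal
specimen reproduces specimen-scale contact areas under the standard load:
at 6° varus the medial/lateral contact areas are 8.27/5.27 mm²
(`conformity_radius` = 483 mm sets the magnitude, `plateau_drop` = 13 µm
the medial/lateral ratio).  These defaults were then frozen.
`calibrate_nominal_geometry()` exposes the same idea at run time: a 1-D
root-find on a uniform scale factor to a target medial area, with a local
bracket search because the angle-mode response is not monotone over large
scale ranges (the engagement and footprint-slide effects scale
differently).

**Variation model.**  Between-animal and within-animal (left–right)
variation are relative SDs on size (2 % / 0.5 %), condylar offset,
conformity radius (5 % / 1.5 %), plateau drop and density levels, plus a
random rigid acquisition pose (1.5°, 0.2 mm) that the Procrustes stage must
remove.  These are choices of the package (single-age, single-sex inbred
animals are geometrically homogeneous); conformity is parameterized
*directly* rather than through independent radii, because articular
congruence is developmentally co-adapted and independent perturbation of
two nearly equal radii would produce anatomically implausible clearances.

**Ligament slack.**  Reference lengths are set from the standing pose with
a 20 % recruitment margin, so the tension-only springs are disengaged
within the tested 0–6° varus range and compartment loads are
contact-dominated; the spring law itself (slack length
`L0 = (1−pretension)·L_ref`, force `k·max(0, L − L0)`) is implemented and
verified in full, and the angle-mode force balance includes the vertical
ligament components whenever they engage.  The pretension convention
(reference-pose engineering strain) is the simplest strain-based reading of
a stated pretension percentage.

## The elastic-foundation solver

The contact model is the standard desk-scale surrogate for thin cartilage
on rigid bone: local pressure proportional to local layer compression,

    p_i = (E_f / t) · max(0, u − g_i),   E_f = E(1−ν)/((1+ν)(1−2ν)),

with `t` = 0.5 mm (two 0.25 mm layers in series), `E_f` ≈ 102.68 MPa from
E = 6 MPa and ν = 0.49, `g_i` the initial gap of tibial element `i`
measured along the joint Z axis between the outer cartilage surfaces (each
bone mesh offset outward along its vertex normals by its layer thickness),
and `u` the rigid femoral approach.  This replaces the continuum
finite-element solve and is the package's single largest modelling
substitution; in exchange it is exactly verifiable against the closed form
for a sphere on a flat foundation (`F = π·E_f·R·u²/t`, area `2πRu`, peak
`E_f·u/t`), which the test suite checks to within 2 % at 0.05 mm elements
(`sphere_plane_specimen()`).

Numerical choices:

* Gaps are evaluated at tibial cartilage element centroids; the femoral
  offset surface is interpolated barycentrically over its triangles in the
  plateau projection.  Force integration uses projected element areas
  (small-slope approximation, with the contact normal taken as the JCS Z
  axis); reported contact areas are true element areas.
* The articular sheets are meshed at 0.1 mm (femur) / 0.15 mm (tibia)
  although the average bone mesh target is the study's 0.3 mm: cartilage
  compressions are only a few micrometres, and the piecewise-linear chord
  error of a 0.3 mm mesh on these curvatures (≈2 µm) would be of the same
  order.  Contact-region refinement is standard practice; the coarser
  average target applies to the shafts.
* Equilibrium is found by bisection on a geometrically grown bracket,
  force tolerance 1e-6 N, at most 200 iterations; F(u) is continuous,
  piecewise-linear and monotone, so bisection cannot fail on a valid
  bracket.  Peak-pressure ties break at the lowest element index.
* The pinball radius (0.1 mm) is the candidate-set gap cutoff; elements
  farther than it from the opposing surface are excluded from the search,
  preventing spurious far-field candidates.  Negative gaps (initial
  interpenetration) are legal inputs and reported as such.
* Fraction mode prescribes per-compartment forces
  (even split at neutral; 1.5×/0.5× at 50 %; all-medial at 100 %) and
  solves the compartments independently, so the force-conservation
  invariant holds by construction and the lateral compartment at 100 % is
  *exactly* unloaded (zero pressure, zero area).  Angle mode rotates the
  rigid femur and solves a single vertical translation against the total
  load including vertical ligament components; compartment forces emerge
  from geometry, and the lateral compartment retains reduced contact.  The
  two modes bracket the published descriptions, which report an unloaded
  lateral compartment in the loading protocol yet nonzero lateral outcomes
  at full varus: those printed nonzero lateral values correspond to the
  coupled (angle) mode, and the specimen-scale area calibration therefore
  uses it.

## Shape model

Rigid-only generalized Procrustes alignment (convergence 1e-10 RMS, ≤100
iterations) of the shape block; the appearance block is untouched.  PCA by
singular value decomposition; `σ_i` are square roots of the sample
eigenvalues; component signs are fixed by making the largest-magnitude
loading positive.  Defaults resolving points the study leaves open:

* `w_a` is chosen so shape and appearance contribute equal total variance
  on the training set (`w_s` = 1); any weighting can be supplied.
* All components with nonzero eigenvalue are retained (at most n−1).
* Fitted coefficients are clipped to ±3 SD by default, mirroring the
  sampling constraint; diagnostics can disable clipping (the unclipped fit
  leaves a residual orthogonal to the basis).
* The constrained sampler (20 uniform draws per component within ±3 SD) is
  provided as in the study design; the pipeline does not use the samples
  downstream, since no downstream use is specified.

Leave-one-out validation reports RMS/maximum surface error per body between
the reconstruction and the Procrustes-aligned target; on the default seeded
cohort the mean RMS error is of order 1e-4 mm, i.e. the cohort's variation
manifold is essentially inside the model span — expected, because the
generator varies a handful of smooth parameters and the training set
includes the contralateral limb.

## Statistics and tables

Shapiro–Wilk, one-way ANOVA and Tukey HSD are the classical procedures
(`stats::shapiro.test`, `stats::aov`, `stats::TukeyHSD`); the test suite
re-derives the ANOVA from explicit sums of squares and Tukey p-values from
the studentized-range distribution as independent oracles.  Because the
factor structure of the published comparison is not fully specified, both
one-way layouts are reported: across varus levels within each model type,
and across model types within each level.  Cells with zero total variance
(the exactly unloaded lateral compartment at 100 % in fraction mode) have
no defined F statistic; they are skipped and listed rather than imputed.
Group means in presentation tables are rounded to two decimals; deltas are
computed on the rounded means; aggregate maxima are exposed both over the
two FEA arms and over all three arms, because the two conventions genuinely
differ for some outcomes in the published numbers and the package reports
both rather than resolving the discrepancy.

The emulated experiment applies the pressure-film measurement model
(mean-one lognormal response noise, detection floor 0.05 MPa, saturation
2.5 MPa, 0.01 MPa quantization, three-trial averaging) to the
specimen-specific pressure fields of the same load cases.  The floor
truncates low-pressure fringes, so film areas run ~10 % below solver areas
— a realistic instrument effect worth remembering when comparing arms.

## Problem sizes and determinism

The default study uses 10 limbs (~4,400 vertices per limb across three
bodies), ~900 candidate contact elements per compartment, and completes in
well under a minute on one CPU; the leave-one-out stage builds ten models
of nine limbs each.  A single master seed drives per-animal and per-limb
substreams, the film trials and the samplers; re-running a configuration is
bit-identical for all deterministic stages.

## Limitations

The surrogate preserves the *comparative* structure of the study —
monotone medial load shift, model-type equivalence, compartment asymmetry —
but not every absolute magnitude: with near-conforming geometry the
foundation model's peak pressures (≈0.5–0.7 MPa) sit below published
specimen values, because a bed-of-springs pressure distribution cannot
match both a prescribed force and independent peak/area values
(F = peak·area/2 for a paraboloid gap).  Contact areas are the calibrated
quantity.  Menisci and patellofemoral contact are excluded by design (the
reference condition is meniscus-deficient); bone is rigid in the contact
stage; ligaments are linear tension-only springs without a toe region;
loading is static.  Passing tests on the synthetic cohort demonstrates the
correctness of the algorithms and the internal consistency of the study
logic, not the anatomical fidelity of any individual rat knee.
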